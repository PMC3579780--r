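test_that("bundled PWM set parses with sane normalization", {
  pwms <- toy_pwms()
  expect_equal(length(pwms), 6L)
  for (p in pwms) {
    expect_gte(p$width, 4L)
    expect_true(all(p$freq > 0))
    expect_equal(colSums(p$freq), rep(1, p$width), tolerance = 1e-9)
    expect_equal(nchar(pwm_consensus(p)), p$width)
  }
  expect_error(read_jaspar(tempfile()), "not found")
})

test_that("scanning the consensus gives a maximal hit; near-misses drop", {
  p <- toy_pwms()$TBOX
  cons <- pwm_consensus(p)
  hits <- pwm_scan(cons, p, min_relative_score = 0.99, both_strands = FALSE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$relative_score, 1.0)

  mism <- cons
  substr(mism, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(cons, 3, 3))[1]
  expect_equal(nrow(pwm_scan(mism, p, min_relative_score = 1.0)), 0L)

  expect_warning(short <- pwm_scan("ACGT", p), "wider than sequence")
  expect_equal(nrow(short), 0L)
})

test_that("hit sets equal naive per-offset rescoring on random sequences", {
  pwms <- toy_pwms()
  set.seed(42)
  for (rep in 1:20) {
    p <- pwms[[sample(length(pwms), 1)]]
    s <- random_dna(200)
    if (rep %% 4 == 0) { # sprinkle Ns
      pos <- sample(200, 5)
      for (q in pos) substr(s, q, q) <- "N"
    }
    thr <- runif(1, 0.6, 0.8)
    got <- pwm_scan(s, p, min_relative_score = thr)
    want <- naive_pwm_hits(s, p, thr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$log_odds, want$log_odds, tolerance = 1e-10)
    }
  }
})

test_that("minus-strand hits are reported in forward coordinates", {
  p <- toy_pwms()$GCBOX
  set.seed(43)
  bg <- random_dna(100, gc = 0.2)
  planted <- paste0(substr(bg, 1, 40), reverse_complement(pwm_consensus(p)),
                    substr(bg, 41, 100))
  hits <- pwm_scan(planted, p, min_relative_score = 0.95)
  minus <- hits[hits$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(c(minus$start, minus$end), c(41L, 50L))
})

test_that("identical sequences conserve every hit with perfect flanks", {
  set.seed(44)
  p <- toy_pwms()$CCAAT
  s <- paste0(random_dna(60), pwm_consensus(p), random_dna(60),
              pwm_consensus(p), random_dna(60))
  aln <- global_align(s, s)
  hits <- pwm_scan(s, p, min_relative_score = 0.9)
  cons <- conserved_sites(aln, hits, hits)
  expect_equal(nrow(cons), nrow(hits))
  expect_true(all(cons$flank_identity == 1.0))
})

test_that("flank conservation filters asymmetric and degraded-context sites", {
  p <- toy_pwms()$TBOX
  motif <- pwm_consensus(p)
  set.seed(45)
  flank <- random_dna(50)
  flank2 <- random_dna(50)
  # site present in both species with conserved context
  a <- paste0(flank, motif, flank2)
  # species b: same context, motif present
  both <- global_align(a, a)
  hits_a <- pwm_scan(a, p, min_relative_score = 0.95)
  expect_equal(nrow(conserved_sites(both, hits_a, hits_a)), nrow(hits_a))

  # species b lacks the motif: not conserved
  b_no <- paste0(flank, random_dna(nchar(motif)), flank2)
  aln2 <- global_align(a, b_no)
  hits_b <- pwm_scan(b_no, p, min_relative_score = 0.95)
  expect_equal(nrow(conserved_sites(aln2, hits_a, hits_b)), 0L)

  # motif in both but flanks scrambled: flank identity fails
  b_scramble <- paste0(random_dna(50), motif, random_dna(50))
  aln3 <- global_align(a, b_scramble)
  hits_bs <- pwm_scan(b_scramble, p, min_relative_score = 0.95)
  strict <- conserved_sites(aln3, hits_a, hits_bs, min_flank_identity = 0.9)
  expect_equal(nrow(strict), 0L)
})

test_that("tightening the flank threshold never grows the conserved set", {
  set.seed(46)
  pwms <- toy_pwms()
  cl <- simulate_pair(background_divergence = 0.2, ancestor_len = 1500,
                      element_len = 300, seed = 46)
  cl <- plant_motifs(cl, pwms$EBOXL, n_inside = 3, n_outside = 3, seed = 46)
  aln <- global_align(cl$records[[1]], cl$records[[2]])
  ha <- pwm_scan(cl$records[[1]], pwms$EBOXL)
  hb <- pwm_scan(cl$records[[2]], pwms$EBOXL)
  ns <- vapply(c(0.5, 0.7, 0.9, 1.0), function(thr) {
    nrow(conserved_sites(aln, ha, hb, min_flank_identity = thr))
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
  # conserved sites are a subset of the reference hits
  cs <- conserved_sites(aln, ha, hb)
  expect_true(all(cs$a_start %in% ha$start))
})

test_that("occupancy affinity is monotone, strand-symmetric and N-calibrated", {
  p <- toy_pwms()$TGACG
  set.seed(47)
  bg <- random_dna(80)
  perfect <- paste0(bg, pwm_consensus(p), random_dna(80))
  worst <- vapply(seq_len(p$width), function(k) {
    rownames(p$freq)[which.min(p$freq[, k])]
  }, character(1))
  degraded <- paste0(bg, paste(worst, collapse = ""), random_dna(80))
  expect_gt(occupancy_affinity(perfect, p), occupancy_affinity(degraded, p))

  s <- random_dna(120)
  expect_equal(occupancy_affinity(s, p),
               occupancy_affinity(reverse_complement(s), p),
               tolerance = 1e-12)

  # all-N sequence: every offset carries the background-expected energy
  W <- p$width
  nn <- strrep("N", 40)
  e_n <- sum(vapply(seq_len(W), function(k) {
    sum(p$background * log(max(p$freq[, k]) / p$freq[, k]))
  }, numeric(1)))
  R0 <- exp(0.584 * W - 5.66)
  x <- R0 * exp(-e_n / 0.7)
  expected <- 2 * (40 - W + 1) * x / (1 + x)
  expect_equal(occupancy_affinity(nn, p), expected, tolerance = 1e-10)
})

test_that("BH correction reproduces step-up arithmetic and bounds Bonferroni", {
  res <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_equal(res$adjusted, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(sum(res$reject), 3L)

  expect_equal(sum(benjamini_hochberg(rep(1, 10))$reject), 0L)
  expect_equal(benjamini_hochberg(0.03)$adjusted, 0.03)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(48)
  for (rep in 1:100) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    bh <- benjamini_hochberg(p, alpha = 0.05)
    bonf <- p.adjust(p, method = "bonferroni") <= 0.05
    expect_true(all(bh$reject[bonf]))
    expect_true(all(diff(sort(bh$adjusted)) >= 0))
  }
})

test_that("site partition counts full containment only", {
  blocks <- list(structure(list(interval = genomic_interval("q", 100, 200),
                                mean_identity = 0.9, label = "ECR"),
                           class = "conserved_block"))
  sites <- data.frame(start = c(110, 195, 300), end = c(119, 204, 309))
  part <- site_block_partition(sites, blocks)
  expect_equal(part$inside, 1L)  # 195..204 straddles the block edge
  expect_equal(part$outside, 2L)
  expect_equal(part$fraction_inside, 1 / 3)

  expect_equal(site_block_partition(sites, list())$fraction_inside, 0)
  empty <- site_block_partition(sites[0, ], blocks)
  expect_true(is.na(empty$fraction_inside))
})
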