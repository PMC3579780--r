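test_that("ancestor simulation is deterministic with calibrated GC", {
  a1 <- simulate_ancestor(1000, 0.45, seed = 5)
  a2 <- simulate_ancestor(1000, 0.45, seed = 5)
  expect_identical(a1$sequence, a2$sequence)
  expect_false(identical(a1$sequence, simulate_ancestor(1000, 0.45, seed = 6)$sequence))

  big <- simulate_ancestor(10000, 0.45, seed = 7)
  gc <- gc_content(big$sequence)
  # 99% binomial interval around 0.45 at n = 10000
  half <- qnorm(0.995) * sqrt(0.45 * 0.55 / 10000)
  expect_lt(abs(gc - 0.45), half)

  expect_error(simulate_ancestor(1000, 0), "between 0 and 1")
  expect_error(simulate_ancestor(50), ">= 100")
})

test_that("zero-rate branches are the identity with an identity map", {
  anc <- simulate_ancestor(500, 0.45, seed = 8)
  ev <- evolve_branch(anc, evolution_params(sub_prob = 0, indel_prob = 0))
  expect_equal(ev$record$sequence, anc$sequence)
  expect_equal(ev$map, 1:500)
  expect_equal(ev$n_sub + ev$n_ins + ev$n_del, 0L)
})

test_that("substitution counts fall in the binomial envelope", {
  anc <- simulate_ancestor(10000, 0.45, seed = 9)
  ev <- evolve_branch(anc, evolution_params(sub_prob = 0.1, indel_prob = 0,
                                            seed = 9))
  half <- qnorm(0.995) * sqrt(10000 * 0.1 * 0.9)
  expect_lt(abs(ev$n_sub - 1000), half)
  # realized sequence differs at exactly the substituted count of sites
  diffs <- sum(strsplit(anc$sequence, "")[[1]] != strsplit(ev$record$sequence, "")[[1]])
  expect_equal(diffs, ev$n_sub)
})

test_that("constraint suppresses divergence inside the mask", {
  anc <- simulate_ancestor(4000, 0.45, seed = 10)
  mask <- genomic_interval(anc$id, 1501, 2500)
  worse <- 0L
  for (rep in 1:20) {
    ev <- evolve_branch(anc, evolution_params(sub_prob = 0.3, indel_prob = 0,
                                              constraint_factor = 0.1,
                                              seed = 1000 + rep),
                        constraint_mask = list(mask))
    a <- strsplit(anc$sequence, "")[[1]]
    b <- strsplit(ev$record$sequence, "")[[1]]
    inside <- mean(a[1501:2500] != b[1501:2500])
    outside <- mean(a[-(1501:2500)] != b[-(1501:2500)])
    if (inside < outside) worse <- worse + 1L
  }
  expect_gte(worse, 20L)
})

test_that("coordinate maps are strictly monotone and contain the element", {
  for (rep in 1:10) {
    cl <- simulate_pair(ancestor_len = 1500, element_len = 300,
                        indel_prob = 0.02, seed = 600 + rep)
    for (id in names(cl$maps)) {
      m <- cl$maps[[id]][!is.na(cl$maps[[id]])]
      expect_true(all(diff(m) > 0))
      iv <- cl$element_intervals[[id]]
      expect_false(is.null(iv))
      expect_gte(iv$start, 1L)
      expect_lte(iv$end, nchar(cl$records[[id]]$sequence))
    }
  }
})

test_that("star clades with zero rates reproduce the ancestor", {
  cl <- simulate_clade(2, "star", ancestor_len = 400,
                       params = evolution_params(sub_prob = 0, indel_prob = 0))
  expect_equal(cl$records$sp01$sequence, cl$records$sp02$sequence)
  expect_equal(cl$records$sp01$sequence, cl$ancestor$sequence)
})

test_that("balanced trees make deeper pairs more diverged on average", {
  # sp01/sp02 share an internal edge that sp03/sp04 do not, and vice versa
  pair_div <- function(cl, i, j) {
    aln <- global_align(cl$records[[i]], cl$records[[j]])
    1 - percent_identity(aln)
  }
  close_minus_far <- vapply(1:8, function(rep) {
    cl <- simulate_clade(4, "balanced", ancestor_len = 600,
                         params = evolution_params(sub_prob = 0.06,
                                                   indel_prob = 0.002,
                                                   seed = 700 + rep))
    within <- (pair_div(cl, "sp01", "sp02") + pair_div(cl, "sp03", "sp04")) / 2
    across <- (pair_div(cl, "sp01", "sp03") + pair_div(cl, "sp02", "sp04")) / 2
    across - within
  }, numeric(1))
  expect_gt(mean(close_minus_far > 0), 0.7)
})

test_that("clade outputs are byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  cl1 <- simulate_clade(3, "star", ancestor_len = 500,
                        params = evolution_params(seed = 99))
  cl2 <- simulate_clade(3, "star", ancestor_len = 500,
                        params = evolution_params(seed = 99))
  p1 <- write_clade(cl1, d1)
  p2 <- write_clade(cl2, d2)
  for (k in seq_along(p1)) {
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  }
})

test_that("motif planting is homologous, truth-tracked and bounded", {
  pwms <- toy_pwms()
  p <- pwms$ATHOOK
  # identical clade: planted sites are perfectly conserved
  cl <- simulate_clade(2, "star", ancestor_len = 1200,
                       params = evolution_params(sub_prob = 0, indel_prob = 0,
                                                 seed = 55))
  cl <- plant_motifs(cl, p, n_inside = 3, n_outside = 0, seed = 55)
  aln <- global_align(cl$records$sp01, cl$records$sp02)
  ha <- pwm_scan(cl$records$sp01, p, min_relative_score = 0.99)
  hb <- pwm_scan(cl$records$sp02, p, min_relative_score = 0.99)
  cs <- conserved_sites(aln, ha, hb)
  expect_equal(sum(cs$a_start %in% cl$motif_intervals$sp01$start), 3L)
  # truth table marks them inside
  expect_true(all(cl$motif_intervals$sp01$inside))

  # outside-only planting partitions to zero
  cl2 <- simulate_clade(2, "star", ancestor_len = 1200,
                        params = evolution_params(sub_prob = 0, indel_prob = 0,
                                                  seed = 56))
  cl2 <- plant_motifs(cl2, p, n_inside = 0, n_outside = 4, seed = 56)
  blocks <- list(structure(list(interval = cl2$element_intervals$sp01,
                                mean_identity = 1, label = "element"),
                           class = "conserved_block"))
  truth_sites <- cl2$motif_intervals$sp01
  part <- site_block_partition(truth_sites, blocks)
  expect_equal(part$fraction_inside, 0)

  # no room for too many motifs
  tiny <- simulate_clade(2, "star", ancestor_len = 600,
                         element = genomic_interval("ancestor", 100, 140),
                         params = evolution_params(seed = 57))
  expect_error(plant_motifs(tiny, p, n_inside = 10), "too short")
})
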