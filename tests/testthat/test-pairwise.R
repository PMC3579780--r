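test_that("global alignment handles the identity case and empty input", {
  a <- global_align("ACGTACGT", "ACGTACGT")
  expect_equal(a$score, 16)
  expect_equal(percent_identity(a), 1.0)
  expect_equal(a$row_a, a$row_b)
  expect_error(global_align("AAAA", ""), "non-empty")
})

test_that("global score matches exhaustive enumeration on tiny strings", {
  s <- scoring_scheme()
  set.seed(11)
  for (i in 1:30) {
    a <- random_dna(sample(2:5, 1))
    b <- random_dna(sample(2:5, 1))
    expect_equal(global_align(a, b, s)$score, enumerate_global_scores(a, b, s),
                 info = paste(a, b))
  }
})

test_that("global score matches the recursion oracle and Biostrings", {
  s <- scoring_scheme()
  m <- Biostrings::nucleotideSubstitutionMatrix(match = s$match,
                                                mismatch = s$mismatch,
                                                baseOnly = TRUE)
  set.seed(12)
  for (i in 1:60) {
    a <- random_dna(sample(3:8, 1))
    b <- random_dna(sample(3:8, 1))
    got <- global_align(a, b, s)$score
    expect_equal(got, oracle_global_score(a, b, s), info = paste(a, b))
    ref <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = m,
                                         gapOpening = -s$gap_open,
                                         gapExtension = -s$gap_extend,
                                         type = "global", scoreOnly = TRUE)
    expect_equal(got, ref, info = paste(a, b))
  }
})

test_that("alignment rows ungap to the input spans", {
  set.seed(13)
  for (i in 1:10) {
    a <- random_dna(60); b <- random_dna(55)
    aln <- global_align(a, b)
    expect_equal(gsub("-", "", aln$row_a), a)
    expect_equal(gsub("-", "", aln$row_b), b)
    expect_equal(nchar(aln$row_a), nchar(aln$row_b))
    # no column gap in both rows
    ca <- strsplit(aln$row_a, "")[[1]]; cb <- strsplit(aln$row_b, "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
  }
})

test_that("local alignment recovers planted sequence on either strand", {
  set.seed(14)
  bg <- random_dna(1000)
  m <- substr(bg, 401, 430)
  hit <- local_align(m, bg, both_strands = TRUE, min_score = 30)
  expect_equal(c(hit$b_span$start, hit$b_span$end), c(401L, 430L))
  expect_equal(hit$strand_b, "+")
  expect_equal(percent_identity(hit), 1.0)

  rc_hit <- local_align(reverse_complement(m), bg, both_strands = TRUE,
                        min_score = 30)
  expect_equal(c(rc_hit$b_span$start, rc_hit$b_span$end), c(401L, 430L))
  expect_equal(rc_hit$strand_b, "-")

  expect_null(local_align("AAAAAAAAAA", "CCCCCCCCCC", min_score = 10))
})

test_that("local score dominates explicit candidate sub-alignments", {
  s <- scoring_scheme()
  set.seed(15)
  for (i in 1:25) {
    a <- random_dna(40); b <- random_dna(40)
    best <- local_align(a, b, s, min_score = -1)
    best_score <- if (is.null(best)) 0 else best$score
    expect_gte(best_score, 0)
    # candidate: global score of a random substring pair
    i1 <- sample(1:30, 1); j1 <- sample(1:30, 1)
    cand <- global_align(substr(a, i1, i1 + 9), substr(b, j1, j1 + 9), s)
    expect_gte(best_score, cand$score)
  }
})

test_that("percent identity counts gaps and N in the denominator only", {
  expect_equal(percent_identity(alignment_from_rows("AC-GT", "ACTGT")), 0.8)
  expect_equal(percent_identity(alignment_from_rows("NNNN", "NNNN")), 0.0)
  expect_equal(percent_identity(alignment_from_rows("ACGT", "ACGA")), 0.75)
})

test_that("chunked self-comparison tiles the target perfectly", {
  q <- seq_record("q", random_dna(5000))
  cs <- chunked_search(q, q)
  expect_equal(nrow(cs), 10L)
  expect_true(all(cs$percent_identity == 1.0))
  expect_true(all(cs$significant))
  expect_equal(cs$target_start, cs$query_start)
  expect_equal(cs$target_end, cs$query_end)
})

test_that("final chunk rule keeps >= half, merges smaller", {
  set.seed(16)
  # self-comparison so every hit spans its full chunk
  s1240 <- random_dna(1240)
  # 1240 = 2 x 500 + 240 (< 250): merged into chunk 2
  cs <- chunked_search(seq_record("q", s1240), seq_record("t", s1240))
  expect_equal(nrow(cs), 2L)
  expect_equal(cs$query_end[2], 1240L)
  s1260 <- random_dna(1260)
  # 1260 = 2 x 500 + 260 (>= 250): kept
  cs2 <- chunked_search(seq_record("q", s1260), seq_record("t", s1260))
  expect_equal(nrow(cs2), 3L)
  expect_equal(cs2$query_start, c(1L, 501L, 1001L))
  expect_warning(
    one <- chunked_search(seq_record("q", random_dna(100)),
                          seq_record("t", random_dna(800))),
    "single chunk")
  expect_equal(nrow(one), 1L)
})

test_that("unrelated random sequences yield no significant chunks", {
  set.seed(17)
  for (rep in 1:5) {
    q <- seq_record("q", random_dna(1000))
    t <- seq_record("t", random_dna(1000))
    cs <- chunked_search(q, t, min_identity = 0.6, min_score = 50)
    expect_false(any(cs$significant))
  }
})

test_that("chunk identities are strand-symmetric", {
  set.seed(18)
  for (rep in 1:5) {
    cl <- simulate_pair(background_divergence = 0.15, ancestor_len = 1000,
                        element_len = 200, seed = rep)
    a <- cl$records[[1]]$sequence; b <- cl$records[[2]]$sequence
    fwd <- local_align(a, b, both_strands = TRUE, min_score = 0)
    rev <- local_align(reverse_complement(a), reverse_complement(b),
                       both_strands = TRUE, min_score = 0)
    expect_equal(fwd$score, rev$score)
    expect_equal(percent_identity(fwd), percent_identity(rev),
                 tolerance = 0.02)
  }
})
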