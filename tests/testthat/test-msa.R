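test_that("identical sequences align without gaps and reduce to pairwise", {
  set.seed(31)
  s <- random_dna(120)
  msa <- progressive_msa(list(seq_record("a", s), seq_record("b", s),
                              seq_record("c", s)))
  expect_equal(length(msa$rows), 3L)
  expect_true(all(msa$rows == s))

  a <- random_dna(100); b <- random_dna(95)
  two <- progressive_msa(list(seq_record("a", a), seq_record("b", b)))
  pw <- global_align(a, b)
  expect_equal(two$rows, c(pw$row_a, pw$row_b))

  expect_error(progressive_msa(list(seq_record("a", a))), ">= 2")
})

test_that("substitution-only evolution yields a gapless alignment", {
  cl <- simulate_clade(8, "star", ancestor_len = 400,
                       params = evolution_params(sub_prob = 0.08,
                                                 indel_prob = 0, seed = 32))
  msa <- progressive_msa(cl$records)
  expect_false(any(grepl("-", msa$rows, fixed = TRUE)))
  expect_equal(unique(nchar(msa$rows)), 400L)
})

test_that("every MSA row ungaps to its input sequence", {
  set.seed(33)
  for (rep in 1:5) {
    cl <- simulate_clade(5, "star", ancestor_len = 300,
                         params = evolution_params(sub_prob = 0.15,
                                                   indel_prob = 0.01,
                                                   seed = 330 + rep))
    msa <- progressive_msa(cl$records)
    for (k in seq_along(msa$rows)) {
      expect_equal(gsub("-", "", msa$rows[k]),
                   cl$records[[msa$row_ids[k]]]$sequence)
    }
  }
})

test_that("shared span is the intersection of per-row coverage", {
  msa <- structure(list(row_ids = c("a", "b", "c"),
                        rows = c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC")),
                   class = "multiple_alignment")
  expect_equal(unname(shared_span(msa)), c(1L, 10L))

  lead <- structure(list(
    row_ids = c("a", "b"),
    rows = c(paste0(strrep("-", 50), strrep("A", 50)), strrep("A", 100))),
    class = "multiple_alignment")
  expect_equal(unname(shared_span(lead)), c(51L, 100L))

  disjoint <- structure(list(
    row_ids = c("a", "b"),
    rows = c(paste0(strrep("A", 100), strrep("-", 100)),
             paste0(strrep("-", 100), strrep("A", 100)))),
    class = "multiple_alignment")
  expect_error(shared_span(disjoint), "no shared span")
})

test_that("consensus case encoding follows the column rules", {
  msa3 <- structure(list(row_ids = c("a", "b", "c"),
                         rows = c("AAC", "AAC", "ACC")),
                    class = "multiple_alignment")
  cons3 <- build_consensus(msa3, c(1, 3))
  # col1 {A,A,A} unanimous, col2 {A,A,C} majority, col3 all C unanimous
  expect_equal(cons3$consensus, "AaC")

  msa4 <- structure(list(row_ids = letters[1:4],
                         rows = c("AA", "AA", "C-", "C-")),
                    class = "multiple_alignment")
  cons4 <- build_consensus(msa4, c(1, 2))
  # col1 {A,A,C,C} no strict majority, col2 two gaps of four rows
  expect_equal(cons4$consensus, "n.")
  expect_equal(cons4$consensus_length, 1L)
  expect_equal(cons4$alignment_length, 2L)
})

test_that("consensus characters verify against a recount on random MSAs", {
  set.seed(34)
  for (rep in 1:200) {
    msa <- random_msa(sample(3:8, 1), sample(10:40, 1))
    cons <- build_consensus(msa)
    chars <- strsplit(cons$consensus, "")[[1]]
    span <- cons$span_columns
    cols <- span[1]:span[2]
    mat <- do.call(rbind, lapply(msa$rows,
                                 function(r) strsplit(r, "")[[1]][cols]))
    for (k in seq_along(cols)) {
      col <- mat[, k]
      n_gap <- sum(col == "-")
      res <- col[col != "-"]
      counts <- table(factor(res, levels = c("A", "C", "G", "T")))
      ch <- chars[k]
      if (n_gap >= length(col) / 2) {
        expect_equal(ch, ".")
      } else if (max(counts) == length(res)) {
        expect_equal(ch, names(which.max(counts)))
      } else if (max(counts) > length(res) / 2) {
        expect_equal(ch, tolower(names(which.max(counts))))
      } else {
        expect_equal(ch, "n")
      }
    }
    expect_equal(cons$consensus_length + sum(chars == "."),
                 cons$alignment_length)
  }
})

test_that("identity to consensus handles gaps, N-columns and strict mode", {
  cons <- strrep("A", 100)
  row <- paste0(strrep("A", 92), strrep("C", 8))
  expect_equal(identity_to_consensus(row, cons), 0.92)
  expect_equal(identity_to_consensus(strrep("A", 100), cons), 1.0)
  expect_equal(identity_to_consensus(strrep("-", 100), cons), 0.0)
  # 'n'/'.' columns excluded by default, mismatches under strict
  expect_equal(identity_to_consensus("AAAA", "AAn."), 1.0)
  expect_equal(identity_to_consensus("AAAA", "AAn.",
                                     identity_mode = "strict"), 0.5)
  # lowercase consensus matches case-insensitively
  expect_equal(identity_to_consensus("AAAA", "aaaa"), 1.0)
  expect_error(identity_to_consensus("AA", "n."), "no comparable")
})

test_that("identity summaries use mean, midpoint median, and range", {
  s <- identity_summary(c(0.79, 0.97))
  expect_equal(s$mean, 0.88)
  expect_equal(s$median, 0.88)
  expect_equal(c(s$min, s$max), c(0.79, 0.97))
  one <- identity_summary(0.9)
  expect_equal(unlist(one), c(mean = 0.9, median = 0.9, min = 0.9, max = 0.9))
})

test_that("per-species identities track simulated branch divergence", {
  # star clade with graded branch lengths: identity order should follow
  scales <- seq(0.4, 2.2, length.out = 8)
  rhos <- vapply(1:5, function(rep) {
    cl <- simulate_clade(8, "star", ancestor_len = 400,
                         params = evolution_params(sub_prob = 0.08,
                                                   indel_prob = 0.002,
                                                   seed = 350 + rep),
                         branch_scales = scales)
    res <- run_minecr(cl$records)
    cor(scales, as.numeric(res$consensus$per_species_identity),
        method = "spearman")
  }, numeric(1))
  expect_true(mean(rhos <= -0.8) >= 0.8)
})
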