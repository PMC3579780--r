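# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: alignment scores come from plain recursions,
# window identities from direct column recounts, PWM hits from naive
# per-offset rescoring.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Optimal affine-gap global score by memoized recursion over
# (i, j, state-of-last-move). Independent of the package's matrix DP.
# Gap convention: a run of length L scores gap_open + L * gap_extend.
oracle_global_score <- function(a, b, s) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca); m <- length(cb)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, st) {
    # best score of aligning a[1..i] with b[1..j], last move st
    # st: 0 = start, 1 = diagonal, 2 = gap in b, 3 = gap in a
    if (i == 0 && j == 0) return(if (st == 0) 0 else -Inf)
    key <- paste(i, j, st)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- -Inf
    if (st == 1 && i >= 1 && j >= 1) {
      sub <- if (ca[i] == cb[j] && ca[i] != "N") s$match else s$mismatch
      val <- sub + max(rec(i - 1, j - 1, 0), rec(i - 1, j - 1, 1),
                       rec(i - 1, j - 1, 2), rec(i - 1, j - 1, 3))
    } else if (st == 2 && i >= 1) {
      open <- s$gap_open + s$gap_extend
      val <- max(rec(i - 1, j, 0) + open, rec(i - 1, j, 1) + open,
                 rec(i - 1, j, 2) + s$gap_extend, rec(i - 1, j, 3) + open)
    } else if (st == 3 && j >= 1) {
      open <- s$gap_open + s$gap_extend
      val <- max(rec(i, j - 1, 0) + open, rec(i, j - 1, 1) + open,
                 rec(i, j - 1, 2) + open, rec(i, j - 1, 3) + s$gap_extend)
    }
    memo[[key]] <- val
    val
  }
  max(rec(n, m, 1), rec(n, m, 2), rec(n, m, 3),
      if (n == 0 && m == 0) 0 else -Inf)
}

# Exhaustive enumeration of every gapped alignment of two tiny strings,
# scored by scanning gap runs. Exponential: lengths <= 5 only.
enumerate_global_scores <- function(a, b, s) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  score_alignment <- function(ra, rb) {
    total <- 0
    run <- "" # current gap state: "", "a", "b"
    for (k in seq_along(ra)) {
      if (ra[k] == "-") {
        total <- total + s$gap_extend + if (run != "a") s$gap_open else 0
        run <- "a"
      } else if (rb[k] == "-") {
        total <- total + s$gap_extend + if (run != "b") s$gap_open else 0
        run <- "b"
      } else {
        total <- total +
          if (ra[k] == rb[k] && ra[k] != "N") s$match else s$mismatch
        run <- ""
      }
    }
    total
  }
  best <- -Inf
  walk <- function(i, j, ra, rb) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score_alignment(ra, rb))
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      walk(i + 1, j + 1, c(ra, ca[i]), c(rb, cb[j]))
    }
    if (i <= length(ca)) walk(i + 1, j, c(ra, ca[i]), c(rb, "-"))
    if (j <= length(cb)) walk(i, j + 1, c(ra, "-"), c(rb, cb[j]))
  }
  walk(1, 1, character(0), character(0))
  best
}

# Build a pairwise_alignment-like object from two gapped rows.
alignment_from_rows <- function(row_a, row_b, seq_id = "ref") {
  ungap <- function(r) gsub("-", "", r)
  structure(list(
    row_a = row_a, row_b = row_b,
    a_span = genomic_interval(seq_id, 1L, nchar(ungap(row_a))),
    b_span = genomic_interval("other", 1L, nchar(ungap(row_b))),
    strand_b = "+", score = 0
  ), class = "pairwise_alignment")
}

# Random gapped alignment with controllable match fraction; no column is
# gap in both rows.
random_alignment <- function(ncol, p_match = 0.7, p_gap = 0.05) {
  ra <- character(ncol); rb <- character(ncol)
  for (k in seq_len(ncol)) {
    u <- runif(1)
    base <- sample(c("A", "C", "G", "T"), 1)
    if (u < p_gap) {
      ra[k] <- base; rb[k] <- "-"
    } else if (u < 2 * p_gap) {
      ra[k] <- "-"; rb[k] <- base
    } else if (u < 2 * p_gap + (1 - 2 * p_gap) * p_match) {
      ra[k] <- base; rb[k] <- base
    } else {
      ra[k] <- base
      rb[k] <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    }
  }
  # reference row must not start or end with a gap for window anchoring
  ra[1] <- ifelse(ra[1] == "-", "A", ra[1])
  ra[ncol] <- ifelse(ra[ncol] == "-", "A", ra[ncol])
  alignment_from_rows(paste(ra, collapse = ""), paste(rb, collapse = ""))
}

# Direct per-window identity recount from the gapped rows.
recount_windows <- function(aln, window, step = 1L) {
  ca <- strsplit(aln$row_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$row_b, "", fixed = TRUE)[[1]]
  ref_cols <- which(ca != "-")
  n_ref <- length(ref_cols)
  starts <- seq.int(1L, n_ref - window + 1L, by = step)
  vapply(starts, function(i) {
    cols <- ref_cols[i]:ref_cols[i + window - 1L]
    mean(ca[cols] == cb[cols] & ca[cols] %in% c("A", "C", "G", "T"))
  }, numeric(1))
}

# Random small MSA as a multiple_alignment (rows may contain gaps).
random_msa <- function(n_rows, ncol, p_gap = 0.15) {
  rows <- vapply(seq_len(n_rows), function(i) {
    chars <- sample(c("A", "C", "G", "T", "-"), ncol, replace = TRUE,
                    prob = c(rep((1 - p_gap) / 4, 4), p_gap))
    paste(chars, collapse = "")
  }, character(1))
  # forbid all-gap columns by forcing row 1 gapless
  rows[1] <- gsub("-", "A", rows[1])
  structure(list(row_ids = paste0("sp", seq_len(n_rows)), rows = rows),
            class = "multiple_alignment")
}

# Naive per-offset PWM rescoring (both strands), independent of pwm_scan.
naive_pwm_hits <- function(seq, p, min_rel) {
  lo <- p$log_odds
  W <- p$width
  smin <- sum(apply(lo, 2, min)); smax <- sum(apply(lo, 2, max))
  score_at <- function(chars, off) {
    tot <- 0
    for (k in seq_len(W)) {
      b <- chars[off + k - 1]
      tot <- tot + if (b == "N") 0 else lo[b, k]
    }
    tot
  }
  out <- list()
  for (strand in c("+", "-")) {
    sc <- if (strand == "+") seq else reverse_complement(seq)
    chars <- strsplit(sc, "", fixed = TRUE)[[1]]
    L <- length(chars)
    for (off in seq_len(L - W + 1L)) {
      sco <- score_at(chars, off)
      rel <- (sco - smin) / (smax - smin)
      if (rel >= min_rel) {
        start <- if (strand == "+") off else L - (off + W - 1L) + 1L
        out[[length(out) + 1L]] <- data.frame(
          pwm_name = p$name, start = start, end = start + W - 1L,
          strand = strand, log_odds = sco, relative_score = rel)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(pwm_name = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      log_odds = numeric(0), relative_score = numeric(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), , drop = FALSE]
}

toy_pwms <- function() {
  read_jaspar(system.file("extdata", "pwms", package = "ecrtools"))
}
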