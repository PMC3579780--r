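#' Position weight matrix
#'
#' Counts (or frequencies) per position with a background model and a
#' pseudocount; scoring uses the log2 odds of the pseudocount-regularized
#' frequencies against the background.
#'
#' @param name Motif name.
#' @param counts 4 x W non-negative matrix, rows A, C, G, T.
#' @param background Background frequencies (A, C, G, T), summing to 1.
#' @param pseudocount Positive pseudocount distributed by background.
#' @return An object of class `pwm` with precomputed frequency and log-odds
#'   matrices.
#' @export
pwm <- function(name, counts, background = rep(0.25, 4), pseudocount = 1) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 4L, all(counts >= 0),
            length(background) == 4L, abs(sum(background) - 1) < 1e-6,
            pseudocount > 0)
  rownames(counts) <- c("A", "C", "G", "T")
  freq <- sweep(counts + pseudocount * background, 2,
                colSums(counts) + pseudocount, "/")
  lo <- log2(sweep(freq, 1, background, "/"))
  structure(list(name = name, counts = counts, background = background,
                 pseudocount = pseudocount, freq = freq, log_odds = lo,
                 width = ncol(counts)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d, consensus %s\n", x$name, x$width,
              pwm_consensus(x)))
  invisible(x)
}

#' Consensus string of a PWM (highest-frequency base per position)
#' @param x A [pwm()].
#' @return Nucleotide string of length W.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$freq)[apply(x$freq, 2, which.max)], collapse = "")
}

#' Read JASPAR-style PWM count files
#'
#' Parses the JASPAR text layout: a `>identifier name` header followed by
#' four lines `A [ counts... ]` (brackets optional). A path may be a single
#' file with one or more records or a directory of `.jaspar`/`.pfm`/`.txt`
#' files.
#'
#' @param path File or directory.
#' @inheritParams pwm
#' @return List of [pwm()] objects, named by motif name.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 1) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(jaspar|pfm|txt)$", full.names = TRUE)
    if (length(files) == 0L) stop("no PWM files found in ", path)
    out <- unlist(lapply(sort(files), read_jaspar, background = background,
                         pseudocount = pseudocount), recursive = FALSE)
    return(out)
  }
  if (!file.exists(path)) stop("PWM file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no JASPAR records in ", path)
  out <- list()
  for (si in seq_along(starts)) {
    i <- starts[si]
    hdr <- sub("^>\\s*", "", lines[i])
    tokens <- strsplit(hdr, "\\s+")[[1]]
    name <- if (length(tokens) >= 2L) tokens[2] else tokens[1]
    rows <- lines[(i + 1):(i + 4)]
    parsed <- lapply(rows, function(r) {
      body <- sub("^[ACGTacgt]\\s*", "", r)
      body <- gsub("[][]", " ", body)
      as.numeric(strsplit(trimws(body), "\\s+")[[1]])
    })
    if (length(unique(lengths(parsed))) != 1L) {
      stop("ragged count rows in JASPAR record '", name, "'")
    }
    out[[name]] <- pwm(name, do.call(rbind, parsed), background, pseudocount)
  }
  out
}

seq_to_codes <- function(seq) {
  # A=1 C=2 G=3 T=4, N=0
  chartr_map <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- chartr_map[chars]
  if (anyNA(codes)) stop("invalid character in sequence")
  unname(codes)
}

score_offsets <- function(codes, lo) {
  W <- ncol(lo)
  L <- length(codes)
  n_off <- L - W + 1L
  if (n_off < 1L) return(numeric(0))
  # pad a zero row so N (code 0 -> index 1) contributes 0
  lo5 <- rbind(0, lo)
  scores <- numeric(n_off)
  for (j in seq_len(W)) {
    scores <- scores + lo5[codes[j:(j + n_off - 1L)] + 1L, j]
  }
  scores
}

#' Scan a sequence with a PWM
#'
#' Log-odds scoring at every offset; the relative score normalizes between
#' the minimum and maximum attainable log-odds sums, and positions containing
#' N contribute the background expectation (0). With `both_strands`, the
#' reverse complement is scanned too and minus-strand hits are reported in
#' forward coordinates.
#'
#' @param seq Nucleotide string or [seq_record()].
#' @param pwm A [pwm()].
#' @param min_relative_score Report hits with relative score at or above this
#'   (default 0.85).
#' @param both_strands Scan both strands (default TRUE).
#' @return Data frame sorted by position: `pwm_name`, `start`, `end`,
#'   `strand`, `log_odds`, `relative_score`. Empty (with a warning) when the
#'   PWM is wider than the sequence.
#' @export
pwm_scan <- function(seq, pwm, min_relative_score = 0.85, both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm"))
  s <- as_sequence(seq)
  W <- pwm$width
  empty <- data.frame(pwm_name = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      log_odds = numeric(0), relative_score = numeric(0))
  if (nchar(s) < W) {
    warning("PWM '", pwm$name, "' wider than sequence; no hits")
    return(empty)
  }
  lo <- pwm$log_odds
  smin <- sum(apply(lo, 2, min)); smax <- sum(apply(lo, 2, max))
  codes <- seq_to_codes(s)
  L <- length(codes)
  collect <- function(scores, strand) {
    rel <- (scores - smin) / (smax - smin)
    keep <- which(rel >= min_relative_score)
    if (length(keep) == 0L) return(empty)
    if (strand == "+") {
      start <- keep
    } else {
      start <- L - (keep + W - 1L) + 1L
    }
    data.frame(pwm_name = pwm$name, start = start, end = start + W - 1L,
               strand = strand, log_odds = scores[keep],
               relative_score = rel[keep])
  }
  hits <- collect(score_offsets(codes, lo), "+")
  if (both_strands) {
    rc <- seq_to_codes(reverse_complement(s))
    hits <- rbind(hits, collect(score_offsets(rc, lo), "-"))
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

#' Cross-species conserved TFBS calling
#'
#' A reference hit is conserved when (i) its aligned image in the second
#' species overlaps a hit of the same PWM in the same orientation relative to
#' the alignment, and (ii) the identity of the `flank`-column alignment
#' window centered on the site midpoint is at least `min_flank_identity` —
#' the flank-conservation filter that keeps only sites in locally conserved
#' context.
#'
#' @param aln A `pairwise_alignment` of the two species' sequences.
#' @param hits_a,hits_b [pwm_scan()] results for the reference (row a) and
#'   second (row b) sequence.
#' @param flank Flank window in alignment columns (default 20).
#' @param min_flank_identity Identity threshold for the flank window
#'   (default 0.8).
#' @param blocks Optional list of `conserved_block`s (reference frame) used
#'   to annotate each conserved site with its containing block label.
#' @return Data frame: `pwm_name`, `a_start`, `a_end`, `a_strand`, `b_start`,
#'   `b_end`, `b_strand`, `flank_identity`, `in_block`.
#' @export
conserved_sites <- function(aln, hits_a, hits_b, flank = 20L,
                            min_flank_identity = 0.8, blocks = list()) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  empty <- data.frame(pwm_name = character(0), a_start = integer(0),
                      a_end = integer(0), a_strand = character(0),
                      b_start = integer(0), b_end = integer(0),
                      b_strand = character(0), flank_identity = numeric(0),
                      in_block = character(0))
  if (nrow(hits_a) == 0L || nrow(hits_b) == 0L) return(empty)
  apos <- col_to_seqpos(aln$row_a, aln$a_span$start)
  bpos <- col_to_seqpos(aln$row_b, aln$b_span$start)
  col_of_a <- rep(NA_integer_, max(apos, na.rm = TRUE))
  col_of_a[apos[!is.na(apos)]] <- which(!is.na(apos))
  ca <- strsplit(aln$row_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$row_b, "", fixed = TRUE)[[1]]
  match_col <- ca == cb & ca %in% c("A", "C", "G", "T")
  ncols <- length(ca)

  rows <- list()
  for (i in seq_len(nrow(hits_a))) {
    h <- hits_a[i, ]
    if (h$start < aln$a_span$start || h$end > aln$a_span$end) {
      warning("hit ", h$pwm_name, "@", h$start, " outside alignment; skipped")
      next
    }
    cols <- col_of_a[h$start:h$end]
    cols <- cols[!is.na(cols)]
    img <- bpos[min(cols):max(cols)]
    img <- img[!is.na(img)]
    if (length(img) == 0L) next
    # same orientation relative to the alignment
    want_strand <- if (aln$strand_b == "+") h$strand else setdiff(c("+", "-"), h$strand)
    partners <- hits_b[hits_b$pwm_name == h$pwm_name &
                         hits_b$strand == want_strand &
                         hits_b$start <= max(img) & hits_b$end >= min(img), ,
                       drop = FALSE]
    if (nrow(partners) == 0L) next
    mid_col <- col_of_a[(h$start + h$end) %/% 2L]
    w1 <- max(1L, mid_col - (flank %/% 2L) + 1L)
    w2 <- min(ncols, w1 + flank - 1L)
    fid <- mean(match_col[w1:w2])
    if (fid < min_flank_identity) next
    p <- partners[1, ]
    in_block <- NA_character_
    for (b in blocks) {
      if (h$start >= b$interval$start && h$end <= b$interval$end) {
        in_block <- b$label
        break
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pwm_name = h$pwm_name, a_start = h$start, a_end = h$end,
      a_strand = h$strand, b_start = p$start, b_end = p$end,
      b_strand = p$strand, flank_identity = fid, in_block = in_block
    )
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Occupancy-style binding affinity of a sequence for a PWM
#'
#' Biophysical occupancy model: each offset (both strands) contributes
#' `p = R0 * exp(-E / lambda) / (1 + R0 * exp(-E / lambda))`, where the
#' mismatch energy `E` is the summed log-ratio of the PWM's best base
#' frequency to the observed base frequency at each position. `lambda = 0.7`
#' and `R0 = exp(0.584 * W - 5.66)` are the model's published defaults. An N
#' contributes its background-expected energy. The total affinity is the sum
#' over all offsets; improving any site never decreases it.
#'
#' @param seq Nucleotide string or [seq_record()].
#' @param pwm A [pwm()].
#' @param lambda Energy scale.
#' @param R0 Offset-level binding constant; default `exp(0.584 * W - 5.66)`.
#' @return Non-negative expected site occupancy summed over offsets.
#' @export
occupancy_affinity <- function(seq, pwm, lambda = 0.7,
                               R0 = exp(0.584 * pwm$width - 5.66)) {
  stopifnot(inherits(pwm, "pwm"))
  s <- as_sequence(seq)
  W <- pwm$width
  if (nchar(s) < W) {
    warning("PWM '", pwm$name, "' wider than sequence; affinity 0")
    return(0)
  }
  f <- pwm$freq
  fbest <- apply(f, 2, max)
  energy <- log(sweep(1 / f, 2, fbest, "*")) # E[base, pos] = ln(fbest/f)
  # N: background-expected energy per position
  e_n <- colSums(energy * pwm$background)
  e5 <- rbind(e_n, energy)
  sum_occ <- function(codes) {
    n_off <- length(codes) - W + 1L
    E <- numeric(n_off)
    for (j in seq_len(W)) {
      E <- E + e5[codes[j:(j + n_off - 1L)] + 1L, j]
    }
    x <- R0 * exp(-E / lambda)
    sum(x / (1 + x))
  }
  sum_occ(seq_to_codes(s)) + sum_occ(seq_to_codes(reverse_complement(s)))
}

#' Benjamini-Hochberg step-up correction
#'
#' Standard FDR step-up procedure (via [stats::p.adjust()]); rejections are
#' the hypotheses whose adjusted p-value is at most `alpha`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return List with `adjusted` (monotone in rank) and logical `reject`.
#' @export
benjamini_hochberg <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1 | is.na(pvalues))) {
    stop("p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Partition conserved sites by conserved blocks
#'
#' A site counts as inside when its full reference interval lies within a
#' single block.
#'
#' @param sites [conserved_sites()] data frame (reference coordinates in
#'   `a_start`/`a_end`), or any data frame with `start`/`end` columns.
#' @param blocks List of `conserved_block` objects in the same frame.
#' @return List with `inside`, `outside` and `fraction_inside`
#'   (`NA` when there are no sites).
#' @export
site_block_partition <- function(sites, blocks) {
  if (nrow(sites) == 0L) {
    return(list(inside = 0L, outside = 0L, fraction_inside = NA_real_))
  }
  starts <- if ("a_start" %in% names(sites)) sites$a_start else sites$start
  ends <- if ("a_end" %in% names(sites)) sites$a_end else sites$end
  inside <- vapply(seq_along(starts), function(i) {
    any(vapply(blocks, function(b) {
      starts[i] >= b$interval$start && ends[i] <= b$interval$end
    }, logical(1)))
  }, logical(1))
  list(inside = sum(inside), outside = sum(!inside),
       fraction_inside = mean(inside))
}
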