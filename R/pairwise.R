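#' Affine-gap scoring scheme
#'
#' Match/mismatch scores with affine gap costs. A gap run of length L scores
#' `gap_open + L * gap_extend`. Defaults mirror classic BLASTN-style scoring
#' (+2/-3 with gap existence -5 and per-base extension -2).
#'
#' @param match Match score (> mismatch).
#' @param mismatch Mismatch score.
#' @param gap_open Gap-opening score, `<= gap_extend <= 0`.
#' @param gap_extend Per-column gap-extension score.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = -5,
                           gap_extend = -2) {
  stopifnot(match > mismatch, gap_open <= gap_extend, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

new_pairwise_alignment <- function(row_a, row_b, a_span, b_span, strand_b,
                                   score) {
  stopifnot(nchar(row_a) == nchar(row_b))
  structure(list(row_a = row_a, row_b = row_b, a_span = a_span,
                 b_span = b_span, strand_b = strand_b, score = score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "<pairwise_alignment> %d columns, score %.1f, identity %.3f, strand_b %s\n",
    nchar(x$row_a), x$score, percent_identity(x), x$strand_b))
  invisible(x)
}

# For each alignment column, the 1-based position in the ungapped row
# (offset into the full input via the span start), or NA at gap columns.
col_to_seqpos <- function(row, span_start = 1L) {
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  nongap <- chars != "-"
  pos <- rep(NA_integer_, length(chars))
  pos[nongap] <- span_start - 1L + seq_len(sum(nongap))
  pos
}

as_sequence <- function(x) {
  if (inherits(x, "seq_record")) x$sequence else normalize_sequence(x)
}

seq_label <- function(x, default) {
  if (inherits(x, "seq_record")) x$id else default
}

#' Optimal global alignment (affine gaps)
#'
#' Needleman-Wunsch-Gotoh alignment returning the maximum-attainable score
#' under the scheme. Traceback tie-breaking is fixed (diagonal, then gap in
#' the second sequence, then gap in the first) so results are deterministic.
#'
#' @param a,b Nucleotide strings or [seq_record()] objects.
#' @param s A [scoring_scheme()].
#' @return A `pairwise_alignment`: gapped rows `row_a`/`row_b`, spans on the
#'   input sequences, and the optimal `score`.
#' @export
global_align <- function(a, b, s = scoring_scheme()) {
  sa <- as_sequence(a); sb <- as_sequence(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("sequences must be non-empty")
  res <- .align_global_cpp(sa, sb, s$match, s$mismatch, s$gap_open, s$gap_extend)
  new_pairwise_alignment(
    res$row_a, res$row_b,
    a_span = genomic_interval(seq_label(a, "a"), 1L, nchar(sa)),
    b_span = genomic_interval(seq_label(b, "b"), 1L, nchar(sb)),
    strand_b = "+", score = res$score
  )
}

#' Best local alignment (affine gaps)
#'
#' Smith-Waterman alignment of `a` against `b`, optionally scanning the
#' reverse complement of `b` as well (the better-scoring strand is reported;
#' forward wins ties). Returns `NULL` when the best score is below
#' `min_score`.
#'
#' @param a,b Nucleotide strings or [seq_record()] objects.
#' @param s A [scoring_scheme()].
#' @param both_strands Also scan the reverse complement of `b`.
#' @param min_score Minimum score to report a hit.
#' @return A `pairwise_alignment` with local spans (coordinates on the input
#'   sequences; `b_span` is always in forward coordinates of `b`, with
#'   `strand_b` indicating the matched strand), or `NULL`.
#' @export
local_align <- function(a, b, s = scoring_scheme(), both_strands = FALSE,
                        min_score = 0) {
  sa <- as_sequence(a); sb <- as_sequence(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("sequences must be non-empty")
  fwd <- .align_local_cpp(sa, sb, s$match, s$mismatch, s$gap_open, s$gap_extend)
  best <- fwd; strand <- "+"
  if (both_strands) {
    rev <- .align_local_cpp(sa, reverse_complement(sb),
                            s$match, s$mismatch, s$gap_open, s$gap_extend)
    if (rev$score > fwd$score) { best <- rev; strand <- "-" }
  }
  if (best$score < min_score || best$score <= 0) return(NULL)
  nb <- nchar(sb)
  b_span <- if (strand == "+") {
    genomic_interval(seq_label(b, "b"), best$b_start, best$b_end)
  } else {
    # map reverse-complement coordinates back to forward coordinates of b
    genomic_interval(seq_label(b, "b"), nb - best$b_end + 1L, nb - best$b_start + 1L,
                     strand = "-")
  }
  new_pairwise_alignment(
    best$row_a, best$row_b,
    a_span = genomic_interval(seq_label(a, "a"), best$a_start, best$a_end),
    b_span = b_span, strand_b = strand, score = best$score
  )
}

#' Percent identity of an alignment
#'
#' Fraction of alignment columns whose two residues are equal unambiguous
#' nucleotides. Gap columns and columns containing N count in the denominator
#' only (N never matches).
#'
#' @param aln A `pairwise_alignment`.
#' @return Fraction in `[0, 1]`.
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  ca <- strsplit(aln$row_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$row_b, "", fixed = TRUE)[[1]]
  if (length(ca) == 0L) stop("empty alignment")
  mean(ca == cb & ca %in% c("A", "C", "G", "T"))
}

#' Chunked cross-species homology search
#'
#' Splits the query into sequential non-overlapping sections of `chunk_len`
#' nucleotides and locally aligns each section against the full target on
#' both strands, so that genomic insertions or deletions between species
#' shift, but do not break, the per-section matches. The final short section
#' is kept if at least `chunk_len / 2` long and merged into the previous one
#' otherwise. At most one best hit is reported per section; sections whose
#' best hit fails `min_identity` or `min_score` are retained as
#' non-significant rows so a full per-section identity table can be emitted.
#'
#' @param query,target [seq_record()] objects (or plain strings).
#' @param chunk_len Section length in nt (>= 50); default 500.
#' @param s A [scoring_scheme()].
#' @param min_identity Identity threshold for a significant hit.
#' @param min_score Score threshold for a significant hit.
#' @return A data frame with one row per section: `chunk_index` (0-based),
#'   `query_start`, `query_end`, `target_start`, `target_end`, `strand`,
#'   `percent_identity`, `alignment_length`, `score`, `significant`.
#'   Target coordinates are `NA` when no local alignment scored above zero.
#' @export
chunked_search <- function(query, target, chunk_len = 500L,
                           s = scoring_scheme(), min_identity = 0.6,
                           min_score = 50) {
  sq <- as_sequence(query); st <- as_sequence(target)
  if (chunk_len < 50L) stop("chunk_len must be >= 50")
  n <- nchar(sq)
  if (chunk_len > n) {
    warning("chunk_len exceeds query length; using a single chunk")
    starts <- 1L; ends <- n
  } else {
    starts <- seq.int(1L, n, by = chunk_len)
    ends <- pmin(starts + chunk_len - 1L, n)
    k <- length(starts)
    if (k > 1L && (ends[k] - starts[k] + 1L) < chunk_len / 2) {
      ends[k - 1L] <- ends[k]
      starts <- starts[-k]; ends <- ends[-k]
    }
  }
  rows <- lapply(seq_along(starts), function(i) {
    chunk <- substr(sq, starts[i], ends[i])
    hit <- local_align(chunk, st, s, both_strands = TRUE, min_score = 0)
    if (is.null(hit)) {
      return(data.frame(
        chunk_index = i - 1L, query_start = starts[i], query_end = ends[i],
        target_start = NA_integer_, target_end = NA_integer_,
        strand = NA_character_, percent_identity = 0,
        alignment_length = 0L, score = 0, significant = FALSE
      ))
    }
    pid <- percent_identity(hit)
    data.frame(
      chunk_index = i - 1L,
      query_start = starts[i] + hit$a_span$start - 1L,
      query_end = starts[i] + hit$a_span$end - 1L,
      target_start = hit$b_span$start, target_end = hit$b_span$end,
      strand = hit$strand_b, percent_identity = pid,
      alignment_length = nchar(hit$row_a), score = hit$score,
      significant = pid >= min_identity && hit$score >= min_score
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "query_id") <- seq_label(query, "query")
  attr(out, "target_id") <- seq_label(target, "target")
  out
}
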