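#' Sliding-window profiling parameters
#'
#' The two presets used throughout ECR detection are 100 nt / 0.75 for
#' ordinary conserved blocks and 350 nt / 0.77 for long, highly conserved
#' core regions.
#'
#' @param window Window length in reference nucleotides (>= 10).
#' @param min_identity Identity threshold in (0, 1].
#' @param step Window step in reference nucleotides (<= window); steps larger
#'   than 1 trade boundary resolution for speed.
#' @return An object of class `profile_params`.
#' @export
profile_params <- function(window = 100L, min_identity = 0.75, step = 1L) {
  window <- as.integer(window); step <- as.integer(step)
  stopifnot(window >= 10L, min_identity > 0, min_identity <= 1,
            step >= 1L, step <= window)
  structure(list(window = window, min_identity = min_identity, step = step),
            class = "profile_params")
}

#' Sliding-window identity profile of a pairwise alignment
#'
#' Windows are anchored in reference coordinates (non-gap positions of
#' `row_a`), not alignment columns, so window positions and any blocks called
#' from them are directly reportable on the reference sequence. A window of
#' `window` consecutive reference positions spans all alignment columns from
#' the first to the last of those positions; its identity is the fraction of
#' matching columns in that span, so insertions in either species count
#' against identity.
#'
#' @param aln A `pairwise_alignment` whose reference row covers at least one
#'   window.
#' @param params A [profile_params()].
#' @return An object of class `conservation_profile`: `ref_positions`
#'   (window-start reference coordinates), parallel `identities`, and the
#'   `params`; internal per-column match/position maps are retained so block
#'   identities can be recomputed exactly.
#' @export
windowed_identity <- function(aln, params = profile_params()) {
  stopifnot(inherits(aln, "pairwise_alignment"), inherits(params, "profile_params"))
  ca <- strsplit(aln$row_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$row_b, "", fixed = TRUE)[[1]]
  match_col <- ca == cb & ca %in% c("A", "C", "G", "T")
  ref_pos <- col_to_seqpos(aln$row_a, aln$a_span$start)
  # column index of each reference position, in reference order
  col_of_ref <- which(!is.na(ref_pos))
  n_ref <- length(col_of_ref)
  w <- params$window
  if (n_ref < w) stop("alignment reference row shorter than one window")
  starts_idx <- seq.int(1L, n_ref - w + 1L, by = params$step)
  cum <- c(0L, cumsum(match_col))
  c1 <- col_of_ref[starts_idx]
  c2 <- col_of_ref[starts_idx + w - 1L]
  ident <- (cum[c2 + 1L] - cum[c1]) / (c2 - c1 + 1L)
  structure(list(
    ref_positions = ref_pos[c1],
    identities = ident,
    params = params,
    seq_id = aln$a_span$seq_id,
    match_col = match_col,
    col_of_ref = col_of_ref,
    ref_offset = aln$a_span$start
  ), class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d windows (%d nt / %.2f), identity %.3f-%.3f\n",
              length(x$identities), x$params$window, x$params$min_identity,
              min(x$identities), max(x$identities)))
  invisible(x)
}

new_conserved_block <- function(interval, mean_identity, label) {
  structure(list(interval = interval, mean_identity = mean_identity,
                 label = label),
            class = "conserved_block")
}

#' @export
print.conserved_block <- function(x, ...) {
  cat(sprintf("<conserved_block> %s %s:%d..%d (%d nt), identity %.3f\n",
              x$label, x$interval$seq_id, x$interval$start, x$interval$end,
              interval_length(x$interval), x$mean_identity))
  invisible(x)
}

#' Call conserved blocks from an identity profile
#'
#' Every window at or above `min_identity` passes; a candidate block is the
#' union of reference extents of a maximal run of passing windows
#' (overlapping or touching extents merged). Because a window straddling a
#' conservation boundary can still pass, raw merged extents overshoot the
#' underlying conserved element by up to a window length per side; with
#' `refine_boundaries = TRUE` (the default) each candidate is therefore
#' trimmed to its maximal-scoring subsegment under per-position scores
#' `match - min_identity`, which places the boundaries where conservation
#' actually drops below the threshold. Each block's `mean_identity` is
#' recomputed directly over its final extent's alignment columns. Blocks are
#' returned in coordinate order; an empty list when nothing passes.
#'
#' @param profile A [windowed_identity()] result.
#' @param label Label stored on each block.
#' @param refine_boundaries Trim block edges to the maximal-scoring
#'   subsegment (default TRUE); FALSE reports raw merged window extents.
#' @return List of `conserved_block` objects.
#' @export
call_blocks <- function(profile, label = "ECR", refine_boundaries = TRUE) {
  stopifnot(inherits(profile, "conservation_profile"))
  w <- profile$params$window
  pass <- profile$identities >= profile$params$min_identity
  if (!any(pass)) return(list())
  starts <- profile$ref_positions[pass]
  ends <- starts + w - 1L
  # merge overlapping/adjacent extents (starts already sorted)
  m_start <- starts[1]; m_end <- ends[1]
  blocks <- list()
  # per-reference-position match indicator (insertion columns ignored here;
  # they re-enter through the final column-span identity)
  ref_match <- profile$match_col[profile$col_of_ref]
  thr <- profile$params$min_identity
  flush <- function(blocks, s, e) {
    if (refine_boundaries) {
      idx <- (s:e) - profile$ref_offset + 1L
      seg <- max_scoring_segment(ref_match[idx] - thr)
      s2 <- s + seg[1] - 1L; e2 <- s + seg[2] - 1L
    } else {
      s2 <- s; e2 <- e
    }
    # recompute identity over the extent's column span
    i1 <- profile$col_of_ref[s2 - profile$ref_offset + 1L]
    i2 <- profile$col_of_ref[e2 - profile$ref_offset + 1L]
    ident <- mean(profile$match_col[i1:i2])
    c(blocks, list(new_conserved_block(
      genomic_interval(profile$seq_id, s2, e2), ident, label)))
  }
  if (length(starts) > 1L) {
    for (k in 2:length(starts)) {
      if (starts[k] <= m_end + 1L) {
        m_end <- max(m_end, ends[k])
      } else {
        blocks <- flush(blocks, m_start, m_end)
        m_start <- starts[k]; m_end <- ends[k]
      }
    }
  }
  flush(blocks, m_start, m_end)
}

# Maximal-sum contiguous subsegment (1-based start/end indices).
# Deterministic tie-break: among equal sums the longest segment wins, and
# among equally long ones the leftmost — so a uniformly zero-score run
# (identity exactly at threshold) is kept whole.
max_scoring_segment <- function(x) {
  eps <- 1e-12
  best_sum <- -Inf; best_s <- 1L; best_e <- 1L
  cur <- 0; cur_start <- 1L
  for (i in seq_along(x)) {
    if (cur < 0) { cur <- 0; cur_start <- i }
    cur <- cur + x[i]
    longer <- (i - cur_start) > (best_e - best_s)
    if (cur > best_sum + eps || (abs(cur - best_sum) <= eps && longer)) {
      best_sum <- cur; best_s <- cur_start; best_e <- i
    }
  }
  c(best_s, best_e)
}

#' Call the core conserved region of an alignment
#'
#' Applies the strict preset (350 nt window, 77% identity) and returns the
#' single block with the highest mean identity, labeled `"CoreECR"`; ties go
#' to the longer block, then the smaller start. `NULL` when no window passes.
#'
#' @param aln A `pairwise_alignment`.
#' @param window,min_identity Preset overrides.
#' @param step Window step passed through to [windowed_identity()].
#' @return A `conserved_block` or `NULL`.
#' @export
core_ecr <- function(aln, window = 350L, min_identity = 0.77, step = 1L) {
  profile <- windowed_identity(aln, profile_params(window, min_identity, step))
  blocks <- call_blocks(profile, label = "CoreECR")
  if (length(blocks) == 0L) return(NULL)
  ident <- vapply(blocks, function(b) b$mean_identity, numeric(1))
  len <- vapply(blocks, function(b) interval_length(b$interval), integer(1))
  start <- vapply(blocks, function(b) b$interval$start, integer(1))
  blocks[[order(-ident, -len, start)[1]]]
}

#' Positional Jaccard index of two intervals
#'
#' Intersection over union of the base sets covered by two intervals on the
#' same sequence (fully-closed convention).
#'
#' @param a,b [genomic_interval()] objects in the same frame.
#' @return Fraction in `[0, 1]`.
#' @export
interval_jaccard <- function(a, b) {
  stopifnot(inherits(a, "genomic_interval"), inherits(b, "genomic_interval"))
  inter <- max(0L, min(a$end, b$end) - max(a$start, b$start) + 1L)
  union <- interval_length(a) + interval_length(b) - inter
  inter / union
}
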