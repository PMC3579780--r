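#' Progressive multiple sequence alignment
#'
#' A deterministic progressive aligner: pairwise 6-mer distances feed a UPGMA
#' guide tree, and profiles are merged up the tree by affine-gap
#' profile-profile global alignment under the supplied scheme. For two
#' sequences the result reduces to [global_align()]. Ties in the guide tree
#' follow input order, so results are reproducible for a fixed input order.
#'
#' @param seqs List of [seq_record()] objects (>= 2).
#' @param s A [scoring_scheme()].
#' @return An object of class `multiple_alignment`: `row_ids` (input order)
#'   and `rows`, equal-length gapped strings; ungapping any row reproduces
#'   its input sequence.
#' @export
progressive_msa <- function(seqs, s = scoring_scheme()) {
  if (length(seqs) < 2L) stop("progressive_msa requires >= 2 sequences")
  ids <- vapply(seqs, function(r) seq_label(r, ""), character(1))
  strs <- vapply(seqs, as_sequence, character(1))
  n <- length(strs)

  if (n == 2L) {
    aln <- global_align(strs[1], strs[2], s)
    return(new_multiple_alignment(ids, c(aln$row_a, aln$row_b)))
  }

  D <- kmer_distance_matrix(strs, k = 6L)
  hc <- stats::hclust(stats::as.dist(D), method = "average")

  # profiles indexed as in hclust$merge: negative = leaf, positive = merge row
  profiles <- vector("list", n - 1L)
  get_profile <- function(idx) {
    if (idx < 0L) list(ids = ids[-idx], rows = strs[-idx]) else profiles[[idx]]
  }
  for (k in seq_len(n - 1L)) {
    pa <- get_profile(hc$merge[k, 1])
    pb <- get_profile(hc$merge[k, 2])
    profiles[[k]] <- merge_profiles(pa, pb, s)
  }
  final <- profiles[[n - 1L]]
  ord <- match(ids, final$ids)
  new_multiple_alignment(ids, final$rows[ord])
}

new_multiple_alignment <- function(row_ids, rows) {
  stopifnot(length(unique(nchar(rows))) == 1L)
  structure(list(row_ids = row_ids, rows = unname(rows)),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d rows x %d columns\n",
              length(x$rows), nchar(x$rows[1])))
  invisible(x)
}

# fractional common 6-mer distance between all sequence pairs
kmer_distance_matrix <- function(strs, k = 6L) {
  counts <- lapply(strs, function(s) {
    L <- nchar(s)
    if (L < k) return(table(character(0)))
    table(substring(s, 1:(L - k + 1L), k:L))
  })
  n <- length(strs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- intersect(names(counts[[i]]), names(counts[[j]]))
      common <- sum(pmin(counts[[i]][shared], counts[[j]][shared]))
      denom <- min(sum(counts[[i]]), sum(counts[[j]]))
      D[i, j] <- D[j, i] <- 1 - common / max(denom, 1L)
    }
  }
  D
}

profile_freq_matrix <- function(rows) {
  alphabet <- c("A", "C", "G", "T", "N", "-")
  L <- nchar(rows[1])
  chars <- vapply(rows, function(r) strsplit(r, "", fixed = TRUE)[[1]],
                  character(L))
  if (is.null(dim(chars))) chars <- matrix(chars, nrow = L)
  m <- matrix(0, nrow = 6L, ncol = L, dimnames = list(alphabet, NULL))
  for (a in seq_along(alphabet)) {
    m[a, ] <- rowSums(chars == alphabet[a]) / length(rows)
  }
  m
}

merge_profiles <- function(pa, pb, s) {
  fa <- profile_freq_matrix(pa$rows)
  fb <- profile_freq_matrix(pb$rows)
  res <- .align_profile_cpp(fa, fb, s$match, s$mismatch, s$gap_open, s$gap_extend)
  moves <- res$moves
  take_a <- moves %in% c(0L, 1L)
  take_b <- moves %in% c(0L, 2L)
  expand <- function(row, take) {
    chars <- strsplit(row, "", fixed = TRUE)[[1]]
    out <- rep("-", length(take))
    out[take] <- chars
    paste(out, collapse = "")
  }
  list(ids = c(pa$ids, pb$ids),
       rows = c(vapply(pa$rows, expand, character(1), take = take_a),
                vapply(pb$rows, expand, character(1), take = take_b)))
}

#' Shared (minimal) column span of a multiple alignment
#'
#' The maximal run of columns in which every row is inside its own aligned
#' extent, i.e. past its leading and before its trailing terminal gaps. This
#' is the intersection of per-row coverage spans and defines the minimal
#' region shared by all species (the minECR when rows are full-length ECRs).
#'
#' @param msa A `multiple_alignment`.
#' @return Integer vector `c(first, last)` of 1-based column indices.
#' @export
shared_span <- function(msa) {
  stopifnot(inherits(msa, "multiple_alignment"))
  spans <- vapply(msa$rows, function(r) {
    nongap <- gregexpr("[^-]", r)[[1]]
    c(min(nongap), max(nongap))
  }, integer(2))
  first <- max(spans[1, ]); last <- min(spans[2, ])
  if (first > last) stop("no shared span: rows have disjoint coverage")
  c(first = first, last = last)
}

#' Build a case-encoded consensus over a column span
#'
#' Per column (gap rule first): if gaps make up at least half of all rows the
#' column is `'.'`; otherwise, counting only non-gap residues, a unanimous
#' nucleotide is written uppercase, a strict-majority (> 50% of non-gap
#' residues) nucleotide lowercase, and `'n'` when no strict majority exists
#' (N residues count in the denominator but never become the consensus).
#' `consensus_length` counts the non-`'.'` characters; `alignment_length`
#' all span columns.
#'
#' @param msa A `multiple_alignment` (>= 2 rows).
#' @param span Column interval `c(first, last)`; defaults to [shared_span()].
#' @param identity_mode `"exclude_n"` (default): `'n'`/`'.'` columns are
#'   excluded from per-species identity; `"strict"`: they count as
#'   mismatches.
#' @return An object of class `consensus_result` with fields `consensus`,
#'   `span_columns`, `per_species_identity` (named by row id),
#'   `consensus_length` and `alignment_length`.
#' @export
build_consensus <- function(msa, span = shared_span(msa),
                            identity_mode = c("exclude_n", "strict")) {
  stopifnot(inherits(msa, "multiple_alignment"), length(msa$rows) >= 2L)
  identity_mode <- match.arg(identity_mode)
  span <- as.integer(span)
  ncol_full <- nchar(msa$rows[1])
  if (length(span) != 2L || span[1] > span[2] || span[1] < 1L ||
      span[2] > ncol_full) {
    stop("invalid or empty column span")
  }
  cols <- span[1]:span[2]
  chars <- vapply(msa$rows, function(r) strsplit(r, "", fixed = TRUE)[[1]][cols],
                  character(length(cols)))
  if (is.null(dim(chars))) chars <- matrix(chars, nrow = length(cols))
  n_rows <- ncol(chars)
  cons <- vapply(seq_along(cols), function(i) {
    col <- chars[i, ]
    n_gap <- sum(col == "-")
    if (n_gap >= n_rows / 2) return(".")
    res <- col[col != "-"]
    counts <- c(A = sum(res == "A"), C = sum(res == "C"),
                G = sum(res == "G"), T = sum(res == "T"))
    top <- which.max(counts)
    if (counts[top] == length(res)) return(names(counts)[top])
    if (counts[top] > length(res) / 2) return(tolower(names(counts)[top]))
    "n"
  }, character(1))
  consensus <- paste(cons, collapse = "")
  rows_span <- vapply(seq_len(n_rows), function(j) paste(chars[, j], collapse = ""),
                      character(1))
  ident <- if (any(toupper(cons) %in% c("A", "C", "G", "T"))) {
    vapply(rows_span, identity_to_consensus, numeric(1),
           consensus = consensus, identity_mode = identity_mode)
  } else {
    # consensus has no residue columns: identity is undefined
    rep(NA_real_, n_rows)
  }
  structure(list(
    consensus = consensus,
    span_columns = span,
    per_species_identity = setNames(ident, msa$row_ids),
    consensus_length = sum(cons != "."),
    alignment_length = length(cols)
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d nt consensus (%d alignment columns), %d species\n",
              x$consensus_length, x$alignment_length,
              length(x$per_species_identity)))
  invisible(x)
}

#' Identity of one aligned row to a case-encoded consensus
#'
#' A match is case-insensitive equality with an `{A,C,G,T}` consensus column;
#' a row gap at such a column is a mismatch; row N never matches. Under
#' `"exclude_n"`, columns whose consensus is `'n'` or `'.'` are excluded from
#' numerator and denominator; under `"strict"` they count as mismatches.
#'
#' @param row Gapped row string over the same span as `consensus`.
#' @param consensus Case-encoded consensus string of equal length.
#' @param identity_mode `"exclude_n"` or `"strict"`.
#' @return Fraction in `[0, 1]`.
#' @export
identity_to_consensus <- function(row, consensus,
                                  identity_mode = c("exclude_n", "strict")) {
  identity_mode <- match.arg(identity_mode)
  stopifnot(nchar(row) == nchar(consensus))
  rc <- strsplit(toupper(row), "", fixed = TRUE)[[1]]
  cc <- strsplit(consensus, "", fixed = TRUE)[[1]]
  residue_col <- toupper(cc) %in% c("A", "C", "G", "T")
  match <- residue_col & rc == toupper(cc) & rc %in% c("A", "C", "G", "T")
  denom <- if (identity_mode == "exclude_n") sum(residue_col) else length(cc)
  if (denom == 0L) stop("no comparable columns")
  sum(match) / denom
}

#' Summary statistics of per-species consensus identities
#'
#' @param per_species_identity Named numeric vector of fractions.
#' @return List with `mean`, `median` (midpoint convention for even counts),
#'   `min` and `max`.
#' @export
identity_summary <- function(per_species_identity) {
  v <- as.numeric(per_species_identity)
  if (length(v) < 1L) stop("need at least one identity value")
  list(mean = mean(v), median = median(v), min = min(v), max = max(v))
}
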