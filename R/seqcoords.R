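#' @useDynLib ecrtools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom rgeom runif setNames
#' @importFrom utils write.table read.table
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")

#' Upstream-region sequence record
#'
#' A nucleotide sequence together with the metadata needed for TSS-relative
#' coordinate bookkeeping: species label, source accession, and the 1-based
#' absolute position of the annotated transcription start site (TSS) on that
#' accession. Sequences are uppercase-normalized over `{A,C,G,T,N}`.
#'
#' @param id Record identifier (unique within a set).
#' @param sequence Nucleotide string; lowercase is uppercased, IUPAC ambiguity
#'   codes other than N are coerced to N with a warning.
#' @param species Species label; defaults to `id`.
#' @param accession Optional source accession.
#' @param tss_abs Optional 1-based absolute TSS position on the accession.
#'   Requires `gene_strand`.
#' @param gene_strand `"+"` or `"-"`; strand of the gene on the accession.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, sequence, species = id, accession = NULL,
                       tss_abs = NULL, gene_strand = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_sequence(sequence, id = id)
  if (nchar(sequence) < 1L) stop("sequence must have length >= 1 (record '", id, "')")
  if (!is.null(tss_abs)) {
    if (is.null(gene_strand)) {
      stop("record '", id, "': tss_abs requires gene_strand")
    }
    tss_abs <- as.integer(tss_abs)
    if (is.na(tss_abs) || tss_abs < 1L) stop("tss_abs must be a positive integer")
  }
  if (!is.null(gene_strand) && !gene_strand %in% c("+", "-")) {
    stop("gene_strand must be '+' or '-'")
  }
  structure(
    list(id = id, species = species, sequence = sequence,
         accession = accession, tss_abs = tss_abs, gene_strand = gene_strand),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%s), %d nt", x$id, x$species, nchar(x$sequence)))
  if (!is.null(x$tss_abs)) {
    cat(sprintf(", TSS %d (%s)", x$tss_abs, x$gene_strand))
  }
  cat("\n")
  invisible(x)
}

# Uppercase, coerce IUPAC ambiguity codes to N (warning), reject anything else
# naming the record and the first offending position.
normalize_sequence <- function(sequence, id = "?") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c(VALID_BASES, IUPAC_AMBIG))
  if (any(bad)) {
    pos <- which(bad)[1]
    stop(sprintf("record '%s': invalid character '%s' at position %d",
                 id, chars[pos], pos))
  }
  ambig <- chars %in% IUPAC_AMBIG
  if (any(ambig)) {
    warning(sprintf("record '%s': %d IUPAC ambiguity code(s) coerced to N",
                    id, sum(ambig)))
    chars[ambig] <- "N"
    s <- paste(chars, collapse = "")
  }
  s
}

#' Genomic interval (1-based, fully closed)
#'
#' Intervals carry a coordinate frame: `absolute` (1-based positions on an
#' accession or sequence, `1 <= start <= end`) or `tss_relative` (negative
#' upstream positions; there is no position 0 and -1 is the base immediately
#' 5' of the TSS, so `start <= end <= -1`). In both frames
#' `length = end - start + 1`.
#'
#' @param seq_id Identifier of the sequence/accession the interval lies on.
#' @param start,end Integer endpoints, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param frame `"absolute"` or `"tss_relative"`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(seq_id, start, end, strand = "+",
                             frame = c("absolute", "tss_relative")) {
  frame <- match.arg(frame)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end)) stop("start/end must be integers")
  if (start > end) stop("start must be <= end")
  if (frame == "absolute" && start < 1L) {
    stop("absolute interval requires 1 <= start <= end")
  }
  if (frame == "tss_relative" && end > -1L) {
    stop("tss_relative interval requires start <= end <= -1 (no position 0)")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(seq_id = seq_id, start = start, end = end,
                 strand = strand, frame = frame),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%d..%d (%s, %s), %d nt\n",
              x$seq_id, x$start, x$end, x$strand, x$frame, interval_length(x)))
  invisible(x)
}

#' Interval length under the fully-closed convention
#'
#' @param iv A [genomic_interval()].
#' @return `end - start + 1`.
#' @examples
#' interval_length(genomic_interval("mm", -1642, -1138, frame = "tss_relative"))
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  iv$end - iv$start + 1L
}

#' Normalize a complement-strand coordinate listing
#'
#' Accession tables list minus-strand features with descending coordinates
#' (e.g. `12332541.12332253, complement`). This returns the ascending
#' absolute interval on the minus strand.
#'
#' @param a,b Endpoint coordinates in either order.
#' @param seq_id Sequence identifier for the result.
#' @return A minus-strand absolute [genomic_interval()].
#' @export
normalize_complement_listing <- function(a, b, seq_id = "") {
  a <- as.integer(a); b <- as.integer(b)
  if (a < 1L || b < 1L) stop("coordinates must be positive")
  genomic_interval(seq_id, min(a, b), max(a, b), strand = "-", frame = "absolute")
}

#' Convert a TSS-relative interval to absolute accession coordinates
#'
#' Upstream position -n maps to `tss_abs - n` for a plus-strand gene and
#' `tss_abs + n` for a minus-strand gene; endpoints are reordered so that
#' `start <= end`. Length is preserved.
#'
#' @param iv A `tss_relative` [genomic_interval()].
#' @param rec A [seq_record()] with `tss_abs` and `gene_strand` set.
#' @return An absolute-frame [genomic_interval()] on `rec`'s accession.
#' @export
tss_relative_to_absolute <- function(iv, rec) {
  stopifnot(inherits(iv, "genomic_interval"), inherits(rec, "seq_record"))
  if (iv$frame != "tss_relative") stop("interval must be tss_relative")
  if (is.null(rec$tss_abs) || is.null(rec$gene_strand)) {
    stop("record '", rec$id, "' lacks a TSS anchor (tss_abs + gene_strand)")
  }
  # iv positions are negative: -n with n = -position
  n1 <- -iv$start; n2 <- -iv$end
  if (rec$gene_strand == "+") {
    p1 <- rec$tss_abs - n1; p2 <- rec$tss_abs - n2
  } else {
    p1 <- rec$tss_abs + n1; p2 <- rec$tss_abs + n2
  }
  lo <- min(p1, p2); hi <- max(p1, p2)
  if (lo < 1L) stop("interval extends beyond contig start (coordinate < 1)")
  genomic_interval(if (is.null(rec$accession)) rec$id else rec$accession,
                   lo, hi, strand = rec$gene_strand, frame = "absolute")
}

#' Reverse complement of a nucleotide string
#'
#' Standard Watson-Crick complement, reversed; N maps to N. Applying it twice
#' returns the input.
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}` (case-insensitive).
#' @return The reverse-complemented uppercase string.
#' @export
reverse_complement <- function(seq) {
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) stop("invalid character in sequence")
  if (!nzchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' GC content of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; N is excluded from the denominator.
#'
#' @param seq Nucleotide string.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  s <- toupper(seq)
  if (!nzchar(s)) stop("empty sequence")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  acgt <- sum(chars %in% c("A", "C", "G", "T"))
  if (acgt == 0L) stop("GC content undefined: no unambiguous bases")
  sum(chars %in% c("G", "C")) / acgt
}

#' Read upstream-region FASTA
#'
#' One [seq_record()] per entry, order preserved. The first
#' whitespace-separated header token is the record id; optional
#' `species=`, `accession=`, `tss=` and `strand=` key-value tokens populate
#' the corresponding fields. Sequences are uppercase-normalized; IUPAC
#' ambiguity codes other than N are coerced to N with a warning; any other
#' character is an error naming the record and position.
#'
#' @param path FASTA file path.
#' @return List of [seq_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  recs <- vector("list", length(set))
  ids <- character(length(set))
  for (k in seq_along(set)) {
    tokens <- strsplit(trimws(headers[k]), "\\s+")[[1]]
    id <- tokens[1]
    kv <- grep("=", tokens[-1], fixed = TRUE, value = TRUE)
    fields <- list()
    for (t in kv) {
      parts <- strsplit(t, "=", fixed = TRUE)[[1]]
      if (length(parts) == 2L) fields[[parts[1]]] <- parts[2]
    }
    recs[[k]] <- seq_record(
      id = id,
      sequence = as.character(set[[k]]),
      species = if (!is.null(fields$species)) gsub("_", " ", fields$species) else id,
      accession = fields$accession,
      tss_abs = if (!is.null(fields$tss)) as.integer(fields$tss) else NULL,
      gene_strand = if (!is.null(fields$tss)) {
        if (!is.null(fields$strand)) fields$strand else "+"
      } else NULL
    )
    ids[k] <- id
  }
  dup <- duplicated(ids)
  if (any(dup)) stop("duplicate FASTA ids: ", paste(unique(ids[dup]), collapse = ", "))
  recs
}

#' Write records to FASTA
#'
#' 60-column wrapped; record metadata is serialized into `key=value` header
#' tokens so that [read_fasta()] round-trips. Case and non-nucleotide
#' consensus characters are preserved bit-exactly.
#'
#' @param records List of [seq_record()] objects, or a named character vector
#'   of raw sequences (names become ids; used for consensus output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    stopifnot(!is.null(names(records)))
    set <- Biostrings::BStringSet(records)
  } else {
    if (inherits(records, "seq_record")) records <- list(records)
    seqs <- vapply(records, function(r) r$sequence, character(1))
    headers <- vapply(records, function(r) {
      h <- r$id
      if (!identical(r$species, r$id)) {
        h <- paste0(h, " species=", gsub(" ", "_", r$species))
      }
      if (!is.null(r$accession)) h <- paste0(h, " accession=", r$accession)
      if (!is.null(r$tss_abs)) {
        h <- paste0(h, " tss=", r$tss_abs, " strand=", r$gene_strand)
      }
      h
    }, character(1))
    set <- Biostrings::BStringSet(setNames(seqs, headers))
  }
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write intervals as BED
#'
#' BED is 0-based half-open: an internal 1-based closed interval
#' `[start, end]` becomes BED `start-1, end`. Emits 6 columns
#' (chrom, start, end, name, score, strand).
#'
#' @param intervals List of [genomic_interval()] (absolute frame).
#' @param path Output path.
#' @param names Feature names (recycled); default `"."`.
#' @param scores Numeric scores, e.g. identities scaled 0-1000 (recycled).
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, names = ".", scores = 0) {
  header <- "#chrom\tstart\tend\tname\tscore\tstrand"
  if (length(intervals) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  stopifnot(all(vapply(intervals, inherits, logical(1), "genomic_interval")))
  if (any(vapply(intervals, function(iv) iv$frame, character(1)) != "absolute")) {
    stop("BED export requires absolute-frame intervals")
  }
  df <- data.frame(
    chrom = vapply(intervals, function(iv) iv$seq_id, character(1)),
    start = vapply(intervals, function(iv) iv$start, integer(1)) - 1L,
    end = vapply(intervals, function(iv) iv$end, integer(1)),
    name = rep_len(names, length(intervals)),
    score = rep_len(scores, length(intervals)),
    strand = vapply(intervals, function(iv) iv$strand, character(1))
  )
  writeLines(header, path)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' @param path BED path.
#' @return List of absolute-frame [genomic_interval()] objects (empty list
#'   for a header-only file).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(list())
  df <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    genomic_interval(df[i, 1], df[i, 2] + 1L, df[i, 3],
                     strand = if (ncol(df) >= 6) df[i, 6] else "+",
                     frame = "absolute")
  })
}

#' Write a report table as TSV
#'
#' Coordinates in TSV reports are 1-based fully-closed; a comment line in the
#' header records the convention.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based, fully-closed", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
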