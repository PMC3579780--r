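#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with the standard
#' presets: conserved blocks at >= 75% identity over a sliding 100 nt
#' window, core regions at >= 77% over 350 nt, chunked search in 500 nt
#' sections, and the 20-column flank-conservation rule for TFBS filtering.
#'
#' @param ecr [profile_params()] preset for ordinary conserved blocks.
#' @param core [profile_params()] preset for CoreECR calling.
#' @param chunk_len Chunk length for [chunked_search()].
#' @param scoring A [scoring_scheme()].
#' @param min_identity,min_score Chunk-level significance thresholds.
#' @param tfbs_min_relative_score PWM hit threshold.
#' @param tfbs_flank Flank window (alignment columns).
#' @param tfbs_min_flank_identity Flank identity threshold.
#' @param identity_mode Consensus identity denominator rule
#'   (see [build_consensus()]).
#' @param seed Integer seed recorded in run logs.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(ecr = profile_params(100L, 0.75),
                            core = profile_params(350L, 0.77),
                            chunk_len = 500L,
                            scoring = scoring_scheme(),
                            min_identity = 0.6, min_score = 50,
                            tfbs_min_relative_score = 0.85,
                            tfbs_flank = 20L,
                            tfbs_min_flank_identity = 0.8,
                            identity_mode = "exclude_n",
                            seed = 1L) {
  structure(list(ecr = ecr, core = core, chunk_len = chunk_len,
                 scoring = scoring, min_identity = min_identity,
                 min_score = min_score,
                 tfbs_min_relative_score = tfbs_min_relative_score,
                 tfbs_flank = tfbs_flank,
                 tfbs_min_flank_identity = tfbs_min_flank_identity,
                 identity_mode = identity_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_lines <- function(config) {
  c(sprintf("ecr_window: %d", config$ecr$window),
    sprintf("ecr_min_identity: %g", config$ecr$min_identity),
    sprintf("core_window: %d", config$core$window),
    sprintf("core_min_identity: %g", config$core$min_identity),
    sprintf("chunk_len: %d", config$chunk_len),
    sprintf("scoring: match=%g mismatch=%g gap_open=%g gap_extend=%g",
            config$scoring$match, config$scoring$mismatch,
            config$scoring$gap_open, config$scoring$gap_extend),
    sprintf("chunk_min_identity: %g", config$min_identity),
    sprintf("chunk_min_score: %g", config$min_score),
    sprintf("tfbs_min_relative_score: %g", config$tfbs_min_relative_score),
    sprintf("tfbs_flank: %d", config$tfbs_flank),
    sprintf("tfbs_min_flank_identity: %g", config$tfbs_min_flank_identity),
    sprintf("identity_mode: %s", config$identity_mode),
    sprintf("seed: %d", config$seed))
}

write_run_log <- function(config, inputs, out_dir, stage) {
  if (is.null(out_dir)) return(invisible(NULL))
  lines <- c(sprintf("stage: %s", stage),
             config_lines(config),
             vapply(inputs, function(r) {
               sprintf("input: %s length=%d", r$id, nchar(r$sequence))
             }, character(1)))
  writeLines(lines, file.path(out_dir, paste0(stage, "_run.log")))
  invisible(NULL)
}

ensure_dir <- function(out_dir) {
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_dir
}

#' Pairwise conservation profiling of two upstream regions
#'
#' Globally aligns the query against the target, profiles the alignment at
#' the ordinary-block preset, calls conserved blocks, and calls the core
#' region at the strict preset. All coordinates are on the query sequence.
#'
#' @param query,target [seq_record()] objects.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory: writes `profile.tsv`,
#'   `blocks.bed`, `core_ecr.bed` and a run log.
#' @return List: `aln`, `profile`, `blocks`, `core` (NULL when no core
#'   region passes).
#' @export
run_profile <- function(query, target, config = pipeline_config(),
                        out_dir = NULL) {
  ensure_dir(out_dir)
  aln <- global_align(query, target, config$scoring)
  profile <- windowed_identity(aln, config$ecr)
  blocks <- call_blocks(profile)
  core <- core_ecr(aln, window = config$core$window,
                   min_identity = config$core$min_identity,
                   step = config$core$step)
  if (!is.null(out_dir)) {
    write_tsv_report(data.frame(position = profile$ref_positions,
                                identity = profile$identities),
                     file.path(out_dir, "profile.tsv"))
    write_bed(lapply(blocks, function(b) b$interval),
              file.path(out_dir, "blocks.bed"),
              names = vapply(blocks, function(b) b$label, character(1)),
              scores = round(1000 * vapply(blocks, function(b) b$mean_identity,
                                           numeric(1))))
    core_ivs <- if (is.null(core)) list() else list(core$interval)
    write_bed(core_ivs, file.path(out_dir, "core_ecr.bed"),
              names = "CoreECR",
              scores = if (is.null(core)) 0 else round(1000 * core$mean_identity))
    write_run_log(config, list(query, target), out_dir, "profile")
  }
  list(aln = aln, profile = profile, blocks = blocks, core = core)
}

#' Chunked homology search of one query against many targets
#'
#' Runs [chunked_search()] of the query against each target and assembles a
#' per-section identity matrix (rows = query sections, columns = targets;
#' `NA` where a section had no significant hit).
#'
#' @param query A [seq_record()].
#' @param targets List of [seq_record()] objects (>= 1).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory: per-target chunk TSVs plus the
#'   identity matrix `chunk_matrix.tsv`.
#' @return List: `per_target` (named list of chunk data frames), `matrix`
#'   (chunk x target identity matrix).
#' @export
run_chunkscan <- function(query, targets, config = pipeline_config(),
                          out_dir = NULL) {
  if (length(targets) == 0L) stop("no target sequences supplied")
  ensure_dir(out_dir)
  per_target <- lapply(targets, function(t) {
    chunked_search(query, t, chunk_len = config$chunk_len, s = config$scoring,
                   min_identity = config$min_identity,
                   min_score = config$min_score)
  })
  names(per_target) <- vapply(targets, function(t) t$id, character(1))
  mat <- vapply(per_target, function(df) {
    ifelse(df$significant, df$percent_identity, NA_real_)
  }, numeric(nrow(per_target[[1]])))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L,
                                       dimnames = list(NULL, names(per_target)))
  rownames(mat) <- sprintf("chunk_%02d", per_target[[1]]$chunk_index)
  if (!is.null(out_dir)) {
    for (id in names(per_target)) {
      write_tsv_report(per_target[[id]],
                       file.path(out_dir, paste0("chunks_", id, ".tsv")))
    }
    write_tsv_report(data.frame(chunk = rownames(mat), round(mat, 4),
                                check.names = FALSE),
                     file.path(out_dir, "chunk_matrix.tsv"))
    write_run_log(config, c(list(query), targets), out_dir, "chunkscan")
  }
  list(per_target = per_target, matrix = mat)
}

#' Minimal shared ECR extraction and consensus
#'
#' Progressively aligns full-length ECR sequences, intersects their aligned
#' coverage ([shared_span()]) to obtain the minimal shared region, and builds
#' the case-encoded consensus with per-species identity statistics.
#'
#' @param ecr_records List of [seq_record()] objects (>= 2), one full-length
#'   ECR per species.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory: aligned FASTA, consensus FASTA
#'   (case/`'n'`/`'.'` preserved bit-exactly), identity TSV, summary TSV.
#' @return List: `msa`, `span`, `consensus` (a `consensus_result`),
#'   `summary`.
#' @export
run_minecr <- function(ecr_records, config = pipeline_config(),
                       out_dir = NULL) {
  if (length(ecr_records) < 2L) stop("need >= 2 ECR sequences")
  ensure_dir(out_dir)
  msa <- progressive_msa(ecr_records, config$scoring)
  span <- shared_span(msa)
  cons <- build_consensus(msa, span, identity_mode = config$identity_mode)
  summ <- identity_summary(cons$per_species_identity)
  if (!is.null(out_dir)) {
    write_fasta(setNames(msa$rows, msa$row_ids),
                file.path(out_dir, "aligned.fasta"))
    write_fasta(c(consensus_minECR = cons$consensus),
                file.path(out_dir, "consensus.fasta"))
    write_tsv_report(data.frame(species = names(cons$per_species_identity),
                                identity = as.numeric(cons$per_species_identity)),
                     file.path(out_dir, "identity.tsv"))
    write_tsv_report(data.frame(
      consensus_length = cons$consensus_length,
      alignment_length = cons$alignment_length,
      mean = summ$mean, median = summ$median,
      min = summ$min, max = summ$max),
      file.path(out_dir, "summary.tsv"))
    write_run_log(config, ecr_records, out_dir, "minecr")
  }
  list(msa = msa, span = span, consensus = cons, summary = summ)
}

#' Conserved-TFBS analysis of a species pair
#'
#' Globally aligns the two regions, scans both with every PWM, keeps the
#' reference hits that are conserved under the flank-conservation rule, and
#' partitions the conserved sites by the core conserved region called from
#' the same alignment (the inside/outside question is asked of the single
#' core element; ordinary blocks are still called and used to annotate each
#' site's containing block).
#'
#' @param query,other [seq_record()] objects (reference first).
#' @param pwms List of [pwm()] objects (non-empty), e.g. from
#'   [read_jaspar()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory: hit TSV/BED, conserved-site TSV,
#'   partition TSV.
#' @return List: `aln`, `blocks`, `core`, `hits_query`, `hits_other`,
#'   `conserved`, `partition`.
#' @export
run_tfbs <- function(query, other, pwms, config = pipeline_config(),
                     out_dir = NULL) {
  if (length(pwms) == 0L) stop("no PWMs supplied")
  ensure_dir(out_dir)
  aln <- global_align(query, other, config$scoring)
  blocks <- call_blocks(windowed_identity(aln, config$ecr))
  core <- core_ecr(aln, window = config$core$window,
                   min_identity = config$core$min_identity,
                   step = config$core$step)
  scan_all <- function(rec) {
    do.call(rbind, lapply(pwms, function(p) {
      pwm_scan(rec, p, min_relative_score = config$tfbs_min_relative_score)
    }))
  }
  hits_q <- scan_all(query)
  hits_o <- scan_all(other)
  conserved <- conserved_sites(aln, hits_q, hits_o,
                               flank = config$tfbs_flank,
                               min_flank_identity = config$tfbs_min_flank_identity,
                               blocks = blocks)
  partition <- site_block_partition(conserved,
                                    if (is.null(core)) blocks else list(core))
  if (!is.null(out_dir)) {
    write_tsv_report(hits_q, file.path(out_dir, "hits_query.tsv"))
    write_tsv_report(hits_o, file.path(out_dir, "hits_other.tsv"))
    write_bed(lapply(seq_len(nrow(hits_q)), function(i) {
      genomic_interval(query$id, hits_q$start[i], hits_q$end[i],
                       strand = hits_q$strand[i])
    }), file.path(out_dir, "hits_query.bed"), names = hits_q$pwm_name,
    scores = round(1000 * hits_q$relative_score))
    write_tsv_report(conserved, file.path(out_dir, "conserved_sites.tsv"))
    write_tsv_report(data.frame(inside = partition$inside,
                                outside = partition$outside,
                                fraction_inside = partition$fraction_inside),
                     file.path(out_dir, "partition.tsv"))
    write_run_log(config, list(query, other), out_dir, "tfbs")
  }
  list(aln = aln, blocks = blocks, core = core, hits_query = hits_q,
       hits_other = hits_o, conserved = conserved, partition = partition)
}

#' Extract the subsequence of a record covered by an interval
#'
#' @param rec A [seq_record()].
#' @param iv An absolute [genomic_interval()] on the record.
#' @param id Id for the extracted record (default `rec$id`).
#' @return A [seq_record()] holding the subsequence.
#' @export
extract_interval <- function(rec, iv, id = rec$id) {
  stopifnot(inherits(rec, "seq_record"), inherits(iv, "genomic_interval"),
            iv$frame == "absolute")
  if (iv$end > nchar(rec$sequence)) stop("interval exceeds sequence length")
  seq_record(id, substr(rec$sequence, iv$start, iv$end), species = rec$species)
}
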