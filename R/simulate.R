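#' Branch-evolution parameters for the promoter simulator
#'
#' Per-branch event probabilities (not rates with time): each site
#' substitutes with `sub_prob` and initiates an indel with `indel_prob`;
#' inside constrained intervals both are multiplied by `constraint_factor`.
#' Indel lengths are geometric with mean `indel_mean_len`; insertions and
#' deletions are equiprobable and insertion content is i.i.d. background.
#'
#' @param sub_prob Per-site substitution probability per branch in `[0, 1)`.
#' @param indel_prob Per-site indel-initiation probability per branch.
#' @param indel_mean_len Mean indel length (geometric model).
#' @param constraint_factor Multiplier in `[0, 1]` applied inside constrained
#'   intervals.
#' @param seed Integer seed; all operations derive their sub-seeds from it.
#' @return An object of class `evolution_params`.
#' @export
evolution_params <- function(sub_prob = 0.3, indel_prob = 0.02,
                             indel_mean_len = 3, constraint_factor = 0.1,
                             seed = 1L) {
  stopifnot(sub_prob >= 0, sub_prob < 1, indel_prob >= 0, indel_prob < 1,
            indel_mean_len > 0, constraint_factor >= 0, constraint_factor <= 1)
  structure(list(sub_prob = sub_prob, indel_prob = indel_prob,
                 indel_mean_len = indel_mean_len,
                 constraint_factor = constraint_factor,
                 seed = as.integer(seed)),
            class = "evolution_params")
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 8191) %% 2147483647)
}

#' Simulate an ancestral upstream region
#'
#' I.i.d. nucleotides at the requested GC content (the default 0.45 matches
#' the GC fraction typical of the upstream regions this pipeline targets).
#'
#' @param length Sequence length (>= 100).
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param id Record id.
#' @return A [seq_record()].
#' @export
simulate_ancestor <- function(length = 5000L, gc = 0.45, seed = 1L,
                              id = "ancestor") {
  stopifnot(length >= 100L)
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly between 0 and 1")
  set.seed(derive_seed(seed, 1L))
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  seq_record(id, paste(bases, collapse = ""))
}

#' Evolve a sequence along one branch
#'
#' Applies substitutions and geometric-length indels site-wise; inside
#' `constraint_mask` intervals both probabilities are multiplied by
#' `constraint_factor`, and inside `frozen_mask` intervals (e.g. planted
#' motif footprints) no events occur at all. Returns the mutated record plus
#' a strictly monotone old-to-new coordinate map (NA for deleted sites) so
#' truth intervals can be carried through.
#'
#' @param rec A [seq_record()].
#' @param params An [evolution_params()].
#' @param constraint_mask List of [genomic_interval()]s under constraint.
#' @param frozen_mask List of intervals where no events occur.
#' @param seed Integer seed (defaults to `params$seed`).
#' @param id Id for the evolved record.
#' @return List: `record`, `map` (integer vector, length of the input),
#'   `n_sub`, `n_ins`, `n_del` (event counts).
#' @export
evolve_branch <- function(rec, params, constraint_mask = list(),
                          frozen_mask = list(), seed = params$seed,
                          id = paste0(rec$id, "_d")) {
  stopifnot(inherits(rec, "seq_record"), inherits(params, "evolution_params"))
  chars <- strsplit(rec$sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  fac <- rep(1, L)
  for (iv in constraint_mask) {
    stopifnot(iv$start >= 1L, iv$end <= L)
    fac[iv$start:iv$end] <- params$constraint_factor
  }
  for (iv in frozen_mask) fac[iv$start:iv$end] <- 0

  set.seed(derive_seed(seed, 2L))
  # substitutions
  sub_here <- runif(L) < params$sub_prob * fac
  if (any(sub_here)) {
    idx <- which(sub_here)
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 3,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    pick <- sample.int(3L, length(idx), replace = TRUE)
    for (k in seq_along(idx)) {
      b <- chars[idx[k]]
      if (b %in% colnames(alt)) chars[idx[k]] <- alt[pick[k], b]
    }
  }
  # indels
  kept <- rep(TRUE, L)
  ins_len <- integer(L + 1L) # insertions emitted after old position i (0 = before start)
  ins_str <- character(L + 1L)
  init <- which(runif(L) < params$indel_prob * fac)
  n_ins <- 0L; n_del <- 0L
  for (i in init) {
    len <- rgeom(1L, 1 / params$indel_mean_len) + 1L
    if (runif(1) < 0.5) { # deletion starting at i
      kept[i:min(i + len - 1L, L)] <- FALSE
      n_del <- n_del + 1L
    } else { # insertion after i
      content <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      ins_len[i + 1L] <- ins_len[i + 1L] + len
      ins_str[i + 1L] <- paste0(ins_str[i + 1L], paste(content, collapse = ""))
      n_ins <- n_ins + 1L
    }
  }
  contrib <- as.integer(kept) + ins_len[-1L]
  before <- ins_len[1L] + c(0L, cumsum(contrib)[-L]) # chars emitted before base i
  map <- ifelse(kept, before + 1L, NA_integer_)
  pieces <- character(2L * L + 1L)
  pieces[1L] <- ins_str[1L]
  pieces[seq(2L, 2L * L, by = 2L)] <- ifelse(kept, chars, "")
  pieces[seq(3L, 2L * L + 1L, by = 2L)] <- ins_str[-1L]
  newseq <- paste(pieces, collapse = "")
  if (!nzchar(newseq)) stop("branch deleted the entire sequence")
  list(record = seq_record(id, newseq, species = id),
       map = as.integer(map), n_sub = sum(sub_here),
       n_ins = n_ins, n_del = n_del)
}

#' Carry an interval through a branch coordinate map
#'
#' @param iv A [genomic_interval()] in the old coordinates.
#' @param map Old-to-new coordinate map from [evolve_branch()].
#' @param seq_id Sequence id for the remapped interval.
#' @return The remapped [genomic_interval()], or `NULL` if every base of the
#'   interval was deleted.
#' @export
remap_interval <- function(iv, map, seq_id = iv$seq_id) {
  vals <- map[iv$start:iv$end]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NULL)
  genomic_interval(seq_id, min(vals), max(vals), strand = iv$strand,
                   frame = "absolute")
}

compose_maps <- function(m1, m2) {
  out <- rep(NA_integer_, length(m1))
  ok <- !is.na(m1)
  out[ok] <- m2[m1[ok]]
  out
}

#' Simulate a promoter clade with a constrained element
#'
#' Evolves an ancestral upstream region independently along each branch of a
#' star tree, or edge-by-edge down a balanced binary tree, with one embedded
#' element under strong constraint (the planted ECR). Truth coordinates of
#' the element in every species are carried through the branch coordinate
#' maps. The default element is 505 nt placed as in a typical upstream ECR
#' (ending ~1.1 kb upstream of the 3' end, which stands for the TSS).
#'
#' @param n_species Number of extant species (>= 2).
#' @param tree_shape `"star"` or `"balanced"`.
#' @param ancestor_len Ancestral sequence length.
#' @param element Absolute [genomic_interval()] on the ancestor, or `NULL`
#'   for the default placement.
#' @param params An [evolution_params()]; `constraint_factor` applies inside
#'   the element.
#' @param gc Ancestral GC content.
#' @param branch_scales Optional per-species multipliers on `sub_prob` and
#'   `indel_prob` (star shape only), emulating unequal divergence across a
#'   clade.
#' @return An object of class `clade_truth`: `records` (named list),
#'   `element_intervals` (named list, NULL where deleted), `maps`
#'   (ancestor-to-species coordinate maps), `tree` (newick), `ancestor`,
#'   `ancestor_element`, `params`, and per-branch realized event counts
#'   (`branch_log`).
#' @export
simulate_clade <- function(n_species, tree_shape = c("star", "balanced"),
                           ancestor_len = 5000L, element = NULL,
                           params = evolution_params(), gc = 0.45,
                           branch_scales = NULL) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_species >= 2L)
  anc <- simulate_ancestor(ancestor_len, gc, seed = params$seed)
  if (is.null(element)) {
    if (ancestor_len >= 1700L) {
      # rel -1642..-1138 with the TSS immediately 3' of the sequence end
      element <- genomic_interval(anc$id, ancestor_len + 1L - 1642L,
                                  ancestor_len + 1L - 1138L)
    } else {
      # short ancestors: a quarter-length element at three quarters in
      len <- max(100L, round(ancestor_len / 4))
      e_end <- round(0.75 * ancestor_len)
      element <- genomic_interval(anc$id, e_end - len + 1L, e_end)
    }
  }
  stopifnot(element$start >= 1L, element$end <= ancestor_len)
  species_ids <- sprintf("sp%02d", seq_len(n_species))
  records <- list(); maps <- list(); logs <- list()

  if (tree_shape == "star") {
    if (is.null(branch_scales)) branch_scales <- rep(1, n_species)
    stopifnot(length(branch_scales) == n_species)
    for (k in seq_len(n_species)) {
      pk <- params
      pk$sub_prob <- min(params$sub_prob * branch_scales[k], 0.95)
      pk$indel_prob <- min(params$indel_prob * branch_scales[k], 0.95)
      ev <- evolve_branch(anc, pk, constraint_mask = list(element),
                          seed = derive_seed(params$seed, 100L + k),
                          id = species_ids[k])
      records[[species_ids[k]]] <- ev$record
      maps[[species_ids[k]]] <- ev$map
      logs[[species_ids[k]]] <- data.frame(
        species = species_ids[k], n_sub = ev$n_sub, n_ins = ev$n_ins,
        n_del = ev$n_del, final_length = nchar(ev$record$sequence))
    }
    tree <- paste0("(", paste0(species_ids, ":1", collapse = ","), ");")
  } else {
    counter <- new.env()
    counter$k <- 0L
    counter$edge <- 0L
    descend <- function(rec, map, n_leaves) {
      counter$edge <- counter$edge + 1L
      ev <- evolve_branch(rec, params,
                          constraint_mask = list(remap_or_die(element, map)),
                          seed = derive_seed(params$seed, 200L + counter$edge),
                          id = paste0("node", counter$edge))
      new_map <- compose_maps(map, ev$map)
      if (n_leaves == 1L) {
        counter$k <- counter$k + 1L
        id <- species_ids[counter$k]
        rec2 <- ev$record; rec2$id <- id; rec2$species <- id
        records[[id]] <<- rec2
        maps[[id]] <<- new_map
        logs[[id]] <<- data.frame(species = id, n_sub = ev$n_sub,
                                  n_ins = ev$n_ins, n_del = ev$n_del,
                                  final_length = nchar(rec2$sequence))
        return(paste0(id, ":1"))
      }
      n_left <- n_leaves %/% 2L
      left <- descend(ev$record, new_map, n_left)
      right <- descend(ev$record, new_map, n_leaves - n_left)
      paste0("(", left, ",", right, "):1")
    }
    remap_or_die <- function(iv, map) {
      # identity map for the root call
      if (is.null(map)) return(iv)
      out <- remap_interval(iv, map)
      if (is.null(out)) stop("constrained element fully deleted on an internal branch")
      out
    }
    id_map <- seq_len(ancestor_len)
    n_left <- n_species %/% 2L
    left <- descend(anc, id_map, n_left)
    right <- descend(anc, id_map, n_species - n_left)
    tree <- paste0("(", left, ",", right, ");")
  }

  element_intervals <- lapply(species_ids, function(id) {
    remap_interval(element, maps[[id]], seq_id = id)
  })
  names(element_intervals) <- species_ids
  structure(list(
    records = records, element_intervals = element_intervals, maps = maps,
    tree = tree, ancestor = anc, ancestor_element = element, params = params,
    motif_intervals = NULL, branch_log = do.call(rbind, logs)
  ), class = "clade_truth")
}

#' @export
print.clade_truth <- function(x, ...) {
  cat(sprintf("<clade_truth> %d species, ancestor %d nt, element %d..%d\n",
              length(x$records), nchar(x$ancestor$sequence),
              x$ancestor_element$start, x$ancestor_element$end))
  invisible(x)
}

#' Simulate the reference eutherian-like study clade
#'
#' A 16-species star clade over a 5 kb ancestral upstream region with the
#' default 505-nt constrained element, using graded per-species branch
#' scales (0.6x to 6.5x on base rates: substitution 0.30, indel 0.02,
#' constraint factor 0.1). The grading emulates a real mammalian cohort in
#' which near relatives retain ~97% element identity while the most diverged
#' members fall to ~80% and their backgrounds become unalignable.
#'
#' @param n_species Number of species (default 16).
#' @param seed Integer seed.
#' @return A `clade_truth` (see [simulate_clade()]).
#' @export
simulate_reference_clade <- function(n_species = 16L, seed = 1L) {
  simulate_clade(
    n_species, "star", ancestor_len = 5000L,
    params = evolution_params(sub_prob = 0.30, indel_prob = 0.02,
                              constraint_factor = 0.1, seed = seed),
    branch_scales = seq(0.6, 6.5, length.out = n_species)
  )
}

#' Simulate a diverged species pair with one constrained element
#'
#' Convenience wrapper around [simulate_clade()] for pairwise benchmarks:
#' each lineage diverges from the common ancestor with per-site substitution
#' probability `background_divergence` outside the element and
#' `element_divergence` inside it (so, e.g., 0.30/0.05 gives a pairwise
#' background identity near 50% against an element identity near 90% —
#' a clearly separable conserved element in a diverged background).
#'
#' @param background_divergence Per-lineage, per-site substitution
#'   probability outside the element.
#' @param element_divergence Per-lineage, per-site substitution probability
#'   inside the element.
#' @param element_len Element length in nt.
#' @param ancestor_len Ancestral sequence length.
#' @param indel_prob Per-site, per-branch indel initiation probability.
#' @param seed Integer seed.
#' @return A `clade_truth` with two species (`sp01`, `sp02`).
#' @export
simulate_pair <- function(background_divergence = 0.30,
                          element_divergence = 0.05,
                          element_len = 400L, ancestor_len = 5000L,
                          indel_prob = 0.005, seed = 1L) {
  stopifnot(element_divergence <= background_divergence,
            element_len < ancestor_len)
  e_end <- round(0.75 * ancestor_len)
  element <- genomic_interval("ancestor", e_end - element_len + 1L, e_end)
  simulate_clade(
    2L, "star", ancestor_len = ancestor_len, element = element,
    params = evolution_params(
      sub_prob = background_divergence,
      indel_prob = indel_prob,
      constraint_factor = element_divergence / background_divergence,
      seed = seed)
  )
}

#' Plant motif instances into a simulated clade
#'
#' Writes the PWM's consensus string at non-overlapping ancestral positions —
#' `n_inside` within the constrained element and `n_outside` in the
#' background — and stamps it into every species at the homologous mapped
#' position, so planted sites are conserved by construction and their truth
#' coordinates are exact. `conserve_flanks` nucleotides of ancestral context
#' on each side are stamped along with the motif, emulating the locally
#' constrained neighbourhood in which functional binding sites sit (without
#' it, a site planted in a diverged background would always fail a
#' flank-conservation filter). With `outside_mode = "species_specific"` the
#' background instances are instead placed independently per species (not
#' homologous), for tests that need non-conserved background sites.
#'
#' @param clade A [simulate_clade()] result.
#' @param pwm A [pwm()]; its consensus string is planted.
#' @param n_inside,n_outside Number of instances inside/outside the element.
#' @param seed Integer seed.
#' @param conserve_flanks Nucleotides of homologous ancestral context
#'   stamped on each side of every planted motif (default 10).
#' @param outside_mode `"homologous"` or `"species_specific"`.
#' @return The clade with sequences modified and `motif_intervals` set: a
#'   named list of data frames (`start`, `end`, `inside`) per species.
#' @export
plant_motifs <- function(clade, pwm, n_inside, n_outside = 0L, seed = 1L,
                         conserve_flanks = 10L,
                         outside_mode = c("homologous", "species_specific")) {
  stopifnot(inherits(clade, "clade_truth"), inherits(pwm, "pwm"))
  outside_mode <- match.arg(outside_mode)
  W <- pwm$width
  motif <- pwm_consensus(pwm)
  el <- clade$ancestor_element
  if (n_inside * W > interval_length(el)) {
    stop("element too short for ", n_inside, " non-overlapping motifs of width ", W)
  }
  set.seed(derive_seed(seed, 3L))
  place <- function(lo, hi, n, taken) {
    # greedy non-overlapping placement in [lo, hi]
    got <- integer(0)
    cand <- sample(lo:(hi - W + 1L))
    for (p in cand) {
      if (length(got) == n) break
      if (!any(abs(c(got, taken) - p) < W)) got <- c(got, p)
    }
    if (length(got) < n) stop("insufficient room to place ", n, " motifs")
    sort(got)
  }
  anc_len <- nchar(clade$ancestor$sequence)
  inside_pos <- if (n_inside > 0L) place(el$start, el$end, n_inside, integer(0)) else integer(0)
  outside_anc <- integer(0)
  if (n_outside > 0L && outside_mode == "homologous") {
    # background positions clear of the element
    cand_lo <- 1L; cand_hi <- anc_len
    repeat_taken <- c(inside_pos, seq.int(el$start - W + 1L, el$end))
    outside_anc <- place(cand_lo, cand_hi, n_outside, repeat_taken)
  }

  stamp <- function(seqstr, pos, what) {
    substr(seqstr, pos, pos + nchar(what) - 1L) <- what
    seqstr
  }
  anc_seq0 <- clade$ancestor$sequence
  motif_tables <- list()
  for (id in names(clade$records)) {
    map <- clade$maps[[id]]
    s <- clade$records[[id]]$sequence
    L <- nchar(s)
    placed <- integer(0)
    rows <- list()
    for (p in c(inside_pos, outside_anc)) {
      # homologous position: leftmost surviving base of the footprint
      m <- map[p:(p + W - 1L)]
      m <- m[!is.na(m)]
      if (length(m) == 0L) next
      q <- min(m)
      if (q + W - 1L > L) next
      # ancestral context on both sides, clipped to both sequences
      fl <- min(conserve_flanks, p - 1L, q - 1L)
      fr <- min(conserve_flanks, anc_len - (p + W - 1L), L - (q + W - 1L))
      patch <- paste0(substr(anc_seq0, p - fl, p - 1L), motif,
                      substr(anc_seq0, p + W, p + W - 1L + fr))
      s <- stamp(s, q - fl, patch)
      placed <- c(placed, q)
      rows[[length(rows) + 1L]] <- data.frame(
        start = q, end = q + W - 1L, inside = p %in% inside_pos)
    }
    # re-stamp cores in case a later patch overwrote an earlier motif
    for (q in placed) s <- stamp(s, q, motif)
    if (outside_mode == "species_specific" && n_outside > 0L) {
      el_sp <- clade$element_intervals[[id]]
      taken <- vapply(rows, function(r) r$start, integer(1))
      avoid <- c(taken, seq.int(max(1L, el_sp$start - W + 1L), el_sp$end))
      pos_sp <- place(1L, L, n_outside, avoid)
      for (q in pos_sp) {
        s <- stamp(s, q, motif)
        rows[[length(rows) + 1L]] <- data.frame(start = q, end = q + W - 1L,
                                                inside = FALSE)
      }
    }
    clade$records[[id]]$sequence <- s
    motif_tables[[id]] <- do.call(rbind, rows)
  }
  # keep the ancestor consistent with homologous planting
  anc_seq <- clade$ancestor$sequence
  for (p in c(inside_pos, outside_anc)) anc_seq <- stamp(anc_seq, p, motif)
  clade$ancestor$sequence <- anc_seq
  clade$motif_intervals <- motif_tables
  clade$planted <- list(inside = inside_pos, outside = outside_anc, width = W,
                        pwm_name = pwm$name)
  clade
}

#' Write a simulated clade to disk
#'
#' Emits the species FASTA, a truth BED of element (and any motif)
#' intervals, the newick tree and a per-branch event-count TSV.
#'
#' @param clade A [simulate_clade()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_clade <- function(clade, dir, prefix = "clade") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, paste0(prefix, ".fasta")),
             bed = file.path(dir, paste0(prefix, "_truth.bed")),
             tree = file.path(dir, paste0(prefix, ".nwk")),
             log = file.path(dir, paste0(prefix, "_branches.tsv")))
  write_fasta(clade$records, paths["fasta"])
  ivs <- list(); nm <- character(0)
  for (id in names(clade$element_intervals)) {
    iv <- clade$element_intervals[[id]]
    if (!is.null(iv)) { ivs <- c(ivs, list(iv)); nm <- c(nm, "element") }
  }
  if (!is.null(clade$motif_intervals)) {
    for (id in names(clade$motif_intervals)) {
      mt <- clade$motif_intervals[[id]]
      if (is.null(mt)) next
      for (i in seq_len(nrow(mt))) {
        ivs <- c(ivs, list(genomic_interval(id, mt$start[i], mt$end[i])))
        nm <- c(nm, if (mt$inside[i]) "motif_inside" else "motif_outside")
      }
    }
  }
  write_bed(ivs, paths["bed"], names = nm, scores = 0)
  writeLines(clade$tree, paths["tree"])
  write_tsv_report(clade$branch_log, paths["log"])
  invisible(paths)
}
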