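---
title: "Detecting conserved upstream elements: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved upstream elements: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecrtools)
```

## The problem

Regulatory elements that control a gene's expression are often detectable as
evolutionarily conserved regions (ECRs): stretches of non-coding sequence
whose identity between species far exceeds the surrounding background.
`ecrtools` implements the comparative-genomics workflow used to locate such
elements upstream of a promoter across a mammalian clade:

1. **Pairwise conservation profiling** — sliding-window percent identity
   over a global alignment of two species' upstream regions, with
   conserved-block calling at two presets: ordinary blocks at ≥ 75%
   identity over a 100-nt window, and long, highly conserved core regions
   ("CoreECRs") at ≥ 77% over a 350-nt window.
2. **Chunked homology search** — the query split into sequential 500-nt
   sections, each locally aligned against the full upstream region of
   another species on both strands, so that genomic insertions or deletions
   between lineages shift rather than destroy per-section matches.
3. **Minimal shared ECR and consensus** — full-length ECRs from every
   species progressively aligned; the intersection of their aligned
   coverage is the minimal shared ECR (minECR); a case-encoded consensus
   (uppercase = unanimous, lowercase = strict majority, `n` = no majority,
   `.` = gap-plurality column) summarizes it, with per-species identity
   statistics.
4. **Conservation-filtered TFBS analysis** — PWM scanning of both species,
   with a site kept only when its aligned partner carries the same motif in
   the same orientation and the 20-column alignment window centered on the
   site passes a flank-identity threshold; conserved sites are then
   partitioned against the core region.

Every stage is exercisable without genome downloads through a bundled
sequence-evolution simulator that plants a constrained element (and,
optionally, motif instances) with known truth coordinates.

## Coordinate conventions

Coordinates are 1-based and fully closed throughout (`length = end − start
+ 1`), matching the way genome accession tables print feature locations; a
505-nt element printed as −1642..−1138 satisfies this arithmetic exactly.
TSS-relative numbering has no position 0: −1 is the base immediately 5′ of
the transcription start site, and relative −n maps to `tss_abs − n` on a
plus-strand gene (`tss_abs + n` on minus). Minus-strand table rows listed
with descending coordinates are normalized to ascending starts with strand
`-`. Only BED export deviates: BED is written (and read back) 0-based
half-open, per the format's convention.

## Alignment engine

Pairwise alignment is exact affine-gap dynamic programming implemented in
C++ (global Needleman–Wunsch–Gotoh and local Smith–Waterman), not a seeded
heuristic: inputs are promoter-scale (≤ ~10 kb), so the O(nm) matrix is
affordable and exactness buys reproducibility. The scoring default
(+2/−3, gap open −5, gap extend −2, a gap run of length L scoring
`gap_open + L·gap_extend`) mirrors classic nucleotide-BLAST-style scoring.
Traceback ties are broken in a fixed order — diagonal, then gap in the
second sequence, then gap in the first — so co-optimal alignments resolve
deterministically. `N` never matches anything. There is no E-value
machinery; chunk-level significance is a minimum identity (default 0.60)
plus a minimum score (default 50), which keeps the tool free of
database-composition assumptions. Because of that, absolute per-section
identities approximate rather than reproduce what a BLAST-based analysis
would print.

The progressive multiple aligner builds a UPGMA guide tree from pairwise
6-mer count distances and merges profiles up the tree with the same affine
scheme (profile columns scored by expected substitution score; existing gap
characters contribute zero). It is a deterministic stand-in for a
general-purpose MSA program: it honors the alignment contract the consensus
stage needs (rows ungap to their inputs; substitution-only divergence
yields gapless alignments) without reproducing any particular program's
objective function.

## Block calling and boundary refinement

Windows are anchored on reference-sequence positions, not alignment
columns, so called blocks are directly reportable in reference coordinates.
A window's identity is matching columns divided by **all** alignment
columns it spans — insertions in either species count against identity,
since the underlying tools do not document their gap rule and this is the
conservative choice.

A candidate block is a maximal run of passing windows with overlapping or
touching extents. Raw extent unions systematically overshoot a conserved
element: a 350-nt window that only partially overlaps the element can still
pass, extending the called block by up to a window length on each side. We
therefore trim each candidate to its maximal-scoring subsegment under
per-position scores `match − min_identity` (a classic maximal-segment
refinement): background positions score negative on average, element
positions positive, so boundaries land where conservation actually drops
through the threshold. This reproduces the tight printed-style boundaries
(a ~500-nt core from a 350-nt window) and is the package's deliberate
deviation from reporting raw window extents; `refine_boundaries = FALSE`
restores the raw behavior. A refined block can be shorter than the window
that discovered it — the window is the detection instrument, not a lower
bound on the element.

`core_ecr()` applies the strict preset and returns the single
highest-mean-identity block, ties broken by length then by smaller start.

## Consensus rules

Per column of the shared span, the gap rule applies first: if gaps occupy
at least half of all rows the column is `.` and contributes to
`alignment_length` but not `consensus_length`. Otherwise, counting only
non-gap residues: unanimity gives the uppercase base, a strict majority
(> 50%) the lowercase base, anything else `n`. Per-species identity to the
consensus is computed over residue columns only (`n`/`.` excluded from
numerator and denominator); `identity_mode = "strict"` instead counts those
columns as mismatches, for sensitivity analysis, since the original
consensus tool does not document its denominator. A row gap at a residue
column is always a mismatch. The median of an even species count is the
midpoint of the two central values.

## TFBS scanning, flank filter, and affinity

PWM scores are log2 odds of pseudocount-regularized frequencies against
the background; a hit's `relative_score` normalizes between the minimum and
maximum attainable sums, with default threshold 0.85 (match thresholds of
the proprietary matrix libraries are unpublished; 0.85 is a conventional
stringent choice). `N` contributes the background expectation (zero).

A reference hit is *conserved* when its aligned image in the second species
overlaps a same-PWM, same-orientation hit and the 20 alignment columns
centered on the site midpoint reach ≥ 0.80 identity. The 20-column window
is the documented part of the rule; the 0.80 cutoff is our interpretation
of "conserved context" and is exposed as a parameter. Conserved sites are
partitioned against the single core region — the inside/outside question
the original analysis asks of its minECR — while ordinary blocks annotate
each site's containing block.

Occupancy-style affinity follows the biophysical binding model: each offset
contributes `p = R0·e^(−E/λ)/(1 + R0·e^(−E/λ))` with mismatch energy `E`
the summed log-ratio of best to observed base frequency, `λ = 0.7`, and
`R0 = exp(0.584·W − 5.66)` — the model's published defaults, adopted as-is
because only the tool, not its settings, is named in the analyses this
package follows. Multiple-testing correction uses the standard
Benjamini–Hochberg step-up (via `stats::p.adjust`).

## The simulator: what it emulates, and what it does not

`simulate_clade()` evolves an i.i.d. ancestor (default 5 kb, GC 0.45 — the
GC content typical of the upstream regions this pipeline targets) along a
star or balanced tree with per-branch, per-site substitution and
indel-initiation probabilities; indel lengths are geometric (mean 3) and
insertions are background-composition. One embedded interval (default
505 nt, ending ~1.1 kb upstream of the 3′ end, which stands for the TSS)
evolves under a constraint factor (default 0.1) multiplying both
probabilities. Strictly monotone coordinate maps carry truth intervals
through every branch.

Key calibration choices, fixed a priori:

* **Divergences are per lineage.** "Background divergence 0.30" means each
  species substitutes 30% of sites from the ancestor (pairwise background
  identity ≈ 0.52, element identity ≈ 0.90 at element divergence 0.05).
  Read as a *pairwise* total instead, background identity (~0.73) would sit
  on top of the 0.75/0.77 calling thresholds and the benchmark would be
  uninformative.
* **The 16-species reference clade** (`simulate_reference_clade()`) uses a
  star tree with branch scales 0.6×–6.5× on base rates (substitution 0.30,
  indel 0.02, constraint 0.1), emulating a real cohort's spread: near
  relatives retain ~97% element identity, the most diverged drop toward
  ~80%, and distant backgrounds become unalignable.
* **Planted motifs are stamped homologously** (PWM consensus written at the
  mapped ancestral position in every species) together with 10 nt of
  ancestral flanking context, because functional binding sites sit in
  locally constrained neighbourhoods; without conserved flanks, a site in a
  30%-per-lineage background could never pass a 20-column/0.80 flank rule
  and the inside/outside benchmark would degenerate. Ten nucleotides cover
  the flank window without giving a 100-nt window enough identical sequence
  to call a spurious block. `outside_mode = "species_specific"` provides
  deliberately non-conserved background sites for discrimination tests.

The simulator does **not** model context-dependent mutation (CpG
transitions), repeat insertions, heterogeneous selection within the
element, or empirical indel spectra. Passing the planted-truth benchmarks
therefore demonstrates that the pipeline's detection logic is correct under
its own statistical assumptions — clean constraint in an i.i.d. background
— not that real-genome complications (repeats, assembly gaps, alignment
ambiguity near tandem duplications) are handled.

## Problem sizes and determinism

The bundled analyses and acceptance checks run at promoter scale: 5-kb
regions, a 16-species clade, 50 simulated pairs for element recovery and 20
for the TFBS partition — sizes chosen so the complete suite executes in a
few minutes on a single CPU while leaving the stochastic benchmarks enough
replicates to be stable. All randomness flows from one integer seed through
deterministic sub-seed derivation; identical seeds give byte-identical
FASTA/BED/TSV outputs.

## Known limitations

* Chunk-level identities depend on the exact aligner and scoring, so they
  approximate, not reproduce, values a BLAST-based analysis prints.
* The progressive aligner is not a drop-in for MUSCLE/MAFFT on hard cases
  (many long indels, repeats); for promoter-scale ECRs it is adequate and
  deterministic.
* Boundary placement of called blocks depends on the refinement rule;
  window-extent boundaries (the `refine_boundaries = FALSE` behavior) can
  differ by up to a window length per side.
* The flank-conservation cutoff (0.80) and PWM threshold (0.85) are
  interpretations of under-documented tool settings; conclusions about
  marginal sites should be checked across a range of both.

## A worked run

```{r example, eval = FALSE}
library(ecrtools)

cl <- simulate_pair(background_divergence = 0.30, element_divergence = 0.05,
                    element_len = 400, seed = 1)
res <- run_profile(cl$records$sp01, cl$records$sp02, out_dir = "profile_out")
res$core
interval_jaccard(res$core$interval, cl$element_intervals$sp01)
```

The numbered scripts under `analysis/` run the full set of analyses
(simulation, profiling, chunked search, minECR consensus, TFBS filtering)
and write their tables under `results/`; `scripts/acceptance.R` recomputes
the headline quantities from scratch.
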