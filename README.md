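# ecrtools

Comparative-genomics detection of evolutionarily conserved regions (ECRs)
in promoter sequences, for researchers mapping candidate *cis*-regulatory
elements upstream of a gene across a mammalian clade.

Non-coding sequence that regulates transcription tends to evolve under
constraint, so it stands out as islands of high percent identity between
species whose neutral background has diverged. `ecrtools` implements the
full desk-side workflow around that signal:

* **Conservation profiling.** For a global alignment of two upstream
  regions, the identity of a sliding window of *w* reference nucleotides is
  `matches / alignment columns spanned` (gaps and N count against). Blocks
  are called where windows pass a threshold — ordinary ECRs at ≥ 75% over
  100 nt, long "CoreECRs" at ≥ 77% over 350 nt — and block boundaries are
  refined to the maximal-scoring subsegment under per-position scores
  `match − threshold`, so they land where conservation actually drops.
* **Chunked homology search.** The query is cut into sequential 500-nt
  sections, each locally aligned (affine-gap Smith–Waterman, both strands)
  against the full opposite region, so insertions/deletions between
  lineages shift rather than break per-section matches. Output is a
  per-section identity table across species.
* **Minimal shared ECR (minECR) and consensus.** Full-length ECRs from all
  species are progressively aligned (UPGMA guide tree on 6-mer distances,
  affine profile–profile merges); the intersection of per-row aligned
  coverage is the minECR; its consensus is case-encoded (uppercase =
  unanimous, lowercase = strict majority, `n` = no majority, `.` =
  gap-plurality column) with per-species identity statistics.
* **Conservation-filtered TFBS analysis.** PWM hits (log2-odds,
  relative score ≥ 0.85) are kept only when the aligned partner species
  carries the same motif in the same orientation and the 20 alignment
  columns around the site reach ≥ 80% identity; conserved sites are
  partitioned against the CoreECR. An occupancy-model affinity
  (`p = R0·e^(−E/λ)/(1+R0·e^(−E/λ))`, λ = 0.7, `R0 = exp(0.584·W − 5.66)`)
  and Benjamini–Hochberg correction support enrichment analyses.
* **A truth-known simulator.** Promoter clades are generated by per-branch
  substitution/indel evolution of a ~5-kb ancestor with one embedded
  element under constraint and optional planted motifs, with exact
  coordinate maps — every stage of the pipeline is benchmarked against
  planted truth without downloading genomes.

Coordinates are 1-based fully closed everywhere (TSS-relative numbering has
no position 0; −1 abuts the TSS); only BED export is 0-based half-open.

## Worked example

```r
library(ecrtools)

# A species pair: 30% per-lineage background divergence, a 400-nt element
# under strong constraint (5% divergence)
cl <- simulate_pair(background_divergence = 0.30, element_divergence = 0.05,
                    element_len = 400, seed = 1)
res <- run_profile(cl$records$sp01, cl$records$sp02, out_dir = "profile_out")
res$core
#> <conserved_block> CoreECR sp01:3345..3745 (401 nt), identity 0.913
interval_jaccard(res$core$interval, cl$element_intervals$sp01)
#> [1] 0.9975
```

The detected core region (401 nt at 91.3% identity) recovers the planted
element (truth 3346..3745) with positional Jaccard 0.998, while the
~52%-identity background yields no blocks. On the bundled 16-species
reference clade, the minECR stage reports (from
`analysis/04_minecr_consensus.R`):

```
Consensus length 472 nt (534 alignment columns including gaps)
Mean identity 91% (range: 85%-98%, median: 90%)
```

and the TFBS stage (`analysis/05_tfbs_conservation.R`), with 10 motifs
planted inside and 5 outside the element, recovers all 15 as conserved
sites and partitions them 10 inside / 5 outside the detected core
(fraction inside 0.667).

## Analysis workflow

The numbered scripts under `analysis/` are thin narrative drivers over the
package and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_clade.R` | generate the 16-species study clade + truth BED |
| `02_pairwise_profile.R` | profile a diverged pair, call blocks and the CoreECR |
| `03_chunked_search.R` | 500-nt section identities of the reference vs all species |
| `04_minecr_consensus.R` | extract ECRs, align, build the minECR consensus |
| `05_tfbs_conservation.R` | conserved-TFBS calling, partition, affinity enrichment |

Run each with `Rscript analysis/<script>` from the repository root.

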