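---
title: "Recovering reference-missing sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering reference-missing sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A reference genome assembled from one individual misses sequence that other
individuals of the species carry. Such *pan-sequences* — mostly
presence/absence variants (PAVs) — bias read mapping and variant calling for
every cohort member that carries them. When multiple de novo assemblies of
the focal species are unavailable, assemblies of closely related taxa can
stand in: at percent-scale divergence their copies of the missing segments
are still recognisable, recoverable, and correctable back to focal-species
alleles using the cohort's own short reads.

`panrecover` implements this strategy end to end at desk scale, together
with a seeded simulator that generates inputs with known planted truth, so
that every stage can be validated against ground truth rather than against
another tool's output.

## Pipeline model

1. **Comparison** (`align_assemblies`). A seed–chain–extend comparator:
   exact k-mer anchors unique in both genomes (default `k = 15`), collinear
   chaining by a longest-increasing-subsequence dynamic program with a
   per-axis gap bound (`max_gap = 2000` bp), and banded gap closure
   (match +1, mismatch −1, gap −2, band 200 bp). Greedy selection by
   descending match count with overlap trimming yields a 1:1 alignment —
   blocks mutually non-overlapping on both genomes. *Genomic divergence* is
   divergent (mismatch) columns over total 1:1 alignment length.
2. **Recovery** (`iterative_build`). Unaligned donor segments (≥ 400 bp)
   are shredded into 1 kb fragments and pass a two-stage cascade: a fast
   anchored stage removing fragments with ≥ 90% identity to the current
   pan-genome, then a sensitive exact local-alignment stage removing
   ≥ 95% identity hits. Survivors with contiguous donor coordinates merge
   back into segments, which are deduplicated by greedy clustering
   (longest first; join at ≥ 95% identity over ≥ 80% of the shorter
   sequence). Donors are added iteratively, most distant first; each round
   compares against the pan-genome built so far.
3. **Validation** (`naive_map`, `window_depth`, `retain_pansequences`).
   Cohort reads are placed by k-mer votes (`k = 21`). Depth is averaged in
   200 bp windows stepped by 100 bp; the *normalized read depth* (NRD) of a
   sequence is the median of its window depths over the individual's
   genome-wide median window depth. On this diploid scale homozygous
   presence ≈ 1, heterozygous ≈ 0.5, absent ≈ 0. Calls are present at
   NRD ≥ 0.4, absent at ≤ 0.2, ambiguous between; a pan-sequence is
   retained when at least two individuals call it present.
4. **Correction** (`iterate_correction`). Reads placed on each
   pan-sequence form a substitution-only pileup; at every position with
   depth ≥ 1 a strict majority base replaces the current base. Individuals
   are applied sequentially and passes repeat until a full pass makes no
   change (or `max_rounds` is hit).
5. **Analysis** (`pansize_K`, `discovery_curve`, `frequency_spectrum`,
   `cluster_individuals`). The total pan-genome size uses the transformed
   Watterson estimator `K = thetaL * a(n)`, `a(n) = 1 + 1/2 + ... + 1/n`,
   with `thetaL` the pairwise individual-specific sequence amount and `n`
   the effective population size. The expected discovery curve is
   `thetaL * a(n)` with per-genome increment `thetaL / n`.

## What the simulator emulates — and what it does not

`sim_config()` defines the synthetic study: an i.i.d. ancestor at 42% GC
(mammal-like), a reference derived by deleting 30 non-overlapping segments
of 0.5–20 kb placed at least 2 kb from contig ends (so flanks exist for
anchoring), donors with i.i.d. substitutions at configurable rates — the
defaults span the 0.21–2.18% range observed between closely related bovid
genomes — and a diploid cohort (20 individuals by default) whose haplotypes
carry each segment independently at its population frequency, sequenced as
uniform single-end 100 bp reads at 10× diploid coverage with 1% base error.
Per-segment frequencies default to draws from {0.1, 0.5, 0.9}, covering
rare, intermediate and common PAVs.

Deletions are placed by a spacing construction (the free interior is
divided uniformly around the segments), which always succeeds and is
deterministic under the seed; rejection sampling is hopeless when the
segments occupy a third of the genome. All randomness flows from one
master seed through named substreams (`ancestor`, `deletions`, `donor1`,
`genotypes`, `reads7`, ...), so any stage regenerates independently.

Real data differ in ways the simulator deliberately omits: indel and
rearrangement divergence (donors are substitution-only; the comparator is
forward-strand and the recovery pipeline excludes translocations and
inversions by construction), repeats and segmental duplications (the
ancestor is i.i.d., so k-mer uniqueness is near-total and mapping
ambiguity minimal), relatedness structure and variable coverage in the
cohort, and base-quality structure in the reads. Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
performance on repeat-rich mammalian genomes.

## Numerical and design choices

- **Identity definition.** `n_matches / n_columns` with gap columns
  counted in the denominator, the BLAST-style convention the filter
  thresholds assume. Divergent sites exclude gap columns.
- **1:1 overlap resolution.** A lower-scoring block overlapping a kept
  block is trimmed to its largest overlap-free remainder (both axes
  trimmed together under a near-diagonal assumption) and kept if ≥ 50
  columns survive; column counts scale proportionally. Trimming rather
  than dropping preserves alignment length for the divergence denominator.
- **Cascade stage 2 scope.** Stage-2 identity is computed over the locally
  aligned region, and a removal additionally requires the alignment to
  cover ≥ 50% of the fragment — otherwise a short spurious local hit could
  delete a genuinely novel fragment. Stage 1 requires ≥ 10 k-mer votes to
  count as a hit; stage 2 re-examines anything with any hit at all, which
  is the sensitivity role of the second filter.
- **Merge rule.** Fragments merge only at strictly contiguous donor
  coordinates (gap 0). Bridging across a dropped fragment risks chimeric
  segments; strictness costs at most one fragment length at a boundary.
- **Dedupe determinism.** Segments are processed longest first with ties
  broken lexicographically by identifier.
- **NRD scale.** The numerator is the *median* of window depths (robust to
  edge windows); the denominator is the diploid genome-wide median, the
  only scale on which the 0.4/0.2 thresholds are coherent
  (heterozygote ≈ 0.5 > 0.4 > noise). Ambiguous calls become `NA` in the
  PAV matrix rather than 0, keeping intermediate (divergent-allele-like)
  evidence distinct from absence.
- **Window tiling.** Full 200 bp windows at 100 bp steps; a ≥ 100 bp tail
  becomes its own window, a shorter tail extends the last window, so
  windows always tile `[0, L)`.
- **Correction convergence.** With 1% read error and minimum depth 1, an
  isolated position covered by a single erroneous read in one individual
  can flip under that individual and flip back under the next — the
  per-individual scheme then has no cohort-level fixed point. The module
  caps passes (`max_rounds`, default 2) and reports convergence honestly;
  on error-free evidence it converges and re-running changes nothing. The
  change log records every substitution with depth and majority fraction.
- **Clustering distance.** Simple matching (mean per-segment
  disagreement) rather than Jaccard, by design: Jaccard ignores shared
  absences, so members of a low-frequency population (e.g. segment
  frequency 0.1) are farther from *each other* (≈ 0.95) than from a
  high-frequency population (≈ 0.90), and no tree cut can separate the
  groups. Simple matching keeps both populations cohesive and separates
  the 0.8-vs-0.1 two-population design perfectly. Jaccard remains
  available (`distance = "jaccard"`), as does complete linkage.
- **Harmonic convention.** `pansize_K` implements `a = H_n` with `n` the
  effective population size, exactly as the transformed estimator is
  stated; classic Watterson theory sums `H_{n-1}` over sampled
  chromosomes, available via `convention = "n-1"`. At `n ≈ 10^4` the
  difference (≈ 10^-4) is far below the one-decimal reporting precision.
- **Identifier convention.** `contig_start_end-Species` with half-open
  coordinates, so length = end − start; parsing takes the rightmost two
  numeric fields, letting accession-style contig names containing
  underscores round-trip.

## Problem sizes

The test suite exercises the full pipeline on a 1 Mb ancestor with 30
planted deletions, one donor at 1% divergence and 20 individuals at 10×
(about 2 million reads), the scale at which every stage's statistical
behaviour (binomial bounds on divergence, NRD class separation, ≥ 99%
divergence-site correction) is measurable in a few minutes on one CPU.
Unit tests use 10–200 kb sequences; exhaustive oracles (subset enumeration
for chaining and 1:1 selection, all-pairs local alignment for dedupe) run
on instances of at most 15 anchors, 10 blocks or 10 segments.

## Known limitations

Forward-strand, substitution-only comparison; no repeat masking or
mapping-quality model; k-mer vote mapping discards multi-mapping reads
rather than distributing them; the dedupe identity comes from the
package's own chained aligner, which on borderline pairs can differ from
an optimal local alignment by a fraction of a percent; `thetaL` and the
effective population size are inputs, not estimates. None of these affect
the synthetic validation surface, but all would matter on real
mammal-scale data.
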