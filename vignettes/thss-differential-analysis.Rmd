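---
title: "Differential Tn5 hypersensitive site analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential Tn5 hypersensitive site analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thssdiff)
```

thssdiff analyses chromatin accessibility (ATAC-seq) differences between
two conditions — labelled HD (Huntington's disease model) and WT — across
differentiation stages, and integrates them with differential gene
expression. This vignette is the package's account of the statistical
procedures, the choices behind them, and what the synthetic-data tests do
and do not demonstrate.

## Fragment preprocessing

ATAC-seq fragment ends mark Tn5 insertion points. Because the transposase
binds as a dimer and duplicates 9 bp of target sequence, the conventional
correction shifts plus-strand cut sites by +4 bp and minus-strand cut
sites by −5 bp (`shift_tn5()`); every retained fragment shortens by 9 bp,
and fragments whose corrected interval would be empty are dropped and
counted in the QC log rather than raised as errors — at genome scale a
handful of degenerate fragments should never abort a run.

Fragments are then classified by corrected length
(`classify_fragment_length()`): sub-nucleosomal fragments (< 125 bp)
arise from protein-bound, nucleosome-free DNA and define Tn5
hypersensitive sites (THSSs); mononucleosome fragments (171–254 bp,
boundaries inclusive) span one nucleosome and drive the promoter
occupancy analysis. All interval arithmetic is 0-based half-open (the BED
convention, which is also the native I/O format); GTF input is converted
on read.

## Differential accessibility

Per stage, each condition's replicates are checked for agreement
(Pearson correlation of log2(count+1) over the peak set,
`replicate_correlation()`) and pooled. Fragments are counted per peak
with ≥ 1 bp overlap; a fragment spanning two peaks counts for both, and
the library size is the total fragment count, not the in-peak sum.

Two pooled samples are compared MAnorm-style. Over peaks present in both
samples ("common" peaks — the biological assumption being that shared
open regions are mostly unchanged), we fit

  M = log2((x₁+0.5)/(x₂+0.5)) against A = ½·log2((x₁+0.5)(x₂+0.5))

with Huber-weighted IRLS (`MASS::rlm`, 20 iterations, tolerance 1e−8).
The intercept absorbs the library-scale bias (≈ −log2 of the scale
factor), the slope any intensity-dependent trend. Sample 2 is rescaled by
2^(intercept + slope·A); the +0.5 pseudocount keeps logs finite at zero
counts. Hitting the iteration cap is deliberate behaviour, not a
failure: the capped fit is used as-is.

Each peak is then tested with a two-sided exact binomial test of
round(x₁) successes in round(x₁) + round(x₂′) trials at probability ½
(round-half-even, for determinism). This is the natural exact test when
counting noise is Poisson with a peak-specific intensity shared between
the two samples — conditioning on the total makes the null distribution
exactly binomial regardless of how intensities vary across peaks.
p-values are BH-adjusted within each stage.

The compound selection rule keeps a peak when logCPM > 1 **and**
(q < 0.01 **or** |logFC| > 3 with p < 0.01); peaks on the chr2a/chr2b
assembly-duplication chromosomes are excluded. "logCPM averaged over the
conditions" is implemented as log2 of the mean of the two samples' CPM
(edgeR-style, not the mean of the logs — an assumption, flagged here).
Direction follows the sign of the normalized logFC (HD_up = more
accessible in HD).

Promoter nucleosome occupancy runs the identical count → normalize →
test → select machinery over 2-kb windows centred at every TSS, using
mononucleosome fragments.

Numerical notes: the exact binomial test is discrete, hence
conservative at shallow depth — with ~200 pooled counts per peak its
realized size at α = 0.05 is ≈ 0.040. Calibration checks in the test
suite therefore run at a pooled depth of ~2000 counts per peak, where
the achievable significance levels are dense and the realized size
matches the nominal level within Monte-Carlo error; the selection
criteria themselves are applied at the generator's default depth.

## Motif analysis

Motifs are position weight matrices read from MEME minimal files
(probability rows off by ≤ 1e−3 are renormalized; worse is an error).
Scoring uses integer-discretized log-odds (1/1000 bit granularity)
against a 0-order background, with a small pseudo-probability (1e−3,
background-proportional) blended into the matrix so zero cells stay
finite. The exact null distribution of the score — and hence an exact
match p-value — is computed by position-wise convolution
(`score_pvalue_table()`), the same construction FIMO uses; tests verify
it against brute-force enumeration of all words up to length 6.

Each peak's window (± 200 bp around the summit) is scanned on both
strands (`scan_peak_windows()`; the minus strand gets its own null
table, so no strand-symmetry assumption is made); positions containing N
are skipped; hits at p ≤ 1e−4 (FIMO's default threshold; the choice is
configurable) are kept, and per peak only the most significant motif
survives (`best_hit_per_peak()`, ties broken deterministically by score,
offset, strand, motif id). Deduplication happens once per peak, before
the proximal/distal split.

Enrichment uses the literal nested contingency: for motif X and, say,
HD-up peaks in one context,

  N11 = HD-up peaks whose best motif is X, N12 = HD-up peaks with another motif,
  N21 = all peaks (same context) with X,  N22 = all peaks with another motif.

The rows are nested — the direction set is a subset of the condition's
peaks — and are intentionally **not** corrected to a disjoint 2×2: the
test contrasts the motif's share among differential peaks with its share
among all peaks. Fisher's two-sided exact test (hypergeometric-mass
summation) gives the p-value; raw p-values are reported without
multiple-test adjustment, with a p < 0.05 significance flag. Because the
generator emits one shared peak set per sample, the pipeline uses that
merged set as "all peaks of the condition"; `build_contingency()` itself
accepts arbitrary peak universes.

## Expression integration

The expression heatmap matrix uses the floored ratio
log2((FPKM_HD + 1e−4)/(FPKM_WT + 1e−4)), forced to 0 when both FPKMs are
below 1: genes unexpressed in both conditions carry no usable ratio and
would otherwise dominate the colour scale. Replicate FPKMs are pooled by
arithmetic mean before the ratio. Rows (genes DE at any stage) are
ordered by agglomerative clustering (Euclidean distance, average
linkage), which is deterministic.

Gene-set overlap uses the same literal nested table (N21/N22 count DE
status over the whole annotated universe, not the set's complement) with
Fisher's exact test, reporting the DE fraction of the set as a
percentage. The DE cutoff defaults to q < 0.05, with the stricter
q < 0.01 available as an argument — both appear in common practice and
the package does not privilege one beyond the default.

Peak-to-gene association takes, per DE gene, the nearest differential
THSS on the same chromosome, measuring from peak edge to the strand-aware
TSS point (promoter width is deliberately not modelled), signed positive
downstream, ties broken toward the upstream peak, and flags associations
within 250 kb. Enhancer overlap is counted in both directions (enhancers
hit by ≥ 1 differential distal THSS, and THSSs hitting ≥ 1 enhancer),
because several peaks can share one enhancer, plus the intragenic
fraction of the overlapped enhancers.

## The synthetic-data generator

`generate_synthetic_dataset()` emulates the structure the analysis
assumes — 2 conditions × 4 stages × 2 replicates — at desk scale, with
all randomness drawn from a single seed:

* **Genome**: 2 × 1 Mb uniform-base chromosomes plus gene-free
  chr2a/chr2b decoys (0.2 Mb) that exercise the exclusion rule; 200
  non-overlapping genes placed in disjoint slots.
* **Peaks**: 1000 disjoint peaks allocated proportionally to chromosome
  length; 10% carry a planted |log2 fold change| of 4 (half in each
  condition, constant across stages — stage-patterning is modelled for
  expression, where the analysis depends on it, not for peaks, where no
  downstream step does).
* **Counts**: each peak has a gamma-distributed intensity (dispersion
  0.05) *shared by both conditions*; per-sample counts are Poisson around
  it, and the HD library carries a 1.5× scale bias that the MA
  normalization must remove. Marginally across peaks the counts are
  negative-binomial, but the two conditions remain exactly exchangeable
  under the null — independent per-sample negative-binomial noise would
  instead make the exact binomial test anticonservative by construction,
  which is a property of that test, not of this generator.
* **Motifs**: 20 random PWMs (length 8–12, 0.85/0.05 columns ≈ 1.15
  bits/position). The first motif's consensus is written into the summit
  window of 80% of HD-up peaks and 10% of all other peaks; each peak
  additionally receives one random other motif at the background rate so
  the "other motifs" contingency cells are populated. Positions and
  strands are recorded as truth.
* **Expression**: baseline log2 FPKM ~ N(3, 1.5²); 30% of genes get a
  log2 shift of 3 following one of four stage patterns (all stages,
  early, late, or an inverse pattern flipping sign between the NPC and
  astrocyte ends). Replicate noise is lognormal (σ = 0.25 log2 units).
  Per-stage p-values come from a common-dispersion z-test — the per-gene
  variance is pooled across all genes, emulating the transcriptome-wide
  dispersion modelling of dedicated DE callers; a per-gene t-test at 2
  replicates would have essentially no power at any realistic effect
  size and would misrepresent what those callers achieve.
* **Promoters**: 5% of genes get a 3× mononucleosome occupancy gain in
  HD around their TSS.

What the generator does **not** model: sequence-composition bias of Tn5,
GC effects, fragment-length–accessibility coupling, peak-calling noise
(every sample shares one peak set), replicate-specific batch effects,
and count overdispersion beyond the shared-intensity model. Passing the
recovery tests therefore shows the pipeline's statistics are correct and
calibrated under its own assumptions, not that those assumptions hold
for any particular real dataset.

## Recovery checks and problem sizes

The test suite's end-to-end checks run the default-scale dataset (1000
peaks, 200 genes, 20 motifs; roughly half a minute for generation plus
pipeline on one core) and require: differential-THSS sensitivity ≥ 0.9
with empirical FDR ≤ 0.05 at every stage, the planted motif ranked first
by Fisher p among HD-up distal peaks, and the planted DE gene set
overlapping the called DE genes at p < 0.01. Unit-level oracles use
brute-force enumeration (Fisher tables, PWM score distributions,
interval operations) at small n. `scripts/acceptance.R` recomputes the
same quantities from scratch, plus the published-table accounting
arithmetic, at a caller-supplied seed.

## Known limitations

* The MAnorm-style normalization and exact binomial test pool
  replicates; replicate-aware variance modelling is out of scope.
* Motif enrichment inherits the best-hit-per-peak rule's winner-take-all
  behaviour: a peak with two genuine motifs contributes only the
  stronger one, which slightly deflates N-cells of co-occurring motifs.
* The proximal/distal boundary (TSS ± 500 bp, measured from region
  edges) treats every annotated TSS equally; transcript-level activity
  is not considered.
* `nearest_feature()` is exhaustive per chromosome — appropriate at the
  scales used here; an interval tree would be the next step for
  genome-scale target lists.
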