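---
title: "Methods: detecting transcriptional and epigenetic obesogenic memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting transcriptional and epigenetic obesogenic memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Adipocytes are long-lived, largely post-mitotic cells. If obesity leaves
durable marks on their chromatin, those marks could keep transcriptional
programs deregulated long after weight loss, and prime an accelerated
response to renewed over-nutrition. This package implements the analysis
machinery for that question on a weight-cycling study design: young and
age-matched controls (C, CC, CCC), obese animals after short or long
high-fat feeding (H, HH), weight-loss arms returned to chow (HC, HHC),
and a rebound arm re-exposed to high-fat diet with its re-exposed control
(HCH, CCH).

Three layers of inference are chained:

1. **Which genes are deregulated, and do they recover?** Per-cell-type
   differential expression in obese-vs-control and WL-vs-control
   contrasts, overlaid into *restored* / *memory* / *sign-flip* calls.
2. **Which regulatory regions are altered, and do they recover?**
   Replicate-level differential enrichment of four histone PTMs and
   chromatin accessibility at promoters and enhancers, combined into
   trajectory classes across the obese and WL contrasts.
3. **Can the persistent transcriptional changes be accounted for by the
   persistent chromatin changes?** A gene-level map linking persistent
   differential regions (own promoter, or enhancers within 20 kb) to
   memory and rebound DEGs.

# Statistical models and procedures

## Single-nucleus differential expression

Counts are normalized per cell to a common total of 10,000 and
log1p-transformed. The test statistic is the two-sided Wilcoxon rank-sum
per gene. Because the rank-sum is invariant to monotone per-cell
transforms applied with a common scaling policy, this simple
normalization is an adequate stand-in for variance-stabilizing
transforms where only the test decision is consumed downstream; this is
a deliberate, documented divergence from heavier normalization
machinery.

The p-value has two regimes:

- both groups ≤ 8 cells: exact enumeration of all C(n, n_a) assignments
  of the (mid-)ranks, two-sided p = 2 × min(lower tail, upper tail),
  capped at 1;
- otherwise: normal approximation with tie correction and a 0.5
  continuity correction.

The switch at 8 keeps the enumeration cost (C(16, 8) = 12,870) trivial
while the approximation error at n ≥ 8 is below 0.01 (checked against
the exact distribution in the test suite). The effect size is
`log2((mean_A + 1) / (mean_B + 1))` on de-logged normalized means; the
pseudocount of 1 (on the counts-per-10k scale) avoids division by zero
and damps fold changes of barely-expressed genes. A DEG requires
|log2FC| > 0.5 and Bonferroni-adjusted P < 0.01.

Cell QC keeps cells with 500–3,000 detected features (inclusive bounds:
the discard rule is *fewer than* 500 / *more than* 3,000) and at most
40,000 UMIs. A mitochondrial-fraction filter is not applied by default
(it is specific to human tissue processing).

## Region counts: exact-conditional negative-binomial test

Region assays have 2–3 replicates per condition, so a count model with
an explicit mean–variance relationship is used rather than rank tests.
Counts are modelled NB with common dispersion φ, Var = μ + φμ². The
dispersion is estimated by a pooled method of moments: after
median-of-ratios library normalization, per-feature group means m and
variances v are formed and φ̂ = max(0, Σ(v − m) / Σ m²) pools the excess
variance across all features and groups. This estimator is simple,
non-iterative, and recovers the truth within the tolerances exercised in
the test suite; it deliberately avoids tagwise shrinkage (out of scope).

The test itself conditions on the per-feature total across both groups
after library equalization (counts divided by size factors and rounded
to integer pseudo-counts). Under the null of equal means, the group-A
total given the overall total t follows the ratio law
`dnbinom(a, n_a/φ) · dnbinom(t − a, n_b/φ)` renormalized over
a = 0, …, t — a Binomial(t, n_a/(n_a+n_b)) in the Poisson limit φ = 0.
The two-sided p sums the probabilities of all outcomes no more likely
than the observed split (relative tie tolerance 1e−7, the convention of
exact-binomial software). Two cut-off policies mirror the locus type:
promoter contrasts call significance on nominal P < 0.01, enhancer
contrasts on BH FDR < 0.05, both with |log2FC| > 1.

Rounding pseudo-counts to integers keeps the conditional law exact; the
distortion is at most half a count per sample and is negligible at the
depths region assays produce (tens to hundreds of counts per region).

## Retention, patterns, trajectories

The retention classifier is a pure rule table on the (obese call, WL
call) pair: (deg, ns) → restored, (deg, same direction) → memory,
(deg, opposite) → sign-flip. Sign flips are kept out of the memory
class deliberately: direction reversal is qualitatively different
behaviour and would otherwise inflate retention. Genes significant only
in the WL contrast are reported (`wl_only`) but excluded from retention
denominators, which are the obese-time DEG sets. Retained proportion =
#memory / (#memory + #restored), reported per cell type and direction,
`NA` (not 0) when there are no obese DEGs; cell types with fewer than 30
cells in any donor group are excluded when group sizes are supplied.

The four-arm pattern classifier considers genes that are DEGs in the
same direction at both obesity time points (H and HH) and distinguishes:
not restored in either WL arm, restored in HC only, restored in both,
restored in HHC only, other (including reversals).

Region trajectories are the analogous rule table on the (obese, WL)
differential pair per modality: gained/lost × maintained/reverted,
WL-only changes, stable; (up, down) and (down, up) are flagged as
reversals rather than forced into a class. Enhancers that gained and
maintained H3K4me1 are the "new enhancers" of the acetylation overlay.

## Enhancer definition and linkage

Enhancers are called by an explicit mark-combination rule on 200-bp
genome bins: H3K4me1 present ∧ H3K27ac present ∧ open (ATAC) ∧ H3K4me3
absent, merged across adjacent qualifying bins (merge gap 0 by default —
the smallest-assumption choice, configurable), then any interval
overlapping a promoter window (≥ 1 bp) is removed. This implements the
selection criterion directly instead of training a multi-state chromatin
HMM whose states would then be filtered by the same criterion; the HMM
itself contributes nothing to the downstream logic here.

Promoters are ±2,000 bp around the strand-aware TSS (half-open, clipped
at chromosome bounds). Region→gene linkage assigns each region to the
closest gene within 20,000 bp, where distance is 0 for gene-body overlap
and otherwise the smaller of the edge gaps to the gene body and to the
TSS (edge-to-edge, not midpoint — the natural reading of a distance
cut-off on intervals; ties break to the lexicographically smaller gene
identifier for determinism). Unlinked regions are dropped from the
table.

Fold enrichment of a peak set in a feature set is
`Σ(bp overlap) × genome_size / (Σ(bp peaks) × Σ(bp feature))` — the
ratio of observed overlap to the expectation under uniform random
placement; it is symmetric and equals 1 when either set tiles the whole
genome.

## Epigenetic explanation

The gene–epigenome map collects, per gene, persistent differential
entries: modality × locus type (own promoter / linked enhancer) ×
direction. Two persistence readings are provided: *obese-and-WL*
(significant, same direction, in both contrasts — used for memory DEGs)
and *WL-only* (differentially marked at the WL time point — used for the
rebound question, where what matters is the state the rebound starts
from). Two explanation modes are reported side by side because the
operational definition of "explained by one or more epigenetic modality"
is genuinely open: *any-modality* (any persistent entry; the permissive
reading closest to figure-legend wording) and *direction-consistent*
(gain of H3K4me3/H3K27ac/H3K4me1/ATAC or loss of H3K27me3 for up-DEGs,
mirrored for down-DEGs). ATAC counts as a modality on equal footing by
default; it can be excluded via the `modalities` argument.

Rebound (HCH vs CCH) DEGs receive three non-exclusive flags: prior DEG
status (same-direction DEG at HC), transcriptional memory at HC, and
epigenetic memory (map entry). Non-exclusive flags mirror stacked
proportional reporting and allow a gene to be, say, both remembered and
marked.

# The synthetic study generator

The generator emulates the statistical structure of the real study so
that every stage is testable with planted ground truth:

- **Gene annotation**: genes on fixed 40-kb slots with jittered starts,
  random strands and 2–10 kb lengths. The slot layout guarantees that
  each gene's distal enhancer (placed 4.5–9 kb from the TSS, away from
  the gene body) is closest to its host gene, making linkage truth
  unambiguous.
- **Single-nucleus counts**: NB with per-gene baseline means log-uniform
  over 0.2–4 counts/cell, dispersion φ = 0.1, and log-normal per-cell
  library factors with CV 0.3. Planted memory genes carry the same
  ±1.5 log2 shift in obese-like (H, HH, HCH) *and* WL (HC, HHC)
  conditions; restored genes only in obese-like conditions; the same
  sign and magnitude in both phases makes the retention truth
  unambiguous. Planted classes are assigned among genes with baseline
  mean ≥ 0.5 counts/cell, since DEGs callable at the study thresholds
  are expressed genes. Defaults: 2,000 genes, 150 memory + 150 restored
  (75 up / 75 down each), 300 cells per condition.
- **Region counts**: one promoter and one distal enhancer region per
  gene; per-modality NB counts (φ = 0.05, baselines 50–200 per
  replicate, 3 replicates per condition over C/CC/H/HC) with planted
  trajectory classes as ×2² mean shifts in the designated conditions. A
  configured fraction (default 0.7) of memory genes receives one
  direction-consistent persistent region — the explanation links;
  repressive-mark links (H3K27me3, opposite direction) are planted for a
  fifth of linked genes. Remaining planted trajectory classes land on
  loci of null genes only, so unexplained memory genes stay clean.
- **Binned tracks**: per modality a two-state Markov chain over 200-bp
  bins (blocky, geometric run lengths; marked fractions ≈ 0.1–0.17).
  The planted enhancer bins are *exactly* the bins satisfying the mark
  rule outside promoters. The interval-level caller can drop a whole
  merged run that straddles a promoter edge where the bin-level truth
  keeps its outside portion; this boundary effect is why recovery is
  measured as a Jaccard index rather than exact identity.
- The condition semantics (which arms carry which planted effects) are
  a generator convention chosen once: obese-like = {H, HH, HCH},
  WL = {HC, HHC}, controls = {C, CC, CCC, CCH}. Restored genes
  re-deregulate in HCH, so the rebound analysis sees HC-recovered genes
  carrying planted epigenetic links — the structure the rebound scorer
  is designed to detect.

What the generator does **not** emulate: doublets, ambient RNA,
cell-type mixtures with type-specific effects (the default is a single
adipocyte population), batch or donor effects, compositional shifts,
fragment-level signal, sequence content, or realistic gene-length and
GC biases. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
artefact of real data.

# Numerical choices and degenerate inputs

- Coordinates are 0-based half-open (BED) on disk and 1-based closed
  (GRanges) in memory; conversion happens only in the BED reader/writer.
- Blacklist filtering and promoter exclusion use the strictest ≥ 1 bp
  overlap reading.
- Exact-test tie handling: rank-sum enumeration compares sums with an
  absolute 1e−8 tolerance; the NB conditional law uses a 1e−7 relative
  tie tolerance.
- All-cells-removed QC is a warning plus empty matrix, not an error;
  empty memory sets yield `NA` fractions, not 0.
- Zero-total cells, mismatched feature universes, unknown modalities or
  condition labels, negative dispersion, and empty peak sets in fold
  enrichment raise explicit errors.
- Every simulation consumes a single top-level seed; sub-stages derive
  fixed small offsets from it, so identical configurations produce
  byte-identical fixture bundles and pipeline outputs.

# Problem sizes

The shipped tests and the acceptance script run the default study
(2,000 genes × 2,700 cells, 20,000 region × sample counts per modality,
400,000 track bins) once, plus reduced studies (120–600 genes, 40–150
cells per condition) for determinism and unit checks, 10,000-feature
null simulations for the NB test calibration, and 1,000 random interval
sets on a 100-kb two-chromosome genome for the bitmap cross-checks.
These sizes were chosen to give stable Monte-Carlo estimates while
keeping a full run in the minutes range on one CPU.

# Known limitations

- The common-dispersion NB test has no tagwise shrinkage or covariate
  adjustment; strongly feature-dependent dispersion would miscalibrate
  borderline calls.
- The log2FC pseudocount convention shifts borderline fold changes of
  weakly expressed features; both the pseudocount and the thresholds are
  arguments.
- Linkage is distance-based only; no contact maps, no strand-specific
  enhancer logic.
- The retention classifier treats contrasts as given; which control arm
  each contrast uses is the caller's choice and is an explicit input.
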