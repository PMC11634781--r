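# adipomem

Analysis toolkit for detecting **obesogenic memory** in adipose-tissue
multi-omic data: the persistence of obesity-induced transcriptional and
epigenetic alterations in adipocytes after substantial weight loss, and
their re-activation upon renewed high-fat feeding.

The package is written for computational biologists working with paired
single-nucleus RNA-seq, CUT&Tag histone-mark profiles (H3K4me3, H3K27me3,
H3K27ac, H3K4me1) and ATAC-seq from weight-cycling study designs
(controls C/CC/CCC/CCH, obese H/HH, weight loss HC/HHC, rebound HCH).

## What it computes

**Differential expression (single-nucleus).** Per-gene two-sided Wilcoxon
rank-sum tests on library-normalized expression, with a DEG defined by
|log2FC| > 0.5 and Bonferroni-adjusted *P* < 0.01. Cell QC discards
nuclei with fewer than 500 or more than 3,000 detected features or more
than 40,000 UMIs.

**Transcriptional retention.** Overlaying the obese-vs-control and
weight-loss-vs-control DEG sets classifies each obese DEG as

- *restored* — no longer deregulated after weight loss,
- *memory* — still deregulated in the same direction, or
- *sign-flip* — deregulated in the opposite direction (reported apart),

with the retained proportion `#memory / (#memory + #restored)` per cell
type and direction, and a four-contrast pattern classifier for the
H/HC/HH/HHC arms.

**Region statistics.** An exact-conditional negative-binomial test for
replicate region counts (common dispersion φ with Var = μ + φμ², library
sizes equalized by median-of-ratios): promoter contrasts use nominal
*P* < 0.01 and |log2FC| > 1, enhancer contrasts BH FDR < 0.05 and
|log2FC| > 1. Differential calls across the obese and weight-loss
contrasts are combined into trajectory classes (gained/lost ×
maintained/reverted, "new enhancers" = gained and maintained H3K4me1).

**Interval layer.** Strand-aware ±2,000-bp promoter windows; rule-based
enhancer calling on 200-bp binned tracks (H3K4me1 ∧ H3K27ac ∧ ATAC ∧
¬H3K4me3, outside promoters); blacklist filtering; union peak lists;
region→gene linkage to the closest gene (TSS or gene body) within
20,000 bp; and peak fold enrichment

```
FE = Σ(bp overlap) × genome_size / (Σ(bp peaks) × Σ(bp feature))
```

**Epigenetic explanation.** A memory DEG is *explained* when a persistent
differential mark (significant in the same direction in both contrasts)
sits at its promoter or a linked enhancer; rebound (HCH) DEGs are
attributed to prior DEG status, transcriptional memory, or epigenetic
memory as non-exclusive sources. Both an any-modality and a
direction-consistent mode (activating marks with up-DEGs, H3K27me3
opposite) are provided.

**Synthetic studies.** `sim_config()` / `simulate_study()` generate a
full study — gene annotation, NB single-nucleus counts, per-modality
region counts, binned tracks, blacklist — with planted restored/memory
genes, planted region trajectories and planted gene↔region explanation
links, so every stage is testable end to end without external data.

## Worked example

```r
library(adipomem)
res <- run_memory_pipeline(sim_config(seed = 1))

retention_proportions(res$retention)
#>   cell_type direction n_memory n_restored proportion_retained
#> 1 adipocyte        up       75         75                 0.5
#> 2 adipocyte      down       75         75                 0.5

res$explanation$any_modality$fractions
#>   direction   n fraction_explained
#> 1        up  75          0.7066667
#> 2      down  75          0.6800000
#> 3   overall 150          0.6933333
```

The default configuration plants 150 memory and 150 restored genes
(|log2FC| = 1.5) among 2,000 genes with 300 cells per condition, so the
retained proportion of 0.5 in each direction recovers the planted 75/75
split exactly, and the estimated explained fraction (0.69) recovers the
configured `explained_fraction = 0.7` of memory genes that were given a
persistent epigenetic link. `res$trajectories` holds per-modality region
trajectory calls, `res$enhancers` the rule-called enhancer intervals, and
`res$rebound` the source attribution of rebound DEGs.

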