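# macEnhancers

Integrative analysis of how loss of the circadian transcription factor
**Bmal1** (gene *Arntl*) reshapes the TLR4-responsive **enhancer
landscape of macrophages**.  The package is aimed at computational
biologists working with ChIP-seq peak sets, GRO-seq tag libraries and
stimulation time-course RNA-seq who want the full analysis cascade —
from peak hygiene to eRNA de-repression — as tested, seeded, reusable
functions rather than one-off scripts.

## What it computes

Five connected stages, on Bioconductor containers (GRanges-backed
`PeakSet`/`TagLibrary`, a SummarizedExperiment-backed count matrix):

1. **Time-course fuzzy clustering.**  Genes with normalized counts
   ≥ 100 at ≥ 1 WT timepoint are standardized per gene (mean 0, SD 1,
   population divisor) over the WT time course and clustered with fuzzy
   c-means: memberships *u* and centers *c* minimize
   `J = Σᵢ Σₖ uᵢₖᵐ ‖xᵢ − cₖ‖²` with `Σₖ uᵢₖ = 1`, alternating
   `cₖ = Σᵢ uᵢₖᵐ xᵢ / Σᵢ uᵢₖᵐ` and
   `uᵢₖ = 1 / Σⱼ (dᵢₖ/dᵢⱼ)^{2/(m−1)}`.  Genes join their argmax cluster
   when max membership ≥ 0.3; knockout profiles are projected through
   the WT-defined clusters, never re-fit.
2. **TF co-occupancy.**  Score filtering (≥ 20), blacklist subtraction,
   condition pooling, and reference-anchored three-way Venn counts with
   inclusion–exclusion (`n_union = n_AB + n_AC − n_ABC`), plus
   cross-tissue shared fractions.
3. **Tag densities.**  Metaprofiles (mean normalized tags per bin per
   site, tags-per-ten-million depth scaling) and per-site density
   matrices around peak centers, with K-means row grouping for heatmaps
   and top-N site selection.
4. **Enhancer activation.**  A PU.1 site is KLA-activated when H3K27ac
   in a ±500 bp window satisfies
   `(treated + 1) / (baseline + 1) ≥ 2`; the activated set is then
   profiled across genotypes and timepoints.
5. **eRNA de-repression cascade.**  Coverage-threshold segmentation of
   pooled, smoothed, strand-summed GRO-seq coverage → gene-body
   exclusion → `(DKO + 1)/(WT + 1) ≥ 1.5` de-repression filter →
   PU.1 adjacency within 500 bp.

A seeded **synthetic-data module** generates a miniature genome (2 × 2 Mb,
1,000 genes, 200 intergenic enhancers) with planted ground truth for
every stage — bound factors, KLA-activated enhancers, de-repressed
eRNAs, five temporal expression templates with a knockout-delayed
cluster — so the whole pipeline can be scored for recovery.  See the
methods vignette (`vignettes/macEnhancers-methods.Rmd`) for every model,
parameter and design choice.

## Worked example

Co-occupancy bookkeeping from reference-anchored counts — a Bmal1
cistrome of 2,026 peaks of which 1,040 overlap PU.1, 729 overlap p65 and
611 overlap both:

```r
library(macEnhancers)
v <- vennSummary(nA = 2026, nB = 32000, nC = 9000,
                 nAB = 1040, nAC = 729, nBC = 0, nABC = 611,
                 setNames = c("Bmal1", "PU.1", "p65"))
v
#> VennSummary (anchored on Bmal1)
#>   |Bmal1|=2026  |PU.1|=32000  |p65|=9000
#>   Bmal1 peaks overlapping PU.1: 1040; p65: 729; both: 611; union: 1158
overlapPercentage(1040, 2026)   # 51
overlapPercentage(729, 2026)    # 36
overlapPercentage(611, 2026)    # 30
```

1,158 of the 2,026 Bmal1 peaks (57%) lie under PU.1 and/or p65 — the
inclusion–exclusion union of the two pairwise overlaps minus the triple.

The full synthetic pipeline, end to end:

```r
report <- runPipeline(runConfig(masterSeed = 1L))
report
#> Pipeline run (master seed 1)
#>   genes: 1000 -> expressed: 808 -> assigned: 808 (ARI vs planted templates: 0.851)
#>   co-occupancy (Bmal1/PU.1/p65): 61 of 76 reference peaks in the union
#>   activation: 45 enhancers (recall 1, precision 1)
#>   eRNA cascade: 1312 -> 200 -> 57 -> 32 (recall 1, contamination 0)
```

Reading the report: 808 of 1,000 genes pass the expression floor (the
other ~20% are planted low-expressed), all 808 are assigned at
membership ≥ 0.3 and recover the planted temporal templates at adjusted
Rand index 0.85; the activation caller finds exactly the planted
KLA-activated PU.1 enhancers; and the eRNA cascade narrows 1,312
nascent-transcription candidates to 200 intergenic regions (every gene
body excluded), 57 de-repressed ones, and 32 PU.1-adjacent enhancers —
all of them planted positives.

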