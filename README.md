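# layerreg

Integrative analysis of cell-class-resolved chromatin accessibility and
gene expression in layered cortex, from peak counts to a putative
layer-specific transcription-factor regulatory network.

## The scientific problem

Excitatory neurons of the mammalian neocortex fall into layer-specific
classes (L2/3, L4, L5, L6) with distinct transcriptomes. ATAC-seq on small
sorted populations of each class yields, per class, a set of accessible
peaks and replicate-level fragment counts; class-level expression profiles
come from single-cell RNA-seq. `layerreg` implements the downstream
integration that connects the two:

1. **Normalization and QC** — TMM normalization factors (via edgeR),
   accessibility scores `max(0, CPM − control CPM)` per peak and class,
   fragment downsampling, FRiP, and insert-size histograms with
   nucleosomal-mode detection.
2. **Differential testing** — a calibrated negative-binomial Wald test
   (`Var = μ + φμ²`, trended method-of-moments dispersion with 50%
   shrinkage, finite-sample null calibration) for every pairwise class
   contrast of peaks and genes; Mann-Whitney U comparisons of peak-score
   distributions for differentially expressed gene sets (exact by
   enumeration for small groups); BH and Bonferroni adjustment.
3. **Peak-gene association** — each peak is positionally associated with
   the gene whose TSS is nearest to its midpoint, with signed distances
   binned into six categories (−3…+3: distal/proximal, up/downstream).
4. **Modules** — peaks and genes that are strongly differential between
   glutamatergic classes are min-max scaled over the four classes and
   clustered by seeded k-means around eight binary patterns (L2/3+, L4+,
   L5+, L6+, Upper+, Lower+, L4−, L6−); module-module coupling is tested
   with Fisher's exact test, and peak-gene profile correlations are
   compared against assignment-permuted controls (KS test).
5. **Motifs and footprints** — PWM scanning with exact log-odds tail
   p-values (dynamic-programming convolution, FIMO-style), motif
   enrichment per module against dissimilar-module backgrounds
   (AME-style, Fisher on per-peak hit presence, both directions), and
   aggregate Tn5 insertion profiles around motif centers with a
   footprint-depth summary.
6. **Network** — the two selection flowcharts: key activator/repressor TF
   nodes chosen by role-consistent motif enrichment in their expression-
   matched module, and motif instances filtered through six gates
   (family-module association, module-gene-module association,
   differential accessibility, differential expression of the target,
   TF-list membership, and role-signed correlation with the source TF) to
   weighted directed edges. Output as igraph/GraphML/TSV.

A first-class synthetic-data generator (`simulate_dataset()`) plants all
of this structure — binary-pattern modules at ≥4-fold (default 6) effect
size, NB counts (φ = 0.1, 3 replicates/class), module-biased motif
placements at a 5× enrichment rate, Tn5 footprints with 80% central
depletion at bound motifs, and a 12-TF activator/repressor network — so
the whole pipeline is verifiable by parameter recovery without any
download.

## Worked example

```r
library(layerreg)

ds  <- simulate_dataset(simulation_config(seed = 1))
res <- run_pipeline(ds)
res
#> pipeline_result: 869 peak / 255 gene module features, 2769 motif hits,
#>   12 key TFs, 32 edges

res$peak_modules
#> module_set (peak): 869 features in 8 modules
#>  L2/3+    L4+    L5+    L6+ Upper+ Lower+    L4-    L6-
#>    107    116    116    114    114    108     90    104

# how well were the planted modules and the planted network recovered?
sel <- names(res$peak_modules$membership)
truth <- ds$truth$peak_module_of[sel]
adjusted_rand_index(res$peak_modules$membership,
                    ifelse(is.na(truth), "null", truth))
#> [1] 0.9786046

evaluate_network(res$edges, ds$truth$network_edges)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
```

The printed numbers mean: 869 peaks and 255 genes passed the differential
filters and were clustered into the eight binary-pattern modules with an
adjusted Rand index of 0.98 against the planted labels; all 12 planted key
TFs were selected as nodes and all 32 planted TF→target edges were
recovered with no false edges.

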