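---
title: "Methods: models, parameters, and design choices in layerreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in layerreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`layerreg` turns cell-class-resolved ATAC-seq peak/count data and
class-level expression profiles into peak-gene associations,
accessibility/expression modules, motif enrichments and footprints, and a
putative layer-specific TF regulatory network. This vignette explains the
statistical models, the tunable parameters and their defaults, the
synthetic-data generator used for validation, and the design decisions
taken where the analysis was genuinely open.

## Coordinates and containers

All interval data use BED-style 0-based half-open coordinates on disk and
`GRanges` in memory. Merging peak sets takes outer boundaries of strictly
overlapping intervals; abutting half-open intervals (`end == start`) do
not merge, reading "overlap" strictly. Count data live in a
`count_matrix` (integer features × samples plus a sample-to-class map).

## Normalization and accessibility scores

Between-sample normalization uses trimmed-mean-of-M-values factors
computed by edgeR (`tmm_factors`; trim 0.30 on M, 0.05 on A; reference =
sample with upper quartile closest to the mean upper quartile; factors
rescaled to geometric mean 1). The per-peak score is

    score = max(0, count / (libsize × factor) − control / control_libsize) × 1e6,

i.e. effective-library CPM minus genomic-control CPM, floored at zero.
The floor is a declared choice: subtraction can go negative for noisy
control counts and the scores feed log fold changes downstream. Class
scores are arithmetic means over replicates.

## The differential test

Differential accessibility and expression use a two-group negative-
binomial Wald test on CPM-scale normalized counts with variance
`μ + φμ²`:

* per-feature dispersion: pooled within-class method-of-moments estimate,
  floored at 0, shrunk 50% toward a lowess trend of dispersion on log
  mean abundance;
* statistic: `z = log2fc / SE`, with `log2fc` on class means plus a 0.5
  pseudocount and a delta-method SE.

With three replicates per class, plugging the estimated dispersion into a
normal reference is anticonservative (the estimate has ~4 degrees of
freedom; empirically the fraction of null p-values below 0.05 is ~0.075
and the p-value distribution fails a KS test against uniform at 20,000
features). Student-t or Satterthwaite references repair the rejection
rate but not the distribution shape, because the moment estimator is not
chi-square distributed (it is floored at zero and inherits the NB fourth
moment). The shipped test therefore computes two-sided p-values against
the *bootstrap null law* of `z`: features are binned by pooled abundance
(25 log-spaced bins), and per bin 20,000 null NB features are simulated
at a bias-corrected trend dispersion and pushed through the identical
estimator. Observed `|z|` in the bulk receive empirical p-values; beyond
the bootstrap resolution (top ~1%) the tail continues as a scaled normal
matched for continuity, so very small p-values remain available to the
downstream gates. The bootstrap uses a fixed internal seed and restores
the caller's RNG state; results are deterministic. With eight or more
replicates per group the correction is unnecessary and the normal
reference is used directly. Under the generator's null conditions the
calibrated test yields a p<0.05 fraction of 0.048–0.052 and KS-vs-uniform
p between 0.09 and 0.30 across seeds, at ~99% power for 6-fold effects
(adjusted p < 0.01).

Mann-Whitney U comparisons (peak-score distributions of differentially
expressed gene sets) use midrank ties; for group sizes ≤ 8 the p-value is
exact by enumeration of all `choose(nA+nB, nA)` group assignments,
otherwise a normal approximation with tie and continuity correction.
Multiple-testing adjustment is BH except where a Bonferroni correction is
the convention (pairwise gene-set tests).

## Peak-gene association

Each peak's anchor is its interval midpoint (floored for odd widths); the
assigned gene owns the TSS minimizing the absolute distance over all
isoform TSSs. Distances are signed by gene strand (negative = upstream)
and binned: −3 (beyond 2 kb upstream), −2 (200 bp–2 kb upstream), −1
(within 200 bp upstream), +1/+2/+3 mirrored downstream. Boundary
conventions, closed toward the middle bins: |d| = 200 → ±2, |d| = 2000 →
±2, d = 0 → +1. Equidistant ties prefer the downstream side, then the
lexicographically smaller gene id; all rules are deterministic and
verified against a brute-force oracle. Nearest-TSS assignment is a
deliberate simplification — chromatin conformation can place true
regulatory targets far away in linear coordinates.

## Modules

Features enter clustering when, in at least one pairwise glutamatergic
contrast, they are significantly differential *and* exceed a fold
threshold on class-mean scores: peaks at adjusted p < 0.01 and > 4-fold
average TMM score; genes at p < 0.05 and > 2-fold. Profiles over the four
glutamatergic classes are min-max scaled to [0, 1] per feature (constant
rows excluded). An exploratory k-means (k = 15, k-means++ seeding, best
of 10 restarts) is retained as a diagnostic; module construction itself
is a seeded Lloyd run from eight fixed binary patterns (one selective
pattern per class plus Upper+, Lower+, L4−, L6−), codified as
configuration defaults rather than a manual step for reproducibility. The
seeded run has no randomness; a cluster that loses all members keeps its
seed center (the stock k-means implementation cannot express this rule,
which is why Lloyd's algorithm is implemented in-package and
cross-checked against `stats::kmeans`). Centers exactly at 0.5 binarize
to 1 (the threshold rule only defines > and <; the tie is declared).
Sample-level structure is summarized by complete-linkage clustering on
1 − Pearson distance over the 7,500 most differential peaks (the distance
metric is a declared choice).

Module-module association counts how often peaks of peak module i are
positionally associated with genes of gene module j, tested two-sided by
Fisher's exact test with direction read from the sample odds ratio
`ad/bc`, BH-adjusted over all 64 pairs. The universe is module peaks with
a gene assignment; peaks whose gene is in no module count against the
pair (this universe is a declared choice, switchable). A caveat worth
knowing: the test treats peaks as independent, but peaks of one gene
share that gene's module, so gene-level label permutations remain
overdispersed at the peak level; the package's null checks permute peak
labels, which is the exchangeability the construction actually assumes.

Peak-gene correlation uses Pearson r between scaled class profiles of
each assigned pair, compared against 10 assignment-permuted datasets by
two-sample KS tests.

## Motifs

PWMs are read from MEME minimal format (one dialect, bit-exact tests;
JASPAR input should be pre-converted). Scoring is log2 odds with an
ε = 0.001 background admixture. Hit p-values are exact: scores are
discretized at 10⁻³ bits and the tail probability of a random background
sequence is computed by dynamic-programming convolution over positions;
scanning reports all windows on both strands with per-position
p ≤ 10⁻⁴ (the conventional single-site threshold; the source analyses do
not state one). Enrichment per module is tested against the
dissimilar-module background: every other module whose binary center is
low in all classes where the foreground is high. Peaks wider than 400 bp
are excluded. The statistic is a one-sided Fisher exact test on per-peak
hit presence — an exact-testable choice among the several statistics
AME-style tools offer — with depletion obtained by exchanging foreground
and background, and BH correction across motifs within each
module/direction (a package-wide consistency choice). Families aggregate
member motifs by best p-value.

## Footprints

Aggregate Tn5 insertion profiles count fragment cut sites at each offset
from motif centers (strand-oriented), normalized to insertions per
million library fragments. Both fragment ends count as insertions by
default — tagmentation cuts at both ends — with a 5'-end-only mode
available; no +4/−5 offset correction is applied by default. The window
is ±250 bp. The `footprint_depth` summary is the mean rate over the
central motif span divided by the mean rate beyond ±50 bp: 1 for flat
profiles, < 1 at protected (bound) motifs.

## Network construction

Key TF nodes: candidates (curated TF genes with motif family and
activator/repressor role; the shipped defaults are the ten activators
Egr1, Fos, Mef2c, Nfia, Neurod6, Pou3f2, Rfx3, Rorb, Meis2, Tbr1 and the
two repressors Foxp2, Cux1) must exceed a class-mean expression of 5 in
at least one glutamatergic class, are assigned the gene module whose
center best correlates with their expression profile, and are kept when
their motif family is enriched (activator) or depleted (repressor) at
adjusted p < 0.01 in the matching peak module; per family and role the
highest-expressed passer (maximum class-mean, a declared metric) becomes
the node.

Edges: a motif instance survives six gates — (1) family associated with
at least one peak module (Fisher p < 0.01); (2) the instance's host-peak
module among those and positively associated (p < 0.01, OR > 1) with at
least one gene module (any gene module, a declared reading of an
ambiguous rule; switchable to target-module); (3) host peak differentially
accessible at p < 0.001 in some glutamatergic contrast; (4) host gene
differentially expressed at p < 10⁻⁵; (5) host gene in the TF gene list;
(6) Pearson correlation between the host peak's scaled class profile and
the source TF's scaled expression profile > 0.3 for activators, < −0.3
for repressors, computed on 0-1 scaled class means. Passing instances
aggregate into directed edges weighted by instance count, with a
per-instance audit trail. Relaxing any single gate threshold can only add
edges (monotonicity, tested). The output is labeled putative: gates
encode coherence, not causality.

## The synthetic-data generator

`simulate_dataset()` emulates the study conditions the analysis assumes,
with all randomness derived from one seed:

* **Design**: four glutamatergic classes (+ one pan-GABAergic, flat
  patterns), 3 ATAC replicates per class, 400 genes spaced 20 kb on one
  synthetic chromosome, 2,000 peaks placed 1–8 per gene at signed TSS
  distances covering all six bins, unambiguous under the nearest rule.
* **Counts**: NB with `Var = μ + φμ²`, φ = 0.1, library size ~10⁶
  (±10%); module features follow their binary pattern at a high/low
  ratio of 6 (the module filters require > 4); 40% of genes are null;
  peaks of a module gene share its module with probability 0.7. A
  genomic-control library has width-proportional uniform coverage.
* **Expression**: class-mean units (low 50, high 300) realized as
  depth-equalized per-cell NB draws (60 cells per class, dispersion
  0.35), emulating class-averaged single-cell profiles; class means over
  cells are the downstream expression, as in the analysis itself.
* **Motifs**: 12 TF-family PWMs plus 4 unbiased null motifs (length 10,
  consensus probability 0.97). An activator's motif is placed in its
  module's peaks at rate 0.4 and elsewhere at 0.08 (enrichment rate 5); a
  repressor's motif is placed in the *complement*-pattern module at 0.4
  and never in the repressor's own module (bound sites are closed there).
  Planted edge host peaks always carry their motif. Background placements
  avoid peaks of TF-list genes, and generated background sequence is
  redrawn until it contains no unintended matches of the simulated motif
  set (undetectable planted draws are replaced by the consensus): the
  scan hit structure then equals the recorded truth, which is what makes
  the enrichment rate and the network identifiable from the data. This
  is a deliberate non-realism — real genomes contain chance motif hits
  near regulators, and with them the planted network would not be the
  unique structure passing the gates at any threshold.
* **Fragments**: per class, 3×10⁵ fragments; 30% placed in
  shoulder-padded peaks with both cut sites drawn from the class's
  accessibility-weighted insertion track, multiplied by 0.2 (80%
  depletion) within ±10 bp of motifs whose owning TF is expressed in
  that class; the rest uniform on the chromosome. Lengths follow a
  mixture with modes near 75/200/400/600 bp (sub-nucleosomal through
  tri-nucleosomal).
* **Network truth**: each of the 12 key TFs receives 2–3 targets among
  module TF-list genes of the required pattern; 8 additional non-
  differential TF-list genes and 2 low-expression candidate decoys
  exercise the negative paths of both flowcharts.

What passing recovery tests does and does not show: the generator plants
exactly the structure the pipeline models (NB counts, binary patterns,
independent peaks, clean motif placement). Recovery therefore validates
the implementation and the identifiability of the procedure under its own
assumptions — not robustness to chance motif matches, correlated
replicates, mappability artifacts, peak-calling errors, or real sequence
composition, all of which are explicit non-goals.

## Numerical choices and degenerate inputs

Scaled profiles with zero range are excluded (with a message) rather than
imputed. Features with all-zero counts in both classes get p = 1 and
log2fc = 0. PWM rows renormalize after pseudocount admixture; zero
background frequencies are an error. The PWM p-value grid is 10⁻³ bits
(exactness verified against 4^L enumeration). Empty AME foregrounds
(after the 400 bp width filter) are an error, not a silent skip. Module
recovery is evaluated by the adjusted Rand index over selected features,
with unplanted features labeled "null".

At the generator's own conditions (φ = 0.1, 3 replicates), min-max
scaling caps the achievable sharpness of recovered centers: for a pattern
with several "high" classes the non-maximal high coordinates scale to
~0.83–0.88 in expectation even with essentially perfect membership, so
recovered centers sit within ~0.2 (L∞) of the binary patterns while the
membership ARI stays ≥ 0.95. This is a property of the scaling under NB
noise, not a clustering error.

## Problem sizes

Defaults were chosen so a full simulate-and-recover cycle (2,000 peaks,
400 genes, 16 motifs, 1.5M fragments) runs in about a minute on one core,
and the complete verification suite, including the exhaustive oracles
(all 2×2 tables with n ≤ 30; all 4^L sequences for L ≤ 6; all
`choose(nA+nB, nA)` rank-sum splits for groups ≤ 6), in a few minutes.
These sizes are a package choice: large enough that every distance bin,
module, motif, and gate is populated, small enough for routine runs.
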