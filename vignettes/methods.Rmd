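---
title: "Responsive cell types, sparse gene panels and patient-level classification"
author: "respanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Responsive cell types, sparse gene panels and patient-level classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Population-scale single-cell RNA-seq profiles many patients across two
clinical conditions (disease vs. control, responder vs. non-responder).
Translating such data into an assay requires three things at once: the cell
population in which the perturbation is actually visible, a *small* set of
genes measured in that population, and a classifier that decides at the
*patient* level — not the cell level — whether a new sample is perturbed.
`respanel` implements this three-stage procedure.

```{r, eval = FALSE}
library(respanel)
sim <- makeFixture("strong", seed = 1)
res <- runPipeline(pipelineConfig(seed = 1, outdir = "runs"),
                   dataset = sim$dataset)
```

## Stage 1: which cell type responds?

For every retained cell type, a random forest is trained to predict the
condition from expression, and its AUROC on *held-out patients* is the
responsiveness score. The critical design point is that the internal
train/validation split is by patient, never by cell: cells of one donor
share technical and biological idiosyncrasies, so a classifier evaluated on
cells of donors it has already seen scores inflated AUROCs on completely
unresponsive populations. The package exposes this failure mode directly:
`responsivenessConfig(split_by = "cell")` reproduces the naive protocol, and
the test suite demonstrates the inflation on simulated cohorts whose only
patient-level structure is a random effect shared by all genes of a donor.

Defaults: 20 repeats; in each repeat an equal number of cells (20, the same
constant as the retention filter's minimum) is drawn from every patient so
large donors cannot dominate; 75/25 patient-stratified internal split;
100 trees; the minority class is up-weighted by `n / (2 n_c)` computed on
the repeat's training cells. Repeats whose validation side degenerates to a
single condition are redrawn up to 10 times, then skipped with a warning.
Ranking ties break by more cells used, then name, so results are
reproducible.

Before scoring, cell types are retained only if at least 3 patients in
*each* condition contribute at least 20 cells of that type, and counts are
normalized to 10,000 per cell followed by `log(1 + x)`. Externally
batch-corrected matrices can be supplied as already-normalized layers and
bypass this step; the package deliberately performs no batch integration of
its own.

## Stage 2: how few genes suffice?

Gene selection is backward elimination around a linear, class-weighted SVM
(`C = 1`): fit, drop the `max(1, floor(0.03 n))` genes with the smallest
squared primal weights, repeat until one gene remains. The 3% step makes
the schedule logarithmic in the gene count. The panel size is chosen from a
cross-validated accuracy curve: patients are partitioned into `k`
condition-stratified folds (default 5; the curve also supports `k = 2` for
small cohorts), genes are re-ranked within each training fold, and the
balanced accuracy of the step SVM on the held-out fold's cells is recorded
at every schedule count. Per-fold re-ranking keeps the curve honest about
selection variance across patients. On the mean curve the parsimonious
count is the point with maximal perpendicular distance to the chord joining
the curve's endpoints; ties resolve to the sparser panel, and an exactly
collinear curve returns the smallest count with a warning.

The final ranking is computed on all training cells by default
(`final_ranking = "full"`); a fold-consensus ranking (mean of per-fold
ranks) is available as an alternative since either convention is defensible.
Features are standardized per training fold and held-out cells are
transformed with the training statistics, preventing leakage through the
scaling. Balanced accuracy is used rather than raw accuracy because
minority-class weighting pervades every other stage. Before every SVM fit,
an equal number of cells per patient (default 20) is subsampled — the same
equal-contribution argument as in stage 1, and it keeps the quadratic SVM
cost tractable at cohort scale. When the curve never reaches 0.7 balanced
accuracy the panel is flagged low-confidence.

The *stable* mode reruns the whole selection on `n_subsets = 20`
downsampled cohorts (80% of patients per class, drawn without replacement
within a subset; cell-level downsampling is the fallback for tiny cohorts)
and retains genes selected in strictly more than 50% of subsets, ordered by
selection frequency then mean within-panel rank. The strict inequality
matters at the boundary: 12/20 is kept, 10/20 is not.

## Stage 3: classifying patients

Five classifiers are trained on the selected cells and genes: ridge
logistic regression, a linear SVM, a probability random forest, a
distance-weighted kNN voter (k = 15), and a two-layer graph attention
network on the symmetrized 15-nearest-neighbour cell graph. The GAT is the
package's own implementation (no R package provides one): 8 hidden units in
4 attention heads, ELU activations, Adam at learning rate 0.01, weighted
cross-entropy, early stopping with patience 20 on nodes of held-out
patients. Two numerical choices deserve note. No dropout is used, so
training is deterministic under the seed. And early stopping neither halts
nor selects parameters before a 50-epoch burn-in: without it, on
weak-signal data the monitor can return an essentially untrained network
whose random output intercept places *every* cell slightly off probability
0.5, which silently biases the downstream patient scores. Prediction on a
new cohort rebuilds the graph within the test data (inductive use).

All members are weighted by `w_i = N / (2 P_c n_p)` so every patient
contributes equal weight within its class and both classes contribute
equally, whatever the cohort composition. The SVM receives the class-level
aggregate of these weights (libsvm has no per-sample weights); its
probabilities come from the package's own Platt scaling of the decision
values, which unlike libsvm's internal cross-validated fit is
deterministic. Single-gene panels are supported throughout.

Per cell, the consensus probability is the median of the member
probabilities (the median of four is the midpoint of the middle pair when
the graph member is disabled). Per patient, the AUC score is the rank
statistic of its cells' consensus probabilities against the 0.5 reference —
the fraction of cells above 0.5 plus half the fraction exactly at it — so a
perturbed patient scores near 1 and a reference patient near 0. A patient
is called perturbed when its AUC exceeds 0.5; exactly 0.5 is flagged
undetermined and counted as reference. Significance comes from resampling
the patient's cells with replacement (B = 1000), with a one-sided,
add-one-corrected p-value counting replicates on the opposite side of 0.5.
Panel genes missing from a test dataset are a hard error; silently imputing
zeros would corrupt every probability.

## The simulator and what it does (not) show

Every stage is validated against cohorts from `simulateDataset()`: negative
binomial counts (dispersion 2) around log-normal gene means (meanlog 0,
sdlog 1), multiplied by a per-patient log-normal random effect (sd 0.3)
shared by all genes of a donor, a per-cell library factor (sd 0.2), and a
`2^log2FC` shift on the marker genes of the responsive type in perturbed
patients. The default design is 10+10 patients, 3 cell types, 60 cells per
patient and type, 300 genes with 12 markers at 4-fold; presets `tiny`,
`null`, `strong` and `imbalanced` (15 vs 5 patients) instantiate it. The
patient random effect is deliberate: it creates exactly the donor-level
leakage that patient-wise splitting exists to guard against, so the tests
can demonstrate the inflation cell-wise splits suffer. The simulator omits
gene–gene correlation, batch structure and trajectory structure; passing
its recovery tests shows the machinery is sound at realistic effect sizes,
not that any particular biological dataset will separate.

Test problem sizes are the package's choices: repeated-seed experiments run
the pipeline with 10 responsiveness repeats and 2-fold gene CV (both
supported configurations; the 2-fold curve mirrors the smallest-cohort use
case), and structural tests use the `tiny` preset.

## Known limitations

The bootstrap p-value resamples cells within a patient and therefore
assumes they are exchangeable. Cells of one donor are correlated — through
the same patient-level effects the simulator models — and classifier scores
inherit a donor-level offset, so under a true null the p-values are
anticonservative: substantially more than the nominal fraction of
unperturbed patients reach p < 0.05 (the package's own null-cohort
experiments measure this directly, and with 60 cells per patient even a
perfectly calibrated consensus would leave roughly 10% of null patients
below 0.05). This is the familiar pseudoreplication problem of cell-level
inference; the per-patient AUC point estimates and cohort-level metrics are
unaffected, but the per-patient p-values should be read as descriptive
confidence of the call, not as calibrated donor-level significance. A
hierarchical bootstrap would address it at the price of many more patients.

Gene identifiers are matched exactly across training and test data; no
ortholog or alias resolution is attempted. Batch correction between cohorts
is out of scope — the pipeline accepts externally corrected expression as a
pre-normalized layer instead.
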