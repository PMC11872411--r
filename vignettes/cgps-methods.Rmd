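---
title: "Methods: B-cell based cGVHD monitoring with cGPS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: B-cell based cGVHD monitoring with cGPS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgps)
library(dplyr)
```

## The problem

Chronic graft-versus-host disease (cGVHD) is the major late complication of
allogeneic hematopoietic stem-cell transplantation. Its diagnosis rests on
clinical organ scoring (the NIH consensus criteria), which reacts only once
tissue damage is manifest. Aberrant B-cell homeostasis precedes and
accompanies cGVHD; in particular, an activated plasmablast-like compartment
(CD19+ CD20- CD27+ CD38hi IgD-, with CD86, CD269/BCMA and CD319/SLAMF7) expands
with disease activity. This package implements a complete, testable pipeline
around that observation:

1. **Discovery** -- cluster pooled single-B-cell cytometry data, find the
   cluster dominated by patient cells, and rank the markers that define it.
2. **Panel selection** -- exhaustively screen small marker subsets with a
   random-forest classifier on a discovery cohort, freeze the survivors, and
   validate them on an independent cohort to find the minimal subset with
   subject-level AUC above 0.90.
3. **Scoring** -- gate the CD27+CD86+CD20- subset among CD19+ B cells, express
   its frequency on the 0--100 cGVHD Progress Score (cGPS) scale, and
   classify risk at fixed decision thresholds (1.15 for non-GVHD patients,
   1.51 for cGVHD patients; the boundary value itself is low risk).
4. **Decision statistics** -- empirical ROC with Youden-index thresholds,
   percentile-bootstrap confidence intervals, Fisher-exact contingency
   evaluation, Wilcoxon rank-sum tests, and one-sample t power analysis.

Patient-level cytometry from the original cohorts is not publicly deposited,
so the package ships a synthetic cohort generator that emulates the study
design closely enough for every stage to be exercised end to end and for the
study's qualitative results to be recovered quantitatively.

## The synthetic cohort generator

`generate_cohort()` draws per-subject B-cell samples as a mixture of
template subpopulations with Gaussian intensities on the arcsinh axis
(negative ≈ 0.5, positive ≈ 3.0, high 3.5--4.0, noise SD 0.4), then maps them
back to the raw fluorescence scale with `sinh(v) * cofactor` (cofactor 150).
Classical subsets (naive, memory, transitional, CD5+ B1-like) make up the
bulk. The planted disease subpopulation carries the plasmablast-like
phenotype above; its per-subject frequency (percent of B cells) is
Beta-distributed with stratum means

| stratum | mean (%) |
|---|---|
| healthy donor | 0.3 |
| non-GVHD, stable | 0.6 |
| non-GVHD, active | 2.0 |
| cGVHD, non-DP | 1.0 |
| cGVHD, DP | 3.0 |

so that the decision boundaries used to assign outcome labels (1.15 and
1.51) sit between the relevant strata. Outcomes are a deterministic function
of the planted frequency (optionally flipped with a configurable label
noise), which makes threshold-recovery experiments well posed: the
generator's own boundary is the quantity the ROC analysis should find.

### Why three confounder populations

A minimal-panel result is only meaningful if smaller panels genuinely fail.
The generator therefore plants three disease-*independent* populations, each
identical to the disease phenotype on the eight candidate markers except for
a single flip:

* conventional **plasmablast** -- CD86- (otherwise CD20- CD27+ CD38hi ...),
* **CD20+ activated B cell** -- CD20+,
* **CD27- plasmablast** -- CD27-.

Any marker pair is matched by at least one confounder, so every 2-marker
classifier is contaminated by a population whose frequency does not track
disease; only a panel containing all of CD20, CD27 and CD86 separates the
disease subset from all three. Recovery of exactly that triple is therefore
a property of the simulated biology, not something the pipeline could
hard-code. (The confounders also differ from the disease template on two or
three non-candidate markers -- CD138, HLA-DR, CD21/CD24/CD95, IgM/CD71 -- so
that clustering can resolve them as distinct communities.)

Confounder frequencies are Beta-distributed with means 2.5--3.5% and shape
α ≈ 2 (SD ≈ 2 percentage points). This calibration matters: the spread must
be wide enough that confounded 2-marker panels reliably fall below the 0.90
validation-AUC criterion, yet not so skewed that most subjects carry none of
the confounder (which would leave 2-marker AUCs high). Similarly the
disease-frequency precision (κ = 3000) was set so that subject-level
discrimination of the true panel matches what the score achieves in practice
(AUC ≈ 0.95). Both were fixed during generator design and are defaults of
`sim_config()`, not quantities a test may adjust.

The eight candidate markers have median contrasts of at least 2.5 arcsinh
units between the disease subset and the rest of the B cells, while every
non-candidate marker stays at 2.0 or below; this makes "the top eight
markers by effect size" a well-defined planted truth for the ranking stage.

What the generator does **not** emulate: spillover/compensation and spectral
unmixing, debris and doublets, non-B contaminating lineages, heavy-tailed or
skewed intensity distributions, instrument drift within a batch, and
subject-level covariance between subpopulation frequencies. Passing tests
therefore show that the pipeline's logic is correct under a clean mixture
model, not that it is robust to every artefact of real cytometry.

## Preprocessing

`arcsinh_transform()` applies `asinh(x / cofactor)` with a double-transform
guard; the cofactor (default 150, the fluorescence-scale convention) is
configurable because upstream acquisition software may already normalise.
`scale_and_regress()` pools all cells of a cohort, regresses each marker on
the covariate indicators (batch, by default, when more than one is present),
replaces values with residuals and standardises each marker to mean 0 and
variance 1. Constant markers are zeroed with a warning rather than aborting:
degenerate synthetic edge cases should not kill a run. Batch regression is a
joint fit across the cohort, matching a pooled two-institute correction.

## Clustering and marker ranking

`cluster_cells()` builds an exact Euclidean k-nearest-neighbour graph
(k = 20 by default) on the scaled marker space and partitions it with
Louvain modularity optimisation (resolution 0.8). Neither k nor the
resolution is treated as a contract about the number of clusters -- cluster
count is data-dependent, and tests assert recovery of planted structure,
never a particular count. `identify_disease_cluster()` picks the cluster
with the highest fraction of disease-group cells, requiring at least 0.75,
with ties broken towards the larger absolute disease cell count.

`rank_cluster_markers()` compares in-cluster and out-of-cluster expression
per marker with the tie-corrected Wilcoxon rank-sum test and uses the median
difference as the effect size. In `run_discovery()` the ranking runs on the
*transformed but unscaled* cohort: per-marker z-scoring would divide each
median shift by that marker's total variance, which depends on its overall
positivity rate and badly distorts effect-size comparisons across markers.
The selection rule (p < 1e-4, |median difference| > 0.5, top 8 by effect) is
a reconstruction of a figure-level display, and all three knobs are exposed.

## Panel screening and validation

`screen_combo()` follows a two-stage, freeze-then-validate protocol. Stage
1: cells restricted to the marker subset, binary labels inherited from the
subject's group, a 100-tree random forest trained on a 70% split, accuracy
measured on the held-out 30%, pass at accuracy > 0.90. The forest considers
every marker at every split (`mtry = p`): subsets have only 2--3 features,
and the default `sqrt(p)` would leave many trees blind to one marker, mixing
phenotypes that differ in exactly that marker. Stage 2
(`validate_combo()`): the frozen model (content-hash checked) scores every
cell of the independent cohort, scores are aggregated per subject as the
mean predicted disease probability, and the subject-level AUC must exceed
0.90. `select_final_panel()` takes stage-2 survivors and picks fewest
markers first, then highest AUC, then lexicographic order.

Two design points deserve emphasis:

* **Cluster-guided screening.** With a disease subset at 0.3--3% of B cells,
  cell-level labels inherited from the subject are almost uninformative on
  whole samples -- most patient cells are phenotypically normal, so no
  marker subset could reach 90% cell-level accuracy. `run_discovery()`
  therefore builds the screening input from the disease-associated cluster's
  cells plus a several-fold sample of healthy-donor cells. The forest then
  learns "disease phenotype versus healthy B-cell repertoire", which is the
  decision the frozen model must make per cell at validation time.
* **Split unit.** The default 70/30 split is per cell, which mirrors a
  per-cell train/test split protocol but lets cells of one subject appear on
  both sides; `split_unit = "subject"` is provided as the leakage-safe
  alternative. The validation cohort is disjoint by construction, so the
  headline stage-2 AUC is unaffected by this choice.

## Gating and the cGPS scale

`fit_gates()` fits a two-component Gaussian mixture per gate marker on
pooled healthy-donor cells and places the cut at the density minimum between
the component means. When the two means are closer than one pooled SD the
marker is treated as unimodal and the cut falls back to a reference
percentile -- on the *rare* side of the bulk: the 99.5th percentile for
rare-positive subset gates, the 0.5th percentile for negative gates and for
the CD19 lineage gate (whose cells are essentially all positive, and whose
role is to keep the bulk as the denominator). `gated_frequency()` counts
CD27+ CD86+ CD20- cells among CD19+ cells; an empty denominator is an
explicit error -- subjects without circulating B cells are out of scope by
design rather than silently scored.

`cgps_score()` maps frequency to the 0--100 score through a pluggable
monotone transform and clamps to [0, 100]. The default transform is the
identity on the percent scale: the published scoring formula itself is not
available in the accessible text, but the score's stated range, its
interpretation as a summary of the subset frequency, and the positions of
the decision thresholds (1.15, 1.51) are all consistent with percent units.
If the true formula differs it can be dropped in as `transform=` without
touching any other stage, and every record carries the threshold actually
used.

## Decision statistics

`roc_with_youden()` computes the empirical ROC over all achievable cuts,
reporting thresholds at midpoints between adjacent distinct scores (the
value of a threshold between two observed scores is otherwise arbitrary).
AUC is the trapezoid area, which equals the tie-corrected Mann-Whitney
U / (n1 n0); tests pin this against exhaustive pair counting. The Youden
maximiser is chosen uniformly at random among ties under the caller's seed.
Confidence intervals are percentile bootstrap over subjects, resampled
within class (2000 replicates by default; the replicate count behind the
published intervals is unknown, and percentile intervals were chosen over
normal-theory ones to avoid distributional assumptions on thresholds).

`contingency_eval()` places the boundary value in the low cell (matching the
"score at most the threshold" group definitions), reports event fractions
with explicit numerators and denominators, and uses the conventional
two-sided Fisher exact rule (sum of tables with point probability at most
the observed). `wilcoxon_rank_sum()` enumerates all rank splits exactly for
m + n ≤ 12 -- midranks included, which base R's exact path does not support
under ties -- and otherwise uses the tie-corrected normal approximation with
continuity correction, recording the mode used. `power_at()` and
`power_sample_size()` use the one-sample noncentral-t formulation, the
formulation consistent with both published numbers (n > 33 at d = 0.5,
power ≈ 0.30 at n = 10); a two-sample formulation reproduces neither.

## Problem sizes used by the test-suite and acceptance script

Full-scale runs use cohorts of 30 subjects per stratum at 2000 cells per
subject. Within a run the pipeline works at sizes chosen for desk-scale
reproducibility: discovery on a 10-subject arm (5 DP patients, 5 healthy
donors, mirroring a small discovery cohort), validation on a 48-subject arm
(31 patients, 17 donors), clustering on a 1000-cell-per-subject subsample,
and stage-2 scoring on 1000 cells per subject. A few hundred cells per
subject resolve subpopulations down to ~1% frequency, and the per-subject
mean probability changes only by binomial noise under subsampling.
Threshold-recovery experiments use 30 + 30 non-GVHD subjects over 50 seeds;
panel-recovery experiments use 20 seeds.

## Numerical choices and degenerate inputs

* Stage seeds fan out from one global seed as `seed * 100 + stage`, so any
  stage can be rerun in isolation; rerunning a pipeline with the same seed
  reproduces identical stage hashes (and tests assert this byte-level).
* Beta draws with κ = Inf collapse to a point mass, giving exact planted
  frequencies for calibration tests.
* Zero-variance markers are zeroed, not dropped, so marker indices stay
  stable across stages.
* `enumerate_combos()` orders subsets lexicographically in the candidate
  order; all tie-breaks downstream are deterministic.
* Every diseased subject's CD19+CD20- compartment is floored at 1% of B
  cells, mirroring the clinical observation that motivates using CD19+
  cells as the denominator.

## Known limitations

* The cGPS transform is an identity stand-in (see above); absolute score
  values on real data depend on the true formula.
* The generator's clean Gaussian mixtures make clustering and gating easier
  than on real spectral cytometry; batch effects are additive and
  marker-independent across cells, which is what the linear regression
  removes exactly. Real batch structure is messier.
* Stage-1 accuracy filtering passes nearly all candidate subsets on
  synthetic data (the disease template differs from the bulk on every
  candidate marker), so the two-stage funnel narrows almost entirely at
  stage 2; on the original data the accuracy stage was reported to be
  selective as well.
* FCS support covers list-mode FCS 3.0/3.1 with a single data segment and
  uniform bit width -- the common case for exported cytometry matrices --
  and reading only.
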