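---
title: "Stability-selected biomarker panels from EV proteomics: methods and design"
author: "evpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-selected biomarker panels from EV proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evpanel)
```

# The problem

Targeted proximity-extension-assay (PEA) panels measure ~100 proteins in
small case/control cohorts — here, extracellular-vesicle (EV) preparations
from plasma of cancer patients and healthy controls, a few dozen subjects
per arm. At this scale, single train/test splits are unstable and a feature
ranked highly once may never replicate. `evpanel` implements a resampling
workflow that asks two separable questions:

1. **Stability** — how often is a protein selected when the training set is
   perturbed? A protein selected in ≥ 60% of 100 random 70/30 splits is
   called *stable*.
2. **Out-of-sample discrimination** — how well do models built on the
   selected proteins classify subjects they never saw? Each subject's
   held-out predictions are aggregated by their median over all splits in
   which the subject was in the test set, and the AUC of these per-subject
   medians is the *pooled out-of-fold (OOF) AUC*.

Decoupling the classifier (always ridge logistic) from the selector (three
different algorithms) isolates the effect of feature choice.

# Data model

The central container is `NpxExperiment`, a `SummarizedExperiment` with
proteins in rows and samples in columns. NPX values are log2-scale relative
abundances; +1 unit is a doubling of signal. Two masks accompany the values:
`missing` (no measurement) and `belowLOD` (measured but under the assay
limit of detection). Below-LOD values are *retained* by the container — the
filtering step owns the censoring policy. Sample metadata carry the group
(`HC`, `PT_BE`, `PT_FU`: healthy control, patient baseline, patient
follow-up) and a subject identifier pairing baseline with follow-up.

## Filtering

Two filters define the analyzable protein set, in this order:

* `filterLOD()` removes proteins whose below-LOD fraction (over non-missing
  cells) exceeds a threshold. The threshold is a design choice — assays
  report LOD per measurement, not a protein-level rule — and defaults to
  0.5. For retained proteins the remaining below-LOD cells become missing
  under the default policy (so the in-split median imputation handles them);
  a substitution-with-LOD policy is available because vendor pipelines
  differ in whether censored values are dropped or substituted upstream.
* `filterMissing()` removes proteins with *strictly more than* 30% missing
  cells; a protein missing in exactly 30% of samples is retained.

# Statistical stages

**Normality gate.** Group comparisons dispatch on a one-sample
Kolmogorov–Smirnov test against a normal with the sample mean and SD
(Gaussian if p ≥ 0.05). KS with estimated parameters is anti-conservative
(it passes too easily); we keep it as the default dispatch rule because it
is the stated method of the workflow the package reproduces, and expose a
Lilliefors-corrected variant (`lilliefors = TRUE`, via nortest) for users
who want a calibrated gate. A constant sample is declared non-Gaussian.

**Differential expression.** Per protein: Student's t (equal variances) if
both groups pass the gate, otherwise Wilcoxon rank-sum; three-group
comparisons use ANOVA or Kruskal–Wallis under the same gate. p-values are
BH-adjusted across proteins. The baseline-vs-follow-up comparison runs
*unpaired* by default because the dispatched tests are the unpaired ones;
a paired mode exists (`paired = TRUE`) since the pairing structure is known —
the workflow's original choice is not documented, so both are offered.

**Volcano rule.** `up` requires q < 0.05 *and* ΔNPX > 1 (strictly); 1 log2
unit corresponds exactly to a 2-fold linear change. Boundary values
(ΔNPX = 1) are non-significant.

**ROC.** Empirical AUC with the midrank tie convention; the operating
threshold maximizes Youden's J, with ties resolved toward the lowest
threshold. The confidence interval is DeLong by default with a seeded
stratified bootstrap (2000 replicates) as fallback for degenerate variance.

# Projections

PCA and PLS-DA both run on centered, unit-variance-scaled data. PLS-DA is a
NIPALS PLS2 fit against a centered one-indicator-column-per-class response.
Two numerical conventions matter for reproducibility:

* **Sign convention** — each component is flipped so the largest-magnitude
  element of its weight vector is positive; scores, loadings and y-loadings
  flip together. This makes fits bit-identical across runs.
* **Prefix-consistent projection** — new samples are projected by sequential
  deflation (score, deflate, next component), so the first *a* columns of
  the projected scores equal the scores of the *a*-component submodel. This
  matters for the component-count cross-validation, where prediction error
  is evaluated at every truncation of one fitted model; truncating the
  columns of the full-model rotation matrix would *not* give the submodel's
  scores because the weight/loading cross-product is triangular rather than
  diagonal.

VIP scores use the standard formula — protein j's squared weight per
component, weighted by the Y-variance each component explains, scaled so the
mean squared VIP is 1.

The PLS-DA component count is chosen by repeated stratified M-fold CV
(default 5 folds × 10 repeats) minimizing the *balanced* misclassification
error of max-indicator class assignment, ties resolved toward fewer
components. The error metric is our choice (the reproduced workflow names
only the CV design); balanced error protects the 28/29 design against
trivial majority-class solutions.

# The three selectors

All selectors see the same in-split standardized training matrix and return
at most five proteins ordered by decreasing importance, ties broken
lexicographically by protein id (determinism).

* **Shadow-feature selection** (`borutaSelect`) — per iteration, every
  feature gets a shuffled shadow copy, a random forest is fitted, and a
  feature scores a "hit" if its importance beats the best shadow. After
  `nIter` iterations a two-sided binomial test (null hit rate 0.5) at
  confidence 0.01 with Bonferroni correction across features classifies
  confirmed / tentative / rejected. The importance learner is ranger with
  *scaled permutation importance* — the learner classical shadow-feature
  selection uses; it is noticeably better calibrated on null data than
  impurity importance, which we found confirms a spurious feature in 2–3×
  more null datasets. Ranking is by median importance across iterations.
  When fewer than five features are confirmed, the top-5 contract is met by
  topping up from the highest-ranked *tentative* features (never rejected
  ones).
* **Elastic net** (`elasticNetSelect`) — glmnet logistic path at mixing
  α = 0.5, penalty chosen by cross-validated AUC at the CV-*optimal* point
  (`lambda.min`; the 1-SE rule is reserved for the ridge classifier). Up to
  five non-zero coefficients by absolute magnitude; the selection may be
  empty when the optimal path point is fully sparse.
* **PLS-DA / VIP** (`plsdaSelect`) — component count by the CV above, top
  five proteins by VIP. The fitted projection is retained so the classifier
  stage can use component scores as predictors.

# The MCCV engine

`runMCCV()` executes, per split (100 stratified 70/30 splits by default;
class-wise training size is `round(0.7 · n_class)`, so the 28/29 design
yields 20 + 20 training samples):

1. training-column medians → imputation values, applied to train *and* test;
2. training mean/SD → z-scoring, applied to train and test;
3. selector on the standardized training data → up to 5 proteins;
4. ridge logistic on the selected features (for the PLS-DA selector, on PLS
   component scores derived from the selected proteins, re-standardized);
5. prediction on the transformed test split.

No statistic ever flows from test to train; the test suite asserts that a
test sample's prediction is invariant to arbitrary perturbation of other
test rows.

**Ridge with the 1-SE rule.** The penalty path is fitted with glmnet over a
fixed grid of 100 log-spaced penalties (10² … 10⁻⁴, appropriate for
z-scored predictors); 10-fold CV binomial deviance per penalty; the chosen
penalty is the *largest* one whose CV loss is within one standard error of
the minimum. The CV curve is stored in the fit so the rule can be recomputed
independently. Edge cases the elastic-net selector can produce: one selected
feature (glmnet requires ≥ 2 columns) is fitted by an internal IRLS ridge on
the same grid; zero selected features degenerate to an intercept-only model
predicting the training prevalence.

**Aggregation.** Per-split test AUCs are summarized by median and IQR; the
pooled OOF AUC is computed over per-subject median held-out probabilities
with a seeded percentile bootstrap over subjects for the CI. All randomness
(split plans, selector seeds, ridge folds, bootstrap) derives from one root
seed.

**Consensus.** Stable sets are computed at the 60% threshold per selector.
Two consensus rules are implemented because the workflow description and its
schematic state different ones: strict stable-set intersection, and the
top-2 proteins by summed selection frequency across selectors. On the
published frequency table they disagree — the second-ranked protein sits at
53% under the elastic net, so the intersection returns a single protein
while the aggregate rule returns the expected pair. The aggregate rule is
therefore the default (`rule = "top_k_aggregate"`, k = 2) and both are
exposed; `consensusPanel()` warns when the intersection is empty. The panel
is re-evaluated on a fresh set of 100 splits with no reselection
(`evaluatePanel()`).

# Treatment response

`%ΔSLD = 100 · (SLD_followup − SLD_baseline)/SLD_baseline` (negative =
regression). Per protein, Spearman correlation between ΔNPX and %ΔSLD with
BH adjustment (ρ < 0: the protein rises with tumor regression). Quartiles of
ΔNPX are *rank-based* (value-based quantile cut-points would leave bin sizes
tie-dependent): subjects are ordered by ΔNPX with ties broken by subject id,
and the remainder is assigned to the lower quartiles first, so n = 27 gives
sizes (7, 7, 7, 6). Q1 vs Q4 %ΔSLD is compared by t-test when both extreme
quartiles pass the normality gate (and have ≥ 3 values), otherwise Wilcoxon.
Patients lacking follow-up imaging are excluded.

# The synthetic cohort generator

Because the motivating study's data are available only on request, the
package ships a generator whose defaults *are* the study design: 28 healthy
controls, 29 patients at baseline, 27 with follow-up, 60 proteins, two
planted diagnostic markers with a +2 log2-unit shift at unit per-protein
noise SD (a 2-SD effect, matching the strong separations reported for the
top markers), 5% missing-completely-at-random cells, below-LOD flagging at
the 2% lower tail of the control distribution, and three planted
treatment-response proteins at target Spearman ρ = 0.6 (the magnitude of
the reported response correlations).

Design choices worth knowing:

* Baseline NPX is independent normal per protein (means uniform on 1–10).
  NPX is log-scale and approximately Gaussian in practice; independence
  makes the planted-recovery oracles exact. Real panels have correlated
  proteins — passing tests here demonstrate correctness of the machinery,
  not performance on correlated proteomes.
* Follow-up values are the subject's baseline minus `fu_reversion` × the
  planted effect plus fresh within-subject noise at half the between-subject
  SD (within-subject variation is smaller than between-subject; the exact
  ratio is a modeling choice).
* The ΔNPX–%ΔSLD coupling uses a Gaussian copula: the bivariate-normal
  Pearson correlation is set to `2·sin(π·ρ/6)` so the *population Spearman*
  equals the target exactly; %ΔSLD is a strictly increasing (hence
  rank-preserving) logistic transform of the latent response, centered on
  partial response. Response coupling is generated at the Δ level by
  `generateResponseData()`; the cohort matrix itself does not couple
  follow-up noise to tumor response.
* Ct-level readouts (`generateCtData()`) exercise the NPX derivation
  exactly: the bundled NPX matrix is reproduced to machine precision by
  `computeNPX()`.

Below-LOD values are retained with a flag rather than truncated, so the
filter module's policy is the only censoring applied.

# Benchmark problem sizes

The resampling checks in the test suite and `scripts/acceptance.R` run the
full study design (28 + 29 subjects, 60 proteins, 100 MCCV splits, 10
pipeline seeds) with reduced *selector internals*, chosen once as the
package's benchmark sizes: shadow-feature selection at 25 iterations × 50
trees inside the MCCV loop (100 iterations × 100 trees for the standalone
type-I-control check), PLS-DA component CV at 5 folds × 2 repeats, elastic
net at 5 internal folds. At these sizes the planted markers are selected in
every split and the planted panel is recovered, so the reduction does not
bind; the defaults (500/500, 10 repeats) remain the production settings.

# Known limitations

* The null distribution of the *evaluated panel's* pooled OOF AUC is wider
  than binomial-chance intuition suggests: the consensus panel is chosen on
  the same cohort it is then re-evaluated on, so on effect-free data the
  top-2-aggregate panel is enriched for spuriously discriminative proteins
  and its pooled AUC can exceed 0.65 in a noticeable fraction of null
  cohorts at n = 57. The fresh splits remove split-level optimism, not
  dataset-level selection bias. A truly unbiased null check would nest the
  consensus derivation inside an outer resampling loop, which the reproduced
  workflow does not do.
* Shadow-feature selection at n ≈ 57 occasionally confirms one spurious
  feature on null data even at confidence 0.01 — a dataset whose most
  extreme spurious correlation is large will beat freshly shuffled shadows
  consistently, whatever the learner. Scaled permutation importance keeps
  this rare (~1 in 10 null cohorts) but cannot eliminate it.
* KS-with-estimated-parameters is anti-conservative as a normality gate
  (see above); the dispatch consequently favors t-tests slightly.
* The generator does not simulate plate effects beyond a single inter-plate
  control, assay cross-reactivity, correlated proteins, or clinical
  covariates; subgroup sensitivity analyses are exercised by subsetting
  (`rerunSubgroup()`), not by simulating confounders.
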