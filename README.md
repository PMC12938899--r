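# evpanel

Biomarker-panel discovery for targeted (proximity extension assay, PEA)
proteomics of extracellular-vesicle (EV) preparations. The package is aimed
at case/control plasma-proteomics studies of modest size — tens of subjects,
~100 proteins on a targeted panel — where the question is not only *which
proteins differ* but *which small panel of proteins is robustly selected and
how well it classifies previously unseen subjects*.

## What it does

Protein abundance enters as **NPX** (Normalized Protein Expression), the
log2-scale relative quantity derived from qPCR cycle thresholds:

    dCt_analyte  = Ct_analyte − Ct_extension-control
    ddCt_analyte = dCt_analyte − dCt_inter-plate-control
    NPX_analyte  = correction factor − ddCt_analyte

so +1 NPX is a doubling of assay signal. On top of that the package
implements:

* **Filtering** — proteins under the assay limit of detection (configurable
  below-LOD fraction, default 0.5) and proteins with >30% missing values.
* **Univariate statistics** — per-protein two-group tests (Student's t /
  Wilcoxon rank-sum, dispatched by a Kolmogorov–Smirnov normality gate),
  three-group ANOVA / Kruskal–Wallis, Benjamini–Hochberg q-values, volcano
  classification (q < 0.05 and |ΔNPX| > 1, i.e. > 2-fold linear change), and
  single-marker ROC curves with the operating point set by Youden's
  J = sensitivity + specificity − 1.
* **Projections** — PCA and NIPALS PLS-DA on centered/scaled data, with
  per-component variance explained and VIP scores (mean squared VIP = 1).
* **The stability-selection loop** — 100-iteration Monte-Carlo
  cross-validation (70/30 stratified splits). Within each training split:
  median imputation, z-scoring, then one of three feature selectors
  (shadow-feature random forest à la Boruta; elastic net with α = 0.5 and
  CV-AUC penalty choice; PLS-DA ranked by VIP), each returning its top 5
  proteins; a ridge-penalized logistic classifier (penalty by 10-fold CV
  with the 1-SE rule, λ.1se) is fitted on the selected features — for the
  PLS-DA selector, on PLS component scores derived from them — and applied
  to the identically transformed test split. Performance is summarized by
  the per-split held-out AUC distribution and a **pooled out-of-fold AUC**
  over per-subject median held-out probabilities.
* **Consensus panel** — per-selector *stable sets* (selection frequency
  ≥ 60%) and a consensus panel by either the top-2 summed-frequency rule or
  strict stable-set intersection, re-evaluated on a fresh set of splits.
* **Treatment response** — per-protein Spearman correlation (BH-corrected)
  between within-patient NPX change (ΔNPX = follow-up − baseline) and
  percent change in RECIST tumor burden (%ΔSLD), plus a Q1-vs-Q4 ΔNPX
  quartile comparison.
* **Synthetic cohorts** — a seeded generator planting known diagnostic
  shifts and response correlations, so every stage can be validated against
  ground truth.

## Worked example

```r
library(evpanel)

cohort <- generateNpxCohort(syntheticConfig(seed = 1))   # 28 HC + 29 PT_BE + 27 PT_FU

# filtering (LOD, >30% missingness), differential stats, ROC, projections,
# three-selector MCCV, consensus panel and fresh-split panel evaluation:
res <- runPipeline(cohort$experiment, nSplits = 100,
                   selectorArgs = list(boruta = list(nIter = 25, numTrees = 50),
                                       plsda  = list(repeats = 2)),
                   seed = 1)

cohort$truth$planted_diag_ids
#> [1] "PROT004" "PROT057"
panelProteins(res$consensus)
#> [1] "PROT004" "PROT057"
res$panel_eval
#> MccvResult (none): 100 splits
#>   per-split AUC median 0.986 (IQR 0.972-1.000)
#>   pooled OOF AUC 0.980 (CI 0.946-1.000)
sort(selectionFreq(res$mccv$boruta), decreasing = TRUE)[1:3]
#> PROT004 PROT057 PROT001
#>    1.00    1.00    0.54
```

The two planted markers (a +2 log2-unit shift at unit noise SD) are selected
in every split by all three selectors, the consensus panel recovers exactly
the planted pair, and the panel classifies held-out subjects with a pooled
out-of-fold AUC of 0.98.

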