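#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom stats median sd quantile rnorm runif setNames var
#'   p.adjust ks.test t.test wilcox.test kruskal.test aov anova cor.test
#'   prcomp predict coef plogis qlogis pbinom model.matrix
#' @importFrom utils head read.csv write.csv write.table
NULL

VALID_GROUPS <- c("HC", "PT_BE", "PT_FU")

#' NpxExperiment: container for NPX protein-expression data
#'
#' An S4 container for Normalized Protein Expression (NPX, log2 scale) data
#' from proximity extension assays, extending
#' [SummarizedExperiment::SummarizedExperiment]. Rows are proteins, columns
#' are samples. Three conformable assays are carried: `npx` (numeric, `NA`
#' at missing cells), `missing` (logical mask, `TRUE` where the value is
#' missing) and `belowLOD` (logical mask, `TRUE` where the measured value
#' fell below the assay limit of detection; such values are retained until a
#' filtering policy decides their fate). Column data must contain `group`
#' (one of `"HC"`, `"PT_BE"`, `"PT_FU"`: healthy control, patient baseline,
#' patient follow-up) and `subject_id` (pairs a patient's baseline with their
#' follow-up sample; `NA` for controls).
#'
#' @slot .. inherited from SummarizedExperiment.
#'
#' @seealso [NpxExperiment()] for construction, [npx()], [missingMask()],
#'   [belowLodMask()], [sampleGroup()], [subjectId()] for access.
#' @export
setClass("NpxExperiment", contains = "SummarizedExperiment")

setValidity("NpxExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  need <- c("npx", "missing", "belowLOD")
  if (!all(need %in% an))
    return(sprintf("assays must include %s", paste(need, collapse = ", ")))
  v <- SummarizedExperiment::assay(object, "npx")
  m <- SummarizedExperiment::assay(object, "missing")
  b <- SummarizedExperiment::assay(object, "belowLOD")
  if (!is.logical(m) || !is.logical(b))
    msg <- c(msg, "'missing' and 'belowLOD' assays must be logical")
  if (!identical(dim(v), dim(m)) || !identical(dim(v), dim(b)))
    msg <- c(msg, "assay dimensions do not agree")
  if (is.logical(m) && any(is.na(v) != m))
    msg <- c(msg, "'npx' must be NA exactly where 'missing' is TRUE")
  if (any(!is.finite(v[!is.na(v)])))
    msg <- c(msg, "non-missing NPX values must be finite")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("group", "subject_id") %in% colnames(cd)))
    return("colData must contain 'group' and 'subject_id'")
  grp <- as.character(cd$group)
  if (!all(grp %in% VALID_GROUPS))
    msg <- c(msg, sprintf("unknown group label(s): %s",
                          paste(unique(setdiff(grp, VALID_GROUPS)), collapse = ", ")))
  sid <- as.character(cd$subject_id)
  for (g in c("PT_BE", "PT_FU")) {
    ids <- sid[grp == g]
    if (anyNA(ids))
      msg <- c(msg, sprintf("%s samples must carry a subject_id", g))
    else if (anyDuplicated(ids))
      msg <- c(msg, sprintf("each subject may have at most one %s sample", g))
  }
  if (any(grp == "HC" & !is.na(sid)))
    msg <- c(msg, "HC samples must not carry a patient subject_id")
  if (length(msg)) msg else TRUE
})

#' Construct an NpxExperiment
#'
#' @param npx numeric matrix of NPX values, proteins in rows, samples in
#'   columns. `NA` marks missing cells. Row and column names are required
#'   (protein and sample identifiers).
#' @param group character or factor of per-sample groups, one of
#'   `"HC"`, `"PT_BE"`, `"PT_FU"`.
#' @param subjectId per-sample subject identifier pairing `PT_BE` with
#'   `PT_FU` rows; `NA` for controls.
#' @param belowLOD optional logical matrix flagging below-LOD cells
#'   (default: none).
#' @param lod optional per-protein limit of detection (NPX units), stored
#'   in `rowData`.
#' @return an [NpxExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2", "s3")))
#' se <- NpxExperiment(m, group = c("HC", "HC", "PT_BE"),
#'                     subjectId = c(NA, NA, "pt1"))
#' @export
NpxExperiment <- function(npx, group, subjectId,
                          belowLOD = NULL, lod = NULL) {
  npx <- as.matrix(npx)
  if (is.null(rownames(npx)) || is.null(colnames(npx)))
    stop("'npx' must have protein row names and sample column names")
  storage.mode(npx) <- "double"
  if (is.null(belowLOD))
    belowLOD <- matrix(FALSE, nrow(npx), ncol(npx), dimnames = dimnames(npx))
  missing <- is.na(npx)
  cd <- S4Vectors::DataFrame(
    group = factor(as.character(group), levels = VALID_GROUPS),
    subject_id = as.character(subjectId),
    row.names = colnames(npx))
  rd <- S4Vectors::DataFrame(row.names = rownames(npx))
  if (!is.null(lod)) rd$lod <- lod
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(npx = npx, missing = missing, belowLOD = belowLOD),
    colData = cd, rowData = rd)
  methods::new("NpxExperiment", se)
}

#' SyntheticConfig: parameters of the synthetic NPX cohort generator
#'
#' Holds the study-design parameters of a simulated case/control proteomics
#' cohort with planted diagnostic and response signal. Defaults mirror the
#' target study design: 28 healthy controls, 29 patients at baseline of whom
#' 27 have a follow-up sample, ~60 analyzable proteins, two strongly
#' discriminative planted markers (a +2 log2-unit shift at unit noise SD).
#'
#' @slot n_hc number of healthy controls.
#' @slot n_pt number of patients (baseline samples).
#' @slot n_fu number of patients with a follow-up sample (<= n_pt).
#' @slot n_proteins number of proteins on the panel.
#' @slot n_planted_diag number of planted diagnostic markers.
#' @slot effect_log2 mean NPX shift (log2 units) of planted markers in
#'   patient baseline vs control.
#' @slot fu_reversion fraction in \[0,1\] of the planted shift removed at
#'   follow-up (treatment response).
#' @slot missing_rate MCAR missingness probability per cell.
#' @slot lod_quantile lower-tail quantile of the control distribution below
#'   which values are flagged below-LOD.
#' @slot n_planted_resp number of planted treatment-response proteins.
#' @slot resp_rho target Spearman correlation between planted-protein
#'   delta-NPX and percent change in tumor burden.
#' @slot noise_sd per-protein NPX standard deviation.
#' @slot seed integer seed; the whole cohort is reproducible from it.
#' @seealso [syntheticConfig()], [generateNpxCohort()]
#' @export
setClass("SyntheticConfig",
  representation(n_hc = "numeric", n_pt = "numeric", n_fu = "numeric",
                 n_proteins = "numeric", n_planted_diag = "numeric",
                 effect_log2 = "numeric", fu_reversion = "numeric",
                 missing_rate = "numeric", lod_quantile = "numeric",
                 n_planted_resp = "numeric", resp_rho = "numeric",
                 noise_sd = "numeric", seed = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  cnt <- c(n_hc = object@n_hc, n_pt = object@n_pt, n_fu = object@n_fu,
           n_proteins = object@n_proteins,
           n_planted_diag = object@n_planted_diag,
           n_planted_resp = object@n_planted_resp)
  bad <- names(cnt)[cnt < 0 | cnt != floor(cnt)]
  if (length(bad))
    msg <- c(msg, sprintf("count field(s) must be non-negative integers: %s",
                          paste(bad, collapse = ", ")))
  if (object@n_fu > object@n_pt)
    msg <- c(msg, "n_fu: must not exceed n_pt")
  if (object@n_planted_diag + object@n_planted_resp > object@n_proteins)
    msg <- c(msg, "n_planted_diag + n_planted_resp: must not exceed n_proteins")
  if (object@missing_rate < 0 || object@missing_rate > 1)
    msg <- c(msg, "missing_rate: must lie in [0, 1]")
  if (object@lod_quantile < 0 || object@lod_quantile >= 1)
    msg <- c(msg, "lod_quantile: must lie in [0, 1)")
  if (object@fu_reversion < 0 || object@fu_reversion > 1)
    msg <- c(msg, "fu_reversion: must lie in [0, 1]")
  if (abs(object@resp_rho) >= 1)
    msg <- c(msg, "resp_rho: must lie in (-1, 1)")
  if (object@noise_sd <= 0)
    msg <- c(msg, "noise_sd: must be positive")
  if (length(msg)) msg else TRUE
})

#' SelectorOutput: one feature selector's result on one training split
#'
#' @slot model selector name: "boruta", "elastic_net" or "plsda".
#' @slot split_index index of the MCCV split the selector was run on.
#' @slot selected up to five protein ids, ordered by decreasing importance
#'   (median shadow-margin importance, absolute coefficient, or VIP), ties
#'   broken lexicographically by protein id.
#' @slot importance named numeric importance score per protein.
#' @slot diagnostics selector-specific list (confirmed/tentative/rejected
#'   sets for the shadow-feature selector; chosen penalty for the elastic
#'   net; chosen component count and fitted projection for PLS-DA).
#' @export
setClass("SelectorOutput",
  representation(model = "character", split_index = "numeric",
                 selected = "character", importance = "numeric",
                 diagnostics = "list"))

setValidity("SelectorOutput", function(object) {
  msg <- character()
  if (!object@model %in% c("boruta", "elastic_net", "plsda"))
    msg <- c(msg, "unknown selector model")
  if (length(object@selected) > 5)
    msg <- c(msg, "at most 5 features may be selected")
  if (length(msg)) msg else TRUE
})

#' MccvResult: Monte-Carlo cross-validation performance summary
#'
#' @slot per_split_auc held-out test-set AUC of each split.
#' @slot per_subject_oof named list: for each subject, the held-out
#'   predicted probabilities from every split in which it was in the test
#'   set.
#' @slot subject_labels named 0/1 class label per subject.
#' @slot pooled_oof_auc AUC over per-subject median out-of-fold
#'   probabilities.
#' @slot pooled_oof_ci bootstrap confidence interval of the pooled AUC.
#' @slot selection_freq named per-protein fraction of splits in which the
#'   protein was selected (all zero for fixed-panel evaluation).
#' @slot selector selector used ("boruta", "elastic_net", "plsda" or
#'   "none" for fixed-panel evaluation).
#' @export
setClass("MccvResult",
  representation(per_split_auc = "numeric", per_subject_oof = "list",
                 subject_labels = "numeric", pooled_oof_auc = "numeric",
                 pooled_oof_ci = "numeric", selection_freq = "numeric",
                 selector = "character"))

setValidity("MccvResult", function(object) {
  msg <- character()
  if (length(object@selection_freq) &&
      (min(object@selection_freq) < 0 || max(object@selection_freq) > 1))
    msg <- c(msg, "selection frequencies must lie in [0, 1]")
  if (length(object@pooled_oof_auc) == 1 &&
      (object@pooled_oof_auc < 0 || object@pooled_oof_auc > 1))
    msg <- c(msg, "pooled OOF AUC must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ConsensusPanel: stable sets per selector and the consensus protein panel
#'
#' @slot stable_sets named list (one element per selector) of proteins whose
#'   selection frequency reached the stability threshold.
#' @slot panel consensus protein ids.
#' @slot rule consensus rule used: "top_k_aggregate" or
#'   "stable_intersection".
#' @slot stability stability threshold (fraction of splits).
#' @slot freq_table data.frame of per-model selection frequencies.
#' @export
setClass("ConsensusPanel",
  representation(stable_sets = "list", panel = "character",
                 rule = "character", stability = "numeric",
                 freq_table = "data.frame"))

#' @describeIn NpxExperiment-class compact display.
#' @param object an object of the documented class.
#' @export
setMethod("show", "NpxExperiment", function(object) {
  callNextMethod()
  grp <- table(sampleGroup(object))
  cat("groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = " "), "\n")
  cat(sprintf("missing: %.1f%%; below LOD: %.1f%%\n",
              100 * mean(missingMask(object)),
              100 * mean(belowLodMask(object))))
})

#' @describeIn MccvResult-class compact display.
#' @param object an object of the documented class.
#' @export
setMethod("show", "MccvResult", function(object) {
  cat(sprintf("MccvResult (%s): %d splits\n",
              object@selector, length(object@per_split_auc)))
  cat(sprintf("  per-split AUC median %.3f (IQR %.3f-%.3f)\n",
              median(object@per_split_auc),
              quantile(object@per_split_auc, 0.25),
              quantile(object@per_split_auc, 0.75)))
  cat(sprintf("  pooled OOF AUC %.3f (CI %.3f-%.3f)\n",
              object@pooled_oof_auc,
              object@pooled_oof_ci[1], object@pooled_oof_ci[2]))
})

#' @describeIn ConsensusPanel-class compact display.
#' @param object an object of the documented class.
#' @export
setMethod("show", "ConsensusPanel", function(object) {
  cat(sprintf("ConsensusPanel (rule=%s, stability=%.2f)\n",
              object@rule, object@stability))
  for (m in names(object@stable_sets))
    cat(sprintf("  stable[%s]: %s\n", m,
                paste(object@stable_sets[[m]], collapse = ", ")))
  cat("  panel:", paste(object@panel, collapse = ", "), "\n")
})
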