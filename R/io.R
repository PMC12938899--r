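## File formats: wide NPX CSV (sample_id, subject_id, group, one column per
## protein; empty cell = missing), long Ct CSV, response CSV; JSON reports.

#' Read a wide NPX table
#'
#' Parses the wide CSV dialect: one row per sample with columns
#' `sample_id`, `subject_id`, `group` followed by one numeric column per
#' protein; empty cells are missing. Validation is strict: duplicate sample
#' ids, unknown group labels and an empty protein column set are rejected
#' with row/column context.
#'
#' @param path CSV file path.
#' @return an [NpxExperiment-class].
#' @export
readNpxTable <- function(path) {
  if (!file.exists(path)) dataError("file not found: %s", path)
  d <- read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "subject_id", "group")
  if (!all(need %in% names(d)))
    dataError("NPX table must start with columns: %s",
              paste(need, collapse = ", "))
  protCols <- setdiff(names(d), need)
  if (length(protCols) == 0)
    dataError("NPX table has no protein columns")
  if (anyDuplicated(d$sample_id)) {
    dup <- d$sample_id[duplicated(d$sample_id)][1]
    dataError("duplicate sample_id: %s", dup)
  }
  bad <- setdiff(unique(d$group), VALID_GROUPS)
  if (length(bad))
    dataError("unknown group label(s): %s", paste(bad, collapse = ", "))
  vals <- matrix(NA_real_, length(protCols), nrow(d),
                 dimnames = list(protCols, d$sample_id))
  for (pc in protCols) {
    raw <- d[[pc]]
    empty <- is.na(raw) | raw == ""
    num <- suppressWarnings(as.numeric(raw))
    if (any(!empty & is.na(num))) {
      row <- which(!empty & is.na(num))[1]
      dataError("non-numeric cell in column '%s', row %d: '%s'",
                pc, row, raw[row])
    }
    vals[pc, ] <- num
  }
  sid <- d$subject_id
  sid[sid == ""] <- NA_character_
  NpxExperiment(vals, group = d$group, subjectId = sid)
}

#' Write a wide NPX table
#'
#' Inverse of [readNpxTable()] (the below-LOD mask is not serialized in
#' this dialect).
#'
#' @param x an [NpxExperiment-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeNpxTable <- function(x, path) {
  d <- data.frame(sample_id = colnames(x),
                  subject_id = ifelse(is.na(subjectId(x)), "",
                                      subjectId(x)),
                  group = as.character(sampleGroup(x)),
                  check.names = FALSE)
  d <- cbind(d, as.data.frame(t(npx(x)), check.names = FALSE))
  write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long-format Ct table
#'
#' Columns: `sample_id`, `analyte_id`, `plate_id`, `ct_analyte`,
#' `ct_extension_control`.
#'
#' @param path CSV file path.
#' @return data.frame suitable for [computeNPX()].
#' @export
readCtTable <- function(path) {
  if (!file.exists(path)) dataError("file not found: %s", path)
  d <- read.csv(path, check.names = FALSE)
  need <- c("sample_id", "analyte_id", "plate_id", "ct_analyte",
            "ct_extension_control")
  if (!all(need %in% names(d)))
    dataError("Ct table lacks column(s): %s",
              paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Read per-patient response (SLD) data
#'
#' Columns: `subject_id`, `sld_baseline`, `sld_followup`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readResponseTable <- function(path) {
  if (!file.exists(path)) dataError("file not found: %s", path)
  d <- read.csv(path, check.names = FALSE)
  need <- c("subject_id", "sld_baseline", "sld_followup")
  if (!all(need %in% names(d)))
    dataError("response table lacks column(s): %s",
              paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Write a synthetic cohort to disk
#'
#' Writes the wide NPX CSV plus a JSON ground-truth sidecar
#' (`<stem>_truth.json`).
#'
#' @param cohort output of [generateNpxCohort()].
#' @param path CSV path for the NPX table.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  writeNpxTable(cohort$experiment, path)
  truth <- cohort$truth
  truth$config <- NULL
  jsonlite::write_json(truth,
                       sub("\\.csv$", "_truth.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full biomarker-discovery pipeline
#'
#' Orchestrates the analysis stages on an [NpxExperiment-class]: below-LOD
#' and >30%-missingness filters; two-group differential expression (control
#' vs patient baseline) with volcano classification; single-marker ROC of
#' the top differential proteins; the three-selector Monte-Carlo
#' cross-validation stability loop; consensus-panel derivation; panel
#' re-evaluation on fresh splits; and, when SLD data are supplied, the
#' treatment-response correlation analysis. Deterministic given the root
#' seed.
#'
#' @param x an [NpxExperiment-class].
#' @param sld optional per-patient SLD data.frame (see [responseTable()]).
#' @param groups the two groups classified (second = positive class).
#' @param maxBelowLodFrac,maxMissingFrac filter thresholds.
#' @param nSplits,trainFrac MCCV design.
#' @param stability,rule,k consensus parameters, see [consensusPanel()].
#' @param selectors selectors to run (default all three).
#' @param selectorArgs named list of per-selector argument lists, e.g.
#'   `list(boruta = list(nIter = 100, numTrees = 100))`.
#' @param internalFolds ridge penalty CV folds.
#' @param seed root seed for every stochastic stage.
#' @param outDir optional directory: reports are written as CSV/TSV + JSON.
#' @return list: `filtered` (experiment), `filter_reports`, `differential`,
#'   `roc`, `pca`, `plsda` (projection summaries), `mccv` (per selector),
#'   `consensus`, `panel_eval`, `response` (or `NULL`), `seed`.
#' @export
runPipeline <- function(x, sld = NULL, groups = c("HC", "PT_BE"),
                        maxBelowLodFrac = 0.5, maxMissingFrac = 0.30,
                        nSplits = 100, trainFrac = 0.7, stability = 0.60,
                        rule = "top_k_aggregate", k = 2,
                        selectors = c("boruta", "elastic_net", "plsda"),
                        selectorArgs = list(), internalFolds = 10,
                        seed = 1, outDir = NULL) {
  if (!methods::is(x, "NpxExperiment"))
    configError("'x' must be an NpxExperiment")
  seeds <- childSeeds(seed, length(selectors) + 2)
  fl <- filterLOD(x, maxBelowLodFrac)
  fm <- filterMissing(fl$experiment, maxMissingFrac)
  xf <- fm$experiment
  diffRes <- twoGroupTest(xf, groups[1], groups[2])
  rocRes <- topMarkerRoc(xf, diffRes, groups[1], groups[2], seed = seed)
  ## projection summaries on globally median-imputed data (display stage;
  ## classifier imputation stays in-split)
  xi <- imputeColumns(t(npx(xf)), columnMedians(t(npx(xf))))
  pca <- fitPCA(xi, nComponents = min(2, nrow(xf)))
  pls <- fitPLSDA(xi[sampleGroup(xf) %in% groups, , drop = FALSE],
                  droplevels(sampleGroup(xf)[sampleGroup(xf) %in% groups]),
                  nComponents = 2)
  mccv <- list()
  for (i in seq_along(selectors)) {
    s <- selectors[i]
    mccv[[s]] <- runMCCV(xf, selector = s, groups = groups,
                         nSplits = nSplits, trainFrac = trainFrac,
                         selectorArgs = if (!is.null(selectorArgs[[s]]))
                           selectorArgs[[s]] else list(),
                         internalFolds = internalFolds, seed = seeds[i])
  }
  consensus <- consensusPanel(mccv, stability = stability, rule = rule,
                              k = k)
  panelEval <- NULL
  if (length(panelProteins(consensus)))
    panelEval <- evaluatePanel(panelProteins(consensus), xf,
                               groups = groups, nSplits = nSplits,
                               trainFrac = trainFrac,
                               internalFolds = internalFolds,
                               seed = seeds[length(selectors) + 1])
  response <- NULL
  if (!is.null(sld)) {
    rt <- responseTable(xf, sld)
    response <- responseAnalysis(rt$delta_npx, rt$response$pct_delta_sld)
  }
  out <- list(filtered = xf,
              filter_reports = list(lod = fl$report, missing = fm$report),
              differential = diffRes, roc = rocRes,
              pca = pca, plsda = pls, mccv = mccv,
              consensus = consensus, panel_eval = panelEval,
              response = response, seed = seed)
  if (!is.null(outDir)) writePipelineReports(out, outDir)
  out
}

writePipelineReports <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) write.table(d, file.path(outDir, f), sep = "\t",
                                  row.names = FALSE, quote = FALSE)
  w(result$differential, "differential.tsv")
  w(result$roc, "roc_top_markers.tsv")
  w(result$consensus@freq_table, "selection_frequencies.tsv")
  perf <- do.call(rbind, lapply(names(result$mccv), function(m) {
    r <- result$mccv[[m]]
    data.frame(model = m,
               median_auc = median(perSplitAuc(r)),
               iqr_low = quantile(perSplitAuc(r), 0.25),
               iqr_high = quantile(perSplitAuc(r), 0.75),
               pooled_oof_auc = r@pooled_oof_auc,
               pooled_ci_low = r@pooled_oof_ci[1],
               pooled_ci_high = r@pooled_oof_ci[2])
  }))
  w(perf, "model_performance.tsv")
  panel <- list(panel = result$consensus@panel,
                rule = result$consensus@rule,
                stability = result$consensus@stability,
                stable_sets = result$consensus@stable_sets,
                seed = result$seed)
  if (!is.null(result$panel_eval)) {
    panel$pooled_oof_auc <- result$panel_eval@pooled_oof_auc
    panel$pooled_oof_ci <- result$panel_eval@pooled_oof_ci
    panel$median_auc <- median(perSplitAuc(result$panel_eval))
  }
  jsonlite::write_json(panel, file.path(outDir, "panel.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$response)) w(result$response, "response.tsv")
  reports <- list(
    lod = result$filter_reports$lod[c("removed", "n_input", "n_retained")],
    missing = result$filter_reports$missing[c("removed", "n_input",
                                              "n_retained")])
  jsonlite::write_json(reports, file.path(outDir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Re-run the pipeline on a sample subset (sensitivity analysis)
#'
#' Runs [runPipeline()] on the subset of samples satisfying `keep` — e.g.
#' restricting controls to ever-smokers — and labels the report with the
#' filter description.
#'
#' @param x an [NpxExperiment-class].
#' @param keep logical vector (per sample of `x`) or character vector of
#'   sample ids to retain.
#' @param description human-readable label of the subset.
#' @param ... passed to [runPipeline()].
#' @return as [runPipeline()], plus `subset_description`.
#' @export
rerunSubgroup <- function(x, keep, description = "subset", ...) {
  if (is.character(keep)) keep <- colnames(x) %in% keep
  if (length(keep) != ncol(x))
    configError("'keep' must select among the %d samples", ncol(x))
  xs <- x[, keep]
  args <- list(...)
  groups <- if (!is.null(args$groups)) args$groups else c("HC", "PT_BE")
  tab <- table(factor(as.character(sampleGroup(xs)), levels = groups))
  if (any(tab < 2))
    configError("subset leaves group '%s' with fewer than 2 samples",
                names(tab)[which(tab < 2)[1]])
  out <- runPipeline(xs, ...)
  out$subset_description <- description
  out
}
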