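#' Compute NPX from Ct-level readouts
#'
#' Applies the three-step derivation of Normalized Protein Expression from
#' qPCR cycle thresholds: correction of the analyte Ct against the
#' per-sample extension control, `dCt = ct_analyte - ct_extension_control`;
#' correction against the per-plate inter-plate control,
#' `ddCt = dCt - dct_interplate_control`; and adjustment against the
#' per-analyte correction factor, `NPX = correction_factor - ddCt`. NPX is
#' on the log2 scale: +1 NPX corresponds to a doubling of assay signal.
#'
#' @param readouts long data.frame with columns `sample_id`, `analyte_id`,
#'   `plate_id`, `ct_analyte`, `ct_extension_control`. Absent
#'   (sample, analyte) records yield missing cells.
#' @param interplate data.frame with columns `plate_id`, `analyte_id`,
#'   `dct`: the inter-plate-control delta-Ct per plate and analyte.
#' @param correction data.frame with columns `analyte_id`,
#'   `correction_factor`.
#' @return numeric matrix of NPX values, analytes in rows, samples in
#'   columns, `NA` where no readout exists.
#' @examples
#' r <- data.frame(sample_id = "s1", analyte_id = "a1", plate_id = "p1",
#'                 ct_analyte = 25, ct_extension_control = 20)
#' ipc <- data.frame(plate_id = "p1", analyte_id = "a1", dct = 3)
#' cf <- data.frame(analyte_id = "a1", correction_factor = 10)
#' computeNPX(r, ipc, cf)  # dCt = 5, ddCt = 2, NPX = 8
#' @export
computeNPX <- function(readouts, interplate, correction) {
  need <- c("sample_id", "analyte_id", "plate_id", "ct_analyte",
            "ct_extension_control")
  if (!all(need %in% names(readouts)))
    dataError("readouts lack column(s): %s",
              paste(setdiff(need, names(readouts)), collapse = ", "))
  ct <- c(readouts$ct_analyte, readouts$ct_extension_control)
  if (any(!is.finite(ct)))
    dataError("all Ct quantities must be finite")
  key <- paste(readouts$plate_id, readouts$analyte_id)
  ipc_idx <- match(key, paste(interplate$plate_id, interplate$analyte_id))
  if (anyNA(ipc_idx)) {
    bad <- unique(key[is.na(ipc_idx)])[1]
    dataError("no inter-plate control for (plate, analyte) pair: %s", bad)
  }
  cf_idx <- match(readouts$analyte_id, correction$analyte_id)
  if (anyNA(cf_idx)) {
    bad <- unique(readouts$analyte_id[is.na(cf_idx)])[1]
    dataError("no correction factor for analyte: %s", bad)
  }
  dct <- readouts$ct_analyte - readouts$ct_extension_control
  ddct <- dct - interplate$dct[ipc_idx]
  npx_val <- correction$correction_factor[cf_idx] - ddct
  ana <- unique(as.character(readouts$analyte_id))
  samp <- unique(as.character(readouts$sample_id))
  out <- matrix(NA_real_, length(ana), length(samp),
                dimnames = list(ana, samp))
  out[cbind(as.character(readouts$analyte_id),
            as.character(readouts$sample_id))] <- npx_val
  out
}

newFilterReport <- function(removed, frac, n_input, kind) {
  structure(list(removed = removed,
                 fraction = frac,
                 n_input = n_input,
                 n_retained = n_input - length(removed),
                 kind = kind),
            class = "npxFilterReport")
}

#' @export
print.npxFilterReport <- function(x, ...) {
  cat(sprintf("NPX %s filter: %d/%d proteins retained (%d removed)\n",
              x$kind, x$n_retained, x$n_input, length(x$removed)))
  if (length(x$removed))
    cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' Filter proteins under the assay limit of detection
#'
#' Removes proteins whose fraction of below-LOD cells (over non-missing
#' cells) exceeds `maxBelowLodFrac`. For retained proteins the remaining
#' below-LOD cells are, under the default policy, set missing (to be handled
#' by in-split median imputation downstream); alternatively they can be
#' substituted with the per-protein LOD stored in `rowData(x)$lod`.
#'
#' @param x an [NpxExperiment-class] with a populated below-LOD mask.
#' @param maxBelowLodFrac removal threshold in \[0, 1\] (default 0.5).
#' @param action `"missing"` (default) sets retained below-LOD cells
#'   missing; `"substitute"` replaces them with the protein's LOD value.
#' @return list with `experiment` (filtered [NpxExperiment-class]) and
#'   `report` (removed ids, per-protein below-LOD fractions, counts).
#' @export
filterLOD <- function(x, maxBelowLodFrac = 0.5,
                      action = c("missing", "substitute")) {
  action <- match.arg(action)
  if (!is.numeric(maxBelowLodFrac) || maxBelowLodFrac < 0 ||
      maxBelowLodFrac > 1)
    configError("maxBelowLodFrac: must lie in [0, 1]")
  below <- belowLodMask(x) & !missingMask(x)
  nonmiss <- rowSums(!missingMask(x))
  frac <- ifelse(nonmiss > 0, rowSums(below) / nonmiss, 0)
  names(frac) <- proteinIds(x)
  drop <- frac > maxBelowLodFrac
  report <- newFilterReport(proteinIds(x)[drop], frac, nrow(x), "below-LOD")
  kept <- x[!drop, ]
  vals <- npx(kept)
  bl <- belowLodMask(kept) & !missingMask(kept)
  if (any(bl)) {
    if (action == "missing") {
      vals[bl] <- NA_real_
    } else {
      rd <- SummarizedExperiment::rowData(kept)
      if (is.null(rd$lod))
        dataError("action='substitute' requires rowData lod values")
      vals[bl] <- matrix(rd$lod, nrow(kept), ncol(kept))[bl]
    }
    SummarizedExperiment::assay(kept, "npx") <- vals
    SummarizedExperiment::assay(kept, "missing") <- is.na(vals)
    methods::validObject(kept)
  }
  list(experiment = kept, report = report)
}

#' Filter proteins with excessive missingness
#'
#' Removes proteins whose missing fraction strictly exceeds
#' `maxMissingFrac` (default 0.30, i.e. proteins with >30% missing values).
#' Intended to run after [filterLOD()], so LOD-induced missingness counts.
#'
#' @param x an [NpxExperiment-class].
#' @param maxMissingFrac removal threshold in \[0, 1\].
#' @return list with `experiment` and `report`, as [filterLOD()].
#' @export
filterMissing <- function(x, maxMissingFrac = 0.30) {
  if (!is.numeric(maxMissingFrac) || maxMissingFrac < 0 ||
      maxMissingFrac > 1)
    configError("maxMissingFrac: must lie in [0, 1]")
  frac <- rowMeans(missingMask(x))
  names(frac) <- proteinIds(x)
  drop <- frac > maxMissingFrac
  report <- newFilterReport(proteinIds(x)[drop], frac, nrow(x), "missingness")
  list(experiment = x[!drop, ], report = report)
}

#' Reverse the dilution-to-fixed-concentration normalization
#'
#' Samples are measured after dilution to a common protein concentration;
#' this sensitivity transform undoes that step on the log2 scale by shifting
#' each sample's NPX values by `log2(preAdjustConc / fixedConc)`, restoring
#' the signal the sample's original (pre-adjustment) concentration implies.
#'
#' @param x an [NpxExperiment-class].
#' @param preAdjustConc per-sample measured pre-adjustment protein
#'   concentration (ug/mL), in column order of `x`.
#' @param fixedConc the common concentration samples were diluted to
#'   (ug/mL).
#' @return an [NpxExperiment-class] with shifted NPX values.
#' @export
reverseNormalization <- function(x, preAdjustConc, fixedConc) {
  if (length(preAdjustConc) != ncol(x))
    contractError("preAdjustConc must have one value per sample")
  if (any(!is.finite(preAdjustConc)) || any(preAdjustConc <= 0) ||
      !is.finite(fixedConc) || fixedConc <= 0)
    dataError("concentrations must be positive and finite")
  shift <- log2(preAdjustConc / fixedConc)
  vals <- sweep(npx(x), 2, shift, "+")
  SummarizedExperiment::assay(x, "npx") <- vals
  methods::validObject(x)
  x
}
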