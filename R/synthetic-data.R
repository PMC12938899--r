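#' Configure a synthetic NPX cohort
#'
#' Builds a validated [SyntheticConfig-class]. Defaults reproduce the study
#' design the package targets: 28 healthy controls (HC), 29 patients at
#' baseline (PT_BE) of whom 27 have a follow-up sample (PT_FU), a 60-protein
#' panel with two planted diagnostic markers shifted by +2 log2 NPX units at
#' unit per-protein noise SD (a 2-SD effect), half of the planted shift
#' reverting at follow-up, 5% missing-completely-at-random cells, below-LOD
#' flagging at the 2% lower tail of the control distribution, and three
#' planted treatment-response proteins at target Spearman rho 0.6.
#'
#' @param n_hc,n_pt,n_fu,n_proteins cohort shape counts (`n_fu <= n_pt`).
#' @param n_planted_diag,effect_log2 planted diagnostic markers and their
#'   mean NPX shift (log2 units) in patient baseline vs control.
#' @param fu_reversion fraction of the planted shift removed at follow-up.
#' @param missing_rate MCAR probability per cell.
#' @param lod_quantile lower-tail quantile of the control distribution
#'   flagged as below-LOD (0 disables flagging).
#' @param n_planted_resp,resp_rho planted response proteins and their target
#'   Spearman correlation with percent change in tumor burden.
#' @param noise_sd per-protein NPX standard deviation.
#' @param seed integer seed; the cohort is bit-reproducible from it.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(n_hc = 28, n_pt = 29, n_fu = 27,
                            n_proteins = 60, n_planted_diag = 2,
                            effect_log2 = 2, fu_reversion = 0.5,
                            missing_rate = 0.05, lod_quantile = 0.02,
                            n_planted_resp = 3, resp_rho = 0.6,
                            noise_sd = 1, seed = 1) {
  tryCatch(
    methods::new("SyntheticConfig",
      n_hc = n_hc, n_pt = n_pt, n_fu = n_fu, n_proteins = n_proteins,
      n_planted_diag = n_planted_diag, effect_log2 = effect_log2,
      fu_reversion = fu_reversion, missing_rate = missing_rate,
      lod_quantile = lod_quantile, n_planted_resp = n_planted_resp,
      resp_rho = resp_rho, noise_sd = noise_sd, seed = seed),
    error = function(e) configError("%s", conditionMessage(e)))
}

#' Generate a synthetic NPX cohort with planted signal
#'
#' Simulates a case/control proximity-extension-assay cohort on the log2 NPX
#' scale. Per-protein baseline levels are independent normals (mean drawn
#' once per protein, SD `noise_sd`). Planted diagnostic proteins are shifted
#' by `effect_log2` in patient baseline samples; follow-up samples belong to
#' the first `n_fu` patient subjects and carry the baseline value minus
#' `fu_reversion` times the planted effect plus fresh within-subject noise
#' (SD `noise_sd/2`). Cells are censored missing-completely-at-random at
#' `missing_rate`; values below the per-protein `lod_quantile` empirical
#' quantile of the control distribution are flagged below-LOD but retained
#' (the filtering step owns the censoring policy).
#'
#' @param config a [SyntheticConfig-class] from [syntheticConfig()].
#' @return a list with elements
#'   \describe{
#'     \item{experiment}{an [NpxExperiment-class] with
#'       `n_hc + n_pt + n_fu` samples;}
#'     \item{truth}{ground truth: `planted_diag_ids`, `planted_resp_ids`,
#'       `true_effects` (named log2 shifts), `true_resp_rho` (named target
#'       correlations) and the `config` used.}
#'   }
#' @examples
#' cohort <- generateNpxCohort(syntheticConfig(seed = 7))
#' cohort$truth$planted_diag_ids
#' @export
generateNpxCohort <- function(config) {
  if (!methods::is(config, "SyntheticConfig"))
    configError("'config' must be a SyntheticConfig")
  v <- methods::validObject(config, test = TRUE)
  if (!isTRUE(v)) configError(paste(v, collapse = "; "))
  withSeed(config@seed, {
    p <- config@n_proteins
    prot <- sprintf("PROT%03d", seq_len(p))
    planted_diag <- sort(sample(prot, config@n_planted_diag))
    planted_resp <- sort(sample(setdiff(prot, planted_diag),
                                config@n_planted_resp))
    mu <- setNames(runif(p, 1, 10), prot)
    effect <- setNames(rep(0, p), prot)
    effect[planted_diag] <- config@effect_log2

    hc_ids <- sprintf("HC%02d", seq_len(config@n_hc))
    pt_sub <- sprintf("PT%02d", seq_len(config@n_pt))
    be_ids <- paste0(pt_sub, "_BE")
    fu_sub <- pt_sub[seq_len(config@n_fu)]
    fu_ids <- paste0(fu_sub, "_FU")

    hc <- matrix(rnorm(p * config@n_hc, mu, config@noise_sd),
                 nrow = p, dimnames = list(prot, hc_ids))
    be <- matrix(rnorm(p * config@n_pt, mu + effect, config@noise_sd),
                 nrow = p, dimnames = list(prot, be_ids))
    fu <- if (config@n_fu > 0) {
      m <- be[, seq_len(config@n_fu), drop = FALSE] -
        config@fu_reversion * effect +
        matrix(rnorm(p * config@n_fu, 0, config@noise_sd / 2), nrow = p)
      colnames(m) <- fu_ids
      m
    } else {
      matrix(numeric(0), nrow = p, ncol = 0,
             dimnames = list(prot, character(0)))
    }

    vals <- cbind(hc, be, fu)
    lod <- if (config@lod_quantile > 0)
      apply(hc, 1, quantile, probs = config@lod_quantile) else
      rep(-Inf, p)
    below <- sweep(vals, 1, lod, "<")
    miss <- matrix(runif(length(vals)) < config@missing_rate,
                   nrow = p, dimnames = dimnames(vals))
    vals[miss] <- NA_real_

    se <- NpxExperiment(
      vals,
      group = c(rep("HC", config@n_hc), rep("PT_BE", config@n_pt),
                rep("PT_FU", config@n_fu)),
      subjectId = c(rep(NA_character_, config@n_hc), pt_sub, fu_sub),
      belowLOD = below, lod = lod)
    truth <- list(
      planted_diag_ids = planted_diag,
      planted_resp_ids = planted_resp,
      true_effects = effect[planted_diag],
      true_resp_rho = setNames(rep(config@resp_rho,
                                   length(planted_resp)), planted_resp),
      config = config)
    list(experiment = se, truth = truth)
  })
}

#' Generate Ct-level assay readouts with their implied NPX matrix
#'
#' Emulates the raw quantities of a proximity extension assay run: per
#' sample and analyte a qPCR cycle threshold, a per-sample extension-control
#' Ct, a per-plate-and-analyte inter-plate-control delta-Ct, and a
#' per-analyte correction factor. The bundled `npx` matrix is the value the
#' three-step NPX derivation implies, so
#' `computeNPX()` on the readouts reproduces it exactly (round-trip
#' identity).
#'
#' @param nSamples,nAnalytes counts (>= 1).
#' @param seed integer seed.
#' @param nPlates number of plates; samples are assigned round-robin.
#' @return list with `readouts` (long data.frame: `sample_id`, `analyte_id`,
#'   `plate_id`, `ct_analyte`, `ct_extension_control`), `interplate`
#'   (`plate_id`, `analyte_id`, `dct`), `correction` (`analyte_id`,
#'   `correction_factor`) and `npx` (analytes x samples matrix).
#' @export
generateCtData <- function(nSamples, nAnalytes, seed = 1, nPlates = 2) {
  if (!isCount(nSamples) || nSamples < 1)
    configError("nSamples: must be a count >= 1")
  if (!isCount(nAnalytes) || nAnalytes < 1)
    configError("nAnalytes: must be a count >= 1")
  nPlates <- min(nPlates, nSamples)
  withSeed(seed, {
    samp <- sprintf("S%03d", seq_len(nSamples))
    ana <- sprintf("A%03d", seq_len(nAnalytes))
    plate <- sprintf("plate%d", rep_len(seq_len(nPlates), nSamples))
    ext <- setNames(runif(nSamples, 19, 22), samp)
    ipc <- expand.grid(plate_id = sprintf("plate%d", seq_len(nPlates)),
                       analyte_id = ana, stringsAsFactors = FALSE)
    ipc$dct <- runif(nrow(ipc), -1.5, 1.5)
    cf <- data.frame(analyte_id = ana,
                     correction_factor = runif(nAnalytes, 15, 25))
    readouts <- expand.grid(sample_id = samp, analyte_id = ana,
                            stringsAsFactors = FALSE)
    readouts$plate_id <- plate[match(readouts$sample_id, samp)]
    readouts$ct_analyte <- runif(nrow(readouts), 18, 30)
    readouts$ct_extension_control <- ext[readouts$sample_id]

    dct <- readouts$ct_analyte - readouts$ct_extension_control
    key <- paste(readouts$plate_id, readouts$analyte_id)
    ddct <- dct - ipc$dct[match(key, paste(ipc$plate_id, ipc$analyte_id))]
    npx_val <- cf$correction_factor[match(readouts$analyte_id,
                                          cf$analyte_id)] - ddct
    npx <- matrix(NA_real_, nAnalytes, nSamples, dimnames = list(ana, samp))
    npx[cbind(readouts$analyte_id, readouts$sample_id)] <- npx_val
    rownames(readouts) <- NULL
    list(readouts = readouts, interplate = ipc, correction = cf, npx = npx)
  })
}

#' Generate per-patient treatment-response data with planted correlation
#'
#' Simulates baseline and follow-up tumor burden (RECIST sum of longest
#' diameters, SLD) together with per-protein within-patient NPX change
#' (delta-NPX, follow-up minus baseline). A Gaussian copula couples each
#' planted protein's delta-NPX to the latent response variable that drives
#' percent change in SLD, targeting the population Spearman correlation
#' `respRho` exactly (the bivariate-normal Pearson correlation is set to
#' `2*sin(pi*respRho/6)`); non-planted proteins are independent of the
#' response.
#'
#' @param nPatients number of patients (>= 5).
#' @param proteinIds protein identifiers for the delta-NPX matrix.
#' @param plantedIds subset of `proteinIds` coupled to the response.
#' @param respRho target Spearman correlation, |respRho| < 1.
#' @param seed integer seed.
#' @return list with `response` (data.frame: `subject_id`, `sld_baseline`,
#'   `sld_followup`, `pct_delta_sld`) and `delta_npx` (patients x proteins
#'   matrix).
#' @export
generateResponseData <- function(nPatients, proteinIds, plantedIds,
                                 respRho = 0.6, seed = 1) {
  if (!isCount(nPatients) || nPatients < 5)
    configError("nPatients: must be a count >= 5")
  if (abs(respRho) >= 1)
    configError("respRho: |respRho| must be < 1")
  if (!all(plantedIds %in% proteinIds))
    configError("plantedIds must be a subset of proteinIds")
  withSeed(seed, {
    n <- nPatients
    subj <- sprintf("PT%02d", seq_len(n))
    z <- rnorm(n)
    rho_p <- 2 * sin(pi * respRho / 6)
    d <- matrix(rnorm(n * length(proteinIds)), nrow = n,
                dimnames = list(subj, proteinIds))
    for (pid in plantedIds)
      d[, pid] <- rho_p * z + sqrt(1 - rho_p^2) * rnorm(n)
    ## %dSLD is a strictly increasing transform of the latent z (Spearman
    ## is rank-invariant), centered on partial response.
    pct <- 100 * (2 * plogis(z - 0.8) - 1)
    sld0 <- round(runif(n, 30, 150), 1)
    sld1 <- round(sld0 * (1 + pct / 100), 1)
    sld1 <- pmax(sld1, 0.1)
    response <- data.frame(
      subject_id = subj, sld_baseline = sld0, sld_followup = sld1,
      pct_delta_sld = 100 * (sld1 - sld0) / sld0)
    list(response = response, delta_npx = d)
  })
}
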