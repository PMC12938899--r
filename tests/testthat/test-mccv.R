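test_that("stratified 70/30 splits have constant class-wise sizes", {
  ids <- sprintf("s%02d", 1:57)
  labels <- rep(c(0, 1), c(28, 29))
  sp <- makeSplits(ids, labels, nSplits = 25, seed = 3)
  expect_length(sp, 25)
  for (s in sp) {
    expect_setequal(c(s$train_ids, s$test_ids), ids)
    expect_length(intersect(s$train_ids, s$test_ids), 0)
    trLab <- labels[match(s$train_ids, ids)]
    # round(0.7*28)=20 controls and round(0.7*29)=20 cases in training
    expect_equal(unname(table(trLab)), c(20L, 20L), ignore_attr = TRUE)
    expect_length(unique(labels[match(s$test_ids, ids)]), 2)
  }
  expect_identical(makeSplits(ids, labels, 5, seed = 9),
                   makeSplits(ids, labels, 5, seed = 9))
  expect_error(makeSplits(ids, labels, 5, trainFrac = 1),
               class = "evpanel_config_error")
  expect_error(makeSplits(ids[1:3], c(0, 1, 1), 5, trainFrac = 0.7),
               class = "evpanel_config_error")
})

test_that("ridge 1-SE penalty equals a brute-force recomputation", {
  set.seed(31)
  x <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("P", 1:4)))
  y <- rbinom(50, 1, plogis(x[, 1]))
  fit <- fitRidge(x, y, internalFolds = 5, seed = 8)
  iMin <- which.min(fit$cv_loss)
  oneSe <- fit$lambda_grid[fit$cv_loss <= fit$cv_loss[iMin] +
                             fit$cv_se[iMin]]
  expect_equal(fit$lambda, max(oneSe))
  expect_length(fit$coefficients, 4)
  expect_error(fitRidge(x, rep(1, 50)), class = "evpanel_config_error")
})

test_that("ridge degenerates gracefully at the penalty and feature edges", {
  set.seed(32)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("Pa", "Pb")))
  y <- rep(0:1, 10)
  fit <- fitRidge(x, y, seed = 1)
  # penalty -> infinity limit: largest grid penalty gives ~zero coefficients
  g <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                      lambda = fit$lambda_grid, standardize = FALSE)
  expect_lt(max(abs(g$beta[, 1])), 1e-2)
  # prediction at the training mean vector is plogis(intercept)
  fit2 <- fitRidge(x, y, seed = 1,
                   standardization = list(mean = colMeans(x),
                                          sd = apply(x, 2, sd)))
  pr <- applyRidge(fit2, matrix(colMeans(x), 1,
                                dimnames = list(NULL, c("Pa", "Pb"))))
  expect_equal(pr, plogis(fit2$intercept), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero features: constant prevalence probability
  fit0 <- fitRidge(x[, 0], y, seed = 1)
  expect_equal(unique(applyRidge(fit0, x[, 0])), mean(y), tolerance = 1e-9)
  # single separable feature: prediction order matches feature order
  xs <- matrix(sort(rnorm(20)), 20, 1, dimnames = list(NULL, "Pz"))
  ys <- as.numeric(xs > 0)
  fit1 <- fitRidge(xs, ys, seed = 2)
  expect_false(is.unsorted(applyRidge(fit1, xs)))
  expect_true(all(applyRidge(fit1, xs) > 0 & applyRidge(fit1, xs) < 1))
})

test_that("pooled OOF AUC aggregates per-subject medians", {
  oof <- list(a = c(0.9, 0.8), b = 0.1)
  labels <- c(a = 1, b = 0)
  out <- pooledOofAuc(oof, labels, nBoot = 50, seed = 1)
  expect_equal(unname(out$medians), c(0.85, 0.1))
  expect_equal(out$auc, 1)
  # all-equal probabilities give 0.5 by the tie convention
  tied <- pooledOofAuc(list(a = 0.5, b = 0.5, c = 0.5),
                       c(a = 1, b = 0, c = 0), nBoot = 10, seed = 1)
  expect_equal(tied$auc, 0.5)
  expect_warning(
    pooledOofAuc(list(a = 0.9, b = 0.2, c = numeric(0)),
                 c(a = 1, b = 0, c = 0), nBoot = 10, seed = 1),
    "never held out")
})

test_that("no information leaks from test rows into predictions", {
  # prediction for one test sample is invariant to other test rows
  fs <- defaultFiltered(seed = 17)
  vals <- t(npx(fs$experiment))
  keep <- sampleGroup(fs$experiment) %in% c("HC", "PT_BE")
  vals <- vals[keep, ]
  labels <- as.numeric(sampleGroup(fs$experiment)[keep] == "PT_BE")
  sp <- makeSplits(rownames(vals), labels, nSplits = 1, seed = 5)[[1]]
  probe <- sp$test_ids[1]
  run <- function(v) {
    r <- runMCCV(v, "elastic_net", labels = labels,
                 splits = list(sp), seed = 11)
    r@per_subject_oof[[probe]]
  }
  p1 <- run(vals)
  vPerturbed <- vals
  others <- setdiff(sp$test_ids, probe)
  vPerturbed[others, ] <- vPerturbed[others, ] + 50
  expect_equal(run(vPerturbed), p1, tolerance = 1e-12)
})

test_that("single-split MCCV reduces pooled AUC to the split AUC", {
  se <- plantedMatrix(14, 14, p = 10, shift = 2, seed = 19)
  r <- runMCCV(se, "elastic_net", nSplits = 1, seed = 4)
  expect_length(perSplitAuc(r), 1)
  held <- lengths(r@per_subject_oof) > 0
  expect_equal(r@pooled_oof_auc, perSplitAuc(r)[1])
  # selection frequencies stay within [0, 1] and sum to at most 5 per split
  expect_lte(sum(selectionFreq(r)), 5)
})

test_that("MCCV with each selector recovers planted markers", {
  fs <- defaultFiltered(seed = 23)
  planted <- fs$truth$planted_diag_ids
  for (sel in c("elastic_net", "plsda", "boruta")) {
    args <- reducedSelectorArgs()[[sel]]
    if (is.null(args)) args <- list()
    r <- runMCCV(fs$experiment, sel, nSplits = 15, selectorArgs = args,
                 seed = 29)
    expect_gte(min(selectionFreq(r)[planted]), 0.6)
    expect_gte(r@pooled_oof_auc, 0.85)
  }
})

test_that("consensus rules reproduce worked selection-frequency tables", {
  freqs <- list(
    boruta = c("LAP TGF-beta-1" = 0.99, "PDGF subunit B" = 0.98,
               "PD-L1" = 0.67, "CD40-L" = 0.66, "ANGPT1" = 0.56),
    elastic_net = c("LAP TGF-beta-1" = 0.86, "CD40-L" = 0.57,
                    "PDGF subunit B" = 0.53, "PD-L1" = 0.24,
                    "CASP-8" = 0.22),
    plsda = c("LAP TGF-beta-1" = 1.00, "PDGF subunit B" = 0.98,
              "CD40-L" = 0.98, "EGF" = 0.62, "PD-L1" = 0.58))
  top2 <- consensusPanel(freqs, rule = "top_k_aggregate", k = 2)
  expect_setequal(panelProteins(top2),
                  c("LAP TGF-beta-1", "PDGF subunit B"))
  inter <- consensusPanel(freqs, rule = "stable_intersection")
  expect_identical(panelProteins(inter), "LAP TGF-beta-1")
  expect_setequal(stableSets(inter)$boruta,
                  c("LAP TGF-beta-1", "PDGF subunit B", "PD-L1", "CD40-L"))
  # all-zero frequencies: empty stable sets plus a warning
  zero <- lapply(freqs, function(f) f * 0)
  expect_warning(empty <- consensusPanel(zero, rule = "stable_intersection"),
                 "empty")
  expect_length(panelProteins(empty), 0)
})

test_that("panel evaluation matches the fixed-feature MCCV workflow", {
  fs <- defaultFiltered(seed = 37)
  planted <- fs$truth$planted_diag_ids
  pe <- evaluatePanel(planted, fs$experiment, nSplits = 25, seed = 41)
  expect_gte(pe@pooled_oof_auc, 0.9)
  expect_identical(pe@selector, "none")
  expect_error(evaluatePanel(c("NOPE"), fs$experiment),
               class = "evpanel_contract_error")
  expect_error(evaluatePanel(character(0), fs$experiment),
               class = "evpanel_config_error")
  # a random panel on a null cohort hovers near chance
  null <- generateNpxCohort(syntheticConfig(effect_log2 = 0, seed = 43))
  pn <- evaluatePanel(proteinIds(null$experiment)[1:2], null$experiment,
                      nSplits = 25, seed = 47)
  expect_gt(pn@pooled_oof_auc, 0.2)
  expect_lt(pn@pooled_oof_auc, 0.8)
})
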