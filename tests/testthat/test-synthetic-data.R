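test_that("config validation names the offending field", {
  expect_error(syntheticConfig(n_fu = 30, n_pt = 29), "n_fu",
               class = "evpanel_config_error")
  expect_error(syntheticConfig(missing_rate = 1.2), "missing_rate",
               class = "evpanel_config_error")
  expect_error(syntheticConfig(n_planted_diag = 40, n_planted_resp = 30,
                               n_proteins = 60),
               "n_planted_diag", class = "evpanel_config_error")
  expect_error(syntheticConfig(lod_quantile = 1), "lod_quantile",
               class = "evpanel_config_error")
})

test_that("cohort generation is bit-reproducible from the seed", {
  a <- generateNpxCohort(syntheticConfig(seed = 99))
  b <- generateNpxCohort(syntheticConfig(seed = 99))
  expect_identical(npx(a$experiment), npx(b$experiment))
  expect_identical(a$truth, b$truth)
  c <- generateNpxCohort(syntheticConfig(seed = 100))
  expect_false(identical(npx(a$experiment), npx(c$experiment)))
})

test_that("cohort shape matches the configured design", {
  cfg <- syntheticConfig(n_hc = 10, n_pt = 8, n_fu = 5, n_proteins = 20,
                         seed = 3)
  co <- generateNpxCohort(cfg)
  expect_equal(dim(co$experiment), c(20L, 23L))
  expect_equal(as.vector(table(sampleGroup(co$experiment))), c(10, 8, 5))
  # follow-up rows belong to the first n_fu patient subjects
  fu <- subjectId(co$experiment)[sampleGroup(co$experiment) == "PT_FU"]
  expect_setequal(fu, sprintf("PT%02d", 1:5))
  # no follow-up rows at all when n_fu = 0
  co0 <- generateNpxCohort(syntheticConfig(n_fu = 0, seed = 3))
  expect_false(any(sampleGroup(co0$experiment) == "PT_FU"))
})

test_that("planted markers dominate the mean difference ranking", {
  # effect 2 at noise SD 1: both planted proteins in top 5 by |delta mean|
  hits <- vapply(1:20, function(s) {
    co <- generateNpxCohort(syntheticConfig(
      n_proteins = 60, n_planted_diag = 2, effect_log2 = 2, noise_sd = 1,
      missing_rate = 0, lod_quantile = 0, seed = s))
    v <- npx(co$experiment)
    grp <- sampleGroup(co$experiment)
    d <- abs(rowMeans(v[, grp == "PT_BE"]) - rowMeans(v[, grp == "HC"]))
    top5 <- names(sort(d, decreasing = TRUE))[1:5]
    all(co$truth$planted_diag_ids %in% top5)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null cohorts are calibrated downstream (no q < 0.05 excess)", {
  anySig <- vapply(1:20, function(s) {
    co <- generateNpxCohort(syntheticConfig(
      effect_log2 = 0, missing_rate = 0, lod_quantile = 0, seed = 1000 + s))
    d <- twoGroupTest(co$experiment, "HC", "PT_BE")
    any(d$q_bh < 0.05)
  }, logical(1))
  # two-sample q-values exceed 0.05 for all proteins in >= 90% of replicates
  expect_gte(mean(!anySig), 0.9)
})

test_that("ct readouts round-trip through the NPX derivation", {
  g <- generateCtData(nSamples = 7, nAnalytes = 5, seed = 21)
  npxBack <- computeNPX(g$readouts, g$interplate, g$correction)
  expect_equal(npxBack, g$npx, tolerance = 1e-12)
  # minimal single-cell case
  g1 <- generateCtData(1, 1, seed = 2)
  expect_equal(dim(g1$npx), c(1L, 1L))
  expect_equal(computeNPX(g1$readouts, g1$interplate, g1$correction), g1$npx)
})

test_that("plate-control differences shift NPX by exactly the dCt gap", {
  # same analyte/extension Ct on two plates: NPX differs by the ipc delta
  r <- data.frame(sample_id = c("s1", "s2"), analyte_id = "a1",
                  plate_id = c("p1", "p2"),
                  ct_analyte = 24, ct_extension_control = 20)
  ipc <- data.frame(plate_id = c("p1", "p2"), analyte_id = "a1",
                    dct = c(1, 2.5))
  cf <- data.frame(analyte_id = "a1", correction_factor = 10)
  m <- computeNPX(r, ipc, cf)
  expect_equal(m["a1", "s2"] - m["a1", "s1"], 2.5 - 1)
})

test_that("planted response coupling hits the target Spearman rho", {
  rhos <- vapply(1:10, function(s) {
    g <- generateResponseData(200, sprintf("P%02d", 1:10), c("P03", "P07"),
                              respRho = 0.6, seed = s)
    mean(c(cor(g$delta_npx[, "P03"], g$response$pct_delta_sld,
               method = "spearman"),
           cor(g$delta_npx[, "P07"], g$response$pct_delta_sld,
               method = "spearman")))
  }, numeric(1))
  # unbiased targeting: the mean across replicates sits on rho = 0.6
  expect_lt(abs(mean(rhos) - 0.6), 0.05)
  expect_true(all(abs(rhos - 0.6) < 0.25))
  # non-planted proteins stay near zero correlation
  nulls <- vapply(1:20, function(s) {
    g <- generateResponseData(200, sprintf("P%02d", 1:5), "P01",
                              respRho = 0.6, seed = s)
    abs(cor(g$delta_npx[, "P04"], g$response$pct_delta_sld,
            method = "spearman"))
  }, numeric(1))
  expect_gte(mean(nulls < 0.2), 0.95)
})

test_that("degenerate response correlations are rejected", {
  expect_error(generateResponseData(20, "P1", "P1", respRho = 1),
               class = "evpanel_config_error")
  expect_error(generateResponseData(3, "P1", "P1", respRho = 0.5),
               class = "evpanel_config_error")
  # pct_delta_sld is internally consistent with the SLD pair
  g <- generateResponseData(30, c("P1", "P2"), "P1", 0.5, seed = 8)
  expect_equal(g$response$pct_delta_sld,
               pctDeltaSLD(g$response$sld_baseline, g$response$sld_followup))
})
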