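test_that("normality gate separates Gaussian from skewed samples", {
  set.seed(11)
  expect_true(normalityGate(rnorm(100)))
  expect_false(normalityGate(rexp(100)))
  expect_false(normalityGate(rep(3, 10)))  # constant: non-Gaussian
  expect_error(normalityGate(c(1, 2)), class = "evpanel_data_error")
})

test_that("BH adjustment reproduces the step-up formula", {
  # hand application: q_i = min over j >= i of p_(j) * m / j
  expect_equal(adjustBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustBH(0.2), 0.2)                 # m = 1 identity
  expect_equal(adjustBH(rep(0.04, 5)), rep(0.04, 5))  # symmetry
  set.seed(2)
  p <- runif(50)
  q <- adjustBH(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p ranks
  expect_true(all(q >= p - 1e-12) && all(q <= 1))
  expect_error(adjustBH(c(0.1, 1.3)), class = "evpanel_data_error")
})

test_that("volcano rule uses strict thresholds on q and log2 fold change", {
  d <- data.frame(delta_npx = c(1.5, 1.0, 3, -1.2, -0.5),
                  q_bh = c(0.01, 0.01, 0.06, 0.04, 0.01))
  out <- volcanoClassify(d)
  expect_equal(out$direction, c("up", "ns", "ns", "down", "ns"))
})

test_that("two-group test recovers a planted shift", {
  se <- plantedMatrix(30, 30, p = 12, shift = 2, noise = 0.5, seed = 9)
  d <- twoGroupTest(se, "HC", "PT_BE")
  r1 <- d[d$protein_id == "P01", ]
  expect_lt(r1$q_bh, 0.05)
  expect_equal(r1$delta_npx, 2, tolerance = 0.3)
  expect_equal(r1$direction, "up")
})

test_that("two-group null calibration holds at ~5% raw positives", {
  rate <- vapply(1:10, function(s) {
    se <- plantedMatrix(25, 25, p = 40, shift = 0, seed = 300 + s)
    d <- twoGroupTest(se, "HC", "PT_BE")
    mean(d$p_raw < 0.05)
  }, numeric(1))
  expect_lt(mean(rate), 0.12)
  expect_gt(mean(rate), 0.005)
})

test_that("swapping group order negates the effect and preserves p", {
  se <- plantedMatrix(15, 18, p = 8, shift = 1, seed = 4)
  a <- twoGroupTest(se, "HC", "PT_BE")
  b <- twoGroupTest(se, "PT_BE", "HC")
  expect_equal(b$delta_npx, -a$delta_npx)
  expect_equal(b$p_raw, a$p_raw)
})

test_that("proteins without enough values are excluded with a warning", {
  m <- npx(plantedMatrix(10, 10, p = 4))
  m[2, 1:9] <- NA  # one non-missing value in group A
  se <- tinyExperiment(m, group = rep(c("HC", "PT_BE"), each = 10))
  expect_warning(d <- twoGroupTest(se, "HC", "PT_BE"), "excluded")
  expect_false("P02" %in% d$protein_id)
  expect_error(twoGroupTest(se, "HC", "PT_FU"),
               class = "evpanel_config_error")
})

test_that("three-group test flags a shifted group and requires 3 groups", {
  co <- generateNpxCohort(syntheticConfig(
    n_proteins = 20, effect_log2 = 3, fu_reversion = 0, missing_rate = 0,
    lod_quantile = 0, noise_sd = 1, seed = 6))
  d <- threeGroupTest(co$experiment)
  planted <- d[d$protein_id %in% co$truth$planted_diag_ids, ]
  expect_true(all(planted$q_bh < 0.05))
  # null three-group calibration
  co0 <- generateNpxCohort(syntheticConfig(
    n_proteins = 40, effect_log2 = 0, missing_rate = 0, lod_quantile = 0,
    seed = 61))
  d0 <- threeGroupTest(co0$experiment)
  expect_lt(mean(d0$p_raw < 0.05), 0.2)
  two <- plantedMatrix(6, 6, p = 3)
  expect_error(threeGroupTest(two), class = "evpanel_config_error")
})

test_that("ROC/Youden matches brute force over all thresholds", {
  scores <- c(1, 2, 3, 4); labels <- c(0, 0, 1, 1)
  r <- rocWithYouden(scores, labels)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$youden_threshold > 2 && r$youden_threshold <= 3)
  # brute force: every threshold between observed scores
  bruteJ <- function(thr) {
    sens <- mean(scores[labels == 1] > thr)
    spec <- mean(scores[labels == 0] <= thr)
    sens + spec - 1
  }
  expect_equal(bruteJ(r$youden_threshold), 1)
  expect_true(all(vapply(c(0.5, 1.5, 3.5), bruteJ, numeric(1)) <= 1))
})

test_that("AUC behaves at the separation and chance extremes", {
  set.seed(13)
  sc <- rnorm(400); lb <- rep(0:1, 200)  # labels independent of scores
  r <- rocWithYouden(sc, lb)
  expect_lt(abs(r$auc - 0.5), 0.1)
  expect_true(r$auc_ci[1] <= r$auc && r$auc <= r$auc_ci[2])
  # invariance under a strictly increasing transform
  sep <- c(rnorm(50), rnorm(50, 3)); lab <- rep(0:1, each = 50)
  a1 <- rocWithYouden(sep, lab)$auc
  a2 <- rocWithYouden(exp(sep / 2), lab)$auc
  expect_equal(a1, a2)
  expect_error(rocWithYouden(1:4, rep(1, 4)),
               class = "evpanel_config_error")
})

test_that("top-marker ROC ranks by delta NPX and reports per-marker AUC", {
  se <- plantedMatrix(20, 20, p = 8, shift = 3, noise = 0.7, seed = 15)
  d <- twoGroupTest(se, "HC", "PT_BE")
  roc <- topMarkerRoc(se, d, k = 3)
  expect_equal(nrow(roc), 3)
  expect_equal(roc$marker_id[1], "P01")
  expect_gt(roc$auc[1], 0.95)
})
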