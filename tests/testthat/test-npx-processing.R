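test_that("NPX arithmetic follows the three-step derivation", {
  r <- data.frame(sample_id = "s1", analyte_id = "a1", plate_id = "p1",
                  ct_analyte = 25, ct_extension_control = 20)
  ipc <- data.frame(plate_id = "p1", analyte_id = "a1", dct = 3)
  cf <- data.frame(analyte_id = "a1", correction_factor = 10)
  expect_equal(computeNPX(r, ipc, cf)["a1", "s1"], 8)  # dCt 5, ddCt 2
  r0 <- transform(r, ct_analyte = 0, ct_extension_control = 0)
  ipc0 <- transform(ipc, dct = 0)
  cf0 <- transform(cf, correction_factor = 0)
  expect_equal(computeNPX(r0, ipc0, cf0)["a1", "s1"], 0)
})

test_that("NPX is affine in the analyte Ct with slope -1", {
  g <- generateCtData(4, 3, seed = 31)
  delta <- 0.75
  shifted <- g$readouts
  shifted$ct_analyte <- shifted$ct_analyte + delta
  m1 <- computeNPX(g$readouts, g$interplate, g$correction)
  m2 <- computeNPX(shifted, g$interplate, g$correction)
  expect_equal(m2, m1 - delta, tolerance = 1e-12)
})

test_that("missing controls raise data-integrity errors naming the pair", {
  r <- data.frame(sample_id = "s1", analyte_id = "a1", plate_id = "p9",
                  ct_analyte = 25, ct_extension_control = 20)
  ipc <- data.frame(plate_id = "p1", analyte_id = "a1", dct = 3)
  cf <- data.frame(analyte_id = "a1", correction_factor = 10)
  expect_error(computeNPX(r, ipc, cf), "p9 a1",
               class = "evpanel_data_error")
  ipc9 <- data.frame(plate_id = "p9", analyte_id = "a1", dct = 3)
  cf2 <- data.frame(analyte_id = "zz", correction_factor = 10)
  expect_error(computeNPX(r, ipc9, cf2), "a1",
               class = "evpanel_data_error")
})

test_that("LOD filter removes exactly the brute-force recounted proteins", {
  set.seed(7)
  p <- 25; n <- 40
  m <- matrix(rnorm(p * n, 5), p,
              dimnames = list(sprintf("P%02d", 1:p), sprintf("HC%02d", 1:n)))
  below <- matrix(runif(p * n) < 0.3, p, dimnames = dimnames(m))
  miss <- matrix(runif(p * n) < 0.1, p)
  m[miss] <- NA
  se <- tinyExperiment(m, group = rep("HC", n), subjectId = rep(NA, n),
                       belowLOD = below)
  out <- filterLOD(se, maxBelowLodFrac = 0.25)
  # independent per-column recount
  frac <- sapply(seq_len(p), function(i) {
    nm <- !is.na(m[i, ])
    sum(below[i, ] & nm) / sum(nm)
  })
  expect_setequal(out$report$removed, rownames(m)[frac > 0.25])
  expect_equal(out$report$n_retained, p - sum(frac > 0.25))
  # retained proteins' below-LOD cells became missing
  kept <- npx(out$experiment)
  keptBelow <- below[rownames(kept), ] & !miss[match(rownames(kept),
                                                     rownames(m)), ]
  expect_true(all(is.na(kept[keptBelow])))
})

test_that("LOD filter is the identity when nothing is below LOD", {
  se <- plantedMatrix(5, 5, p = 6)
  out <- filterLOD(se, 0.5)
  expect_identical(npx(out$experiment), npx(se))
  expect_length(out$report$removed, 0)
  # a fully-censored protein is removed at threshold 0.5
  below <- matrix(FALSE, 6, 10, dimnames = dimnames(npx(se)))
  below[3, ] <- TRUE
  se2 <- tinyExperiment(npx(se), group = sampleGroup(se),
                        subjectId = subjectId(se), belowLOD = below)
  out2 <- filterLOD(se2, 0.5)
  expect_identical(out2$report$removed, rownames(se2)[3])
})

test_that("substitute policy writes the LOD value into censored cells", {
  m <- matrix(c(1, 5, 5, 5), 1, 4,
              dimnames = list("P1", paste0("HC0", 1:4)))
  below <- matrix(c(TRUE, FALSE, FALSE, FALSE), 1, 4,
                  dimnames = dimnames(m))
  se <- tinyExperiment(m, group = rep("HC", 4), subjectId = rep(NA, 4),
                       belowLOD = below, lod = 2.5)
  out <- filterLOD(se, 0.5, action = "substitute")
  expect_equal(npx(out$experiment)["P1", 1], 2.5)
})

test_that("missingness filter applies the strict >30% rule", {
  # 10 samples: 3 missing (30%) retained, 4 missing (40%) removed
  m <- matrix(rnorm(30, 5), 3, 10,
              dimnames = list(c("Pa", "Pb", "Pc"), sprintf("HC%02d", 1:10)))
  m["Pb", 1:3] <- NA
  m["Pc", 1:4] <- NA
  se <- tinyExperiment(m, group = rep("HC", 10), subjectId = rep(NA, 10))
  out <- filterMissing(se, 0.30)
  expect_identical(out$report$removed, "Pc")
  expect_setequal(rownames(out$experiment), c("Pa", "Pb"))
})

test_that("missingness removal matches a brute-force recount", {
  set.seed(12)
  m <- matrix(rnorm(600, 5), 20, 30,
              dimnames = list(sprintf("P%02d", 1:20), sprintf("HC%02d", 1:30)))
  m[runif(600) < 0.25] <- NA
  se <- tinyExperiment(m, group = rep("HC", 30), subjectId = rep(NA, 30))
  out <- filterMissing(se, 0.30)
  frac <- rowMeans(is.na(m))
  expect_setequal(out$report$removed, rownames(m)[frac > 0.30])
  expect_equal(out$report$n_input - out$report$n_retained,
               length(out$report$removed))
})

test_that("reverse normalization is a log2 concentration-ratio shift", {
  se <- plantedMatrix(4, 4, p = 5)
  # pre-adjustment equal to fixed concentration: identity
  same <- reverseNormalization(se, rep(50, 8), 50)
  expect_equal(npx(same), npx(se))
  # doubled concentration adds exactly +1 NPX to that sample
  conc <- rep(50, 8); conc[2] <- 100
  up <- reverseNormalization(se, conc, 50)
  expect_equal(npx(up)[, 2], npx(se)[, 2] + 1)
  expect_equal(npx(up)[, -2], npx(se)[, -2])
  # round trip: applying the inverse shift restores the matrix
  set.seed(5)
  conc <- runif(8, 10, 200)
  fwd <- reverseNormalization(se, conc, 50)
  back <- reverseNormalization(fwd, rep(50, 8)^2 / conc, 50)
  expect_equal(npx(back), npx(se), tolerance = 1e-12)
  expect_error(reverseNormalization(se, rep(-1, 8), 50),
               class = "evpanel_data_error")
})
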