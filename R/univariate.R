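#' Kolmogorov-Smirnov normality gate
#'
#' Decides whether a sample of NPX values is treated as Gaussian for the
#' parametric/nonparametric test dispatch: a one-sample Kolmogorov-Smirnov
#' test against a normal with the sample mean and SD, declared Gaussian when
#' p >= `alpha`. KS with estimated parameters is anti-conservative; an
#' optional Lilliefors correction (via the nortest package) is available
#' behind `lilliefors = TRUE`. A constant sample (zero variance) is reported
#' non-Gaussian.
#'
#' @param values numeric vector; at least 3 non-missing values required.
#' @param alpha significance level of the gate (default 0.05).
#' @param lilliefors use the Lilliefors-corrected test instead.
#' @return logical: `TRUE` if the sample passes as Gaussian.
#' @export
normalityGate <- function(values, alpha = 0.05, lilliefors = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) < 3)
    dataError("normality gate requires >= 3 non-missing values")
  if (sd(values) == 0) return(FALSE)
  p <- if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE))
      configError("lilliefors = TRUE requires the nortest package")
    nortest::lillie.test(values)$p.value
  } else {
    suppressWarnings(
      ks.test(values, "pnorm", mean(values), sd(values))$p.value)
  }
  p >= alpha
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; reported as q-values.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted q-values, same length and order as `p`.
#' @examples
#' adjustBH(c(0.01, 0.02, 0.03))  # all become 0.03
#' @export
adjustBH <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    dataError("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Volcano classification of differential results
#'
#' Labels each protein `up` if `q_bh < qMax` and `delta_npx > fcMinLog2`,
#' `down` if `q_bh < qMax` and `delta_npx < -fcMinLog2`, otherwise `ns`.
#' Both inequalities are strict; with the default `fcMinLog2 = 1` the
#' enrichment threshold of one log2 NPX unit corresponds to a two-fold
#' change on the linear scale.
#'
#' @param results data.frame with columns `delta_npx` and `q_bh`.
#' @param qMax significance threshold on the BH-adjusted q-value.
#' @param fcMinLog2 minimum absolute log2 fold change.
#' @return `results` with a `direction` column (`up`/`down`/`ns`).
#' @export
volcanoClassify <- function(results, qMax = 0.05, fcMinLog2 = 1) {
  stopifnot(all(c("delta_npx", "q_bh") %in% names(results)))
  dir <- rep("ns", nrow(results))
  sig <- !is.na(results$q_bh) & results$q_bh < qMax
  dir[sig & results$delta_npx > fcMinLog2] <- "up"
  dir[sig & results$delta_npx < -fcMinLog2] <- "down"
  results$direction <- dir
  results
}

## Shared per-protein extraction of group values with missingness handling.
groupValues <- function(x, group) {
  keep <- sampleGroup(x) == group
  npx(x)[, keep, drop = FALSE]
}

#' Two-group differential expression with a normality gate
#'
#' For each protein, compares NPX between two sample groups: Student's
#' t-test when both groups pass the [normalityGate()], otherwise the
#' Wilcoxon rank-sum test. The effect size `delta_npx` is the mean of group
#' B minus the mean of group A (log2 units). p-values are BH-adjusted across
#' the tested proteins and classified with the volcano rule. Proteins with
#' fewer than 3 non-missing values in either group are excluded with a
#' warning.
#'
#' @param x an [NpxExperiment-class].
#' @param groupA,groupB group labels to compare (`"HC"`, `"PT_BE"`,
#'   `"PT_FU"`).
#' @param paired treat samples as subject-paired (both groups restricted to
#'   subjects present in each; applies paired t / Wilcoxon signed-rank).
#'   Default `FALSE`: the rank-sum and Student's t tests are unpaired.
#' @param alpha normality-gate level.
#' @param qMax,fcMinLog2 volcano thresholds, see [volcanoClassify()].
#' @return data.frame: `protein_id`, `delta_npx`, `statistic`, `p_raw`,
#'   `q_bh`, `test_used`, `direction`.
#' @export
twoGroupTest <- function(x, groupA, groupB, paired = FALSE, alpha = 0.05,
                         qMax = 0.05, fcMinLog2 = 1) {
  for (g in c(groupA, groupB))
    if (!any(sampleGroup(x) == g))
      configError("group '%s' has no samples", g)
  a <- groupValues(x, groupA)
  b <- groupValues(x, groupB)
  if (paired) {
    sa <- subjectId(x)[sampleGroup(x) == groupA]
    sb <- subjectId(x)[sampleGroup(x) == groupB]
    common <- intersect(sa, sb)
    if (length(common) < 3)
      configError("paired comparison requires >= 3 common subjects")
    a <- a[, match(common, sa), drop = FALSE]
    b <- b[, match(common, sb), drop = FALSE]
  }
  rows <- lapply(proteinIds(x), function(pid) {
    va <- a[pid, ]; vb <- b[pid, ]
    if (paired) {
      ok <- !is.na(va) & !is.na(vb)
      va <- va[ok]; vb <- vb[ok]
      if (length(va) < 3) return(NULL)
    } else {
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      if (length(va) < 3 || length(vb) < 3) return(NULL)
    }
    gaussian <- normalityGate(va, alpha) && normalityGate(vb, alpha)
    ht <- if (gaussian)
      t.test(vb, va, var.equal = TRUE, paired = paired)
    else
      suppressWarnings(wilcox.test(vb, va, paired = paired, exact = FALSE))
    data.frame(protein_id = pid,
               delta_npx = mean(vb) - mean(va),
               statistic = unname(ht$statistic),
               p_raw = ht$p.value,
               test_used = if (gaussian) "t" else "wilcoxon")
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped))
    warning(sprintf("%d protein(s) excluded: fewer than 3 non-missing values per group",
                    sum(dropped)))
  out <- do.call(rbind, rows[!dropped])
  if (is.null(out))
    dataError("no protein has enough non-missing values in both groups")
  out$q_bh <- adjustBH(out$p_raw)
  volcanoClassify(out, qMax = qMax, fcMinLog2 = fcMinLog2)
}

#' Three-group comparison (ANOVA / Kruskal-Wallis) with a normality gate
#'
#' For each protein, one-way ANOVA across the sample groups when every group
#' passes the [normalityGate()], otherwise the Kruskal-Wallis test; BH
#' adjustment across proteins.
#'
#' @param x an [NpxExperiment-class] with at least 3 groups present.
#' @param alpha normality-gate level.
#' @return data.frame: `protein_id`, `statistic`, `p_raw`, `q_bh`,
#'   `test_used`.
#' @export
threeGroupTest <- function(x, alpha = 0.05) {
  grp <- droplevels(sampleGroup(x))
  if (nlevels(grp) < 3)
    configError("three-group test requires >= 3 groups, found %d",
                nlevels(grp))
  rows <- lapply(proteinIds(x), function(pid) {
    v <- npx(x)[pid, ]
    ok <- !is.na(v)
    v <- v[ok]; g <- droplevels(grp[ok])
    if (nlevels(g) < 3 || any(table(g) < 3)) return(NULL)
    gaussian <- all(vapply(levels(g),
                           function(l) normalityGate(v[g == l], alpha),
                           logical(1)))
    if (gaussian) {
      fit <- anova(aov(v ~ g))
      data.frame(protein_id = pid, statistic = fit$`F value`[1],
                 p_raw = fit$`Pr(>F)`[1], test_used = "anova")
    } else {
      ht <- kruskal.test(v, g)
      data.frame(protein_id = pid, statistic = unname(ht$statistic),
                 p_raw = ht$p.value, test_used = "kruskal")
    }
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped))
    warning(sprintf("%d protein(s) excluded from the three-group test",
                    sum(dropped)))
  out <- do.call(rbind, rows[!dropped])
  if (is.null(out)) dataError("no testable protein")
  out$q_bh <- adjustBH(out$p_raw)
  out
}

#' Single-marker ROC with Youden's J operating point
#'
#' Empirical ROC analysis of one marker (positives expected to score
#' higher): AUC with the midrank tie convention, a confidence interval
#' (DeLong by default, falling back to a seeded stratified bootstrap when
#' the DeLong variance is degenerate), and the operating threshold
#' maximizing Youden's J = sensitivity + specificity - 1.
#'
#' @param scores numeric marker values.
#' @param labels binary class per sample (0/1 or logical; 1 = case).
#' @param ciMethod `"delong"` (default) or `"bootstrap"` (2000 stratified
#'   replicates).
#' @param seed seed for the bootstrap CI.
#' @return list: `auc`, `auc_ci` (length 2), `youden_threshold`,
#'   `sensitivity`, `specificity`.
#' @export
rocWithYouden <- function(scores, labels, ciMethod = c("delong", "bootstrap"),
                          seed = 1) {
  ciMethod <- match.arg(ciMethod)
  labels <- as.numeric(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2)
    configError("ROC requires both classes present")
  if (length(unique(scores)) < 2)
    configError("ROC requires >= 2 distinct scores")
  r <- pROC::roc(labels, scores, direction = "<", levels = c(0, 1),
                 quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- withSeed(seed, {
    if (ciMethod == "delong") {
      out <- tryCatch(suppressWarnings(pROC::ci.auc(r, method = "delong")),
                      error = function(e) NULL)
      if (is.null(out) || anyNA(out))
        out <- suppressWarnings(
          pROC::ci.auc(r, method = "bootstrap", boot.n = 2000,
                       boot.stratified = TRUE, progress = "none"))
      out
    } else {
      suppressWarnings(
        pROC::ci.auc(r, method = "bootstrap", boot.n = 2000,
                     boot.stratified = TRUE, progress = "none"))
    }
  })
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, ]  # ties in J: first (lowest) threshold, documented
  list(auc = auc, auc_ci = c(ci[1], ci[3]),
       youden_threshold = as.numeric(best$threshold),
       sensitivity = as.numeric(best$sensitivity),
       specificity = as.numeric(best$specificity))
}

#' Single-marker ROC screen of the top differential proteins
#'
#' Convenience wrapper mirroring the study workflow: rank proteins by
#' `delta_npx` from a two-group comparison, keep the top `k` upregulated
#' markers, and run [rocWithYouden()] on each against the case/control
#' labels.
#'
#' @param x an [NpxExperiment-class].
#' @param differential result of [twoGroupTest()].
#' @param groupA,groupB the groups compared (control first).
#' @param k number of top markers (default 5).
#' @param seed seed for bootstrap CIs.
#' @return data.frame: `marker_id`, `auc`, `auc_ci_low`, `auc_ci_high`,
#'   `youden_threshold`, `sensitivity`, `specificity`.
#' @export
topMarkerRoc <- function(x, differential, groupA = "HC", groupB = "PT_BE",
                         k = 5, seed = 1) {
  ord <- differential[order(-differential$delta_npx), ]
  top <- head(ord$protein_id, k)
  keep <- sampleGroup(x) %in% c(groupA, groupB)
  labels <- as.numeric(sampleGroup(x)[keep] == groupB)
  rows <- lapply(top, function(pid) {
    rr <- rocWithYouden(npx(x)[pid, keep], labels, seed = seed)
    data.frame(marker_id = pid, auc = rr$auc,
               auc_ci_low = rr$auc_ci[1], auc_ci_high = rr$auc_ci[2],
               youden_threshold = rr$youden_threshold,
               sensitivity = rr$sensitivity, specificity = rr$specificity)
  })
  do.call(rbind, rows)
}
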