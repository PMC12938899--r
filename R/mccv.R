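#' Monte-Carlo cross-validation split plans
#'
#' Draws `nSplits` independent random train/test partitions at the given
#' training fraction (default 70/30). Splits are stratified by class by
#' default: within each class, `round(trainFrac * n_class)` samples go to
#' training, so split sizes are constant across iterations.
#'
#' @param sampleIds sample identifiers.
#' @param labels binary class per sample.
#' @param nSplits number of Monte-Carlo splits (default 100).
#' @param trainFrac training fraction in (0, 1) (default 0.7).
#' @param stratified stratify by class (default `TRUE`).
#' @param seed integer seed.
#' @return list of split plans; each has `split_index`, `train_ids`,
#'   `test_ids`.
#' @export
makeSplits <- function(sampleIds, labels, nSplits = 100, trainFrac = 0.7,
                       stratified = TRUE, seed = 1) {
  if (!is.numeric(trainFrac) || trainFrac <= 0 || trainFrac >= 1)
    configError("trainFrac: must lie strictly within (0, 1)")
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) != 2) configError("two classes required")
  if (min(tab) < 2) configError("each class needs >= 2 samples")
  nTrain <- round(trainFrac * tab)
  if (any(nTrain < 1) || any(nTrain >= tab))
    configError("trainFrac leaves a class empty in train or test")
  withSeed(seed, {
    lapply(seq_len(nSplits), function(i) {
      if (stratified) {
        train <- unlist(lapply(names(tab), function(cl) {
          ids <- sampleIds[labels == cl]
          sample(ids, nTrain[cl])
        }), use.names = FALSE)
      } else {
        repeat {
          train <- sample(sampleIds, round(trainFrac * length(sampleIds)))
          test <- setdiff(sampleIds, train)
          if (length(unique(labels[match(train, sampleIds)])) == 2 &&
              length(unique(labels[match(test, sampleIds)])) == 2) break
        }
      }
      list(split_index = i, train_ids = train,
           test_ids = setdiff(sampleIds, train))
    })
  })
}

## Ridge logistic IRLS for the p = 1 edge case (glmnet needs >= 2 columns).
## Matches the glmnet objective -(1/n) loglik + lambda * beta^2 / 2
## (intercept unpenalized).
ridgeIrls1 <- function(x, y, lambda, maxIter = 50, tol = 1e-9) {
  n <- length(y)
  b <- c(qlogis(pmin(pmax(mean(y), 0.05), 0.95)), 0)
  X <- cbind(1, as.numeric(x))
  pen <- c(0, lambda * n)
  for (it in seq_len(maxIter)) {
    eta <- as.numeric(X %*% b)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    H <- crossprod(X, w * X) + diag(pen)
    bNew <- solve(H, crossprod(X, w * z))
    if (sum((bNew - b)^2) < tol) { b <- bNew; break }
    b <- bNew
  }
  as.numeric(b)
}

binomialDeviance <- function(prob, y) {
  prob <- pmin(pmax(prob, 1e-10), 1 - 1e-10)
  mean(-2 * (y * log(prob) + (1 - y) * log(1 - prob)))
}

#' Ridge-penalized logistic classifier with the 1-SE penalty rule
#'
#' Fits an L2-penalized logistic regression over a fixed grid of 100
#' log-spaced penalties (10^2 down to 10^-4, appropriate for z-scored
#' predictors), selects the penalty by K-fold cross-validated binomial
#' deviance using the 1-SE rule — the largest penalty whose CV loss is
#' within one standard error of the minimum — and returns the coefficients
#' at that penalty. The CV loss curve (`cv_loss`, `cv_se`, `lambda_grid`)
#' is stored so the rule can be audited.
#'
#' Edge cases: with a single predictor an internal IRLS ridge is used; with
#' zero predictors the fit degenerates to the intercept (training
#' prevalence).
#'
#' @param x complete, standardized training matrix (samples x features).
#' @param y binary 0/1 labels.
#' @param internalFolds CV folds for the penalty choice (default 10).
#' @param nlambda penalty-grid size (default 100).
#' @param seed integer seed for fold assignment.
#' @param imputationValues,standardization optional per-feature training
#'   medians and z-scoring parameters, stored for [applyRidge()] to apply
#'   to raw test data.
#' @return object of class `evpanelRidgeFit`: `intercept`, `coefficients`,
#'   `lambda`, `lambda_grid`, `cv_loss`, `cv_se`, `feature_ids`, and the
#'   stored preprocessing parameters.
#' @export
fitRidge <- function(x, y, internalFolds = 10, nlambda = 100, seed = 1,
                     imputationValues = NULL, standardization = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    configError("single-class training set")
  if (anyNA(x)) dataError("ridge fit requires complete data")
  p <- ncol(x)
  ids <- colnames(x)
  if (is.null(ids) && p > 0) ids <- paste0("V", seq_len(p))
  lam <- 10^seq(2, -4, length.out = nlambda)
  if (p == 0) {
    fit <- list(intercept = qlogis(pmin(pmax(mean(y), 1e-6), 1 - 1e-6)),
                coefficients = setNames(numeric(0), character(0)),
                lambda = NA_real_, lambda_grid = lam,
                cv_loss = rep(NA_real_, nlambda),
                cv_se = rep(NA_real_, nlambda),
                feature_ids = character(0),
                imputationValues = imputationValues,
                standardization = standardization)
    return(structure(fit, class = "evpanelRidgeFit"))
  }
  n <- nrow(x)
  folds <- withSeed(seed, sample(rep_len(seq_len(internalFolds), n)))
  pathCoef <- function(xt, yt) {
    if (ncol(xt) >= 2) {
      g <- glmnet::glmnet(xt, yt, family = "binomial", alpha = 0,
                          lambda = lam, standardize = FALSE)
      rbind(g$a0, as.matrix(g$beta))
    } else {
      vapply(lam, function(l) ridgeIrls1(xt, yt, l), numeric(2))
    }
  }
  loss <- matrix(NA_real_, internalFolds, nlambda)
  for (k in seq_len(internalFolds)) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2) next
    cf <- pathCoef(x[tr, , drop = FALSE], y[tr])
    eta <- cbind(1, x[!tr, , drop = FALSE]) %*% cf
    loss[k, ] <- apply(plogis(eta), 2, binomialDeviance, y = y[!tr])
  }
  used <- rowSums(is.na(loss)) == 0
  cvm <- colMeans(loss[used, , drop = FALSE])
  cvse <- apply(loss[used, , drop = FALSE], 2, sd) / sqrt(sum(used))
  iMin <- which.min(cvm)
  i1se <- which(cvm <= cvm[iMin] + cvse[iMin])[1]  # grid is descending
  cf <- pathCoef(x, y)[, i1se]
  structure(list(intercept = cf[1],
                 coefficients = setNames(cf[-1], ids),
                 lambda = lam[i1se], lambda_grid = lam,
                 cv_loss = cvm, cv_se = cvse,
                 feature_ids = ids,
                 imputationValues = imputationValues,
                 standardization = standardization),
            class = "evpanelRidgeFit")
}

#' Predict with a fitted ridge classifier
#'
#' Applies the training-split preprocessing stored in the fit — median
#' imputation values and z-scoring mean/SD — to the test features, then the
#' logistic model, without any further tuning.
#'
#' @param fit an `evpanelRidgeFit` from [fitRidge()].
#' @param x test feature matrix (samples x features, same features as the
#'   fit). May contain `NA` when imputation values are stored in the fit.
#' @return per-sample predicted probability, strictly within (0, 1).
#' @export
applyRidge <- function(fit, x) {
  x <- as.matrix(x)
  if (length(fit$feature_ids)) {
    if (ncol(x) != length(fit$feature_ids))
      contractError("test matrix has %d features; fit expects %d",
                    ncol(x), length(fit$feature_ids))
    if (!is.null(colnames(x)) && !identical(colnames(x), fit$feature_ids))
      contractError("test feature names do not match the fit")
    if (!is.null(fit$imputationValues))
      x <- imputeColumns(x, fit$imputationValues)
    if (!is.null(fit$standardization))
      x <- applyStandardization(x, fit$standardization)
    if (anyNA(x)) dataError("test features incomplete after imputation")
    eta <- fit$intercept + as.numeric(x %*% fit$coefficients)
  } else {
    eta <- rep(fit$intercept, nrow(x))
  }
  pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
}

#' Pooled out-of-fold AUC over per-subject median probabilities
#'
#' Aggregates held-out predictions across Monte-Carlo repeats by taking, for
#' each subject, the median predicted probability over all repeats in which
#' the subject was held out, and computing the AUC on these per-subject
#' medians. The confidence interval is a seeded percentile bootstrap over
#' subjects (resamples with a single class are redrawn).
#'
#' @param perSubjectOof named list: held-out probabilities per subject.
#' @param labels named 0/1 label per subject.
#' @param nBoot bootstrap replicates (default 2000).
#' @param level CI level (default 0.95).
#' @param seed integer seed.
#' @return list: `auc`, `ci` (length 2), `medians` (per subject).
#' @export
pooledOofAuc <- function(perSubjectOof, labels, nBoot = 2000, level = 0.95,
                         seed = 1) {
  nPred <- lengths(perSubjectOof)
  if (any(nPred == 0)) {
    warning(sprintf("%d subject(s) never held out; excluded from pooled AUC",
                    sum(nPred == 0)))
    perSubjectOof <- perSubjectOof[nPred > 0]
  }
  subj <- names(perSubjectOof)
  med <- vapply(perSubjectOof, median, numeric(1))
  lab <- labels[subj]
  auc <- empiricalAuc(med, lab)
  ci <- withSeed(seed, {
    reps <- vapply(seq_len(nBoot), function(b) {
      repeat {
        idx <- sample(length(med), replace = TRUE)
        if (length(unique(lab[idx])) == 2) break
      }
      empiricalAuc(med[idx], lab[idx])
    }, numeric(1))
    quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  })
  list(auc = auc, ci = ci, medians = med)
}

selectorFun <- function(selector) {
  switch(selector,
         boruta = borutaSelect,
         elastic_net = elasticNetSelect,
         plsda = plsdaSelect,
         configError("unknown selector '%s'", selector))
}

## Core MCCV loop shared by runMCCV (with in-split selection) and
## evaluatePanel (fixed feature set, selector = "none").
mccvCore <- function(vals, labels, subjects, selector, splits,
                     selectorArgs, internalFolds, seed, fixedFeatures) {
  nSplits <- length(splits)
  seeds <- childSeeds(seed, 2 * nSplits + 1)
  selCount <- setNames(numeric(ncol(vals)), colnames(vals))
  perSplitAuc <- numeric(nSplits)
  subjAll <- unique(subjects)
  oof <- setNames(vector("list", length(subjAll)), subjAll)
  subjectLabels <- setNames(labels[match(subjAll, subjects)], subjAll)
  for (i in seq_len(nSplits)) {
    sp <- splits[[i]]
    trIdx <- match(sp$train_ids, rownames(vals))
    teIdx <- match(sp$test_ids, rownames(vals))
    xtr <- vals[trIdx, , drop = FALSE]
    xte <- vals[teIdx, , drop = FALSE]
    ytr <- labels[trIdx]; yte <- labels[teIdx]
    med <- columnMedians(xtr)
    xtr <- imputeColumns(xtr, med)
    xte <- imputeColumns(xte, med)
    std <- standardizationParams(xtr)
    xtrS <- applyStandardization(xtr, std)
    xteS <- applyStandardization(xte, std)
    if (selector == "none") {
      feats <- fixedFeatures
      selModel <- NULL
    } else {
      selArgs <- c(list(x = xtrS, y = ytr, seed = seeds[2 * i - 1],
                        splitIndex = i), selectorArgs)
      selOut <- tryCatch(do.call(selectorFun(selector), selArgs),
                         error = function(e)
                           stop(sprintf("split %d: %s", i, conditionMessage(e)),
                                call. = FALSE))
      feats <- selOut@selected
      selModel <- selOut
      if (length(feats)) selCount[feats] <- selCount[feats] + 1
    }
    if (selector == "plsda" && length(feats) >= 2) {
      ## PLS component scores derived from the selected proteins are the
      ## classifier's predictors.
      ncomp <- min(selModel@diagnostics$ncomp, length(feats))
      pfit <- fitPLSDA(xtrS[, feats, drop = FALSE], ytr,
                       nComponents = ncomp)
      ptr <- pfit$scores
      pte <- plsdaScores(pfit, xteS[, feats, drop = FALSE])
      colnames(ptr) <- colnames(pte) <- paste0("LV", seq_len(ncol(ptr)))
      pstd <- standardizationParams(ptr)
      rtr <- applyStandardization(ptr, pstd)
      rte <- applyStandardization(pte, pstd)
    } else {
      rtr <- xtrS[, feats, drop = FALSE]
      rte <- xteS[, feats, drop = FALSE]
    }
    fit <- fitRidge(rtr, ytr, internalFolds = internalFolds,
                    seed = seeds[2 * i])
    prob <- applyRidge(fit, rte)
    perSplitAuc[i] <- empiricalAuc(prob, yte)
    for (j in seq_along(teIdx)) {
      s <- subjects[teIdx[j]]
      oof[[s]] <- c(oof[[s]], prob[j])
    }
  }
  heldOut <- lengths(oof) > 0
  pooled <- pooledOofAuc(oof[heldOut], subjectLabels, seed = seeds[2 * nSplits + 1])
  methods::new("MccvResult",
               per_split_auc = perSplitAuc,
               per_subject_oof = oof,
               subject_labels = subjectLabels,
               pooled_oof_auc = pooled$auc,
               pooled_oof_ci = as.numeric(pooled$ci),
               selection_freq = selCount / nSplits,
               selector = selector)
}

## Normalize runMCCV/evaluatePanel input to (values, labels, subjects).
mccvInput <- function(x, labels, subjects, groups) {
  if (methods::is(x, "NpxExperiment")) {
    keep <- sampleGroup(x) %in% groups
    vals <- t(npx(x)[, keep, drop = FALSE])
    labels <- as.numeric(sampleGroup(x)[keep] == groups[2])
    subjects <- subjectId(x)[keep]
    subjects[is.na(subjects)] <- rownames(vals)[is.na(subjects)]
  } else {
    vals <- as.matrix(x)
    if (is.null(rownames(vals)))
      rownames(vals) <- sprintf("S%03d", seq_len(nrow(vals)))
    if (is.null(labels)) configError("labels required for matrix input")
    labels <- as.numeric(labels)
    if (is.null(subjects)) subjects <- rownames(vals)
  }
  if (is.null(colnames(vals)))
    colnames(vals) <- sprintf("PROT%03d", seq_len(ncol(vals)))
  list(vals = vals, labels = labels, subjects = subjects)
}

#' Run the Monte-Carlo cross-validation stability loop for one selector
#'
#' The study's within-iteration workflow on each of `nSplits` random 70/30
#' splits: median imputation values and z-scoring parameters are computed on
#' the training split only and applied to the test split; the selector picks
#' its top (up to) five proteins on the standardized training data; a
#' ridge-penalized logistic classifier with the 1-SE penalty rule is fitted
#' on the selected features (for the PLS-DA selector, on PLS component
#' scores derived from the selected proteins) and applied to the test split.
#' Per-split held-out AUC, per-subject out-of-fold probabilities and
#' per-protein selection frequencies are aggregated across splits, and the
#' pooled out-of-fold AUC is computed from per-subject median probabilities.
#'
#' @param x an [NpxExperiment-class] (filtered; the two `groups` are
#'   compared) or a samples x proteins matrix (possibly with `NA`).
#' @param selector `"boruta"`, `"elastic_net"` or `"plsda"`.
#' @param labels,subjects for matrix input: 0/1 labels and subject ids
#'   (defaults to one subject per sample).
#' @param groups for [NpxExperiment-class] input: the two groups compared;
#'   the second is the positive class (default HC vs PT_BE).
#' @param nSplits,trainFrac,stratified split design, see [makeSplits()].
#' @param splits optionally, precomputed split plans (overrides the split
#'   design).
#' @param selectorArgs named list of extra arguments for the selector (e.g.
#'   `nIter`, `numTrees` for `"boruta"`; `repeats` for `"plsda"`).
#' @param internalFolds ridge penalty CV folds (default 10).
#' @param seed root seed; split plans, selector seeds, ridge fold seeds and
#'   the bootstrap CI all derive from it.
#' @return an [MccvResult-class].
#' @export
runMCCV <- function(x, selector = c("boruta", "elastic_net", "plsda"),
                    labels = NULL, subjects = NULL,
                    groups = c("HC", "PT_BE"), nSplits = 100,
                    trainFrac = 0.7, stratified = TRUE, splits = NULL,
                    selectorArgs = list(), internalFolds = 10, seed = 1) {
  selector <- match.arg(selector)
  inp <- mccvInput(x, labels, subjects, groups)
  if (is.null(splits))
    splits <- makeSplits(rownames(inp$vals), inp$labels, nSplits = nSplits,
                         trainFrac = trainFrac, stratified = stratified,
                         seed = childSeeds(seed, 1))
  mccvCore(inp$vals, inp$labels, inp$subjects, selector, splits,
           selectorArgs, internalFolds, seed, NULL)
}

#' Derive the consensus biomarker panel from selection frequencies
#'
#' Computes each selector's stable set — proteins selected in at least
#' `stability` of the Monte-Carlo repeats — and derives the consensus panel
#' by one of two rules: `"top_k_aggregate"` (default) ranks proteins by
#' their summed selection frequency across selectors and takes the top `k`;
#' `"stable_intersection"` intersects the selectors' stable sets. An empty
#' intersection triggers a warning suggesting the aggregate rule.
#'
#' @param freqs per-selector selection frequencies: a named list of named
#'   numeric vectors (fractions in \[0, 1\]), a named list of
#'   [MccvResult-class] objects, or a data.frame with columns `model`,
#'   `protein`, `freq`.
#' @param stability stability threshold (default 0.60).
#' @param rule consensus rule (see above).
#' @param k panel size for the aggregate rule (default 2).
#' @return a [ConsensusPanel-class].
#' @export
consensusPanel <- function(freqs, stability = 0.60,
                           rule = c("top_k_aggregate", "stable_intersection"),
                           k = 2) {
  rule <- match.arg(rule)
  if (is.data.frame(freqs)) {
    stopifnot(all(c("model", "protein", "freq") %in% names(freqs)))
    freqs <- lapply(split(freqs, freqs$model),
                    function(d) setNames(d$freq, d$protein))
  } else if (is.list(freqs)) {
    freqs <- lapply(freqs, function(f)
      if (methods::is(f, "MccvResult")) selectionFreq(f) else f)
  }
  if (is.null(names(freqs)) || any(names(freqs) == ""))
    configError("each selector's frequencies must be named")
  prot <- sort(unique(unlist(lapply(freqs, names))))
  fm <- vapply(freqs, function(f) {
    v <- setNames(numeric(length(prot)), prot)
    v[names(f)] <- f
    v
  }, numeric(length(prot)))
  if (is.null(dim(fm))) fm <- matrix(fm, nrow = length(prot),
                                     dimnames = list(prot, names(freqs)))
  stable <- lapply(colnames(fm), function(m) prot[fm[, m] >= stability])
  names(stable) <- colnames(fm)
  panel <- if (rule == "top_k_aggregate") {
    total <- rowSums(fm)
    head(prot[order(-total, prot)], k)
  } else {
    inter <- Reduce(intersect, stable)
    if (length(inter) == 0)
      warning("stable-set intersection is empty; consider rule = 'top_k_aggregate'")
    inter
  }
  ft <- data.frame(protein = rep(prot, ncol(fm)),
                   model = rep(colnames(fm), each = length(prot)),
                   freq = as.vector(fm))
  methods::new("ConsensusPanel", stable_sets = stable,
               panel = as.character(panel), rule = rule,
               stability = stability, freq_table = ft)
}

#' Evaluate a fixed biomarker panel on fresh MCCV splits
#'
#' Re-runs the ridge logistic workflow — in-split median imputation,
#' z-scoring, ridge with the 1-SE rule, out-of-fold aggregation — on a fresh
#' set of Monte-Carlo splits with the feature set fixed to the panel (no
#' reselection).
#'
#' @param panel character vector of panel protein ids (non-empty).
#' @param x as in [runMCCV()].
#' @inheritParams runMCCV
#' @return an [MccvResult-class] with `selector = "none"`.
#' @export
evaluatePanel <- function(panel, x, labels = NULL, subjects = NULL,
                          groups = c("HC", "PT_BE"), nSplits = 100,
                          trainFrac = 0.7, stratified = TRUE,
                          internalFolds = 10, seed = 1) {
  if (length(panel) == 0) configError("panel must be non-empty")
  inp <- mccvInput(x, labels, subjects, groups)
  missing <- setdiff(panel, colnames(inp$vals))
  if (length(missing))
    contractError("panel protein(s) absent from the matrix: %s",
                  paste(missing, collapse = ", "))
  splits <- makeSplits(rownames(inp$vals), inp$labels, nSplits = nSplits,
                       trainFrac = trainFrac, stratified = stratified,
                       seed = childSeeds(seed, 1))
  mccvCore(inp$vals, inp$labels, inp$subjects, "none", splits,
           list(), internalFolds, seed, panel)
}
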