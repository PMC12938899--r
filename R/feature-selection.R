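## The three in-split feature selectors. Each is a pure function of
## (x, y, seed) returning a SelectorOutput with at most five features,
## ordered by decreasing importance (ties broken lexicographically).

newSelectorOutput <- function(model, selected, importance, diagnostics,
                              splitIndex = 0) {
  methods::new("SelectorOutput", model = model,
               split_index = splitIndex,
               selected = selected, importance = importance,
               diagnostics = diagnostics)
}

#' Shadow-feature (Boruta-style) all-relevant selection
#'
#' At each iteration the feature matrix is augmented with a shuffled
#' "shadow" copy of every feature, a random forest is fitted (ranger,
#' scaled permutation importance — the learner classical shadow-feature
#' selection uses), and each real feature scores a hit when its
#' importance beats the best shadow importance. After `nIter` iterations a
#' two-sided binomial test (null: hit probability 1/2) at level `conf` with
#' Bonferroni correction across features classifies features as confirmed
#' (significantly more hits), rejected (significantly fewer) or tentative.
#' Features are ranked by median importance across iterations; the top 5
#' confirmed features are returned, topping up from the highest-ranked
#' tentative features when fewer than 5 are confirmed.
#'
#' @param x standardized complete feature matrix, samples x proteins.
#' @param y binary labels (0/1, logical or 2-level factor).
#' @param nIter number of shadow iterations (default 500).
#' @param conf confidence level of the binomial decision (default 0.01).
#' @param numTrees trees per forest (default 500).
#' @param seed integer seed.
#' @param splitIndex bookkeeping index recorded in the output.
#' @return a [SelectorOutput-class]; diagnostics carry the confirmed,
#'   tentative and rejected sets and the per-feature hit counts.
#' @export
borutaSelect <- function(x, y, nIter = 500, conf = 0.01, numTrees = 500,
                         seed = 1, splitIndex = 0) {
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x)))
    dataError("shadow-feature selection requires finite, complete features")
  if (!isCount(nIter) || nIter < 1)
    configError("nIter: must be a count >= 1")
  y <- factor(y)
  if (nlevels(y) != 2) configError("binary labels required")
  p <- ncol(x)
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  colnames(x) <- ids
  iterSeeds <- childSeeds(seed, nIter)
  hits <- setNames(integer(p), ids)
  imp <- matrix(NA_real_, nIter, p, dimnames = list(NULL, ids))
  for (i in seq_len(nIter)) {
    withSeed(iterSeeds[i], {
      shadow <- apply(x, 2, sample)
      colnames(shadow) <- paste0(".shadow.", ids)
      fit <- ranger::ranger(x = cbind(x, shadow), y = y,
                            num.trees = numTrees,
                            importance = "permutation",
                            scale.permutation.importance = TRUE,
                            num.threads = 1, seed = iterSeeds[i])
      iv <- fit$variable.importance
      real <- iv[ids]
      imp[i, ] <- real
      hits <- hits + (real > max(iv[paste0(".shadow.", ids)]))
    })
  }
  ## two-sided binomial test at level conf, Bonferroni across the p features
  pLow <- pbinom(hits, nIter, 0.5)
  pHigh <- pbinom(hits - 1, nIter, 0.5, lower.tail = FALSE)
  pTwo <- pmin(1, 2 * pmin(pLow, pHigh) * p)
  confirmed <- ids[pTwo < conf & hits > nIter / 2]
  rejected <- ids[pTwo < conf & hits < nIter / 2]
  tentative <- setdiff(ids, c(confirmed, rejected))
  medImp <- apply(imp, 2, median)
  ranked <- orderByImportance(medImp)
  sel <- ranked[ranked %in% confirmed]
  if (length(sel) < 5)  # top up from tentative, never from rejected
    sel <- c(sel, ranked[ranked %in% tentative])
  newSelectorOutput("boruta", head(sel, 5), medImp,
                    list(confirmed = confirmed, tentative = tentative,
                         rejected = rejected, hits = hits, n_iter = nIter),
                    splitIndex)
}

#' Elastic-net selection
#'
#' Penalized logistic regression path with mixing parameter
#' `alphaMix = 0.5` between the L1 and L2 penalties; the penalty is chosen
#' by cross-validated AUC and features with non-zero coefficients at the
#' CV-optimal penalty are retained, of which the (up to) five largest
#' absolute coefficients are returned. The selection may legitimately be
#' empty when the CV-optimal path point is fully sparse.
#'
#' @param x standardized complete feature matrix, samples x proteins.
#' @param y binary labels.
#' @param alphaMix L1/L2 mixing (default 0.5).
#' @param nfolds internal CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param splitIndex bookkeeping index.
#' @return a [SelectorOutput-class]; diagnostics carry the chosen penalty
#'   and the number of non-zero coefficients.
#' @export
elasticNetSelect <- function(x, y, alphaMix = 0.5, nfolds = 5, seed = 1,
                             splitIndex = 0) {
  x <- as.matrix(x)
  y <- as.numeric(factor(y)) - 1
  if (length(unique(y)) != 2) configError("binary labels required")
  ids <- colnames(x)
  cv <- withSeed(seed, suppressWarnings(
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = alphaMix,
                      type.measure = "auc", nfolds = nfolds,
                      standardize = FALSE)))
  beta <- coef(cv, s = "lambda.min")[-1, 1]
  names(beta) <- ids
  nz <- beta[beta != 0]
  sel <- head(orderByImportance(abs(nz)), 5)
  newSelectorOutput("elastic_net", sel, abs(beta),
                    list(lambda = cv$lambda.min, n_nonzero = length(nz)),
                    splitIndex)
}

#' PLS-DA / VIP selection
#'
#' Fits a PLS-DA model with the component count chosen by repeated M-fold
#' cross-validation ([chooseNcompCV()]), ranks proteins by VIP and returns
#' the top five. The fitted projection is kept in the diagnostics so the
#' downstream classifier can use PLS component scores derived from the
#' selected proteins as its predictors.
#'
#' @param x standardized complete feature matrix, samples x proteins.
#' @param y binary labels.
#' @param maxComponents cap on the latent-variable count (default 5).
#' @param folds,repeats component-choice CV design (default 5 folds,
#'   10 repeats).
#' @param seed integer seed.
#' @param splitIndex bookkeeping index.
#' @return a [SelectorOutput-class]; diagnostics carry `ncomp` and the
#'   fitted `model`.
#' @export
plsdaSelect <- function(x, y, maxComponents = 5, folds = 5, repeats = 10,
                        seed = 1, splitIndex = 0) {
  if (!isCount(maxComponents) || maxComponents < 1)
    configError("maxComponents: must be a count >= 1")
  x <- as.matrix(x)
  y <- factor(y)
  ncomp <- chooseNcompCV(x, y, maxComponents = maxComponents, folds = folds,
                         repeats = repeats, seed = seed)
  fit <- fitPLSDA(x, y, nComponents = ncomp)
  v <- vip(fit)
  sel <- head(orderByImportance(v), 5)
  newSelectorOutput("plsda", sel, v,
                    list(ncomp = fit$nComponents, model = fit), splitIndex)
}
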