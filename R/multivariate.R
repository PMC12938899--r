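## PCA and PLS-DA on centered/scaled data. PLS-DA is a NIPALS PLS2 fit
## against a centered one-indicator-column-per-class response, with a
## deterministic sign convention (each component is flipped so the
## largest-magnitude element of its weight/loading vector is positive).

setOldClass("evpanelPca")
setOldClass("evpanelPlsda")

flipSign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -1 else 1
}

#' Principal component analysis of an NPX matrix
#'
#' PCA on centered and scaled data (unit-variance proteins). Deterministic:
#' each component's loading vector is flipped so that its largest-magnitude
#' element is positive.
#'
#' @param x numeric matrix, samples in rows, proteins in columns; complete
#'   (impute first).
#' @param nComponents number of components to retain,
#'   `<= min(nrow - 1, ncol)`.
#' @return an object of class `evpanelPca`: `scores` (samples x
#'   components), `loadings` (proteins x components), `varianceExplained`
#'   (fraction per retained component), `center`, `scale`.
#' @export
fitPCA <- function(x, nComponents = 2) {
  x <- as.matrix(x)
  if (anyNA(x)) dataError("PCA requires complete data; impute first")
  if (!isCount(nComponents) || nComponents < 1)
    configError("nComponents: must be a count >= 1")
  kmax <- min(nrow(x) - 1, ncol(x))
  if (nComponents > kmax)
    configError("nComponents: at most min(n_samples - 1, n_proteins) = %d", kmax)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- seq_len(nComponents)
  sgn <- apply(pc$rotation[, k, drop = FALSE], 2, flipSign)
  structure(list(kind = "pca",
                 scores = sweep(pc$x[, k, drop = FALSE], 2, sgn, "*"),
                 loadings = sweep(pc$rotation[, k, drop = FALSE], 2, sgn, "*"),
                 varianceExplained = ve[k],
                 nComponents = nComponents,
                 center = ctr, scale = scl),
            class = "evpanelPca")
}

## Core NIPALS PLS2 on already centered/scaled X and centered indicator Y.
nipals <- function(xs, ys, ncomp, tol = 1e-10, maxIter = 500) {
  n <- nrow(xs); p <- ncol(xs); q <- ncol(ys)
  totSS <- sum(xs^2)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); Tm <- matrix(0, n, ncomp)
  ve <- numeric(ncomp)
  a <- 0
  for (comp in seq_len(ncomp)) {
    u <- ys[, which.max(apply(ys, 2, var))]
    if (sum(abs(u)) < 1e-12) break
    t_old <- rep(Inf, n)
    for (it in seq_len(maxIter)) {
      w <- crossprod(xs, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      tt <- xs %*% w
      qv <- crossprod(ys, tt) / sum(tt^2)
      u <- ys %*% qv / sum(qv^2)
      if (sum((tt - t_old)^2) < tol * sum(tt^2)) break
      t_old <- tt
    }
    if (nw < 1e-12 || sum(tt^2) < 1e-12) break
    pv <- crossprod(xs, tt) / sum(tt^2)
    s <- flipSign(w)
    w <- s * w; tt <- s * tt; pv <- s * pv; qv <- s * qv
    a <- comp
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Tm[, a] <- tt
    ve[a] <- sum(tt^2) * sum(pv^2) / totSS
    xs <- xs - tcrossprod(tt, pv)
    ys <- ys - tcrossprod(tt, qv)
  }
  if (a == 0) dataError("PLS-DA fit degenerate: no usable component")
  k <- seq_len(a)
  list(W = W[, k, drop = FALSE], P = P[, k, drop = FALSE],
       Q = Q[, k, drop = FALSE], T = Tm[, k, drop = FALSE],
       varianceExplained = ve[k], ncomp = a)
}

#' Partial least squares discriminant analysis (PLS-DA)
#'
#' NIPALS PLS2 fit of centered/scaled NPX data against a centered
#' one-indicator-column-per-class response. Deterministic up to the
#' documented sign convention (largest-magnitude weight element positive per
#' component).
#'
#' @param x numeric matrix, samples x proteins, complete.
#' @param labels class label per sample (2 or 3 classes).
#' @param nComponents number of latent variables to fit (the fit stops
#'   early if the data support fewer).
#' @param scale scale proteins to unit variance (default `TRUE`, matching
#'   "centered and scaled" processing).
#' @return an object of class `evpanelPlsda`: `scores`, `weights`,
#'   `xloadings`, `yloadings`, `rotation` (project new data with
#'   `scale(xnew) %*% rotation`), `varianceExplained` (X-variance per LV),
#'   `classLevels`, `center`, `scale`, `yCenter`.
#' @seealso [vip()], [plsdaScores()], [chooseNcompCV()]
#' @export
fitPLSDA <- function(x, labels, nComponents = 2, scale = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) dataError("PLS-DA requires complete data; impute first")
  if (!isCount(nComponents) || nComponents < 1)
    configError("nComponents: must be a count >= 1")
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    configError("PLS-DA requires >= 2 classes")
  ctr <- colMeans(x)
  scl <- if (scale) apply(x, 2, sd) else rep(1, ncol(x))
  scl[scl == 0] <- 1
  xs <- base::scale(x, center = ctr, scale = scl)
  y <- model.matrix(~ labels - 1)
  colnames(y) <- levels(labels)
  yc <- colMeans(y)
  ys <- base::scale(y, center = yc, scale = FALSE)
  ncomp <- min(nComponents, nrow(x) - 1, ncol(x))
  fit <- nipals(xs, ys, ncomp)
  rotation <- fit$W %*% solve(crossprod(fit$P, fit$W))
  dimnames(rotation) <- list(colnames(x), paste0("LV", seq_len(fit$ncomp)))
  structure(list(kind = "plsda",
                 scores = fit$T, weights = fit$W, xloadings = fit$P,
                 yloadings = fit$Q, rotation = rotation,
                 varianceExplained = fit$varianceExplained,
                 nComponents = fit$ncomp, classLevels = levels(labels),
                 center = ctr, scale = scl, yCenter = yc),
            class = "evpanelPlsda")
}

#' Project new samples onto fitted PLS-DA components
#'
#' @param model an `evpanelPlsda` fit.
#' @param xnew matrix with the same proteins (columns) the model was fitted
#'   on.
#' @return matrix of component scores, samples x latent variables.
#' @export
plsdaScores <- function(model, xnew) {
  xnew <- as.matrix(xnew)
  if (ncol(xnew) != length(model$center))
    contractError("xnew has %d proteins; model was fitted on %d",
                  ncol(xnew), length(model$center))
  xs <- base::scale(xnew, center = model$center, scale = model$scale)
  ## sequential deflation, so the first a columns are exactly the scores of
  ## the a-component submodel (prefix-truncation consistent)
  W <- model$weights; P <- model$xloadings
  Tm <- matrix(0, nrow(xs), ncol(W),
               dimnames = list(rownames(xnew),
                               paste0("LV", seq_len(ncol(W)))))
  for (a in seq_len(ncol(W))) {
    tt <- xs %*% W[, a]
    Tm[, a] <- tt
    xs <- xs - tcrossprod(tt, P[, a])
  }
  Tm
}

#' @describeIn vip VIP scores of a PLS-DA fit: for protein j,
#'   `VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)` with `SS_a` the Y
#'   sum of squares explained by component a and unit-norm weight vectors;
#'   the mean squared VIP equals 1 by construction.
#' @export
setMethod("vip", "evpanelPlsda", function(object, ...) {
  ss <- colSums(object$scores^2) * colSums(object$yloadings^2)
  p <- nrow(object$weights)
  v <- sqrt(p * as.numeric(object$weights^2 %*% ss) / sum(ss))
  setNames(v, rownames(object$rotation))
})

#' @describeIn vip VIP is defined for discriminant PLS fits only.
#' @export
setMethod("vip", "evpanelPca", function(object, ...)
  contractError("VIP is defined for PLS-DA models, not PCA"))

#' Choose the PLS-DA component count by repeated M-fold cross-validation
#'
#' Repeated stratified M-fold CV on the training set; for each candidate
#' component count the balanced misclassification error (mean per-class
#' error of max-indicator class assignment) is averaged over folds and
#' repeats, and the count minimizing it is returned (ties broken toward the
#' smaller count).
#'
#' @param x samples x proteins matrix, complete.
#' @param labels class per sample.
#' @param maxComponents largest count considered (default 5).
#' @param folds,repeats CV design (default 5 folds, 10 repeats).
#' @param seed integer seed for fold assignment.
#' @return the chosen component count.
#' @export
chooseNcompCV <- function(x, labels, maxComponents = 5, folds = 5,
                          repeats = 10, seed = 1) {
  if (!isCount(maxComponents) || maxComponents < 1)
    configError("maxComponents: must be a count >= 1")
  labels <- factor(labels)
  cls <- levels(labels)
  if (min(table(labels)) < folds)
    configError("folds (%d) exceeds the smallest class size (%d)",
                folds, min(table(labels)))
  if (maxComponents == 1) return(1L)
  x <- as.matrix(x)
  withSeed(seed, {
    err <- matrix(0, repeats * folds, maxComponents)
    row <- 0
    for (r in seq_len(repeats)) {
      fold <- integer(length(labels))
      for (cl in cls) {
        idx <- which(labels == cl)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      for (k in seq_len(folds)) {
        tr <- fold != k
        fit <- fitPLSDA(x[tr, , drop = FALSE], labels[tr],
                        nComponents = maxComponents)
        ts <- plsdaScores(fit, x[!tr, , drop = FALSE])
        row <- row + 1
        for (a in seq_len(maxComponents)) {
          aa <- min(a, fit$nComponents)
          yhat <- ts[, seq_len(aa), drop = FALSE] %*%
            t(fit$yloadings[, seq_len(aa), drop = FALSE])
          yhat <- sweep(yhat, 2, fit$yCenter, "+")
          pred <- fit$classLevels[max.col(yhat, ties.method = "first")]
          obs <- labels[!tr]
          percls <- vapply(cls, function(cl) {
            n <- sum(obs == cl)
            if (n == 0) NA_real_ else mean(pred[obs == cl] != cl)
          }, numeric(1))
          err[row, a] <- mean(percls, na.rm = TRUE)
        }
      }
    }
    which.min(colMeans(err))  # which.min takes the first (smallest) count
  })
}
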