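## Shared internal helpers: typed conditions, seed streams, empirical AUC,
## in-split imputation / standardization.

configError <- function(fmt, ...) {
  stop(structure(class = c("evpanel_config_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

dataError <- function(fmt, ...) {
  stop(structure(class = c("evpanel_data_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

contractError <- function(fmt, ...) {
  stop(structure(class = c("evpanel_contract_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

## One root seed fans out into per-stage child seeds; keeps every stage
## reproducible without coupling stages through global RNG state.
childSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

withSeed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Empirical AUC: probability a positive outscores a negative, ties 1/2
## (midrank convention). labels are 0/1.
empiricalAuc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    configError("AUC requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Column medians over non-missing cells; constant fallback 0 for columns
## that are entirely missing in the training split.
columnMedians <- function(x) {
  med <- apply(x, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  med
}

imputeColumns <- function(x, values) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- values[j]
  }
  x
}

## z-scoring parameters from a training matrix; zero-variance columns get
## unit scale so they map to constant zero rather than NaN.
standardizationParams <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

applyStandardization <- function(x, params) {
  sweep(sweep(x, 2, params$mean, "-"), 2, params$sd, "/")
}

## Deterministic importance ordering: decreasing score, ties broken
## lexicographically by feature id.
orderByImportance <- function(importance) {
  ids <- names(importance)
  ids[order(-importance, ids)]
}

isCount <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == floor(x)
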