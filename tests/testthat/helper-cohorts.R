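# Small fixture builders shared across tests; everything is generated in
# code from fixed seeds.

tinyExperiment <- function(values, group, subjectId = NULL, ...) {
  if (is.null(subjectId))
    subjectId <- ifelse(group == "HC", NA_character_,
                        sub("_(BE|FU)$", "", colnames(values)))
  NpxExperiment(values, group = group, subjectId = subjectId, ...)
}

# deterministic two-group matrix with a known planted shift on protein 1
plantedMatrix <- function(nA = 30, nB = 30, p = 10, shift = 2, seed = 42,
                          noise = 1) {
  set.seed(seed)
  prot <- sprintf("P%02d", seq_len(p))
  samp <- c(sprintf("HC%02d", seq_len(nA)), sprintf("PT%02d_BE", seq_len(nB)))
  m <- matrix(rnorm(p * (nA + nB), 5, noise), p,
              dimnames = list(prot, samp))
  m[1, (nA + 1):(nA + nB)] <- m[1, (nA + 1):(nA + nB)] + shift
  tinyExperiment(m, group = rep(c("HC", "PT_BE"), c(nA, nB)))
}

defaultFiltered <- function(seed) {
  co <- generateNpxCohort(syntheticConfig(seed = seed))
  fl <- filterLOD(co$experiment)
  fm <- filterMissing(fl$experiment)
  list(experiment = fm$experiment, truth = co$truth)
}

reducedSelectorArgs <- function() {
  list(boruta = list(nIter = 25, numTrees = 50),
       plsda = list(repeats = 2))
}
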