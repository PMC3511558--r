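# Shared fixtures: small seeded cohorts and a compact SVM grid so the
# nested CV tests stay fast. Cohorts are built once per test run.

smallGrid <- svmGrid(cost = c(1, 32), gamma = c(2^-7, 2^-3))

# 5 balanced, well-separated classes, no label noise
cleanCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateCohort(syntheticConfig(
        nClasses = 5, proteinsPerClass = rep(20, 5), nFeatures = 60,
        nInformative = 20, classSeparation = 4, mislabelRate = 0, seed = 42))
    cache
  }
})

# same geometry with 10% injected mislabels
noisyCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateCohort(syntheticConfig(
        nClasses = 5, proteinsPerClass = rep(20, 5), nFeatures = 60,
        nInformative = 20, classSeparation = 3, mislabelRate = 0.1, seed = 7))
    cache
  }
})

# well-separated spherical blobs for clustering tests
makeBlobs <- function(k, m, d, sep, seed) {
  set.seed(seed)
  mu <- matrix(rnorm(k * d), k, d)
  mu <- mu / sqrt(rowSums(mu^2)) * sep
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(m * d), m, d) + matrix(mu[i, ], m, d, byrow = TRUE)))
  rownames(x) <- sprintf("b%03d", seq_len(k * m))
  list(x = x, cluster = rep(seq_len(k), each = m))
}

# tiny in-memory feature table
tinyTable <- function(m, proteins, images = "i1", cells = NULL) {
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(nrow(m)))
  CellFeatureSet(m, proteins, rep_len(images, nrow(m)), cells)
}
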