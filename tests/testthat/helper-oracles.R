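# Independent oracles and small generators used across the suite.

# Exhaustive double-loop enumeration of eligible peak pairs; deliberately
# independent of candidatePairs().
oraclePairs <- function(a, b, tol, shift, transform = "sqrt") {
  ia <- if (transform == "sqrt") sqrt(a@intensity) else a@intensity
  ib <- if (transform == "sqrt") sqrt(b@intensity) else b@intensity
  wa <- ia / sqrt(sum(ia^2)); wb <- ib / sqrt(sum(ib^2))
  rows <- list()
  for (i in seq_along(a@mz)) for (j in seq_along(b@mz)) {
    if (abs(a@mz[i] - b@mz[j]) <= tol ||
        abs(a@mz[i] - (b@mz[j] + shift)) <= tol)
      rows[[length(rows) + 1L]] <- c(i = i, j = j, weight = wa[i] * wb[j])
  }
  if (!length(rows))
    return(data.frame(i = integer(), j = integer(), weight = numeric()))
  as.data.frame(do.call(rbind, rows))
}

# Exhaustive maximum-weight one-to-one assignment score by subset dynamic
# programming over the columns (exact for small spectra; independent of the
# Hungarian solver used by the package).
oracleBestScore <- function(a, b, cfg) {
  shift <- precursorMz(a) - precursorMz(b)
  ia <- if (cfg@intensityTransform == "sqrt") sqrt(a@intensity) else a@intensity
  ib <- if (cfg@intensityTransform == "sqrt") sqrt(b@intensity) else b@intensity
  wa <- ia / sqrt(sum(ia^2)); wb <- ib / sqrt(sum(ib^2))
  nA <- length(wa); nB <- length(wb)
  M <- matrix(0, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    if (abs(a@mz[i] - b@mz[j]) <= cfg@fragmentTol ||
        abs(a@mz[i] - (b@mz[j] + shift)) <= cfg@fragmentTol)
      M[i, j] <- wa[i] * wb[j]
  }
  nMasks <- bitwShiftL(1L, nB)
  f <- numeric(nMasks)
  for (i in seq_len(nA)) {
    g <- f
    for (j in seq_len(nB)) {
      if (all(M[i, j] == 0)) next
      bit <- bitwShiftL(1L, j - 1L)
      prev <- which(bitwAnd(seq_len(nMasks) - 1L, bit) == 0L)
      cand <- f[prev] + M[i, j]
      tgt <- prev + bit
      upd <- cand > g[tgt]
      g[tgt[upd]] <- cand[upd]
    }
    f <- pmax(f, g)
  }
  max(f)
}

# Random small spectrum whose peaks sit near a coarse shared grid, so that
# direct and precursor-shifted coincidences are common.
gridSpectrum <- function(id, nPeaks = NULL, gridFrom = 100, gridTo = 130) {
  grid <- seq(gridFrom, gridTo, by = 0.5)
  if (is.null(nPeaks)) nPeaks <- sample(3:8, 1)
  mz <- sort(sample(grid, nPeaks)) + stats::runif(nPeaks, -0.02, 0.02)
  Spectrum(id, precursorMz = sample(grid, 1) + stats::runif(1, -0.02, 0.02),
           mz = mz, intensity = stats::rlnorm(nPeaks, log(50), 1))
}

# Count violations of parent/child conservation on the biological subtree
# (pseudo-nodes never feed taxon counters). Zero means fully conserved.
conservationViolations <- function(tree) {
  nd <- treeNodes(tree)
  bad <- 0L
  for (k in seq_len(nrow(nd))) {
    if (nd$isPseudo[k]) next
    ch <- nd[!is.na(nd$parentId) & nd$parentId == nd$nodeId[k] &
               !nd$isPseudo, , drop = FALSE]
    if (nd$nFiles[k] != nd$nFilesOwn[k] + sum(ch$nFiles)) bad <- bad + 1L
    if (nd$nMatched[k] != nd$nMatchedOwn[k] + sum(ch$nMatched)) bad <- bad + 1L
    if (nd$nMatched[k] > nd$nFiles[k]) bad <- bad + 1L
    if (nd$nFiles[k] > 0 &&
        (nd$proportion[k] < 0 || nd$proportion[k] > 1)) bad <- bad + 1L
  }
  bad
}

expectConserved <- function(tree) {
  expect_equal(conservationViolations(tree), 0L)
}

# Hand-built 5-vs-1 cohort toy: only s3 sits inside both edge thresholds.
toyCohorts <- function() {
  g1 <- Spectrum("g1", 400.00, mz = 100, intensity = 1)
  s1 <- Spectrum("s1", 400.005, mz = c(100, 300, 410, 520),
                 intensity = c(49, 25, 25, 1))     # cosine exactly 0.7
  s2 <- Spectrum("s2", 450.0, mz = 100, intensity = 1)   # delta 50 Th
  s3 <- Spectrum("s3", 400.01, mz = 100, intensity = 1)  # cosine 1, delta 0.01
  s4 <- Spectrum("s4", 400.002, mz = 250, intensity = 1) # cosine 0
  s5 <- Spectrum("s5", 399.99, mz = c(100, 300),
                 intensity = c(36, 64))            # cosine 0.6
  list(colonized = list(s1, s2, s3, s4, s5), germfree = list(g1))
}

# Shared mid-sized fixture; built once per test run.
sharedFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeRepository(fixtureSpec(seed = 42L, nTaxa = 12L,
                                           nPlantedAnalogues = 2L))
    cache
  }
})
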