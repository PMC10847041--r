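#' @include AllClasses.R
NULL

transformIntensity <- function(x, mode) {
  if (mode == "sqrt") sqrt(x) else x
}

normalizedWeights <- function(s, mode) {
  w <- transformIntensity(s@intensity, mode)
  n <- sqrt(sum(w^2))
  if (n > 0) w / n else w
}

#' Enumerate candidate peak pairs between two spectra
#'
#' A peak pair (i, j) is a candidate when the peaks agree directly
#' (`|mz_a - mz_b| <= fragmentTol`) or after shifting the second spectrum by
#' the precursor mass difference (`|mz_a - (mz_b + shift)| <= fragmentTol`).
#' A pair eligible both ways appears once. Pair weight is the product of the
#' two peaks' transformed, per-spectrum L2-normalized intensities.
#'
#' @param a,b [Spectrum-class] objects.
#' @param fragmentTol fragment tolerance (Th).
#' @param shift precursor m/z difference `precursorMz(a) - precursorMz(b)`.
#' @param intensityTransform `"sqrt"` or `"none"`.
#' @return data.frame with columns `i` (peak index in `a`), `j` (peak index
#'   in `b`), `weight`, `shifted` (logical: only eligible via the shift).
#' @export
candidatePairs <- function(a, b, fragmentTol, shift,
                           intensityTransform = "sqrt") {
  wa <- normalizedWeights(a, intensityTransform)
  wb <- normalizedWeights(b, intensityTransform)
  dmz <- outer(a@mz, b@mz, "-")
  direct <- abs(dmz) <= fragmentTol
  shiftedOk <- abs(dmz - shift) <= fragmentTol
  elig <- direct | shiftedOk
  idx <- which(elig, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(i = integer(), j = integer(), weight = numeric(),
                      shifted = logical()))
  data.frame(i = idx[, 1], j = idx[, 2],
             weight = wa[idx[, 1]] * wb[idx[, 2]],
             shifted = !direct[idx])
}

# Exact minimum-cost assignment on a square cost matrix (Hungarian algorithm
# with row/column potentials, O(n^3)). Returns, for each row, the assigned
# column. Costs may be negative.
solveAssignment <- function(C) {
  n <- nrow(C)
  stopifnot(ncol(C) == n)
  u <- numeric(n + 1L)          # row potentials, u[r + 1] for row r (0 = virtual)
  v <- numeric(n + 1L)          # column potentials, v[c + 1] for column c
  p <- integer(n + 1L)          # p[c + 1]: row assigned to column c (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      jfree <- which(!used[2:(n + 1L)])
      idx <- jfree + 1L
      cur <- C[i0, jfree] - u[i0 + 1L] - v[idx]
      better <- cur < minv[idx]
      if (any(better)) {
        minv[idx[better]] <- cur[better]
        way[idx[better]] <- j0
      }
      k <- which.min(minv[idx])
      delta <- minv[idx][k]
      j1 <- jfree[k]
      usedIdx <- which(used)
      u[p[usedIdx] + 1L] <- u[p[usedIdx] + 1L] + delta
      v[usedIdx] <- v[usedIdx] - delta
      minv[idx] <- minv[idx] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

# Maximum-weight one-to-one selection among candidate pairs. Peaks not in any
# pair are dropped before solving; the profit matrix is zero-padded to square
# so leaving a peak unmatched costs nothing.
bestAssignment <- function(pairs) {
  if (!nrow(pairs)) return(list(score = 0, pairs = pairs[0, ]))
  ai <- sort(unique(pairs$i))
  bj <- sort(unique(pairs$j))
  n <- max(length(ai), length(bj))
  P <- matrix(0, n, n)
  ri <- match(pairs$i, ai)
  cj <- match(pairs$j, bj)
  # a pair may be listed once; fill its weight
  P[cbind(ri, cj)] <- pairs$weight
  assign <- solveAssignment(-P)
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs)))
    keep[k] <- assign[ri[k]] == cj[k] && pairs$weight[k] > 1e-15
  list(score = sum(pairs$weight[keep]), pairs = pairs[keep, , drop = FALSE])
}

#' Modified cosine similarity between two spectra
#'
#' Computes the modified cosine score: candidate peak pairs (direct or
#' precursor-shift matched, see [candidatePairs()]) are assembled into a
#' one-to-one assignment of maximal total weight, each peak used at most
#' once; the score is the total assigned weight after square-root (or no)
#' intensity transformation and per-spectrum L2 normalization, so it lies in
#' \[0, 1\] and equals 1 for identical spectra. The assignment is solved
#' exactly (Hungarian algorithm), making the score deterministic and
#' symmetric.
#'
#' @param a,b [Spectrum-class] objects with precursors and at least one peak.
#' @param cfg a [SearchConfig-class]; `fragmentTol` and `intensityTransform`
#'   are used here.
#' @return one-row data.frame (a match record) with `query_id`,
#'   `reference_id`, `cosine`, `n_matched_ions`, `precursor_delta`
#'   (query minus reference).
#' @examples
#' s <- Spectrum("q", 303.1, c(100, 150, 200), c(5, 10, 2))
#' modifiedCosine(s, s, searchConfig())
#' @export
modifiedCosine <- function(a, b, cfg = searchConfig()) {
  if (!isSearchable(a) || !isSearchable(b))
    stop("modified cosine requires a precursor m/z and at least one peak ",
         "in both spectra")
  shift <- a@precursorMz - b@precursorMz
  pairs <- candidatePairs(a, b, cfg@fragmentTol, shift,
                          cfg@intensityTransform)
  sol <- bestAssignment(pairs)
  data.frame(query_id = a@spectrumId, reference_id = b@spectrumId,
             cosine = min(1, sol$score), n_matched_ions = nrow(sol$pairs),
             precursor_delta = shift, stringsAsFactors = FALSE)
}

#' Does a match pass the acceptance thresholds?
#'
#' Both comparisons are inclusive: a cosine exactly at `minCosine` and an ion
#' count exactly at `minMatchedIons` pass.
#'
#' @param m a match record as returned by [modifiedCosine()] (or any list
#'   with `cosine` and `n_matched_ions`).
#' @param cfg a [SearchConfig-class].
#' @return logical scalar.
#' @export
passesThresholds <- function(m, cfg = searchConfig()) {
  m$cosine >= cfg@minCosine && m$n_matched_ions >= cfg@minMatchedIons
}
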