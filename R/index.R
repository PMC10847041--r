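#' @include AllClasses.R
NULL

#' Build a precursor m/z index
#'
#' Sorts searchable spectra by precursor m/z so that candidate retrieval can
#' use binary search. Spectra without a precursor or without peaks are
#' excluded and counted in the build report (`nSkipped`); duplicate precursor
#' values are allowed.
#'
#' @param spectra list of [Spectrum-class] objects.
#' @return a [SpectrumIndex-class].
#' @examples
#' sp <- list(Spectrum("a", 300, 100, 1), Spectrum("b", 100, 100, 1))
#' buildIndex(sp)
#' @export
buildIndex <- function(spectra) {
  ok <- vapply(spectra, isSearchable, logical(1))
  if (!length(spectra)) warning("building an index from zero spectra")
  kept <- spectra[ok]
  prec <- vapply(kept, function(s) s@precursorMz, numeric(1))
  o <- order(prec)
  new("SpectrumIndex", precursorMz = prec[o], spectra = kept[o],
      nSpectra = length(kept), nSkipped = sum(!ok),
      buildFingerprint = contentFingerprint(spectra))
}

#' Retrieve candidate reference spectra for a query precursor
#'
#' Exact mode returns every indexed spectrum with
#' `|precursor - query| <= precursorTol`; analogue mode widens the window to
#' `analogueMaxDelta`. Both window bounds are inclusive. Retrieval is two
#' binary searches over the sorted precursor vector and is identical to a
#' linear scan.
#'
#' @param ix a [SpectrumIndex-class].
#' @param precursorMz query precursor m/z (Th).
#' @param cfg a [SearchConfig-class].
#' @return integer vector of index positions; use `ix@spectra[positions]`
#'   or [candidateSpectra()] for the spectra themselves.
#' @export
queryCandidates <- function(ix, precursorMz, cfg = searchConfig()) {
  if (!ix@nSpectra) return(integer())
  window <- if (cfg@analogue) cfg@analogueMaxDelta else cfg@precursorTol
  prec <- ix@precursorMz
  lo <- findInterval(precursorMz - window, prec, left.open = TRUE) + 1L
  hi <- findInterval(precursorMz + window, prec)
  if (hi < lo) return(integer())
  seq.int(lo, hi)
}

#' @rdname queryCandidates
#' @return `candidateSpectra()`: list of candidate [Spectrum-class] objects.
#' @export
candidateSpectra <- function(ix, precursorMz, cfg = searchConfig()) {
  ix@spectra[queryCandidates(ix, precursorMz, cfg)]
}
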