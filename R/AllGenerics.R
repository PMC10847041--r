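#' @include AllClasses.R
NULL

#' Spectrum accessors
#'
#' @param object a [Spectrum-class].
#' @return `peaksData()` a two-column matrix (`mz`, `intensity`);
#'   `precursorMz()` / `spectrumId()` / `scanNumber()` the corresponding
#'   scalar; `peakCount()` the number of peaks; `isSearchable()` whether the
#'   spectrum has a precursor and at least one peak.
#' @examples
#' s <- Spectrum("s1", 303.1, mz = c(91.05, 150.1), intensity = c(55, 10))
#' precursorMz(s); peakCount(s)
#' @name spectrum-accessors
NULL

#' @rdname spectrum-accessors
#' @export
setGeneric("peaksData", function(object) standardGeneric("peaksData"))
#' @rdname spectrum-accessors
#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))
#' @rdname spectrum-accessors
#' @export
setGeneric("spectrumId", function(object) standardGeneric("spectrumId"))
#' @rdname spectrum-accessors
#' @export
setGeneric("scanNumber", function(object) standardGeneric("scanNumber"))
#' @rdname spectrum-accessors
#' @export
setGeneric("peakCount", function(object) standardGeneric("peakCount"))
#' @rdname spectrum-accessors
#' @export
setGeneric("isSearchable", function(object) standardGeneric("isSearchable"))

#' @rdname spectrum-accessors
setMethod("peaksData", "Spectrum", function(object) {
  cbind(mz = object@mz, intensity = object@intensity)
})
#' @rdname spectrum-accessors
setMethod("precursorMz", "Spectrum", function(object) object@precursorMz)
#' @rdname spectrum-accessors
setMethod("spectrumId", "Spectrum", function(object) object@spectrumId)
#' @rdname spectrum-accessors
setMethod("scanNumber", "Spectrum", function(object) object@scan)
#' @rdname spectrum-accessors
setMethod("peakCount", "Spectrum", function(object) length(object@mz))
#' @rdname spectrum-accessors
setMethod("isSearchable", "Spectrum", function(object) {
  !is.na(object@precursorMz) && length(object@mz) >= 1L
})

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum", object@spectrumId, "\n",
      sprintf("  precursor m/z: %s  peaks: %d  scan: %s\n",
              format(object@precursorMz), length(object@mz),
              format(object@scan)))
})

setMethod("show", "Usi", function(object) {
  cat("USI:", serializeUsi(object), "\n")
})

setMethod("show", "SearchConfig", function(object) {
  cat("SearchConfig\n",
      sprintf("  precursor tol: %g Th  fragment tol: %g Th\n",
              object@precursorTol, object@fragmentTol),
      sprintf("  min cosine: %g  min matched ions: %d\n",
              object@minCosine, object@minMatchedIons),
      sprintf("  analogue: %s (max delta %g Th)  intensity transform: %s\n",
              object@analogue, object@analogueMaxDelta,
              object@intensityTransform))
})

setMethod("show", "SpectrumIndex", function(object) {
  cat(sprintf("SpectrumIndex with %d spectra (%d skipped as unsearchable)\n",
              object@nSpectra, object@nSkipped))
  if (object@nSpectra)
    cat(sprintf("  precursor m/z range: %.4f - %.4f\n",
                min(object@precursorMz), max(object@precursorMz)))
})

setMethod("show", "TaxonomyTree", function(object) {
  nd <- object@nodes
  cat(sprintf("TaxonomyTree: %d nodes (%d pseudo), %d files, %d matched\n",
              nrow(nd), sum(nd$isPseudo),
              nd$nFiles[nd$nodeId == 1L],
              nd$nMatched[nd$nodeId == 1L]))
})

setMethod("show", "SpectralRepository", function(object) {
  cat(sprintf("SpectralRepository: %d spectra in %d files, %d taxa nodes\n",
              length(object@spectra), nrow(object@metadata),
              sum(!object@tree@nodes$isPseudo)))
})

setMethod("show", "QueryJob", function(object) {
  cat(sprintf("QueryJob %s [%s]: %d matches\n", object@queryId,
              object@status, nrow(object@matches)))
})

#' Number of indexed spectra
#' @param x a [SpectrumIndex-class].
#' @return integer count of searchable spectra in the index.
#' @export
indexSize <- function(x) x@nSpectra

#' Extract the node table of a taxonomy tree
#' @param x a [TaxonomyTree-class].
#' @return the flat node data.frame.
#' @export
treeNodes <- function(x) x@nodes

#' Match table of a query job
#' @param x a [QueryJob-class].
#' @return the data.frame of accepted matches.
#' @export
jobMatches <- function(x) x@matches

#' Result tables of a query job
#' @param x a [QueryJob-class].
#' @return named list with `dataset_matches`, `taxa_matches`,
#'   `library_matches` data.frames.
#' @export
jobTables <- function(x) x@tables

#' Match-aggregated tree of a query job
#' @param x a [QueryJob-class].
#' @return the aggregated [TaxonomyTree-class].
#' @export
jobTree <- function(x) x@tree

#' Repository accessors
#' @param x a [SpectralRepository-class].
#' @return `repoIndex()` the [SpectrumIndex-class]; `repoTree()` the
#'   [TaxonomyTree-class]; `repoMetadata()` the metadata data.frame;
#'   `repoSpectra()` the list of reference spectra.
#' @name repository-accessors
NULL

#' @rdname repository-accessors
#' @export
repoIndex <- function(x) x@index
#' @rdname repository-accessors
#' @export
repoTree <- function(x) x@tree
#' @rdname repository-accessors
#' @export
repoMetadata <- function(x) x@metadata
#' @rdname repository-accessors
#' @export
repoSpectra <- function(x) x@spectra
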