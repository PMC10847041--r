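#' @import methods
NULL

#' Tandem mass spectrum
#'
#' In-memory model of one MS/MS spectrum: a precursor m/z plus an ordered
#' peak list. Peaks are stored as parallel `mz`/`intensity` vectors, sorted
#' strictly ascending in m/z; duplicate peaks closer than 1e-5 Th are merged
#' at construction (intensity sum at the intensity-weighted mean m/z) so that
#' no peak is double-counted during matching. Charge is carried but unused by
#' scoring, which operates purely in m/z space.
#'
#' A spectrum without a precursor m/z (`NA`) is representable but not
#' searchable; readers flag such spectra instead of dropping them.
#'
#' @slot spectrumId unique identifier (local id or USI string).
#' @slot precursorMz precursor m/z in Th, or `NA_real_` when unknown.
#' @slot charge precursor charge state, `NA_integer_` when unknown.
#' @slot mz numeric vector of fragment m/z values (Th), strictly ascending.
#' @slot intensity numeric vector of non-negative fragment intensities.
#' @slot sourceFile repository-relative file name the spectrum came from.
#' @slot datasetId dataset accession (e.g. a MassIVE-style id), or `NA`.
#' @slot scan scan number in the source file, `NA_integer_` when unknown.
#' @slot extra named character vector of additional header fields (e.g.
#'   library annotations), preserved verbatim.
#'
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    spectrumId = "character",
    precursorMz = "numeric",
    charge = "integer",
    mz = "numeric",
    intensity = "numeric",
    sourceFile = "character",
    datasetId = "character",
    scan = "integer",
    extra = "character"
  ),
  prototype(
    spectrumId = NA_character_, precursorMz = NA_real_,
    charge = NA_integer_, mz = numeric(), intensity = numeric(),
    sourceFile = NA_character_, datasetId = NA_character_,
    scan = NA_integer_, extra = character()
  )
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have the same length")
  if (any(object@mz <= 0))
    msg <- c(msg, "all peak m/z values must be positive")
  if (any(object@intensity < 0))
    msg <- c(msg, "peak intensities must be non-negative")
  if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
    msg <- c(msg, "peaks must be strictly ascending in m/z")
  if (!is.na(object@precursorMz) && object@precursorMz <= 0)
    msg <- c(msg, "precursorMz must be positive when present")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' Peaks are sorted by m/z and near-duplicates (within `mergeTol` Th) are
#' merged by intensity sum at the intensity-weighted mean m/z.
#'
#' @param spectrumId unique spectrum identifier.
#' @param precursorMz precursor m/z (Th); `NA` yields an unsearchable spectrum.
#' @param mz,intensity parallel numeric peak vectors.
#' @param charge optional precursor charge.
#' @param sourceFile,datasetId,scan provenance fields.
#' @param extra named character vector of extra header fields.
#' @param mergeTol m/z distance below which peaks are considered duplicates.
#' @return a [Spectrum-class] object.
#' @examples
#' s <- Spectrum("s1", 303.1, mz = c(150.1, 91.05), intensity = c(10, 55))
#' peaksData(s)
#' @export
Spectrum <- function(spectrumId, precursorMz = NA_real_, mz = numeric(),
                     intensity = numeric(), charge = NA_integer_,
                     sourceFile = NA_character_, datasetId = NA_character_,
                     scan = NA_integer_, extra = character(),
                     mergeTol = 1e-5) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (length(mz) > 1L) {
      grp <- cumsum(c(TRUE, diff(mz) > mergeTol))
      if (max(grp) < length(mz)) {
        w <- intensity
        # zero-intensity groups fall back to the plain mean m/z
        mzm <- vapply(split(seq_along(mz), grp), function(ii) {
          if (sum(w[ii]) > 0) sum(mz[ii] * w[ii]) / sum(w[ii]) else mean(mz[ii])
        }, numeric(1))
        intensity <- vapply(split(intensity, grp), sum, numeric(1))
        mz <- unname(mzm)
        intensity <- unname(intensity)
      }
    }
  }
  new("Spectrum", spectrumId = as.character(spectrumId),
      precursorMz = as.numeric(precursorMz), charge = as.integer(charge),
      mz = as.numeric(mz), intensity = as.numeric(intensity),
      sourceFile = as.character(sourceFile),
      datasetId = as.character(datasetId), scan = as.integer(scan),
      extra = extra)
}

#' Universal Spectrum Identifier
#'
#' Parsed form of a colon-delimited USI string such as
#' `mzspec:MSV000079949:some/file.mzML:scan:17`. Unknown trailing components
#' are preserved verbatim so that parsing and serialization round-trip.
#'
#' @slot collection USI preamble (normally `"mzspec"`).
#' @slot datasetId dataset accession.
#' @slot filePath path of the data file within the dataset.
#' @slot selectorType `"scan"` or `"index"`.
#' @slot selector non-negative integer scan/index value.
#' @slot extra trailing components beyond the selector, verbatim.
#' @exportClass Usi
setClass("Usi",
  representation(collection = "character", datasetId = "character",
                 filePath = "character", selectorType = "character",
                 selector = "integer", extra = "character"),
  prototype(collection = "mzspec", datasetId = NA_character_,
            filePath = NA_character_, selectorType = "scan",
            selector = NA_integer_, extra = character())
)

setValidity("Usi", function(object) {
  msg <- character()
  if (is.na(object@datasetId) || !nzchar(object@datasetId))
    msg <- c(msg, "datasetId must be non-empty")
  if (!object@selectorType %in% c("scan", "index"))
    msg <- c(msg, "selectorType must be 'scan' or 'index'")
  if (is.na(object@selector) || object@selector < 0L)
    msg <- c(msg, "selector must be a non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Search configuration
#'
#' Tolerances and thresholds controlling candidate retrieval and match
#' acceptance. Defaults follow common repository-search practice: precursor
#' and fragment tolerances of 0.05 Th, a minimum modified cosine of 0.7, at
#' least 3 matched fragment ions, analogue mode off. In analogue mode the
#' precursor window widens to `analogueMaxDelta` so related molecules whose
#' precursor differs by a modification mass can still match through shifted
#' fragments.
#'
#' @slot precursorTol precursor m/z tolerance (Th), exact mode.
#' @slot fragmentTol fragment m/z tolerance (Th).
#' @slot minCosine minimum modified cosine score in \[0, 1\].
#' @slot minMatchedIons minimum number of matched fragment ions.
#' @slot analogue logical; widen the precursor window for analogue search.
#' @slot analogueMaxDelta maximum |precursor delta| (Th) in analogue mode.
#' @slot intensityTransform `"sqrt"` (default) or `"none"`, applied before
#'   per-spectrum L2 normalization.
#' @exportClass SearchConfig
setClass("SearchConfig",
  representation(precursorTol = "numeric", fragmentTol = "numeric",
                 minCosine = "numeric", minMatchedIons = "integer",
                 analogue = "logical", analogueMaxDelta = "numeric",
                 intensityTransform = "character"),
  prototype(precursorTol = 0.05, fragmentTol = 0.05, minCosine = 0.7,
            minMatchedIons = 3L, analogue = FALSE, analogueMaxDelta = 130,
            intensityTransform = "sqrt")
)

setValidity("SearchConfig", function(object) {
  msg <- character()
  if (object@precursorTol <= 0) msg <- c(msg, "precursorTol must be > 0")
  if (object@fragmentTol <= 0) msg <- c(msg, "fragmentTol must be > 0")
  if (object@minCosine < 0 || object@minCosine > 1)
    msg <- c(msg, "minCosine must lie in [0, 1]")
  if (object@minMatchedIons < 1L) msg <- c(msg, "minMatchedIons must be >= 1")
  if (object@analogueMaxDelta <= 0) msg <- c(msg, "analogueMaxDelta must be > 0")
  if (!object@intensityTransform %in% c("sqrt", "none"))
    msg <- c(msg, "intensityTransform must be 'sqrt' or 'none'")
  if (length(msg)) msg else TRUE
})

#' @rdname SearchConfig-class
#' @param precursorTol,fragmentTol,minCosine,minMatchedIons,analogue,analogueMaxDelta,intensityTransform
#'   see the class slots.
#' @return a `SearchConfig` object.
#' @examples
#' searchConfig(analogue = TRUE)
#' @export
searchConfig <- function(precursorTol = 0.05, fragmentTol = 0.05,
                         minCosine = 0.7, minMatchedIons = 3L,
                         analogue = FALSE, analogueMaxDelta = 130,
                         intensityTransform = c("sqrt", "none")) {
  new("SearchConfig", precursorTol = precursorTol, fragmentTol = fragmentTol,
      minCosine = minCosine, minMatchedIons = as.integer(minMatchedIons),
      analogue = analogue, analogueMaxDelta = analogueMaxDelta,
      intensityTransform = match.arg(intensityTransform))
}

#' Precursor m/z index over reference spectra
#'
#' Entries are kept sorted ascending by precursor m/z so candidate retrieval
#' is a pair of binary searches. Spectra without a precursor or without peaks
#' are excluded at build time and reported in `nSkipped`.
#'
#' @slot precursorMz sorted numeric vector of indexed precursor m/z values.
#' @slot spectra list of [Spectrum-class] objects, parallel to `precursorMz`.
#' @slot nSpectra number of indexed (searchable) spectra.
#' @slot nSkipped number of unsearchable spectra excluded at build time.
#' @slot buildFingerprint digest of the indexed content, used to check that
#'   an index and a metadata table came from the same repository.
#' @exportClass SpectrumIndex
setClass("SpectrumIndex",
  representation(precursorMz = "numeric", spectra = "list",
                 nSpectra = "integer", nSkipped = "integer",
                 buildFingerprint = "character"),
  prototype(precursorMz = numeric(), spectra = list(), nSpectra = 0L,
            nSkipped = 0L, buildFingerprint = "")
)

setValidity("SpectrumIndex", function(object) {
  msg <- character()
  if (length(object@precursorMz) != length(object@spectra))
    msg <- c(msg, "precursorMz and spectra must be parallel")
  if (is.unsorted(object@precursorMz))
    msg <- c(msg, "index entries must be sorted by precursor m/z")
  if (object@nSpectra != length(object@spectra))
    msg <- c(msg, "nSpectra must equal the number of entries")
  if (length(msg)) msg else TRUE
})

#' Taxonomic tree with file and match counters
#'
#' Flat node table (parent-pointer form) of an NCBI-style taxonomy restricted
#' to the taxa present in a repository, plus a file-to-node assignment. Each
#' node carries the number of repository files attached at the node itself
#' (`nFilesOwn`) and subtree totals (`nFiles`, `nMatched`); the root counters
#' cover biological files only. Blank, QC and unclassified files live on
#' pseudo-children of the root with reserved negative ids (-1, -2, -3) so
#' they can never collide with NCBI ids and never inflate taxon counts.
#'
#' @slot nodes data.frame with columns `nodeId`, `parentId`, `name`, `rank`,
#'   `depth`, `isPseudo`, `nFilesOwn`, `nFiles`, `nMatchedOwn`, `nMatched`,
#'   `proportion`.
#' @slot fileNode named integer vector mapping `file_name` to the node the
#'   file is attached to.
#' @slot fileMeta data.frame with `file_name`, `is_blank`, `is_qc`.
#' @exportClass TaxonomyTree
setClass("TaxonomyTree",
  representation(nodes = "data.frame", fileNode = "integer",
                 fileMeta = "data.frame"),
  prototype(nodes = data.frame(), fileNode = integer(),
            fileMeta = data.frame())
)

#' Spectral repository handle
#'
#' Bundles everything a search needs: the reference spectra, the file-level
#' metadata, the lineage table, the precursor index and the taxonomy tree.
#' The index fingerprint ties index and metadata to the same build.
#'
#' @slot spectra list of reference [Spectrum-class] objects.
#' @slot metadata data.frame of validated metadata records.
#' @slot lineages data.frame lineage table (`ncbi_id`, `parent_ncbi_id`,
#'   `name`, `rank`).
#' @slot index a [SpectrumIndex-class].
#' @slot tree a [TaxonomyTree-class] with per-taxon file totals.
#' @slot fingerprint content digest shared with the index.
#' @exportClass SpectralRepository
setClass("SpectralRepository",
  representation(spectra = "list", metadata = "data.frame",
                 lineages = "data.frame", index = "SpectrumIndex",
                 tree = "TaxonomyTree", fingerprint = "character"))

#' Result of one repository query
#'
#' Holds the accepted matches (all of which pass the configured thresholds),
#' the match-aggregated taxonomy tree, and the three result tables
#' (dataset matches, taxa matches, library matches).
#'
#' @slot queryId query identifier.
#' @slot query the query [Spectrum-class].
#' @slot config the [SearchConfig-class] used.
#' @slot matches data.frame of accepted matches.
#' @slot tree match-aggregated [TaxonomyTree-class].
#' @slot tables named list of data.frames: `dataset_matches`, `taxa_matches`,
#'   `library_matches`.
#' @slot status `"ok"` or `"error"`.
#' @slot message error message when status is `"error"`.
#' @exportClass QueryJob
setClass("QueryJob",
  representation(queryId = "character", query = "Spectrum",
                 config = "SearchConfig", matches = "data.frame",
                 tree = "TaxonomyTree", tables = "list", status = "character",
                 message = "character"),
  prototype(status = "ok", message = ""))

#' Synthetic repository specification
#'
#' Parameters of the deterministic fixture generator. The seed fully
#' determines every generated artefact (spectra, metadata, lineages,
#' queries), so two runs with the same spec are identical.
#'
#' @slot seed integer RNG seed.
#' @slot nTaxa number of terminal microbial taxa.
#' @slot ranksDepth lineage depth (ranks from domain to species).
#' @slot filesPerTaxon integer range (min, max) of files per taxon.
#' @slot peaksPerSpectrum integer range (min, max) of peaks per spectrum.
#' @slot nBlanks,nQcs,nHostcell numbers of blank, QC and host-cell-line files.
#' @slot patternsPerTaxon characteristic producer patterns per taxon.
#' @slot noiseMzSd m/z jitter standard deviation (Th) applied to queries.
#' @slot noiseIntensityCv intensity coefficient of variation for queries.
#' @slot nPlantedAnalogues number of analogue-shifted query variants.
#' @slot analogueShift precursor/fragment shift (Th) of planted analogues.
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(seed = "integer", nTaxa = "integer", ranksDepth = "integer",
                 filesPerTaxon = "integer", peaksPerSpectrum = "integer",
                 nBlanks = "integer", nQcs = "integer", nHostcell = "integer",
                 patternsPerTaxon = "integer", noiseMzSd = "numeric",
                 noiseIntensityCv = "numeric", nPlantedAnalogues = "integer",
                 analogueShift = "numeric"),
  prototype(seed = 1L, nTaxa = 20L, ranksDepth = 7L,
            filesPerTaxon = c(1L, 3L), peaksPerSpectrum = c(8L, 40L),
            nBlanks = 2L, nQcs = 2L, nHostcell = 2L, patternsPerTaxon = 2L,
            noiseMzSd = 0.005, noiseIntensityCv = 0.1,
            nPlantedAnalogues = 0L, analogueShift = 42.0106))

setValidity("FixtureSpec", function(object) {
  msg <- character()
  if (object@nTaxa < 1L) msg <- c(msg, "nTaxa must be >= 1")
  if (length(object@filesPerTaxon) != 2L ||
      any(object@filesPerTaxon < 1L) || diff(object@filesPerTaxon) < 0L)
    msg <- c(msg, "filesPerTaxon must be an increasing (min, max) pair >= 1")
  if (length(object@peaksPerSpectrum) != 2L ||
      any(object@peaksPerSpectrum < 1L) || diff(object@peaksPerSpectrum) < 0L)
    msg <- c(msg, "peaksPerSpectrum must be an increasing (min, max) pair")
  if (any(c(object@nBlanks, object@nQcs, object@nHostcell,
            object@nPlantedAnalogues) < 0L))
    msg <- c(msg, "counts must be >= 0")
  if (object@noiseMzSd < 0 || object@noiseIntensityCv < 0)
    msg <- c(msg, "noise parameters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname FixtureSpec-class
#' @param seed,nTaxa,ranksDepth,filesPerTaxon,peaksPerSpectrum,nBlanks,nQcs,nHostcell,patternsPerTaxon,noiseMzSd,noiseIntensityCv,nPlantedAnalogues,analogueShift
#'   see the class slots.
#' @return a `FixtureSpec` object.
#' @export
fixtureSpec <- function(seed = 1L, nTaxa = 20L, ranksDepth = 7L,
                        filesPerTaxon = c(1L, 3L),
                        peaksPerSpectrum = c(8L, 40L), nBlanks = 2L,
                        nQcs = 2L, nHostcell = 2L, patternsPerTaxon = 2L,
                        noiseMzSd = 0.005, noiseIntensityCv = 0.1,
                        nPlantedAnalogues = 0L, analogueShift = 42.0106) {
  new("FixtureSpec", seed = as.integer(seed), nTaxa = as.integer(nTaxa),
      ranksDepth = as.integer(ranksDepth),
      filesPerTaxon = as.integer(filesPerTaxon),
      peaksPerSpectrum = as.integer(peaksPerSpectrum),
      nBlanks = as.integer(nBlanks), nQcs = as.integer(nQcs),
      nHostcell = as.integer(nHostcell),
      patternsPerTaxon = as.integer(patternsPerTaxon),
      noiseMzSd = noiseMzSd, noiseIntensityCv = noiseIntensityCv,
      nPlantedAnalogues = as.integer(nPlantedAnalogues),
      analogueShift = analogueShift)
}
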