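#' @include AllClasses.R
NULL

#' Assemble a spectral repository from in-memory parts
#'
#' Builds the precursor index and the taxonomy tree and stamps both with a
#' shared content fingerprint, so a search can verify that index and
#' metadata belong together. Reference spectra must carry `sourceFile` equal
#' to the metadata `file_name` they belong to.
#'
#' @param spectra list of reference [Spectrum-class] objects.
#' @param metadata metadata data.frame (see [loadMetadata()]).
#' @param lineages lineage data.frame (see [loadLineages()]).
#' @return a [SpectralRepository-class].
#' @export
spectralRepository <- function(spectra, metadata, lineages) {
  sf <- vapply(spectra, function(s) s@sourceFile, character(1))
  unknown <- setdiff(unique(sf[!is.na(sf)]), metadata$file_name)
  if (length(unknown))
    stop("spectra reference files absent from metadata: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  ix <- buildIndex(spectra)
  tree <- buildTaxTree(metadata, lineages)
  new("SpectralRepository", spectra = spectra, metadata = metadata,
      lineages = lineages, index = ix, tree = tree,
      fingerprint = ix@buildFingerprint)
}

#' Load a repository from a directory
#'
#' Expects `metadata.tsv` (or `.csv`), `lineages.tsv`, and one MGF file per
#' metadata record under `spectra/`, at the relative path given by the
#' record's `file_path` (falling back to `spectra/<file_name>.mgf`). The
#' spectra of each file are tagged with the record's `file_name` and
#' `dataset_id` so that matches can be traced back to their sample.
#'
#' @param dir repository root directory.
#' @return a [SpectralRepository-class].
#' @export
loadRepository <- function(dir) {
  metaPath <- file.path(dir, "metadata.tsv")
  if (!file.exists(metaPath)) metaPath <- file.path(dir, "metadata.csv")
  metadata <- loadMetadata(metaPath)
  lineages <- loadLineages(file.path(dir, "lineages.tsv"))
  spectra <- list()
  for (r in seq_len(nrow(metadata))) {
    rel <- metadata$file_path[r]
    if (is.na(rel) || !nzchar(rel))
      rel <- file.path("spectra", paste0(metadata$file_name[r], ".mgf"))
    p <- file.path(dir, rel)
    if (!file.exists(p))
      stop("spectrum file missing for metadata record '",
           metadata$file_name[r], "': ", p)
    sp <- readMgf(p)
    sp <- lapply(sp, function(s) {
      s@sourceFile <- metadata$file_name[r]
      s@datasetId <- metadata$dataset_id[r]
      s
    })
    spectra <- c(spectra, sp)
  }
  spectralRepository(spectra, metadata, lineages)
}
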