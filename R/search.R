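#' @include AllClasses.R
NULL

emptyMatches <- function() {
  data.frame(query_id = character(), reference_id = character(),
             cosine = numeric(), n_matched_ions = integer(),
             precursor_delta = numeric(), file_name = character(),
             stringsAsFactors = FALSE)
}

#' Search one query spectrum against a repository
#'
#' Candidate references are retrieved from the precursor index (exact or
#' analogue window per the config), scored with the modified cosine, and
#' thresholded inclusively on cosine and matched-ion count. The distinct
#' matched files are then aggregated onto the taxonomy tree with upstream
#' propagation, and the dataset/taxa/library result tables are assembled.
#' The whole pipeline is deterministic.
#'
#' @param query a searchable [Spectrum-class].
#' @param repository a [SpectralRepository-class].
#' @param cfg a [SearchConfig-class].
#' @param library optional annotated spectral library (list of
#'   [Spectrum-class]); see [libraryMatch()].
#' @return a [QueryJob-class].
#' @export
searchOne <- function(query, repository, cfg = searchConfig(),
                      library = NULL) {
  if (!isSearchable(query))
    stop("invalid query '", query@spectrumId,
         "': a precursor m/z and at least one peak are required")
  if (repository@index@buildFingerprint != repository@fingerprint)
    stop("repository index/metadata fingerprint mismatch; rebuild the index")
  cand <- candidateSpectra(repository@index, query@precursorMz, cfg)
  rows <- lapply(cand, function(ref) {
    m <- modifiedCosine(query, ref, cfg)
    if (passesThresholds(m, cfg)) {
      m$file_name <- ref@sourceFile
      m
    } else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  matches <- if (length(rows)) do.call(rbind, rows) else emptyMatches()
  tree <- aggregateMatches(repository@tree, unique(matches$file_name))
  job <- new("QueryJob", queryId = query@spectrumId, query = query,
             config = cfg, matches = matches, tree = tree,
             tables = list(), status = "ok", message = "")
  libTab <- if (is.null(library)) emptyLibraryTable() else
    libraryMatch(query, library, cfg)
  job@tables <- list(dataset_matches = datasetMatchesTable(job, repository),
                     taxa_matches = taxaMatchesTable(job),
                     library_matches = libTab)
  job
}

#' Batch search from an MGF file, a USI list, or spectra
#'
#' Accepts a `.mgf` path, a `.tsv`/`.txt` path with one USI per line (a
#' header line named `usi` is allowed; USIs are resolved against the
#' repository), or a list of [Spectrum-class] objects. Each query is
#' searched independently; per-query failures (e.g. a malformed USI or an
#' unsearchable spectrum) are recorded in the summary without aborting the
#' batch.
#'
#' @param input input path or list of spectra.
#' @param repository a [SpectralRepository-class].
#' @param cfg a [SearchConfig-class].
#' @param library optional annotated library, as in [searchOne()].
#' @return list with `jobs` (list of [QueryJob-class], successful queries
#'   only) and `summary` (one row per input: `query_id`, `status`,
#'   `n_matches`, `top_taxon`, `top_cosine`, `error`).
#' @export
searchBatch <- function(input, repository, cfg = searchConfig(),
                        library = NULL) {
  entries <- list()   # each: list(id=, spectrum=) or list(id=, error=)
  if (is.character(input) && length(input) == 1L) {
    if (!file.exists(input)) stop("batch input file not found: ", input)
    if (grepl("\\.mgf$", input, ignore.case = TRUE)) {
      sp <- readMgf(input)
      if (!length(sp)) warning("batch input contains no spectra")
      entries <- lapply(sp, function(s) list(id = s@spectrumId, spectrum = s))
    } else {
      lines <- trimws(readLines(input, warn = FALSE))
      lines <- lines[nzchar(lines)]
      if (length(lines) && tolower(lines[1]) %in% c("usi", "usis"))
        lines <- lines[-1]
      entries <- lapply(lines, function(u) {
        tryCatch(list(id = u, spectrum = resolveUsi(parseUsi(u), repository)),
                 error = function(e) list(id = u, error = conditionMessage(e)))
      })
    }
  } else if (is.list(input)) {
    entries <- lapply(input, function(s) list(id = s@spectrumId, spectrum = s))
  } else stop("unsupported batch input")
  jobs <- list()
  summ <- vector("list", length(entries))
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    if (!is.null(e$error)) {
      summ[[k]] <- data.frame(query_id = e$id, status = "error",
                              n_matches = NA_integer_,
                              top_taxon = NA_character_,
                              top_cosine = NA_real_, error = e$error,
                              stringsAsFactors = FALSE)
      next
    }
    job <- tryCatch(searchOne(e$spectrum, repository, cfg, library),
                    error = function(err)
                      new("QueryJob", queryId = e$id, query = e$spectrum,
                          config = cfg, matches = emptyMatches(),
                          tree = repository@tree, tables = list(),
                          status = "error",
                          message = conditionMessage(err)))
    if (job@status == "ok") {
      jobs[[length(jobs) + 1L]] <- job
      dt <- job@tables$dataset_matches
      topTaxon <- if (nrow(dt)) dt$taxon_name[1] else NA_character_
      summ[[k]] <- data.frame(query_id = job@queryId, status = "ok",
                              n_matches = nrow(job@matches),
                              top_taxon = topTaxon,
                              top_cosine = if (nrow(job@matches))
                                max(job@matches$cosine) else NA_real_,
                              error = NA_character_, stringsAsFactors = FALSE)
    } else {
      summ[[k]] <- data.frame(query_id = job@queryId, status = "error",
                              n_matches = NA_integer_,
                              top_taxon = NA_character_,
                              top_cosine = NA_real_, error = job@message,
                              stringsAsFactors = FALSE)
    }
  }
  summary <- if (length(summ)) do.call(rbind, summ) else
    data.frame(query_id = character(), status = character(),
               n_matches = integer(), top_taxon = character(),
               top_cosine = numeric(), error = character(),
               stringsAsFactors = FALSE)
  list(jobs = jobs, summary = summary)
}

emptyLibraryTable <- function() {
  data.frame(library_id = character(), compound_name = character(),
             cosine = numeric(), n_matched_ions = integer(),
             precursor_delta = numeric(), stringsAsFactors = FALSE)
}

#' Match a query against an annotated spectral library
#'
#' Same precursor windowing, scoring and thresholds as the repository
#' search. Rows carry the library spectrum's annotation (its
#' `COMPOUND_NAME`/`NAME` extra header when present, else the spectrum id).
#' Hits are candidate-level ("level 2"-style) annotations, not confirmed
#' identifications.
#'
#' @param query a searchable [Spectrum-class].
#' @param library list of annotated [Spectrum-class] objects (an empty
#'   library yields an empty table).
#' @param cfg a [SearchConfig-class].
#' @return data.frame `library_id`, `compound_name`, `cosine`,
#'   `n_matched_ions`, `precursor_delta`, sorted by cosine descending.
#' @export
libraryMatch <- function(query, library, cfg = searchConfig()) {
  if (!length(library)) return(emptyLibraryTable())
  ix <- buildIndex(library)
  cand <- candidateSpectra(ix, query@precursorMz, cfg)
  rows <- lapply(cand, function(ref) {
    m <- modifiedCosine(query, ref, cfg)
    if (!passesThresholds(m, cfg)) return(NULL)
    nm <- ref@spectrumId
    for (key in c("NAME", "COMPOUND_NAME"))
      if (key %in% names(ref@extra)) nm <- unname(ref@extra[[key]])
    data.frame(library_id = ref@spectrumId, compound_name = nm,
               cosine = m$cosine, n_matched_ions = m$n_matched_ions,
               precursor_delta = m$precursor_delta, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else emptyLibraryTable()
  out[order(-out$cosine, out$library_id), , drop = FALSE]
}

#' Dataset matches table
#'
#' One row per matching reference scan, annotated with the file's metadata
#' (taxon, NCBI id, rank, blank/QC flags), sorted by cosine descending with
#' ties broken by file name.
#'
#' @param job a [QueryJob-class].
#' @param repository the [SpectralRepository-class] the job was run against.
#' @return data.frame with `file_name`, `dataset_id`, `taxon_name`,
#'   `ncbi_id`, `rank`, `n_matched_ions`, `cosine`, `precursor_delta`,
#'   `is_blank`, `is_qc`.
#' @export
datasetMatchesTable <- function(job, repository) {
  m <- job@matches
  meta <- repository@metadata
  empty <- data.frame(file_name = character(), dataset_id = character(),
                      taxon_name = character(), ncbi_id = integer(),
                      rank = character(), n_matched_ions = integer(),
                      cosine = numeric(), precursor_delta = numeric(),
                      is_blank = logical(), is_qc = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(m)) return(empty)
  mi <- match(m$file_name, meta$file_name)
  nodeId <- repository@tree@fileNode[m$file_name]
  nodes <- repository@tree@nodes
  ni <- match(nodeId, nodes$nodeId)
  out <- data.frame(file_name = m$file_name,
                    dataset_id = meta$dataset_id[mi],
                    taxon_name = meta$taxon_name[mi],
                    ncbi_id = nodes$nodeId[ni], rank = nodes$rank[ni],
                    n_matched_ions = m$n_matched_ions, cosine = m$cosine,
                    precursor_delta = m$precursor_delta,
                    is_blank = meta$is_blank[mi], is_qc = meta$is_qc[mi],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$cosine, out$file_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Taxa matches table
#'
#' One row per taxon node with at least one matched file, consistent with
#' the aggregated tree's counters. Pseudo-nodes (blanks, QCs, unclassified)
#' and the root are not taxa and are excluded.
#'
#' @param job a [QueryJob-class].
#' @return data.frame `name`, `ncbi_id`, `rank`, `n_matched`, `n_files`,
#'   `proportion`, ordered by rank then name.
#' @export
taxaMatchesTable <- function(job) {
  nd <- job@tree@nodes
  nd <- nd[!nd$isPseudo & nd$nodeId != 1L & nd$nMatched > 0L, , drop = FALSE]
  nd <- nd[order(rankIndex(nd$rank), nd$name), , drop = FALSE]
  out <- data.frame(name = nd$name, ncbi_id = nd$nodeId, rank = nd$rank,
                    n_matched = nd$nMatched, n_files = nd$nFiles,
                    proportion = nd$proportion, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write the result tables of a job to TSV
#'
#' Writes `dataset_matches.tsv`, `taxa_matches.tsv`, `library_matches.tsv`
#' and the filtered tree (`tree.json`) under `dir`.
#'
#' @param job a [QueryJob-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeJobResults <- function(job, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(job@tables))
    utils::write.table(job@tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  exportTree(job@tree, file.path(dir, "tree.json"), "json")
  invisible(dir)
}
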