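#' @include AllClasses.R
NULL

#' Remove colonized-cohort spectra explained by the germ-free cohort
#'
#' Isolates candidate microbial spectra by comparing a colonized (e.g. SPF)
#' cohort against a germ-free cohort. Two filters apply in order: (1) a
#' presence filter removing colonized spectra whose ids also occur in the
#' germ-free cohort (shared features when the two cohorts were clustered
#' together), then (2) an edge filter removing any remaining colonized
#' spectrum that has at least one germ-free spectrum with cosine similarity
#' strictly greater than `edgeCosine` and an absolute precursor-mass delta
#' of at most `edgeDelta`. A pair sitting exactly at the cosine threshold is
#' therefore retained.
#'
#' @param colonized list of searchable [Spectrum-class] (colonized cohort).
#' @param germfree list of searchable [Spectrum-class] (germ-free cohort).
#' @param edgeCosine cosine threshold (strict `>`), default 0.7.
#' @param edgeDelta maximum |precursor delta| in Th, default 0.02.
#' @param fragmentTol fragment tolerance used for the pairwise cosine.
#' @param intensityTransform `"sqrt"` or `"none"`.
#' @return list with `retained` (list of spectra), `removed` (data.frame
#'   `spectrum_id`, `reason`, `partner_id`).
#' @export
subtractCohort <- function(colonized, germfree, edgeCosine = 0.7,
                           edgeDelta = 0.02, fragmentTol = 0.05,
                           intensityTransform = c("sqrt", "none")) {
  intensityTransform <- match.arg(intensityTransform)
  stopifnot(length(colonized) > 0, length(germfree) > 0)
  cfg <- searchConfig(fragmentTol = fragmentTol,
                      intensityTransform = intensityTransform)
  gfIds <- vapply(germfree, spectrumId, character(1))
  gfPrec <- vapply(germfree, precursorMz, numeric(1))
  removed <- list()
  retained <- list()
  for (s in colonized) {
    id <- s@spectrumId
    if (id %in% gfIds) {
      removed[[length(removed) + 1L]] <- data.frame(
        spectrum_id = id, reason = "shared_id", partner_id = id,
        stringsAsFactors = FALSE)
      next
    }
    near <- which(abs(gfPrec - s@precursorMz) <= edgeDelta)
    hit <- NA_character_
    for (g in near) {
      m <- modifiedCosine(s, germfree[[g]], cfg)
      if (m$cosine > edgeCosine) { hit <- gfIds[g]; break }
    }
    if (!is.na(hit)) {
      removed[[length(removed) + 1L]] <- data.frame(
        spectrum_id = id, reason = "gf_edge", partner_id = hit,
        stringsAsFactors = FALSE)
    } else {
      retained[[length(retained) + 1L]] <- s
    }
  }
  list(retained = retained,
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(spectrum_id = character(), reason = character(),
                    partner_id = character(), stringsAsFactors = FALSE))
}

# Producer domain of one repository file, derived from its lineage: host
# cell lines are recognized by a Homo sapiens / Metazoa lineage, bacteria by
# the Bacteria domain node, fungi by the Fungi kingdom node.
fileDomain <- function(repository, fileName) {
  node <- repository@tree@fileNode[[fileName]]
  if (is.na(node) || node < 0L) return("nonbiological")
  path <- lineagePath(repository@lineages, node)
  li <- match(path, repository@lineages$ncbi_id)
  nms <- repository@lineages$name[li]
  if (any(nms %in% c("Homo sapiens", "Metazoa"))) return("host_cell")
  if ("Bacteria" %in% nms) return("bacteria")
  if ("Fungi" %in% nms) return("fungi")
  "ambiguous"
}

#' Partition queries by the producer domain of their matches
#'
#' Each searched query is binned by the domains of the biological files it
#' matched: any host-cell-line match takes precedence (`host_cell`);
#' otherwise `bacteria_only`, `fungi_only` or `both` according to the
#' matched microbial domains, and `unmatched` when no biological file
#' matched. Files whose domain cannot be derived from the lineage are
#' counted in an `ambiguous` bin with a warning, never dropped. The bins are
#' disjoint and exhaustive over the input jobs.
#'
#' @param jobs list of [QueryJob-class] objects.
#' @param repository the [SpectralRepository-class] they were searched
#'   against.
#' @return data.frame, one row per job: `query_id`, `bin`,
#'   `n_bacteria_files`, `n_fungi_files`, `n_hostcell_files`.
#' @export
partitionByDomain <- function(jobs, repository) {
  rows <- lapply(jobs, function(job) {
    dt <- job@tables$dataset_matches
    bio <- dt[!dt$is_blank & !dt$is_qc, , drop = FALSE]
    files <- unique(bio$file_name)
    doms <- vapply(files, function(f) fileDomain(repository, f), character(1))
    nb <- sum(doms == "bacteria"); nf <- sum(doms == "fungi")
    nh <- sum(doms == "host_cell")
    if (any(doms == "ambiguous"))
      warning("query '", job@queryId,
              "' matched file(s) with underivable domain")
    bin <- if (!length(files)) "unmatched"
      else if (nh > 0L) "host_cell"
      else if (nb > 0L && nf > 0L) "both"
      else if (nb > 0L) "bacteria_only"
      else if (nf > 0L) "fungi_only"
      else "ambiguous"
    data.frame(query_id = job@queryId, bin = bin, n_bacteria_files = nb,
               n_fungi_files = nf, n_hostcell_files = nh,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
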