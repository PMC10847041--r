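#' @include AllClasses.R
NULL

metadataCanonical <- c("file_path", "file_name", "dataset_id", "taxon_name",
                       "alt_taxon_name", "ncbi_id", "id_assignment",
                       "redu_available", "is_blank", "is_qc")

# Accepted header synonyms (lower-cased) for the 10-column metadata schema.
metadataSynonyms <- list(
  file_path = c("file_path", "filepath", "full_path", "path"),
  file_name = c("file_name", "filename", "file"),
  dataset_id = c("dataset_id", "massive_id", "dataset", "accession"),
  taxon_name = c("taxon_name", "taxaname_file", "taxon", "taxa_name"),
  alt_taxon_name = c("alt_taxon_name", "alternative_taxon_name", "alt_name"),
  ncbi_id = c("ncbi_id", "taxa_ncbi", "ncbi", "taxid"),
  id_assignment = c("id_assignment", "ncbi_assignment", "assignment"),
  redu_available = c("redu_available", "redu", "in_redu"),
  is_blank = c("is_blank", "blank"),
  is_qc = c("is_qc", "qc", "qcmix")
)

asFlag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "yes", "y", "1")
}

#' Load and validate the repository metadata table
#'
#' Reads the 10-column file-to-taxon mapping (TSV or CSV, chosen by
#' extension) that assigns every repository data file a dataset accession,
#' taxon name, optional NCBI id, and blank/QC flags. Header names are matched
#' case-insensitively through a synonym map. Duplicated file names and
#' records flagged both blank and QC are errors; biological records without
#' an NCBI id are kept and later resolved by the closest-taxon fallback.
#'
#' @param path metadata file path (`.tsv`/`.txt` tab-delimited, `.csv`
#'   comma-delimited).
#' @return data.frame with the canonical columns (`file_path`, `file_name`,
#'   `dataset_id`, `taxon_name`, `alt_taxon_name`, `ncbi_id`,
#'   `id_assignment`, `redu_available`, `is_blank`, `is_qc`).
#' @export
loadMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character")
  hdr <- tolower(trimws(colnames(raw)))
  out <- data.frame(row.names = seq_len(nrow(raw)))
  missing <- character()
  for (canon in metadataCanonical) {
    hit <- which(hdr %in% metadataSynonyms[[canon]])
    if (length(hit)) {
      out[[canon]] <- raw[[hit[1]]]
    } else if (canon %in% c("alt_taxon_name", "id_assignment",
                            "redu_available", "file_path")) {
      out[[canon]] <- NA_character_   # optional columns
    } else {
      missing <- c(missing, canon)
    }
  }
  if (length(missing))
    stop("metadata schema error; missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  out$ncbi_id <- suppressWarnings(as.integer(out$ncbi_id))
  out$is_blank <- asFlag(out$is_blank)
  out$is_qc <- asFlag(out$is_qc)
  out$redu_available <- asFlag(out$redu_available)
  if (anyDuplicated(out$file_name))
    stop("duplicated file_name in metadata: ",
         paste(unique(out$file_name[duplicated(out$file_name)]),
               collapse = ", "))
  if (any(out$is_blank & out$is_qc))
    stop("records flagged as both blank and QC: ",
         paste(out$file_name[out$is_blank & out$is_qc], collapse = ", "))
  out
}

#' Load a lineage table
#'
#' Parent-pointer table of the taxonomy restricted to the repository's taxa:
#' one row per node with columns `ncbi_id`, `parent_ncbi_id`, `name`,
#' `rank`. A `parent_ncbi_id` of 1 (or NA) attaches the node directly under
#' the root.
#'
#' @param path tab-delimited lineage file.
#' @return validated data.frame.
#' @export
loadLineages <- function(path) {
  if (!file.exists(path)) stop("lineage file not found: ", path)
  lin <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  need <- c("ncbi_id", "parent_ncbi_id", "name", "rank")
  miss <- setdiff(need, colnames(lin))
  if (length(miss))
    stop("lineage schema error; missing column(s): ",
         paste(miss, collapse = ", "))
  lin$ncbi_id <- as.integer(lin$ncbi_id)
  lin$parent_ncbi_id <- as.integer(lin$parent_ncbi_id)
  if (anyDuplicated(lin$ncbi_id))
    stop("duplicated ncbi_id in lineage table")
  lin
}

# Walk the parent pointers from a node to the root (exclusive); returns the
# ncbi id path root-side first, ending at the node itself.
lineagePath <- function(lineages, ncbiId) {
  path <- integer()
  cur <- ncbiId
  byId <- match(cur, lineages$ncbi_id)
  steps <- 0L
  while (!is.na(byId)) {
    path <- c(cur, path)
    cur <- lineages$parent_ncbi_id[byId]
    if (is.na(cur) || cur == 1L) break
    byId <- match(cur, lineages$ncbi_id)
    steps <- steps + 1L
    if (steps > 100L) stop("lineage cycle detected at ncbi_id ", ncbiId)
  }
  path
}

# Resolve a metadata record to the node it attaches to. Order: ncbi_id if in
# the lineage table; else alt_taxon_name, then taxon_name, matched against
# lineage names (the closest-taxon rescue, mirroring curation of unknown
# strains to their species); else NA (-> unclassified pseudo-node).
resolveRecordNode <- function(rec, lineages) {
  if (!is.na(rec$ncbi_id) && rec$ncbi_id %in% lineages$ncbi_id)
    return(rec$ncbi_id)
  for (nm in c(rec$alt_taxon_name, rec$taxon_name)) {
    if (!is.na(nm) && nzchar(nm)) {
      hit <- match(nm, lineages$name)
      if (!is.na(hit)) return(lineages$ncbi_id[hit])
    }
  }
  NA_integer_
}

pseudoNodes <- function() {
  data.frame(nodeId = c(-1L, -2L, -3L), parentId = 1L,
             name = c("Blanks", "QCs", "Unclassified"),
             rank = "pseudo", depth = 1L, isPseudo = TRUE,
             stringsAsFactors = FALSE)
}

#' Build the taxonomic tree for a repository
#'
#' Constructs the taxonomy restricted to the lineages of the supplied
#' records. Every biological file contributes +1 to `nFiles` along its full
#' lineage; records whose NCBI id is absent from the lineage table are
#' rescued by name (alternative name first), and files that cannot be
#' resolved at all are routed to an "Unclassified" pseudo-node with a
#' warning. Blank and QC files attach to dedicated pseudo-children of the
#' root and are excluded from all taxon counters, including the root's.
#'
#' @param records metadata data.frame from [loadMetadata()].
#' @param lineages lineage data.frame from [loadLineages()].
#' @return a [TaxonomyTree-class] with file totals and zeroed match counters.
#' @export
buildTaxTree <- function(records, lineages) {
  lineages$ncbi_id <- as.integer(lineages$ncbi_id)
  lineages$parent_ncbi_id <- as.integer(lineages$parent_ncbi_id)
  records$ncbi_id <- as.integer(records$ncbi_id)
  nodes <- data.frame(nodeId = 1L, parentId = NA_integer_, name = "root",
                      rank = "root", depth = 0L, isPseudo = FALSE,
                      stringsAsFactors = FALSE)
  # materialize every lineage node reachable from an attached record
  fileNode <- integer(nrow(records))
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    if (rec$is_blank) { fileNode[r] <- -1L; next }
    if (rec$is_qc) { fileNode[r] <- -2L; next }
    target <- resolveRecordNode(rec, lineages)
    if (is.na(target)) {
      warning("no resolvable taxon for file '", rec$file_name,
              "'; routed to the Unclassified pseudo-node")
      fileNode[r] <- -3L
      next
    }
    fileNode[r] <- target
    path <- lineagePath(lineages, target)
    newIds <- setdiff(path, nodes$nodeId)
    if (length(newIds)) {
      li <- match(newIds, lineages$ncbi_id)
      parent <- lineages$parent_ncbi_id[li]
      parent[is.na(parent)] <- 1L
      nodes <- rbind(nodes, data.frame(
        nodeId = newIds, parentId = parent, name = lineages$name[li],
        rank = lineages$rank[li], depth = 0L, isPseudo = FALSE,
        stringsAsFactors = FALSE))
    }
  }
  names(fileNode) <- records$file_name
  nodes <- rbind(nodes, pseudoNodes())
  # depths from parent chain
  depth <- setNames(rep(NA_integer_, nrow(nodes)), nodes$nodeId)
  depth["1"] <- 0L
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    progressed <- FALSE
    for (k in todo) {
      pd <- depth[as.character(nodes$parentId[k])]
      if (!is.na(pd)) { depth[k] <- pd + 1L; progressed <- TRUE }
    }
    if (!progressed) stop("disconnected lineage nodes: ",
                          paste(nodes$nodeId[todo], collapse = ", "))
  }
  nodes$depth <- unname(depth)
  # canonical order: depth, then rank position, then name
  nodes <- nodes[order(nodes$depth, rankIndex(nodes$rank), nodes$name,
                       nodes$nodeId), ]
  rownames(nodes) <- NULL
  nodes$nFilesOwn <- 0L
  tb <- table(fileNode)
  hit <- match(as.integer(names(tb)), nodes$nodeId)
  nodes$nFilesOwn[hit] <- as.integer(tb)
  nodes$nMatchedOwn <- 0L
  nodes <- subtreeTotals(nodes)
  fileMeta <- data.frame(file_name = records$file_name,
                         is_blank = records$is_blank, is_qc = records$is_qc,
                         stringsAsFactors = FALSE)
  new("TaxonomyTree", nodes = nodes, fileNode = fileNode,
      fileMeta = fileMeta)
}

# Subtree sums for nFiles/nMatched from the own-attachment counters. Pseudo
# nodes keep their own counts and never feed taxon (or root) totals.
subtreeTotals <- function(nodes) {
  nodes$nFiles <- nodes$nFilesOwn
  nodes$nMatched <- nodes$nMatchedOwn
  o <- order(nodes$depth, decreasing = TRUE)
  for (k in o) {
    p <- nodes$parentId[k]
    if (is.na(p) || nodes$isPseudo[k]) next
    pi <- match(p, nodes$nodeId)
    nodes$nFiles[pi] <- nodes$nFiles[pi] + nodes$nFiles[k]
    nodes$nMatched[pi] <- nodes$nMatched[pi] + nodes$nMatched[k]
  }
  nodes$proportion <- ifelse(nodes$nFiles > 0,
                             nodes$nMatched / nodes$nFiles, NA_real_)
  nodes
}

#' Aggregate matched files onto the taxonomy tree
#'
#' Recomputes match counters from zero for the given set of matched file
#' names (so the operation is idempotent): each matched biological file
#' contributes +1 to `nMatched` along its full lineage up to the root, while
#' matched blank/QC files count only on their pseudo-nodes. Proportions are
#' recomputed as `nMatched / nFiles`.
#'
#' @param tree a [TaxonomyTree-class].
#' @param matchedFiles character vector of matched `file_name`s (any
#'   duplicates count once: counters are per distinct file).
#' @return the updated [TaxonomyTree-class].
#' @export
aggregateMatches <- function(tree, matchedFiles) {
  matchedFiles <- unique(matchedFiles)
  unknown <- setdiff(matchedFiles, names(tree@fileNode))
  if (length(unknown))
    stop("matched file(s) not present in metadata: ",
         paste(unknown, collapse = ", "))
  nodes <- tree@nodes
  nodes$nMatchedOwn <- 0L
  if (length(matchedFiles)) {
    targets <- tree@fileNode[matchedFiles]
    tb <- table(targets)
    hit <- match(as.integer(names(tb)), nodes$nodeId)
    nodes$nMatchedOwn[hit] <- as.integer(tb)
  }
  nodes <- subtreeTotals(nodes)
  new("TaxonomyTree", nodes = nodes, fileNode = tree@fileNode,
      fileMeta = tree@fileMeta)
}

#' Filter a taxonomy tree by rank and match count
#'
#' `maxRank` collapses everything below the given rank: nodes whose rank is
#' deeper than `maxRank` are removed, and because counters are subtree
#' totals the surviving ancestor keeps the collapsed subtree's counts.
#' `minMatches` prunes nodes with fewer matched files, except ancestors of
#' retained nodes (so the tree stays connected) and the root. File
#' assignments are remapped to the deepest surviving ancestor so the
#' filtered tree can still be re-aggregated.
#'
#' @param tree a [TaxonomyTree-class].
#' @param maxRank optional rank name (e.g. `"genus"`); see `taxRanks` in the
#'   package source for the recognized ladder.
#' @param minMatches non-negative integer.
#' @return the filtered [TaxonomyTree-class].
#' @export
filterTree <- function(tree, maxRank = NULL, minMatches = 0L) {
  nodes <- tree@nodes
  keep <- rep(TRUE, nrow(nodes))
  if (!is.null(maxRank)) {
    ri <- rankIndex(maxRank)
    if (is.na(ri))
      stop("unknown rank '", maxRank, "'; valid ranks: ",
           paste(setdiff(taxRanks(), "root"), collapse = ", "))
    nodeRank <- rankIndex(nodes$rank)
    # nodes of unknown rank are kept (their depth relative to maxRank is
    # judged by their deepest ranked ancestor having survived)
    keep <- keep & (nodes$isPseudo | is.na(nodeRank) | nodeRank <= ri)
  }
  if (minMatches > 0L) {
    retain <- nodes$nMatched >= minMatches
    # ancestors of retained nodes survive
    anc <- rep(FALSE, nrow(nodes))
    for (k in which(retain & keep)) {
      p <- nodes$parentId[k]
      while (!is.na(p)) {
        pi <- match(p, nodes$nodeId)
        if (anc[pi]) break
        anc[pi] <- TRUE
        p <- nodes$parentId[pi]
      }
    }
    keep <- keep & (retain | anc)
  }
  keep[nodes$nodeId == 1L] <- TRUE
  # drop nodes whose parent is dropped (rank collapse keeps chains intact by
  # construction; this guards pathological rank orderings)
  repeat {
    orphan <- !is.na(nodes$parentId) & keep &
      !nodes$parentId %in% nodes$nodeId[keep]
    if (!any(orphan)) break
    keep[orphan] <- FALSE
  }
  kept <- nodes[keep, , drop = FALSE]
  rownames(kept) <- NULL
  # remap file attachments to the deepest surviving ancestor
  fileNode <- tree@fileNode
  for (i in seq_along(fileNode)) {
    cur <- fileNode[i]
    while (!cur %in% kept$nodeId) {
      pi <- match(cur, nodes$nodeId)
      cur <- nodes$parentId[pi]
      if (is.na(cur)) { cur <- 1L; break }
    }
    fileNode[i] <- cur
  }
  new("TaxonomyTree", nodes = kept, fileNode = fileNode,
      fileMeta = tree@fileMeta)
}

treeAsNestedList <- function(tree, nodeId = 1L) {
  nodes <- tree@nodes
  k <- match(nodeId, nodes$nodeId)
  ch <- nodes[!is.na(nodes$parentId) & nodes$parentId == nodeId, ,
              drop = FALSE]
  ch <- ch[order(rankIndex(ch$rank), ch$name, ch$nodeId), , drop = FALSE]
  out <- list(ncbi_id = nodes$nodeId[k], name = nodes$name[k],
              rank = nodes$rank[k], n_files = nodes$nFiles[k],
              n_matched = nodes$nMatched[k],
              proportion = nodes$proportion[k])
  if (nrow(ch))
    out$children <- lapply(ch$nodeId, function(id) treeAsNestedList(tree, id))
  out
}

sanitizeNewickLabel <- function(x) {
  gsub("[()\\[\\],:;'\"]", "_", gsub(" ", "_", x))
}

treeAsNewick <- function(tree, nodeId = 1L) {
  nodes <- tree@nodes
  k <- match(nodeId, nodes$nodeId)
  ch <- nodes[!is.na(nodes$parentId) & nodes$parentId == nodeId, ,
              drop = FALSE]
  ch <- ch[order(rankIndex(ch$rank), ch$name, ch$nodeId), , drop = FALSE]
  label <- paste0(sanitizeNewickLabel(nodes$name[k]), "|", nodes$nodeId[k],
                  sprintf("[&rank=%s,n_files=%d,n_matched=%d]",
                          sanitizeNewickLabel(nodes$rank[k]),
                          nodes$nFiles[k], nodes$nMatched[k]))
  if (!nrow(ch)) return(label)
  paste0("(", paste(vapply(ch$nodeId, function(id) treeAsNewick(tree, id),
                           character(1)), collapse = ","), ")", label)
}

treeAsHtmlList <- function(tree, nodeId = 1L) {
  nodes <- tree@nodes
  k <- match(nodeId, nodes$nodeId)
  ch <- nodes[!is.na(nodes$parentId) & nodes$parentId == nodeId, ,
              drop = FALSE]
  ch <- ch[order(rankIndex(ch$rank), ch$name, ch$nodeId), , drop = FALSE]
  lab <- sprintf("%s <span class=\"rank\">%s</span> <span class=\"counts\">%d/%d</span>",
                 nodes$name[k], nodes$rank[k], nodes$nMatched[k],
                 nodes$nFiles[k])
  if (!nrow(ch)) return(sprintf("<li>%s</li>", lab))
  inner <- paste(vapply(ch$nodeId, function(id) treeAsHtmlList(tree, id),
                        character(1)), collapse = "\n")
  sprintf("<li><details open><summary>%s</summary><ul>\n%s\n</ul></details></li>",
          lab, inner)
}

#' Export a taxonomy tree
#'
#' `json`: nested hierarchy with `ncbi_id`, `name`, `rank`, `n_files`,
#' `n_matched`, `proportion` and `children` per node. `newick`: topology
#' with labels `name|ncbi_id` and the counters in comment blocks. `html`:
#' a static, self-contained page rendering the tree as collapsible lists
#' (no external assets) and embedding the JSON.
#'
#' @param tree a [TaxonomyTree-class].
#' @param path output file path.
#' @param format `"json"`, `"newick"` or `"html"`.
#' @return `path`, invisibly.
#' @export
exportTree <- function(tree, path, format = c("json", "newick", "html")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(treeAsNestedList(tree), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  } else if (format == "newick") {
    writeLines(paste0(treeAsNewick(tree), ";"), path)
  } else {
    json <- jsonlite::toJSON(treeAsNestedList(tree), auto_unbox = TRUE,
                             digits = NA, null = "null", na = "null")
    html <- c(
      "<!DOCTYPE html>",
      "<html><head><meta charset=\"utf-8\"><title>Taxonomic matches</title>",
      "<style>body{font-family:sans-serif}ul{list-style:none;border-left:1px solid #ccc;margin-left:.4em;padding-left:1em}.rank{color:#888;font-size:smaller}.counts{color:#06c}</style>",
      "</head><body>",
      "<h1>Taxonomic match tree</h1>",
      "<ul>", treeAsHtmlList(tree), "</ul>",
      sprintf("<script type=\"application/json\" id=\"tree-data\">%s</script>",
              json),
      "</body></html>")
    writeLines(html, path)
  }
  invisible(path)
}

#' Read back a JSON tree export
#'
#' Parses the nested JSON written by [exportTree()] into a flat data.frame
#' of nodes (one row per node, with a `depth` column). Used for round-trip
#' verification and downstream processing of exported results.
#'
#' @param path JSON file written by `exportTree(..., format = "json")`.
#' @return data.frame with `ncbi_id`, `name`, `rank`, `n_files`,
#'   `n_matched`, `proportion`, `depth`.
#' @export
readTreeJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- list()
  walk <- function(node, depth) {
    rows[[length(rows) + 1L]] <<- data.frame(
      ncbi_id = as.integer(node$ncbi_id), name = node$name,
      rank = node$rank, n_files = as.integer(node$n_files),
      n_matched = as.integer(node$n_matched),
      proportion = if (is.null(node$proportion)) NA_real_ else
        as.numeric(node$proportion),
      depth = depth, stringsAsFactors = FALSE)
    for (ch in node$children) walk(ch, depth + 1L)
  }
  walk(x, 0L)
  do.call(rbind, rows)
}
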