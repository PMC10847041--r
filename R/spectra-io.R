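#' @include AllClasses.R
NULL

#' Read spectra from a Mascot Generic Format file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. Header keys are treated
#' case-insensitively; the precursor m/z is the first numeric token of the
#' `PEPMASS` field (a second token, if present, is the precursor intensity
#' and is ignored). Peaks are sorted ascending by m/z and near-duplicate
#' peaks are merged. Spectra without a precursor are returned with
#' `precursorMz = NA` (unsearchable) rather than silently dropped.
#'
#' @param path path to an existing `.mgf` file.
#' @return list of [Spectrum-class] objects, in file order.
#' @examples
#' f <- tempfile(fileext = ".mgf")
#' writeMgf(list(Spectrum("a", 303.1, c(100, 150), c(1, 2))), f)
#' readMgf(f)
#' @export
readMgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (!length(lines) || !any(nzchar(lines))) {
    warning("empty MGF file: ", path)
    return(list())
  }
  begins <- which(toupper(lines) == "BEGIN IONS")
  ends <- which(toupper(lines) == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF (unbalanced BEGIN IONS/END IONS) in ", path)
  out <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    body <- lines[seq(begins[k] + 1L, ends[k] - 1L)]
    body <- body[nzchar(body) & !startsWith(body, "#")]
    isHeader <- grepl("=", body, fixed = TRUE)
    headers <- body[isHeader]
    keys <- toupper(sub("=.*$", "", headers))
    vals <- sub("^[^=]*=", "", headers)
    names(vals) <- keys
    peakLines <- body[!isHeader]
    nPk <- length(peakLines)
    mz <- numeric(nPk); int <- numeric(nPk)
    if (nPk) {
      toks <- strsplit(peakLines, "[ \t]+")
      for (i in seq_len(nPk)) {
        v <- suppressWarnings(as.numeric(toks[[i]][1:2]))
        if (anyNA(v))
          stop(sprintf("malformed peak line in block %d (near line %d) of %s: '%s'",
                       k, begins[k] + which(!isHeader)[i], path, peakLines[i]))
        mz[i] <- v[1]; int[i] <- v[2]
      }
    }
    prec <- NA_real_
    if ("PEPMASS" %in% keys) {
      tok <- strsplit(trimws(vals[["PEPMASS"]]), "[ \t]+")[[1]][1]
      prec <- suppressWarnings(as.numeric(tok))
      if (is.na(prec))
        stop(sprintf("malformed PEPMASS in block %d of %s: '%s'",
                     k, path, vals[["PEPMASS"]]))
    }
    scan <- NA_integer_
    if ("SCANS" %in% keys)
      scan <- suppressWarnings(as.integer(strsplit(vals[["SCANS"]], "-")[[1]][1]))
    charge <- NA_integer_
    if ("CHARGE" %in% keys)
      charge <- suppressWarnings(as.integer(gsub("[+-]", "", vals[["CHARGE"]])))
    id <- if ("TITLE" %in% keys) vals[["TITLE"]] else
      sprintf("%s#%d", basename(path), k)
    known <- c("PEPMASS", "SCANS", "CHARGE", "TITLE")
    extra <- vals[!keys %in% known]
    out[[k]] <- Spectrum(spectrumId = id, precursorMz = prec, mz = mz,
                         intensity = int, charge = charge,
                         sourceFile = path, scan = scan,
                         extra = extra)
  }
  out
}

#' Write spectra to a Mascot Generic Format file
#'
#' The spectrum id is written to `TITLE`, the precursor to `PEPMASS`, and the
#' scan number to `SCANS` when present; extra header fields are written
#' verbatim. Every spectrum must carry a precursor m/z.
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMgf <- function(spectra, path) {
  hasPrec <- vapply(spectra, function(s) !is.na(s@precursorMz), logical(1))
  if (!all(hasPrec))
    stop("cannot write spectra without a precursor m/z: ",
         paste(vapply(spectra[!hasPrec], spectrumId, character(1)),
               collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    lines <- c("BEGIN IONS",
               paste0("TITLE=", s@spectrumId),
               sprintf("PEPMASS=%.6f", s@precursorMz))
    if (!is.na(s@charge)) lines <- c(lines, sprintf("CHARGE=%d+", s@charge))
    if (!is.na(s@scan)) lines <- c(lines, sprintf("SCANS=%d", s@scan))
    if (length(s@extra))
      lines <- c(lines, paste0(names(s@extra), "=", s@extra))
    if (length(s@mz))
      lines <- c(lines, sprintf("%.6f %.6f", s@mz, s@intensity))
    lines <- c(lines, "END IONS", "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Parse a Universal Spectrum Identifier
#'
#' Accepts the colon-delimited form
#' `collection:dataset:filePath:selectorType:selector[:extra...]`, e.g.
#' `mzspec:MSV000079949:some/file.mzML:scan:17`. Components after the
#' selector are preserved verbatim and re-emitted by [serializeUsi()].
#'
#' @param text a single USI string.
#' @return a [Usi-class] object.
#' @examples
#' parseUsi("mzspec:MSV000079949:some/file.mzML:scan:17")
#' @export
parseUsi <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) < 5L)
    stop("malformed USI (expected at least 5 colon-delimited fields): '",
         text, "'")
  selType <- parts[4]
  if (!selType %in% c("scan", "index"))
    stop("malformed USI: unknown selector type '", selType, "' in '", text, "'")
  sel <- suppressWarnings(as.integer(parts[5]))
  if (is.na(sel) || as.character(sel) != parts[5])
    stop("malformed USI: non-integer selector '", parts[5], "' in '", text, "'")
  new("Usi", collection = parts[1], datasetId = parts[2], filePath = parts[3],
      selectorType = selType, selector = sel,
      extra = if (length(parts) > 5L) parts[6:length(parts)] else character())
}

#' Serialize a Usi back to its string form
#'
#' Inverse of [parseUsi()]: `serializeUsi(parseUsi(x)) == x` for every valid
#' USI string.
#'
#' @param usi a [Usi-class] object.
#' @return the colon-delimited USI string.
#' @export
serializeUsi <- function(usi) {
  paste(c(usi@collection, usi@datasetId, usi@filePath, usi@selectorType,
          as.character(usi@selector), usi@extra), collapse = ":")
}

#' Resolve a USI against a local repository
#'
#' Looks the spectrum up by dataset accession, file path and exact scan
#' number. Failures state which level did not resolve.
#'
#' @param usi a [Usi-class] or USI string.
#' @param repository a [SpectralRepository-class].
#' @return the matching [Spectrum-class].
#' @export
resolveUsi <- function(usi, repository) {
  if (is.character(usi)) usi <- parseUsi(usi)
  spectra <- repository@spectra
  ds <- vapply(spectra, function(s) s@datasetId, character(1))
  inDs <- which(!is.na(ds) & ds == usi@datasetId)
  if (!length(inDs))
    stop("USI dataset not found in repository: '", usi@datasetId, "'")
  # file paths are matched on the repository-relative name or its basename
  sf <- vapply(spectra[inDs], function(s) s@sourceFile, character(1))
  hit <- inDs[sf == usi@filePath | basename(sf) == basename(usi@filePath)]
  if (!length(hit))
    stop("USI file not found in dataset '", usi@datasetId, "': '",
         usi@filePath, "'")
  scans <- vapply(spectra[hit], function(s) s@scan, integer(1))
  sel <- hit[!is.na(scans) & scans == usi@selector]
  if (!length(sel))
    stop("USI scan ", usi@selector, " not found in file '", usi@filePath,
         "' of dataset '", usi@datasetId, "'")
  spectra[[sel[1]]]
}
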