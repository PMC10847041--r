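# Internal helpers shared across modules.

# FNV-1a over a character scalar; cheap content fingerprint, not cryptographic.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    # xor affects only the low byte (b < 256); keep h a double throughout
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit multiply by the FNV prime, split to stay within double precision
    lo16 <- h %% 65536
    hi16 <- (h - lo16) / 65536
    h <- (((hi16 * 16777619) %% 65536) * 65536 + lo16 * 16777619) %% 4294967296
  }
  lo16 <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo16) / 65536), as.integer(lo16))
}

contentFingerprint <- function(spectra) {
  if (!length(spectra)) return("empty")
  ids <- vapply(spectra, function(s) s@spectrumId, character(1))
  prec <- vapply(spectra, function(s) s@precursorMz, numeric(1))
  fnv1a(paste(c(ids, sprintf("%.6f", prec)), collapse = "|"))
}

# Ordered taxonomic ranks from root to terminal; "domain" is accepted as a
# synonym of "superkingdom".
taxRanks <- function() {
  c("root", "superkingdom", "kingdom", "phylum", "class", "order", "family",
    "genus", "subgenus", "species", "subspecies", "varietas", "strain")
}

rankIndex <- function(rank) {
  rank <- ifelse(rank == "domain", "superkingdom", rank)
  match(rank, taxRanks())
}

#' Percentage growth implied by newly deposited files
#'
#' Given the size of a corpus after a deposition drive and the number of files
#' added by the drive, returns the percentage increase relative to the
#' pre-deposition corpus: `100 * newFiles / (totalFiles - newFiles)`.
#'
#' @param newFiles number of newly deposited files.
#' @param totalFiles corpus size including the new files.
#' @return percentage increase (numeric scalar).
#' @examples
#' depositionIncreasePct(3142, 60781)
#' @export
depositionIncreasePct <- function(newFiles, totalFiles) {
  stopifnot(newFiles >= 0, totalFiles > newFiles)
  100 * newFiles / (totalFiles - newFiles)
}
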