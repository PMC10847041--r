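#' @include AllClasses.R
NULL

# Build a rank ladder assignment: species index -> named lineage levels.
# Group sizes halve per rank so the tree branches realistically.
ladderCounts <- function(nSpecies) {
  nGenus <- max(1L, ceiling(nSpecies / 2))
  nFamily <- max(1L, ceiling(nGenus / 2))
  nOrder <- max(1L, ceiling(nFamily / 2))
  nClass <- max(1L, ceiling(nOrder / 2))
  nPhylum <- max(1L, min(8L, ceiling(nClass / 2)))
  c(phylum = nPhylum, class = nClass, order = nOrder, family = nFamily,
    genus = nGenus)
}

# Deterministic taxonomy block for one domain group; returns lineage rows
# and, per species, its terminal ncbi id and genus name.
makeTaxonomyBlock <- function(prefix, nSpecies, rootId, rootRows, idStart) {
  cnt <- ladderCounts(nSpecies)
  ranks <- names(cnt)
  nextId <- idStart
  rows <- rootRows
  ids <- list()
  for (rk in ranks) {
    n <- cnt[[rk]]
    ids[[rk]] <- seq(nextId, length.out = n)
    nextId <- nextId + n
  }
  parentRank <- c(phylum = NA, class = "phylum", order = "class",
                  family = "order", genus = "family")
  for (rk in ranks) {
    n <- cnt[[rk]]
    for (g in seq_len(n)) {
      parent <- if (is.na(parentRank[[rk]])) rootId else
        ids[[parentRank[[rk]]]][((g - 1L) %% cnt[[parentRank[[rk]]]]) + 1L]
      rows <- rbind(rows, data.frame(
        ncbi_id = ids[[rk]][g], parent_ncbi_id = parent,
        name = sprintf("%s_%s_%02d", prefix, rk, g), rank = rk,
        stringsAsFactors = FALSE))
    }
  }
  speciesIds <- seq(nextId, length.out = nSpecies)
  species <- data.frame(
    ncbi_id = speciesIds,
    parent_ncbi_id = ids$genus[((seq_len(nSpecies) - 1L) %% cnt[["genus"]]) + 1L],
    name = sprintf("%s_species_%02d", prefix, seq_len(nSpecies)),
    rank = "species", stringsAsFactors = FALSE)
  rows <- rbind(rows, species)
  genusName <- rows$name[match(species$parent_ncbi_id, rows$ncbi_id)]
  list(lineage = rows, species = cbind(species, genus_name = genusName),
       nextId = nextId + nSpecies)
}

# sample() treats a scalar as 1:x; draw from the vector itself instead
resample <- function(x, ...) x[sample.int(length(x), ...)]

samplePattern <- function(grid, peaksRange, patternId) {
  n <- resample(seq(peaksRange[1], peaksRange[2]), 1L)
  list(id = patternId,
       precursor = round(stats::runif(1, 150, 1200), 2),
       mz = sort(sample(grid, n)),
       intensity = stats::rlnorm(n, meanlog = log(100), sdlog = 1))
}

patternSpectrum <- function(pat, id, sourceFile, datasetId, scan) {
  Spectrum(spectrumId = id, precursorMz = pat$precursor, mz = pat$mz,
           intensity = pat$intensity, sourceFile = sourceFile,
           datasetId = datasetId, scan = scan)
}

#' Generate a miniature synthetic spectral repository
#'
#' Deterministically (the spec's seed fully determines the output) builds a
#' toy repository emulating a curated collection of microbial monoculture
#' runs: a taxonomy (bacteria plus fungi, with ladders phylum to species,
#' and Homo sapiens for host cell lines), per-taxon characteristic
#' "producer" fragment patterns (peaks on a 0.01 Th grid in 80-1500 Th,
#' log-normal intensities), data files carrying those patterns, blank and
#' QC files carrying shared contaminant patterns, and host-cell files
#' carrying host patterns plus one pattern shared with a bacterium (to
#' exercise host-match precedence). One species record is emitted without
#' an NCBI id (name-resolvable) to exercise the closest-taxon fallback.
#'
#' @param spec a [FixtureSpec-class].
#' @param dir optional directory; when given, the repository is written to
#'   disk (`metadata.tsv`, `lineages.tsv`, `manifest.tsv`, one MGF per
#'   file under `spectra/`) in a form [loadRepository()] reads back.
#' @return list with `repository` ([SpectralRepository-class]), `metadata`,
#'   `lineages`, `manifest` (one row per reference spectrum with its true
#'   producer), `patterns` (the generating patterns), and `spec`.
#' @examples
#' fix <- makeRepository(fixtureSpec(seed = 7, nTaxa = 5, nHostcell = 0))
#' nrow(fix$metadata)
#' @export
makeRepository <- function(spec, dir = NULL) {
  withr::with_seed(spec@seed, {
    grid <- seq(80, 1500, by = 0.01)
    nFungi <- if (spec@nTaxa >= 5L) max(1L, floor(0.2 * spec@nTaxa)) else 0L
    nBact <- spec@nTaxa - nFungi
    lineage <- data.frame(ncbi_id = integer(), parent_ncbi_id = integer(),
                          name = character(), rank = character(),
                          stringsAsFactors = FALSE)
    bactRoot <- data.frame(ncbi_id = 2L, parent_ncbi_id = 1L,
                           name = "Bacteria", rank = "superkingdom",
                           stringsAsFactors = FALSE)
    bact <- makeTaxonomyBlock("Bact", nBact, 2L, bactRoot, 10000L)
    lineage <- rbind(lineage, bact$lineage)
    speciesTab <- bact$species
    speciesTab$domain <- "bacteria"
    if (nFungi > 0L) {
      eukRows <- data.frame(
        ncbi_id = c(2759L, 4751L), parent_ncbi_id = c(1L, 2759L),
        name = c("Eukaryota", "Fungi"),
        rank = c("superkingdom", "kingdom"), stringsAsFactors = FALSE)
      fung <- makeTaxonomyBlock("Fung", nFungi, 4751L, eukRows, bact$nextId)
      lineage <- rbind(lineage, fung$lineage)
      fs <- fung$species
      fs$domain <- "fungi"
      speciesTab <- rbind(speciesTab, fs)
    }
    if (spec@nHostcell > 0L) {
      hostRows <- data.frame(
        ncbi_id = c(2759L, 33208L, 9606L),
        parent_ncbi_id = c(1L, 2759L, 33208L),
        name = c("Eukaryota", "Metazoa", "Homo sapiens"),
        rank = c("superkingdom", "kingdom", "species"),
        stringsAsFactors = FALSE)
      lineage <- rbind(lineage, hostRows)
      lineage <- lineage[!duplicated(lineage$ncbi_id), ]
    }
    # producer patterns per species
    patterns <- list()
    for (i in seq_len(nrow(speciesTab)))
      for (p in seq_len(spec@patternsPerTaxon)) {
        pid <- sprintf("P_%s_%d", speciesTab$name[i], p)
        patterns[[pid]] <- samplePattern(grid, spec@peaksPerSpectrum, pid)
      }
    contam <- list()
    for (p in 1:3) {
      pid <- sprintf("P_contaminant_%d", p)
      contam[[pid]] <- samplePattern(grid, spec@peaksPerSpectrum, pid)
    }
    hostPats <- list()
    if (spec@nHostcell > 0L) {
      for (p in 1:3) {
        pid <- sprintf("P_host_%d", p)
        hostPats[[pid]] <- samplePattern(grid, spec@peaksPerSpectrum, pid)
      }
      # one pattern shared between host cells and the first bacterium
      shared <- patterns[[sprintf("P_%s_1", speciesTab$name[1])]]
      shared$id <- "P_host_shared"
      hostPats[["P_host_shared"]] <- shared
    }
    nDatasets <- max(2L, ceiling(spec@nTaxa / 10))
    datasets <- sprintf("MSV%06d", 100000L + seq_len(nDatasets))
    meta <- list(); manifest <- list(); spectra <- list()
    addFile <- function(fileBase, datasetId, taxonName, altName, ncbi,
                        idAssign, isBlank, isQc, pats, kinds, speciesName,
                        genusName, domain, trueNcbi = ncbi) {
      rawName <- paste0(fileBase, ".mzML")
      fileName <- paste0(datasetId, "/", rawName)
      relPath <- file.path("spectra", datasetId, paste0(fileBase, ".mgf"))
      meta[[length(meta) + 1L]] <<- data.frame(
        file_path = relPath, file_name = fileName, dataset_id = datasetId,
        taxon_name = taxonName, alt_taxon_name = altName, ncbi_id = ncbi,
        id_assignment = idAssign, redu_available = TRUE,
        is_blank = isBlank, is_qc = isQc, stringsAsFactors = FALSE)
      for (k in seq_along(pats)) {
        pat <- pats[[k]]
        sid <- sprintf("mzspec:%s:%s:scan:%d", datasetId, rawName, k)
        spectra[[length(spectra) + 1L]] <<- patternSpectrum(
          pat, sid, fileName, datasetId, k)
        manifest[[length(manifest) + 1L]] <<- data.frame(
          spectrum_id = sid, file_name = fileName, dataset_id = datasetId,
          scan = k, kind = kinds[k], pattern_id = pat$id,
          ncbi_id = if (is.na(trueNcbi)) NA_integer_ else trueNcbi,
          species_name = speciesName, genus_name = genusName,
          domain = domain, stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(speciesTab))) {
      sp <- speciesTab[i, ]
      ds <- datasets[((i - 1L) %% nDatasets) + 1L]
      nFiles <- resample(seq(spec@filesPerTaxon[1], spec@filesPerTaxon[2]), 1L)
      pats <- patterns[sprintf("P_%s_%d", sp$name,
                               seq_len(spec@patternsPerTaxon))]
      kinds <- rep("producer", length(pats))
      for (f in seq_len(nFiles)) {
        # species 1 exercises the closest-taxon name fallback: its metadata
        # carries no NCBI id, only a resolvable alternative taxon name
        noId <- (i == 1L)
        addFile(sprintf("%s_r%02d", sp$name, f), ds, sp$name,
                if (noId) sp$name else NA_character_,
                if (noId) NA_integer_ else sp$ncbi_id,
                if (noId) "curated" else "automatic", FALSE, FALSE,
                pats, kinds, sp$name, sp$genus_name, sp$domain,
                trueNcbi = sp$ncbi_id)
      }
    }
    for (b in seq_len(spec@nBlanks))
      addFile(sprintf("blank_%02d", b), datasets[1], "media blank",
              NA_character_, NA_integer_, "automatic", TRUE, FALSE,
              contam, rep("contaminant", length(contam)),
              NA_character_, NA_character_, "none")
    for (q in seq_len(spec@nQcs))
      addFile(sprintf("qc_%02d", q), datasets[1], "QC mix",
              NA_character_, NA_integer_, "automatic", FALSE, TRUE,
              contam, rep("contaminant", length(contam)),
              NA_character_, NA_character_, "none")
    if (spec@nHostcell > 0L) {
      hk <- c(rep("host", 3), "host_shared")
      for (h in seq_len(spec@nHostcell))
        addFile(sprintf("hostcell_%02d", h), datasets[nDatasets],
                "Homo sapiens cell line", "Homo sapiens", 9606L,
                "curated", FALSE, FALSE, hostPats, hk,
                "Homo sapiens", NA_character_, "host_cell")
    }
    metadata <- do.call(rbind, meta)
    manifest <- do.call(rbind, manifest)
    repo <- spectralRepository(spectra, metadata, lineage)
    fix <- list(repository = repo, metadata = metadata, lineages = lineage,
                manifest = manifest,
                patterns = c(patterns, contam, hostPats), spec = spec)
    if (!is.null(dir)) writeFixtureRepository(fix, dir)
    fix
  })
}

writeFixtureRepository <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(fix$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fix$lineages, file.path(dir, "lineages.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fix$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  byFile <- split(seq_along(fix$repository@spectra),
                  vapply(fix$repository@spectra,
                         function(s) s@sourceFile, character(1)))
  for (fn in names(byFile)) {
    rel <- fix$metadata$file_path[match(fn, fix$metadata$file_name)]
    p <- file.path(dir, rel)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    writeMgf(fix$repository@spectra[byFile[[fn]]], p)
  }
  invisible(dir)
}

noisyCopy <- function(s, id, mzSd, intCv) {
  mz <- s@mz + stats::rnorm(length(s@mz), 0, mzSd)
  int <- s@intensity * exp(stats::rnorm(length(s@mz), 0, intCv))
  Spectrum(spectrumId = id,
           precursorMz = s@precursorMz + stats::rnorm(1, 0, mzSd),
           mz = mz, intensity = int)
}

#' Generate query spectra with known ground truth
#'
#' Positive queries are noisy copies of producer reference spectra (m/z
#' jitter and intensity variation per the fixture spec); negative controls
#' carry random peaks and precursors placed far beyond every reference
#' precursor, so they cannot retrieve candidates at the default tolerance;
#' analogue variants shift the precursor and a random half of the fragments
#' of a producer spectrum by `analogueShift`, choosing base spectra whose
#' shifted precursor is at least 0.2 Th from every reference precursor (so
#' they only match in analogue mode).
#'
#' @param fix fixture list from [makeRepository()].
#' @param nPositives,nNegatives query counts.
#' @param seed RNG seed for the query draw (defaults to the fixture seed
#'   plus 1000).
#' @return list with `spectra` (list of query [Spectrum-class]) and `truth`
#'   (data.frame `query_id`, `kind`, `true_spectrum`, `true_file`,
#'   `true_ncbi`, `true_species`, `true_genus`).
#' @export
makeQueries <- function(fix, nPositives = 50L, nNegatives = 10L,
                        seed = fix$spec@seed + 1000L) {
  spec <- fix$spec
  man <- fix$manifest
  refIds <- vapply(fix$repository@spectra, spectrumId, character(1))
  refPrec <- vapply(fix$repository@spectra, precursorMz, numeric(1))
  withr::with_seed(seed, {
    producers <- which(man$kind == "producer")
    spectra <- list(); truth <- list()
    pick <- sample(producers, nPositives, replace = TRUE)
    for (k in seq_len(nPositives)) {
      row <- man[pick[k], ]
      ref <- fix$repository@spectra[[match(row$spectrum_id, refIds)]]
      qid <- sprintf("q_pos_%03d", k)
      spectra[[qid]] <- noisyCopy(ref, qid, spec@noiseMzSd,
                                  spec@noiseIntensityCv)
      truth[[qid]] <- data.frame(
        query_id = qid, kind = "positive", true_spectrum = row$spectrum_id,
        true_file = row$file_name, true_ncbi = row$ncbi_id,
        true_species = row$species_name, true_genus = row$genus_name,
        stringsAsFactors = FALSE)
    }
    negBase <- max(refPrec) + 50
    for (k in seq_len(nNegatives)) {
      qid <- sprintf("q_neg_%03d", k)
      n <- 10L
      spectra[[qid]] <- Spectrum(qid, precursorMz = negBase + 10 * k,
                                 mz = sort(stats::runif(n, 80, 1500)),
                                 intensity = stats::rlnorm(n, log(100), 1))
      truth[[qid]] <- data.frame(
        query_id = qid, kind = "negative", true_spectrum = NA_character_,
        true_file = NA_character_, true_ncbi = NA_integer_,
        true_species = NA_character_, true_genus = NA_character_,
        stringsAsFactors = FALSE)
    }
    if (spec@nPlantedAnalogues > 0L) {
      shift <- spec@analogueShift
      clear <- producers[vapply(producers, function(p) {
        pr <- refPrec[match(man$spectrum_id[p], refIds)]
        min(abs(refPrec - (pr + shift))) > 0.2
      }, logical(1))]
      picks <- sample(clear, min(spec@nPlantedAnalogues, length(clear)))
      for (k in seq_along(picks)) {
        row <- man[picks[k], ]
        ref <- fix$repository@spectra[[match(row$spectrum_id, refIds)]]
        qid <- sprintf("q_ana_%03d", k)
        mz <- ref@mz
        shifted <- sample(length(mz), ceiling(length(mz) / 2))
        mz[shifted] <- mz[shifted] + shift
        spectra[[qid]] <- Spectrum(qid, precursorMz = ref@precursorMz + shift,
                                   mz = mz, intensity = ref@intensity)
        truth[[qid]] <- data.frame(
          query_id = qid, kind = "analogue", true_spectrum = row$spectrum_id,
          true_file = row$file_name, true_ncbi = row$ncbi_id,
          true_species = row$species_name, true_genus = row$genus_name,
          stringsAsFactors = FALSE)
      }
    }
    list(spectra = spectra, truth = do.call(rbind, truth))
  })
}

#' Generate a colonized/germ-free cohort pair with known ground truth
#'
#' Emulates the input of the cohort spectral-subtraction workflow: the
#' germ-free cohort carries host-derived spectra; the colonized cohort
#' carries (a) a subset of the same spectra under the same feature ids
#' (removed by the presence filter), (b) noisy germ-free variants under new
#' ids within the edge thresholds (removed by the edge filter), and (c)
#' private microbial spectra with precursors far from every germ-free
#' precursor (the ground-truth retained set).
#'
#' @param nGermfree,nShared,nNearDup,nPrivate cohort composition.
#' @param seed RNG seed.
#' @return list with `colonized`, `germfree` (lists of [Spectrum-class])
#'   and `truthRetained` (character ids of the private spectra).
#' @export
makeCohorts <- function(nGermfree = 4L, nShared = 2L, nNearDup = 1L,
                        nPrivate = 5L, seed = 1L) {
  stopifnot(nShared <= nGermfree, nNearDup <= nGermfree)
  withr::with_seed(seed, {
    grid <- seq(80, 1500, by = 0.01)
    gf <- lapply(seq_len(nGermfree), function(k) {
      pat <- samplePattern(grid, c(8L, 20L), sprintf("gf_%d", k))
      patternSpectrum(pat, sprintf("gf_%03d", k), NA_character_,
                      NA_character_, k)
    })
    colonized <- list()
    for (k in seq_len(nShared))       # same feature id as in germ-free
      colonized[[length(colonized) + 1L]] <- gf[[k]]
    for (k in seq_len(nNearDup)) {
      base <- gf[[nGermfree - k + 1L]]
      nd <- noisyCopy(base, sprintf("spf_dup_%03d", k), 0.002, 0.05)
      nd@precursorMz <- base@precursorMz + 0.01
      colonized[[length(colonized) + 1L]] <- nd
    }
    gfMax <- max(vapply(gf, precursorMz, numeric(1)))
    private <- lapply(seq_len(nPrivate), function(k) {
      pat <- samplePattern(grid, c(8L, 20L), sprintf("priv_%d", k))
      pat$precursor <- gfMax + 10 + k
      patternSpectrum(pat, sprintf("spf_priv_%03d", k), NA_character_,
                      NA_character_, k)
    })
    colonized <- c(colonized, private)
    list(colonized = colonized, germfree = gf,
         truthRetained = vapply(private, spectrumId, character(1)))
  })
}
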