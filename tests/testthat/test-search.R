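test_that("a copied reference spectrum self-matches at cosine 1", {
  fix <- sharedFixture()
  repo <- fix$repository
  ref <- repoSpectra(repo)[[1]]
  q <- Spectrum("copy", precursorMz(ref), ref@mz, ref@intensity)
  job <- searchOne(q, repo)
  m <- jobMatches(job)
  self <- m[m$reference_id == spectrumId(ref), ]
  expect_gte(nrow(self), 1)
  expect_equal(self$cosine[1], 1, tolerance = 1e-9)
  # tree matched counts equal distinct matched biological files
  nd <- treeNodes(jobTree(job))
  bioFiles <- unique(m$file_name[!m$file_name %in%
    fix$metadata$file_name[fix$metadata$is_blank | fix$metadata$is_qc]])
  expect_equal(nd$nMatched[nd$nodeId == 1L], length(bioFiles))
})

test_that("queries far from all reference precursors match nothing", {
  fix <- sharedFixture()
  q <- Spectrum("far", 5000, c(100, 200, 300), c(1, 1, 1))
  job <- searchOne(q, fix$repository)
  expect_equal(nrow(jobMatches(job)), 0)
  expect_true(all(treeNodes(jobTree(job))$nMatched == 0L))
  expect_equal(nrow(jobTables(job)$taxa_matches), 0)
  bad <- Spectrum("nopeaks", 500, numeric(), numeric())
  expect_error(searchOne(bad, fix$repository), "invalid query")
})

test_that("planted analogues match only in analogue mode", {
  fix <- sharedFixture()
  qs <- makeQueries(fix, nPositives = 1, nNegatives = 0)
  ana <- qs$spectra[startsWith(names(qs$spectra), "q_ana")]
  expect_gte(length(ana), 1)
  for (q in ana) {
    off <- searchOne(q, fix$repository, searchConfig())
    expect_equal(nrow(jobMatches(off)), 0)
    on <- searchOne(q, fix$repository, searchConfig(analogue = TRUE))
    expect_gte(nrow(jobMatches(on)), 1)
  }
})

test_that("result tables reconcile with the match set and the tree", {
  fix <- sharedFixture()
  qs <- makeQueries(fix, nPositives = 8, nNegatives = 0)
  for (q in qs$spectra) {
    job <- searchOne(q, fix$repository)
    m <- jobMatches(job)
    dt <- jobTables(job)$dataset_matches
    tt <- jobTables(job)$taxa_matches
    expect_equal(nrow(dt), nrow(m))          # one row per matching scan
    expect_false(is.unsorted(rev(dt$cosine)))  # cosine descending
    nd <- treeNodes(jobTree(job))
    # every taxa-table row equals its tree node
    mm <- match(tt$ncbi_id, nd$nodeId)
    expect_equal(tt$n_matched, nd$nMatched[mm])
    expect_equal(tt$n_files, nd$nFiles[mm])
    distinctBio <- length(unique(dt$file_name[!dt$is_blank & !dt$is_qc]))
    expect_equal(nd$nMatched[nd$nodeId == 1L], distinctBio)
  }
})

test_that("tightening thresholds shrinks the match set monotonically", {
  fix <- sharedFixture()
  qs <- makeQueries(fix, nPositives = 10, nNegatives = 2)
  cfgs <- list(loose = searchConfig(minCosine = 0.6, minMatchedIons = 2L),
               mid = searchConfig(minCosine = 0.7, minMatchedIons = 3L),
               tight = searchConfig(minCosine = 0.8, minMatchedIons = 4L))
  keys <- lapply(cfgs, function(cfg) {
    out <- character()
    for (q in qs$spectra) {
      m <- jobMatches(searchOne(q, fix$repository, cfg))
      if (nrow(m)) out <- c(out, paste(m$query_id, m$reference_id))
    }
    out
  })
  expect_true(all(keys$tight %in% keys$mid))
  expect_true(all(keys$mid %in% keys$loose))
})

test_that("batch search handles MGF input, USI lists and malformed rows", {
  fix <- sharedFixture()
  repo <- fix$repository
  qs <- makeQueries(fix, nPositives = 3, nNegatives = 0)
  pos <- qs$spectra[startsWith(names(qs$spectra), "q_pos")]
  mgf <- tempfile(fileext = ".mgf")
  writeMgf(pos, mgf)
  res <- searchBatch(mgf, repo)
  expect_length(res$jobs, 3)
  expect_true(all(res$summary$status == "ok"))
  expect_true(all(res$summary$n_matches >= 1))
  # batch of size 1 is identical to the single search
  one <- searchBatch(list(pos[[1]]), repo)
  single <- searchOne(pos[[1]], repo)
  expect_identical(jobMatches(one$jobs[[1]]), jobMatches(single))
  expect_identical(jobTables(one$jobs[[1]]), jobTables(single))
  # USI list with one malformed row: two jobs plus one error row
  ids <- vapply(repoSpectra(repo)[1:2], spectrumId, character(1))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("usi", ids, "mzspec:only:two"), tsv)
  res2 <- searchBatch(tsv, repo)
  expect_length(res2$jobs, 2)
  expect_equal(sum(res2$summary$status == "error"), 1)
  # empty MGF: empty summary with a warning, no failure
  empty <- tempfile(fileext = ".mgf")
  writeLines("", empty)
  expect_warning(expect_warning(res3 <- searchBatch(empty, repo),
                                "empty MGF"), "no spectra")
  expect_equal(nrow(res3$summary), 0)
})

test_that("library matching annotates and orders candidate hits", {
  q <- Spectrum("q", 301.1, c(100, 150, 200, 250), c(5, 9, 2, 7))
  lib1 <- Spectrum("LIB0001", 301.1, q@mz, q@intensity,
                   extra = c(COMPOUND_NAME = "compound X"))
  near <- q@intensity * c(1.3, 0.8, 1.1, 1)
  lib2 <- Spectrum("LIB0002", 301.12, q@mz, near,
                   extra = c(COMPOUND_NAME = "compound X analogue"))
  tab <- libraryMatch(q, list(lib2, lib1), searchConfig())
  expect_equal(nrow(tab), 2)
  expect_equal(tab$compound_name[1], "compound X")
  expect_equal(tab$cosine[1], 1, tolerance = 1e-9)
  expect_false(is.unsorted(rev(tab$cosine)))
  expect_equal(nrow(libraryMatch(q, list(), searchConfig())), 0)
})
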