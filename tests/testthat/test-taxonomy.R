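# Small hand-built metadata/lineage fixtures for direct tree checks.
miniLineages <- function() {
  data.frame(
    ncbi_id =        c(2L, 201L, 202L, 203L, 204L, 301L),
    parent_ncbi_id = c(1L,   2L, 201L, 202L, 202L,   2L),
    name = c("Bacteria", "Phy1", "GenA", "SpA1", "SpA2", "Phy2"),
    rank = c("superkingdom", "phylum", "genus", "species", "species",
             "phylum"),
    stringsAsFactors = FALSE)
}

miniMetadata <- function() {
  data.frame(
    file_path = NA_character_,
    file_name = c("D1/a1.mzML", "D1/a2.mzML", "D1/b.mzML", "D1/blank.mzML",
                  "D1/qc.mzML", "D1/odd.mzML"),
    dataset_id = "D1",
    taxon_name = c("SpA1", "SpA1", "SpA2", "blank", "qc", "SpA2 strain X"),
    alt_taxon_name = c(NA, NA, NA, NA, NA, "SpA2"),
    ncbi_id = c(203L, 203L, 204L, NA, NA, NA),
    id_assignment = "automatic", redu_available = TRUE,
    is_blank = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    is_qc = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

test_that("metadata loading validates schema, flags and duplicates", {
  md <- miniMetadata()
  f <- tempfile(fileext = ".tsv")
  write.table(md, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- loadMetadata(f)
  expect_equal(nrow(got), 6)
  expect_equal(sum(got$is_blank), 1)
  expect_equal(sum(got$is_qc), 1)
  # duplicated file_name rejected
  bad <- rbind(md, md[1, ])
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadMetadata(f), "duplicated file_name")
  # missing mandatory column named in the error
  f2 <- tempfile(fileext = ".tsv")
  write.table(md[, setdiff(colnames(md), "taxon_name")], f2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(loadMetadata(f2), "taxon_name")
})

test_that("tree build conserves counts, attaches pseudo files, rescues names", {
  tree <- buildTaxTree(miniMetadata(), miniLineages())
  nd <- treeNodes(tree)
  # two files of SpA1 count at the species and every ancestor
  expect_equal(nd$nFiles[nd$nodeId == 203L], 2L)
  expect_equal(nd$nFiles[nd$nodeId == 202L], 4L)  # GenA: SpA1 x2 + SpA2 x2
  expect_equal(nd$nFiles[nd$nodeId == 2L], 4L)
  expect_equal(nd$nFiles[nd$nodeId == 1L], 4L)    # root = biological only
  # blank/QC pseudo children carry one file each
  expect_equal(nd$nFiles[nd$nodeId == -1L], 1L)
  expect_equal(nd$nFiles[nd$nodeId == -2L], 1L)
  # the strain without an NCBI id lands on its species via the alt name
  expect_equal(unname(tree@fileNode[["D1/odd.mzML"]]), 204L)
  expectConserved(tree)
})

test_that("unresolvable records route to the Unclassified pseudo-node", {
  md <- miniMetadata()[1, ]
  md$ncbi_id <- NA_integer_
  md$taxon_name <- "never heard of it"
  md$alt_taxon_name <- NA_character_
  expect_warning(tree <- buildTaxTree(md, miniLineages()), "Unclassified")
  expect_equal(treeNodes(tree)$nFiles[treeNodes(tree)$nodeId == -3L], 1L)
  expect_equal(treeNodes(tree)$nFiles[treeNodes(tree)$nodeId == 1L], 0L)
})

test_that("match aggregation propagates upstream and is idempotent", {
  tree <- buildTaxTree(miniMetadata(), miniLineages())
  agg <- aggregateMatches(tree, c("D1/a1.mzML"))
  nd <- treeNodes(agg)
  for (id in c(203L, 202L, 201L, 2L, 1L))
    expect_equal(nd$nMatched[nd$nodeId == id], 1L)
  expect_equal(nd$nMatched[nd$nodeId == 204L], 0L)
  # blank matches count only on the pseudo-node, never at the root
  aggB <- aggregateMatches(tree, c("D1/blank.mzML"))
  ndB <- treeNodes(aggB)
  expect_equal(ndB$nMatched[ndB$nodeId == -1L], 1L)
  expect_equal(ndB$nMatched[ndB$nodeId == 1L], 0L)
  # recomputed from zero each call
  again <- aggregateMatches(aggB, c("D1/a1.mzML"))
  expect_equal(treeNodes(again)$nMatched, nd$nMatched)
  # empty matched set zeroes everything
  none <- aggregateMatches(agg, character())
  expect_true(all(treeNodes(none)$nMatched == 0L))
  expect_error(aggregateMatches(tree, "no/such.mzML"), "no/such.mzML")
})

test_that("conservation holds for random matched subsets on a 40-taxon tree", {
  fix <- makeRepository(fixtureSpec(seed = 3L, nTaxa = 40L))
  tree <- repoTree(fix$repository)
  bio <- fix$metadata$file_name[!fix$metadata$is_blank & !fix$metadata$is_qc]
  all <- fix$metadata$file_name
  withr::with_seed(31, {
    for (rep in 1:30) {
      picked <- sample(all, sample(0:length(all), 1))
      agg <- aggregateMatches(tree, picked)
      expectConserved(agg)
      nd <- treeNodes(agg)
      expect_equal(nd$nMatched[nd$nodeId == 1L],
                   length(intersect(picked, bio)))
    }
  })
})

test_that("rank collapse preserves counts and min-match pruning keeps lineages", {
  tree <- buildTaxTree(miniMetadata(), miniLineages())
  agg <- aggregateMatches(tree, c("D1/a1.mzML", "D1/b.mzML"))
  gen <- filterTree(agg, maxRank = "genus")
  nd <- treeNodes(gen)
  expect_false(any(nd$rank == "species"))
  expect_equal(nd$nFiles[nd$nodeId == 202L], 4L)   # genus counts unchanged
  expect_equal(nd$nMatched[nd$nodeId == 202L], 2L)
  # min-match pruning: only the matched lineage plus root survives
  one <- aggregateMatches(tree, "D1/a1.mzML")
  pruned <- filterTree(one, minMatches = 1L)
  expect_setequal(treeNodes(pruned)$nodeId, c(1L, 2L, 201L, 202L, 203L))
  # pruning never changes counters of surviving nodes
  before <- treeNodes(one)
  after <- treeNodes(pruned)
  m <- match(after$nodeId, before$nodeId)
  expect_equal(after$nMatched, before$nMatched[m])
  expect_equal(after$nFiles, before$nFiles[m])
  expect_error(filterTree(tree, maxRank = "tribe"), "valid ranks")
})

test_that("tree exports round-trip counts (JSON) and leaf counts (Newick)", {
  tree <- buildTaxTree(miniMetadata(), miniLineages())
  agg <- aggregateMatches(tree, c("D1/a1.mzML", "D1/qc.mzML"))
  jf <- tempfile(fileext = ".json")
  exportTree(agg, jf, "json")
  flat <- readTreeJson(jf)
  nd <- treeNodes(agg)
  m <- match(flat$ncbi_id, nd$nodeId)
  expect_false(anyNA(m))
  expect_equal(flat$n_files, nd$nFiles[m])
  expect_equal(flat$n_matched, nd$nMatched[m])
  expect_equal(nrow(flat), nrow(nd))
  # newick leaves = terminal taxon nodes + pseudo-nodes
  nf <- tempfile(fileext = ".nwk")
  exportTree(agg, nf, "newick")
  nwk <- gsub("\\[[^]]*\\]", "", readLines(nf))  # strip comment blocks
  leaves <- lengths(regmatches(nwk, gregexpr("[(,][^(,)]+", nwk)))
  isParent <- nd$nodeId %in% nd$parentId
  expect_equal(sum(!isParent), leaves)
  # html is self-contained and embeds the JSON payload
  hf <- tempfile(fileext = ".html")
  exportTree(agg, hf, "html")
  html <- paste(readLines(hf), collapse = "\n")
  expect_match(html, "tree-data")
  expect_match(html, "<details")
  expect_error(exportTree(agg, tempfile(), "svg"))
})
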