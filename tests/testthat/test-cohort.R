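test_that("the 5-vs-1 toy removes exactly the one in-threshold spectrum", {
  toy <- toyCohorts()
  res <- subtractCohort(toy$colonized, toy$germfree)
  ids <- vapply(res$retained, spectrumId, character(1))
  expect_setequal(ids, c("s1", "s2", "s4", "s5"))
  expect_equal(res$removed$spectrum_id, "s3")
  expect_equal(res$removed$reason, "gf_edge")
})

test_that("a pair exactly at the cosine threshold is retained (strict >)", {
  toy <- toyCohorts()
  s1 <- toy$colonized[[1]]
  m <- modifiedCosine(s1, toy$germfree[[1]],
                      searchConfig(fragmentTol = 0.05))
  expect_identical(m$cosine, 0.7)
  res <- subtractCohort(list(s1), toy$germfree)
  expect_length(res$retained, 1)
})

test_that("shared feature ids are removed before the edge filter", {
  coh <- makeCohorts(seed = 5)
  res <- subtractCohort(coh$colonized, coh$germfree)
  ids <- vapply(res$retained, spectrumId, character(1))
  expect_setequal(ids, coh$truthRetained)
  expect_true("shared_id" %in% res$removed$reason)
  expect_true("gf_edge" %in% res$removed$reason)
})

test_that("raising the edge-cosine threshold never shrinks the retained set", {
  coh <- makeCohorts(seed = 6, nNearDup = 2, nPrivate = 4)
  sizes <- vapply(c(0.3, 0.7, 0.95), function(thr)
    length(subtractCohort(coh$colonized, coh$germfree,
                          edgeCosine = thr)$retained), numeric(1))
  expect_true(all(diff(sizes) >= 0))
  # output is always a subset of the input cohort
  all <- vapply(coh$colonized, spectrumId, character(1))
  res <- subtractCohort(coh$colonized, coh$germfree, edgeCosine = 0.3)
  expect_true(all(vapply(res$retained, spectrumId, character(1)) %in% all))
})

test_that("domain partition is exhaustive, disjoint, host-precedent", {
  fix <- sharedFixture()
  repo <- fix$repository
  man <- fix$manifest
  pickSpectrum <- function(kind) {
    rows <- man[man$kind == kind, ]
    if (kind == "producer")  # species 1 patterns are host-shared by design
      rows <- rows[rows$species_name != man$species_name[1], ]
    row <- rows[1, ]
    ref <- repoSpectra(repo)[[match(row$spectrum_id,
      vapply(repoSpectra(repo), spectrumId, character(1)))]]
    Spectrum(paste0("q_", kind), precursorMz(ref), ref@mz, ref@intensity)
  }
  jobs <- list(
    searchOne(pickSpectrum("producer"), repo),       # pure microbial
    searchOne(pickSpectrum("host_shared"), repo),    # bacterium + host cell
    searchOne(pickSpectrum("host"), repo),           # host only
    searchOne(Spectrum("q_none", 4999, c(100, 200), c(1, 1)), repo))
  part <- partitionByDomain(jobs, repo)
  expect_equal(nrow(part), 4)
  expect_true(all(part$bin %in% c("host_cell", "bacteria_only", "fungi_only",
                                  "both", "unmatched", "ambiguous")))
  # host-cell match takes precedence even when bacteria also match
  expect_equal(part$bin[part$query_id == "q_host_shared"], "host_cell")
  expect_gt(part$n_bacteria_files[part$query_id == "q_host_shared"], 0)
  expect_equal(part$bin[part$query_id == "q_host"], "host_cell")
  expect_equal(part$bin[part$query_id == "q_none"], "unmatched")
  expect_equal(part$bin[part$query_id == "q_producer"], "bacteria_only")
})

test_that("partition sizes equal generator truth on a mixed query set", {
  fix <- sharedFixture()
  repo <- fix$repository
  man <- fix$manifest
  refIds <- vapply(repoSpectra(repo), spectrumId, character(1))
  # one exact query per producer pattern of known domain
  withr::with_seed(12, rows <- man[man$kind == "producer", ][
    sample(sum(man$kind == "producer"), 10), ])
  jobs <- lapply(seq_len(nrow(rows)), function(k) {
    ref <- repoSpectra(repo)[[match(rows$spectrum_id[k], refIds)]]
    q <- Spectrum(sprintf("q%02d", k), precursorMz(ref), ref@mz,
                  ref@intensity)
    searchOne(q, repo)
  })
  part <- partitionByDomain(jobs, repo)
  # species 1 patterns are shared with host cells (host precedence);
  # everything else resolves to its generator domain
  sp1 <- fix$manifest$species_name[1]
  for (k in seq_len(nrow(rows))) {
    expected <- if (rows$species_name[k] == sp1 &&
                    rows$pattern_id[k] == sprintf("P_%s_1", sp1))
      "host_cell"
    else if (rows$domain[k] == "bacteria") "bacteria_only" else "fungi_only"
    expect_equal(part$bin[k], expected)
  }
})
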