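test_that("candidate pairs match forced constructions", {
  a <- Spectrum("a", 200, c(100, 110, 120), c(1, 1, 1))
  # identical spectra at shift 0: the three diagonal pairs (plus any other
  # in-tolerance coincidences; none here since peaks are 10 Th apart)
  p <- candidatePairs(a, a, 0.05, 0)
  expect_equal(nrow(p), 3)
  expect_true(all(p$i == p$j))
  # a forced shifted-only pair
  b <- Spectrum("b", 150, 150.0, 1)
  q <- Spectrum("q", 200, 100.0, 1)
  p2 <- candidatePairs(b, q, 0.05, 50)  # 150 matches 100 + 50 only via the shift
  expect_equal(nrow(p2), 1)
  expect_true(p2$shifted)
})

test_that("candidate pair sets equal the exhaustive double-loop oracle", {
  withr::with_seed(101, {
    for (rep in 1:50) {
      a <- gridSpectrum("a"); b <- gridSpectrum("b")
      shift <- precursorMz(a) - precursorMz(b)
      got <- candidatePairs(a, b, 0.05, shift)
      want <- oraclePairs(a, b, 0.05, shift)
      expect_equal(nrow(got), nrow(want))
      o1 <- got[order(got$i, got$j), c("i", "j", "weight")]
      o2 <- want[order(want$i, want$j), ]
      expect_equal(unname(as.matrix(o1)), unname(as.matrix(o2)),
                   tolerance = 1e-12)
    }
  })
})

test_that("self-similarity is exactly one and disjoint spectra score zero", {
  s <- Spectrum("s", 303.1, c(100, 150.2, 200.5, 280.1), c(5, 1, 9, 2))
  m <- modifiedCosine(s, s)
  expect_equal(m$cosine, 1, tolerance = 1e-9)
  expect_equal(m$n_matched_ions, peakCount(s))
  far <- Spectrum("far", 900, c(500, 600), c(1, 1))
  m0 <- modifiedCosine(s, far)
  expect_equal(m0$cosine, 0)
  expect_equal(m0$n_matched_ions, 0L)
  noPrec <- Spectrum("x", NA_real_, 100, 1)
  expect_error(modifiedCosine(noPrec, s), "precursor")
})

test_that("assignment score equals the exhaustive subset-DP oracle", {
  cfg <- searchConfig()
  withr::with_seed(202, {
    for (rep in 1:200) {
      a <- gridSpectrum("a"); b <- gridSpectrum("b")
      got <- modifiedCosine(a, b, cfg)$cosine
      want <- oracleBestScore(a, b, cfg)
      expect_equal(got, min(1, want), tolerance = 1e-9)
    }
  })
})

test_that("modified cosine is symmetric, bounded, and transform-aware", {
  cfgs <- list(searchConfig(), searchConfig(intensityTransform = "none"))
  withr::with_seed(303, {
    for (rep in 1:60) {
      a <- gridSpectrum("a"); b <- gridSpectrum("b")
      for (cfg in cfgs) {
        ab <- modifiedCosine(a, b, cfg)
        ba <- modifiedCosine(b, a, cfg)
        expect_lt(abs(ab$cosine - ba$cosine), 1e-9)
        expect_equal(ab$n_matched_ions, ba$n_matched_ions)
        expect_true(ab$cosine >= 0 && ab$cosine <= 1)
        expect_equal(ab$precursor_delta, -ba$precursor_delta)
      }
    }
  })
})

test_that("removing a non-matched peak never decreases the cosine", {
  cfg <- searchConfig()
  withr::with_seed(404, {
    checked <- 0
    for (rep in 1:80) {
      a <- gridSpectrum("a"); b <- gridSpectrum("b")
      m <- modifiedCosine(a, b, cfg)
      pairs <- candidatePairs(a, b, cfg@fragmentTol,
                              precursorMz(a) - precursorMz(b))
      loose <- setdiff(seq_len(peakCount(a)), pairs$i)
      if (!length(loose)) next
      drop <- loose[1]
      a2 <- Spectrum("a2", precursorMz(a), a@mz[-drop], a@intensity[-drop])
      expect_gte(modifiedCosine(a2, b, cfg)$cosine, m$cosine - 1e-12)
      checked <- checked + 1
    }
    expect_gt(checked, 10)
  })
})

test_that("threshold acceptance is inclusive at both boundaries", {
  cfg <- searchConfig()  # min cosine 0.7, min ions 3
  expect_true(passesThresholds(list(cosine = 0.70, n_matched_ions = 3), cfg))
  expect_false(passesThresholds(list(cosine = 0.69, n_matched_ions = 10), cfg))
  expect_false(passesThresholds(list(cosine = 0.95, n_matched_ions = 2), cfg))
})

test_that("an engineered spectrum pair scores exactly 0.7", {
  # transformed intensities (7,5,5,1) have L2 norm exactly 10; the single
  # matched peak against a one-peak spectrum gives cosine 7/10
  a <- Spectrum("a", 400.005, mz = c(100, 300, 410, 520),
                intensity = c(49, 25, 25, 1))
  b <- Spectrum("b", 400.0, mz = 100, intensity = 1)
  m <- modifiedCosine(a, b, searchConfig())
  expect_identical(m$cosine, 7 / 10)
  expect_equal(m$n_matched_ions, 1L)
})
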