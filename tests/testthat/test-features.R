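test_that("discrete mode energy matches simple cases and a quadrature oracle", {
  expect_identical(imfEnergy(numeric(0), 10), 0)
  expect_identical(imfEnergy(numeric(0), 10), 0)
  expect_equal(imfEnergy(rep(1, 10), 10), 1.0)      # 1 s of unit signal
  set.seed(3)
  x <- rnorm(500)
  fs <- 50
  trap <- (sum(x^2) - x[1]^2 / 2 - x[500]^2 / 2) / fs
  expect_equal(imfEnergy(x, fs), trap, tolerance = 0.01)
})

test_that("normalized energies sum to one, zero-fill shallow levels and ignore scale", {
  rec <- generateRecording(tiny_cohorts(n = 1, dur = 6, fs = 720)$normal, 2)
  d <- emd(rec)
  expect_gte(nIMF(d), 7L)
  ev <- normalizedEnergy(d)
  expect_lt(abs(sum(ev@normalized) - 1), 1e-12)
  expect_true(all(ev@raw >= 0))

  # full-decomposition denominator: retained shares no longer sum to 1
  ev_all <- normalizedEnergy(d, denominator = "all")
  expect_lte(sum(ev_all@normalized), 1 + 1e-12)

  # shallow decomposition: a three-tone signal yields < 7 modes
  t <- seq(0, 5, by = 1 / 100)
  x <- sin(2 * pi * 8 * t) + 0.8 * sin(2 * pi * 3 * t) + 0.5 * sin(2 * pi * 1 * t)
  d3 <- emd(x, fsHz = 100)
  expect_lt(nIMF(d3), 7L)
  ev3 <- normalizedEnergy(d3)
  present <- seq_len(ev3@nLevelsPresent)
  expect_true(all(ev3@raw[-present] == 0))
  expect_true(all(ev3@normalized[-present] == 0))
  expect_lt(abs(sum(ev3@normalized[present]) - 1), 1e-12)

  # amplitude scale invariance of the shares
  d_scaled <- emd(3 * pulseSamples(rec), fsHz = fsHz(rec))
  expect_equal(normalizedEnergy(d_scaled)@normalized, ev@normalized,
               tolerance = 1e-9)

  zero <- new("IMFSet", imfs = matrix(0, 50, 1), residual = numeric(50),
              source = numeric(50), fsHz = 10, subjectId = "z",
              groupLabel = "unknown")
  expect_error(normalizedEnergy(zero), "zero total energy")
})

test_that("sample entropy equals the naive definition exactly", {
  set.seed(7)
  for (i in 1:6) {
    N <- sample(150:600, 1)
    u <- rnorm(N)
    for (rf in c(0.1, 0.2, 0.25)) {
      ref <- oracle_sampen(u, 2, rf * sd(u))
      got <- sampleEntropy(u, m = 2, rFraction = rf)
      cnt <- pulseHHT:::.sampen_counts_cpp(u, 2L, rf * sd(u))
      expect_identical(cnt$A, ref$A)
      expect_identical(cnt$B, ref$B)
      expect_identical(as.numeric(got), ref$value)
    }
  }
})

test_that("sample entropy anchors: regularity, noise response, r-monotonicity, scaling", {
  expect_identical(sampleEntropy(rep(2.5, 100)), 0)
  expect_error(sampleEntropy(c(1, 2, 3), m = 2), "degenerate")

  saw <- rep(seq(0, 1, length.out = 25), 16)
  set.seed(15)
  noisy <- saw + rnorm(length(saw), sd = 0.5 * diff(range(saw)))
  expect_gt(sampleEntropy(noisy), sampleEntropy(saw))

  u <- noisy
  vals <- vapply(c(0.1, 0.15, 0.2, 0.25),
                 function(rf) sampleEntropy(u, rFraction = rf), 0)
  expect_true(all(diff(vals) <= 0))          # more matches, lower entropy

  expect_identical(sampleEntropy(5 * u), sampleEntropy(u))
})

test_that("per-level entropy vectors zero-fill and flag absent or undefined levels", {
  t <- seq(0, 5, by = 1 / 100)
  d <- emd(sin(2 * pi * 8 * t) + 0.5 * sin(2 * pi * 1 * t), fsHz = 100)
  sv <- sampenVector(d, maxPoints = 1000)
  k <- nIMF(d)
  expect_true(all(sv@missingMask[(k + 1):7]))
  expect_true(all(sv@values[(k + 1):7] == 0))
  expect_lt(sv@values[1], 0.5)               # clean tone: low entropy

  # values equal the brute-force oracle level by level
  rec <- generateRecording(tiny_cohorts(n = 1, dur = 4, fs = 240)$chd, 1)
  dr <- emd(rec)
  svr <- sampenVector(dr, maxPoints = 800)
  for (lev in seq_len(min(4, nIMF(dr)))) {
    series <- pulseHHT:::decimate_series(imfs(dr)[, lev], 800)
    ref <- oracle_sampen(series, 2, 0.2 * sd(series))
    if (!svr@missingMask[lev]) expect_identical(svr@values[lev], ref$value)
  }
})

test_that("feature extraction assembles a labelled 7+7 table per subject", {
  cfgs <- tiny_cohorts(n = 3, dur = 4, fs = 240)
  recs <- generateCohorts(cfgs$chd, cfgs$normal)
  fset <- pulseFeatures(recs, maxPoints = 800)
  expect_s4_class(fset, "PulseFeatureSet")
  expect_identical(dim(fset), c(7L, 6L))
  tb <- featureTable(fset)
  expect_identical(names(tb),
                   c("subject_id", "group", paste0("E", 1:7), paste0("S", 1:7),
                     "flags"))
  expect_identical(nrow(tb), 6L)

  # single recording still yields one 14-feature row
  one <- featureTable(recs[1], maxPoints = 800)
  expect_identical(nrow(one), 1L)

  # shuffling then sorting by subject id reproduces the table
  set.seed(4)
  shuf <- featureTable(pulseFeatures(sample(recs), maxPoints = 800))
  expect_equal(shuf[order(shuf$subject_id), ][, -1],
               tb[order(tb$subject_id), ][, -1],
               ignore_attr = TRUE)

  m <- featureMatrix(fset, "combined")
  expect_identical(dim(m), c(6L, 14L))
  expect_identical(colnames(featureMatrix(fset, "sampen",
                                          excludeSampenLevels = c(1, 2))),
                   paste0("S", 3:7))
})
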