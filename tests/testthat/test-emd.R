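test_that("extrema detection matches hand-checked and brute-force results", {
  expect_identical(findExtrema(c(0, 1, 0, -1, 0, 1, 0)),
                   list(maxima = c(2L, 6L), minima = 4L))
  mono <- findExtrema(as.numeric(1:50))
  expect_length(mono$maxima, 0)
  expect_length(mono$minima, 0)
  # plateau collapses to its midpoint (rounded down)
  expect_identical(findExtrema(c(0, 1, 1, 1, 0))$maxima, 3L)
  expect_identical(findExtrema(c(0, 1, 1, 0))$maxima, 2L)
  expect_error(findExtrema(c(1, 2)), "degenerate")

  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(200)
    if (rep > 3) x <- round(x, 1)            # force ties/plateaus
    got <- findExtrema(x)
    ref <- oracle_extrema(x)
    expect_identical(got$maxima, as.integer(ref$maxima))
    expect_identical(got$minima, as.integer(ref$minima))
  }
})

test_that("envelope mean behaves on symmetric oscillations and matches an independent spline", {
  t <- seq(0, 10, by = 1 / 100)
  x <- sin(2 * pi * t)
  interior <- 200:800
  em <- envelopeMean(x)
  expect_lt(max(abs(em[interior])), 0.01)
  em_c <- envelopeMean(x + 2.5)
  expect_lt(max(abs(em_c[interior] - 2.5)), 0.01)

  set.seed(21)
  for (i in 1:5) {
    y <- cumsum(rnorm(300))                   # smooth-ish random walk
    got <- envelopeMean(y)
    ref <- oracle_envelope_mean(y)
    expect_lt(max(abs(got - ref)), 1e-8)
  }
  # too few extrema: a termination signal, not an exception
  expect_null(envelopeMean(as.numeric(1:100)))
})

test_that("IMF conditions compare extrema and zero-crossing counts", {
  t <- seq(0, 5, by = 0.01)
  expect_true(isIMF(sin(2 * pi * t)))
  expect_false(isIMF(sin(2 * pi * t) + 1.5))  # extrema but no crossings
  expect_identical(zeroCrossings(c(1, -1, 1, -1)), 3L)
  expect_identical(zeroCrossings(c(1, 0, -1)), 1L)   # zero takes next sign
  expect_identical(zeroCrossings(c(1, 0, 1)), 0L)
})

test_that("sifting is a near-fixed point on clean tones and separates a two-tone mix", {
  t <- seq(0, 3, by = 1 / 200)
  tone <- sin(2 * pi * 10 * t)
  h <- sift(tone)
  expect_lte(attr(h, "iterations"), 2)
  expect_lt(sum((h - tone)^2) / sum(tone^2), 0.2)

  two <- sin(2 * pi * 10 * t) + sin(2 * pi * 1 * t)
  h2 <- sift(two)
  interior <- 100:500
  expect_gt(stats::cor(h2[interior], sin(2 * pi * 10 * t)[interior]), 0.95)

  # idempotence in the stopping-rule sense
  h3 <- sift(as.numeric(h2))
  sd_change <- sum((h2 - h3)^2) / sum(h2^2)
  expect_lt(sd_change, siftConfig()@sdThreshold)
})

test_that("decomposition is complete, valid and deterministic", {
  expect_identical(nIMF(emd(rep(1, 100), fsHz = 10)), 0L)
  expect_equal(residualSignal(emd(rep(1, 100), fsHz = 10)), rep(1, 100))

  cfgs <- tiny_cohorts(n = 2, dur = 5, fs = 240)
  for (rec in generateCohorts(cfgs$chd, cfgs$normal)) {
    d <- emd(rec)
    x <- pulseSamples(rec)
    recon <- rowSums(imfs(d)) + residualSignal(d)
    expect_lt(sqrt(sum((recon - x)^2) / sum(x^2)), 1e-9)
    expect_true(all(apply(imfs(d), 2, isIMF)))
  }
  rec <- generateRecording(cfgs$chd, 1)
  expect_identical(imfs(emd(rec)), imfs(emd(rec)))
})

test_that("modes come out ordered from high to low frequency", {
  cfgs <- tiny_cohorts(n = 10, dur = 4, fs = 240)
  recs <- generateCohorts(cfgs$chd, cfgs$normal)
  ok <- 0L; total <- 0L
  for (rec in recs) {
    d <- emd(rec)
    zc <- apply(imfs(d), 2, zeroCrossings)
    if (length(zc) > 1) {
      total <- total + length(zc) - 1L
      ok <- ok + sum(diff(zc) <= 0)
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("a full-scale default pulse recording decomposes to at least 7 modes", {
  cfgs <- defaultCohortConfigs()
  d <- emd(generateRecording(cfgs$normal, 3))
  expect_gte(nIMF(d), 7L)
})

test_that("IMF matrices write to CSV in the documented layout", {
  d <- emd(generateRecording(tiny_cohorts(n = 1)$chd, 1))
  path <- tempfile(fileext = ".csv")
  writeIMFSetCSV(d, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c(paste0("imf", seq_len(nIMF(d))), "residual"))
  expect_equal(back$imf1, imfs(d)[, 1], tolerance = 1e-12)
})
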