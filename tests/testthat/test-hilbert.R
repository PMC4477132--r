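test_that("analytic trace recovers amplitude and frequency of a pure tone", {
  fs <- 720
  t <- seq(0, 3, by = 1 / fs)
  A <- 2.3
  tr <- analyticTrace(A * sin(2 * pi * 5 * t), fs)
  interior <- 200:(length(t) - 200)
  expect_lt(max(abs(tr@amplitude[interior] - A)) / A, 0.02)
  expect_lt(max(abs(tr@instFreq[interior] - 5)) / 5, 0.02)
  expect_true(all(abs(diff(tr@phase)) <= pi + 1e-8))

  z <- analyticTrace(numeric(64), fs)
  expect_true(all(z@amplitude == 0))
})

test_that("instantaneous frequency tracks a linear chirp", {
  fs <- 200
  t <- seq(0, 8, by = 1 / fs)
  x <- sin(2 * pi * (t + t^2))               # f(t) = 1 + 2 t Hz
  tr <- analyticTrace(x, fs)
  interior <- 300:(length(t) - 300)
  truth <- 1 + 2 * t[interior]
  expect_lt(max(abs(tr@instFreq[interior] - truth) / truth), 0.05)
})

test_that("spectrum binning conserves energy and is additive over modes", {
  fs <- 240
  t <- seq(0, 4, by = 1 / fs)
  d <- emd(sin(2 * pi * 8 * t) + sin(2 * pi * 1 * t), fsHz = fs)
  sp <- hilbertSpectrum(d, nFreqBins = 48)
  mass <- sum(vapply(seq_len(nIMF(d)), function(k)
    sum(analyticTrace(imfs(d)[, k], fs)@amplitude^2), 0))
  expect_lt(abs(sum(sp@energy) - mass) / mass, 1e-6)

  # additivity: the grid is the sum of the single-mode grids
  parts <- lapply(seq_len(nIMF(d)), function(k) {
    one <- new("IMFSet", imfs = imfs(d)[, k, drop = FALSE],
               residual = numeric(nrow(imfs(d))),
               source = imfs(d)[, k], fsHz = fs,
               subjectId = "part", groupLabel = "unknown")
    hilbertSpectrum(one, nFreqBins = 48)@energy
  })
  expect_equal(sp@energy, Reduce(`+`, parts), tolerance = 1e-12)
})

test_that("a pure tone concentrates its spectral energy at its frequency", {
  fs <- 240
  t <- seq(0, 4, by = 1 / fs)
  tone <- sin(2 * pi * 5 * t)
  one <- new("IMFSet", imfs = matrix(tone, ncol = 1), residual = 0 * tone,
             source = tone, fsHz = fs, subjectId = "tone",
             groupLabel = "unknown")
  sp <- hilbertSpectrum(one, nFreqBins = 40)   # 3 Hz bins up to 120
  bin5 <- findInterval(5, sp@freqBins)
  near <- max(1, bin5 - 1):min(nrow(sp@energy), bin5 + 1)
  expect_gt(sum(sp@energy[near, ]) / sum(sp@energy), 0.9)
})

test_that("per-mode spectral mass agrees with the discrete energy integral", {
  rec <- generateRecording(tiny_cohorts(n = 1, dur = 4, fs = 240)$normal, 1)
  d <- emd(rec)
  fs <- fsHz(d)
  for (k in seq_len(min(3, nIMF(d)))) {
    tr <- analyticTrace(imfs(d)[, k], fs)
    # Parseval: sum a^2 ~ 2 sum c^2 for an oscillatory mode
    expect_equal(sum(tr@amplitude^2) / (2 * fs), imfEnergy(imfs(d)[, k], fs),
                 tolerance = 0.02)
  }
  # empty decomposition gives an empty spectrum
  sp0 <- hilbertSpectrum(emd(rep(2, 50), fsHz = 10), nFreqBins = 8)
  expect_identical(ncol(sp0@energy), 0L)
})
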