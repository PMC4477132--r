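test_that("recording length follows duration x sampling rate", {
  cfg <- cohortConfig(groupLabel = "normal_like", durationS = 60, fsHz = 720,
                      seed = 5)
  rec <- generateRecording(cfg, 1)
  expect_length(pulseSamples(rec), 43200)
  expect_true(all(is.finite(pulseSamples(rec))))
})

test_that("generation is deterministic and cohort order-independent", {
  cfg <- cohortConfig(nSubjects = 3, groupLabel = "CHD_like", durationS = 3,
                      fsHz = 180, seed = 42)
  r1 <- generateRecording(cfg, 2)
  r2 <- generateRecording(cfg, 2)
  expect_identical(pulseSamples(r1), pulseSamples(r2))
  # subject 2's samples do not depend on whether subject 1 was generated
  r3 <- lapply(1:3, function(i) generateRecording(cfg, i))[[2]]
  expect_identical(pulseSamples(r1), pulseSamples(r3))
})

test_that("noiseless constant-rate configuration is periodic", {
  cfg <- cohortConfig(groupLabel = "normal_like",
                      heartRateBpm = c(75, 0), systolicAmplitude = c(1, 0),
                      hfComplexity = 0, baselineWanderAmp = 0, noiseSd = 0,
                      resonanceAmp = 0, durationS = 10, fsHz = 200, seed = 1)
  x <- pulseSamples(generateRecording(cfg, 1))
  lag <- round(200 * 60 / 75)                 # one beat in samples
  n <- length(x)
  r <- stats::cor(x[1:(n - lag)], x[(lag + 1):n])
  expect_gt(r, 0.999)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohortConfig(nSubjects = 0), "nSubjects")
  expect_error(cohortConfig(heartRateBpm = c(500, 5)), "heartRateBpm")
  expect_error(cohortConfig(dicroticRatio = 1.4), "dicroticRatio")
  expect_error(cohortConfig(fsHz = -1), "fsHz")
  expect_error(cohortConfig(durationS = 0), "durationS")
})

test_that("two-cohort generation yields labelled recordings, CHD first", {
  cfgs <- defaultCohortConfigs()
  expect_identical(cfgs$chd@nSubjects, 225L)
  expect_identical(cfgs$normal@nSubjects, 117L)
  expect_equal(cfgs$chd@durationS, 60)
  expect_equal(cfgs$chd@fsHz, 720)
  small <- tiny_cohorts(n = 2, dur = 2, fs = 120)
  recs <- generateCohorts(small$chd, small$normal)
  expect_length(recs, 4)
  expect_identical(vapply(recs, function(r) r@groupLabel, ""),
                   c("CHD_like", "CHD_like", "normal_like", "normal_like"))
  expect_error(generateCohorts(small$chd, small$chd), "groupLabel")
})

test_that("default effect design separates the groups in the designed direction", {
  cfgs <- tiny_cohorts(n = 30, dur = 6, fs = 720)
  fset <- pulseFeatures(generateCohorts(cfgs$chd, cfgs$normal),
                        maxPoints = 1500)
  e <- SummarizedExperiment::assay(fset, "energy")
  s <- SummarizedExperiment::assay(fset, "sampen")
  g <- groupLabels(fset)
  med <- function(m, grp) apply(m[, g == grp, drop = FALSE], 1, stats::median)
  # normalized energy: normal-like median exceeds CHD-like at all 7 levels
  expect_true(all(med(e, "normal_like") > med(e, "CHD_like")))
  # sample entropy: normal-like median exceeds CHD-like at mid levels 3-6
  expect_true(all(med(s, "normal_like")[3:6] > med(s, "CHD_like")[3:6]))
})

test_that("recording and cohort CSV round-trips preserve data", {
  cfg <- cohortConfig(nSubjects = 2, groupLabel = "CHD_like", durationS = 2,
                      fsHz = 100, seed = 9)
  rec <- generateRecording(cfg, 1)
  path <- tempfile(fileext = ".csv")
  writePulseCSV(rec, path)
  back <- readPulseCSV(path, subjectId = rec@subjectId,
                       groupLabel = rec@groupLabel)
  expect_equal(fsHz(back), 100)
  expect_equal(pulseSamples(back), pulseSamples(rec), tolerance = 1e-12)

  dir <- tempfile()
  recs <- lapply(1:2, function(i) generateRecording(cfg, i))
  mp <- writeCohortCSV(recs, dir)
  back2 <- readCohortCSV(mp)
  expect_length(back2, 2)
  expect_identical(back2[[1]]@subjectId, recs[[1]]@subjectId)
  expect_identical(back2[[2]]@groupLabel, "CHD_like")
  expect_equal(pulseSamples(back2[[2]]), pulseSamples(recs[[2]]),
               tolerance = 1e-12)
})
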