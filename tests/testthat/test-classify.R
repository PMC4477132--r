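# small deterministic feature set with a moderate group effect, reused
# across the classifier tests
make_fset <- function(n = 12, effectSize = 1) {
  cfgs <- tiny_cohorts(n = n, dur = 4, fs = 240, effectSize = effectSize)
  pulseFeatures(generateCohorts(cfgs$chd, cfgs$normal), maxPoints = 800)
}

test_that("forest training follows the sqrt(m_all) feature-sampling rule", {
  expect_identical(pulseHHT:::.forest_mtry(14), 3L)
  expect_identical(pulseHHT:::.forest_mtry(7), 2L)

  set.seed(51)
  x <- rbind(matrix(rnorm(20 * 4, 0), ncol = 4),
             matrix(rnorm(20 * 4, 4), ncol = 4))
  y <- rep(c("a", "b"), each = 20)
  fit <- trainForest(x, y, forestConfig(seed = 2, nTrees = 200))
  expect_equal(fit$mtry, 2)
  expect_identical(fit$ntree, 200L)
  oob_err <- mean(fit$predicted != y)
  expect_lte(oob_err, 0.05)                  # linearly separable toy set

  expect_error(trainForest(x, rep("a", 40), forestConfig()), "2 classes")
})

test_that("recognition reports are deterministic and structurally sound", {
  fset <- make_fset()
  cfg <- forestConfig(seed = 7, nTrees = 150, kFolds = 4, nRepeats = 2)
  r1 <- evaluateFeatureSets(fset, cfg)
  r2 <- evaluateFeatureSets(fset, cfg)
  expect_identical(r1@rates, r2@rates)
  expect_identical(r1@oob, r2@oob)
  expect_true(all(r1@rates$mean >= 0 & r1@rates$mean <= 100))
  expect_setequal(unique(r1@rates$feature_set), c("sampen", "energy", "combined"))
  expect_setequal(unique(r1@rates$group), c("CHD_like", "normal_like", "average"))
  expect_identical(r1@nPerGroup, c(CHD_like = 12L, normal_like = 12L))

  path <- tempfile(fileext = ".csv")
  writeRecognitionCSV(r1, path)
  out <- utils::read.csv(path)
  expect_identical(dim(out), c(3L, 4L))
})

test_that("duplicated feature columns barely change recognition", {
  fset <- make_fset()
  cfg <- forestConfig(seed = 3, nTrees = 200, kFolds = 4, nRepeats = 2)
  base <- recognitionRate(evaluateFeatureSets(fset, cfg), "energy")
  dup <- fset
  SummarizedExperiment::assay(dup, "sampen") <-
    SummarizedExperiment::assay(dup, "energy")  # sampen slot now duplicates energy
  dup_rate <- recognitionRate(evaluateFeatureSets(dup, cfg), "combined")
  expect_lt(abs(dup_rate - base), 6)
})

test_that("label permutation collapses recognition to chance", {
  fset <- make_fset(n = 12)
  grp <- groupLabels(fset)
  set.seed(61)
  rates <- replicate(3, {
    perm <- fset
    SummarizedExperiment::colData(perm)$group <- sample(grp)
    recognitionRate(
      evaluateFeatureSets(perm, forestConfig(seed = 13, nTrees = 150,
                                             kFolds = 4, nRepeats = 1)),
      "combined")
  })
  # majority class is 50% here; noise forests sit near chance
  expect_lt(abs(mean(rates) - 50), 15)
})

test_that("recognition responds monotonically to the designed effect size", {
  rate_at <- function(es) {
    recognitionRate(
      evaluateFeatureSets(make_fset(n = 10, effectSize = es),
                          forestConfig(seed = 5, nTrees = 200, kFolds = 4,
                                       nRepeats = 2)),
      "combined")
  }
  r <- vapply(c(0, 0.5, 1), rate_at, 0)
  expect_true(r[3] >= r[1] + 5)              # clear gain at full effect
  expect_true(r[2] <= r[3] + 5)              # middle not above full (slack for noise)
})

test_that("too-small classes reduce the fold count with a warning", {
  fset <- make_fset(n = 4)
  expect_warning(
    evaluateFeatureSets(fset, forestConfig(seed = 1, nTrees = 50, kFolds = 10,
                                           nRepeats = 1)),
    "folds reduced")
})
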