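#' Construct random-forest evaluation controls
#'
#' @param nTrees trees per forest (500 by default).
#' @param mtryRule `"sqrt_mall"`: `floor(sqrt(m_all))` candidate features
#'   per split.
#' @param seed integer seed driving fold assignment and tree growing; the
#'   whole evaluation is deterministic given it.
#' @param kFolds stratified cross-validation folds.
#' @param nRepeats cross-validation repeats with fresh fold draws.
#' @return a [ForestConfig-class].
#' @export
forestConfig <- function(nTrees = 500L, mtryRule = "sqrt_mall", seed = 1L,
                         kFolds = 5L, nRepeats = 10L) {
  cfg <- new("ForestConfig", nTrees = as.integer(nTrees), mtryRule = mtryRule,
             seed = as.integer(seed), kFolds = as.integer(kFolds),
             nRepeats = as.integer(nRepeats))
  validObject(cfg)
  cfg
}

.forest_mtry <- function(m_all) max(1L, as.integer(floor(sqrt(m_all))))

#' Train one random forest on a labelled feature matrix
#'
#' Grows `nTrees` unpruned trees, each on a bootstrap resample, sampling
#' `floor(sqrt(m_all))` candidate features at every split; prediction is
#' the majority vote over trees (ties broken towards the first class label
#' in lexicographic factor order, the behaviour of the underlying forest).
#'
#' @param x numeric matrix, subjects x features.
#' @param labels factor (or coercible) of class labels, 2+ classes with at
#'   least 2 samples each.
#' @param config a [ForestConfig-class]; its seed is applied locally so the
#'   fit is reproducible.
#' @return a `randomForest` classifier handle.
#' @export
trainForest <- function(x, labels, config = forestConfig()) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2)
    stop("configuration error: need at least 2 classes to train")
  if (any(table(labels) < 2))
    stop("configuration error: need at least 2 samples per class")
  with_local_seed(config@seed, {
    randomForest::randomForest(x = x, y = labels, ntree = config@nTrees,
                               mtry = .forest_mtry(ncol(x)), replace = TRUE)
  })
}

# stratified fold assignment: within each class, shuffled 1..k recycling
.stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Recognition experiment over three feature sets
#'
#' For each of the feature sets `sampen`, `energy` and `combined`, runs a
#' repeated stratified k-fold cross-validation with a fresh forest per
#' training split. Per-group recognition rate = percentage of that group's
#' held-out subjects classified correctly; the `average` rate is the pooled
#' proportion correct over both groups (not the mean of the two per-group
#' rates). Rates are reported as mean and sd across the
#' `kFolds * nRepeats` held-out evaluations; fold draws are shared across
#' the three feature sets so their comparison is paired. Out-of-bag
#' accuracies of single full-data forests are attached for reference.
#'
#' If a fold cannot contain both classes, `kFolds` is reduced to the
#' smaller class size with a warning.
#'
#' @param features a [PulseFeatureSet-class] with both groups present.
#' @param config a [ForestConfig-class].
#' @param excludeSampenLevels sample-entropy levels to drop from the
#'   feature vectors (default none; the statistics-stage exclusion of
#'   levels 1-2 is not applied to the classifier unless requested).
#' @return a [RecognitionReport-class].
#' @export
evaluateFeatureSets <- function(features, config = forestConfig(),
                                excludeSampenLevels = integer(0)) {
  grp <- droplevels(groupLabels(features))
  if (nlevels(grp) < 2) stop("configuration error: both groups must be present")
  k <- config@kFolds
  if (min(table(grp)) < k) {
    k <- max(2L, min(table(grp)))
    warning(sprintf("folds reduced to %d so every fold holds both classes", k))
  }
  mats <- list(
    sampen = featureMatrix(features, "sampen",
                           excludeSampenLevels = excludeSampenLevels),
    energy = featureMatrix(features, "energy"),
    combined = featureMatrix(features, "combined",
                             excludeSampenLevels = excludeSampenLevels))
  lv <- levels(grp)
  res <- list()
  with_local_seed(config@seed, {
    for (rep_i in seq_len(config@nRepeats)) {
      folds <- .stratified_folds(grp, k)
      for (fold_i in seq_len(k)) {
        test <- folds == fold_i
        for (fam in names(mats)) {
          m <- mats[[fam]]
          fit <- randomForest::randomForest(
            x = m[!test, , drop = FALSE], y = grp[!test],
            ntree = config@nTrees, mtry = .forest_mtry(ncol(m)),
            replace = TRUE)
          pred <- predict(fit, m[test, , drop = FALSE])
          ok <- pred == grp[test]
          res[[length(res) + 1L]] <- data.frame(
            feature_set = fam, rep = rep_i, fold = fold_i,
            rate_a = 100 * mean(ok[grp[test] == lv[1]]),
            rate_b = 100 * mean(ok[grp[test] == lv[2]]),
            rate_avg = 100 * mean(ok))
        }
      }
    }
  })
  res <- do.call(rbind, res)
  agg <- function(fam, col, group) {
    v <- res[res$feature_set == fam, col]
    data.frame(feature_set = fam, group = group,
               mean = mean(v), sd = stats::sd(v))
  }
  rates <- do.call(rbind, lapply(c("sampen", "energy", "combined"), function(fam)
    rbind(agg(fam, "rate_a", lv[1]), agg(fam, "rate_b", lv[2]),
          agg(fam, "rate_avg", "average"))))
  rownames(rates) <- NULL
  oob <- vapply(names(mats), function(fam) {
    fit <- with_local_seed(config@seed + 7919L,
      randomForest::randomForest(x = mats[[fam]], y = grp,
                                 ntree = config@nTrees,
                                 mtry = .forest_mtry(ncol(mats[[fam]])),
                                 replace = TRUE))
    100 * mean(fit$predicted == grp)
  }, 0)
  new("RecognitionReport", rates = rates, oob = oob,
      nPerGroup = stats::setNames(as.integer(table(grp)), lv), config = config)
}

#' Average recognition rate of one feature set
#'
#' @param report a [RecognitionReport-class].
#' @param featureSet `"sampen"`, `"energy"` or `"combined"`.
#' @return the mean pooled recognition rate in percent.
#' @export
recognitionRate <- function(report, featureSet = "combined") {
  r <- report@rates
  r$mean[r$feature_set == featureSet & r$group == "average"]
}

setMethod("show", "RecognitionReport", function(object) {
  cat(sprintf("RecognitionReport: %s (stratified %d-fold x %d repeats, %d trees)\n",
              paste(sprintf("%s n=%d", names(object@nPerGroup), object@nPerGroup),
                    collapse = ", "),
              object@config@kFolds, object@config@nRepeats, object@config@nTrees))
  r <- object@rates
  for (g in unique(r$group)) {
    sub <- r[r$group == g, ]
    cells <- sprintf("%s %.2f±%.2f", sub$feature_set, sub$mean, sub$sd)
    cat(sprintf("  %-12s %s\n", g, paste(cells, collapse = "  ")))
  }
  cat("  OOB reference:",
      paste(sprintf("%s %.2f", names(object@oob), object@oob), collapse = "  "), "\n")
})

#' Write a recognition report as CSV
#'
#' Rows: CHD-like, normal-like, average; columns: the three feature sets,
#' cells `mean ± sd` in percent.
#'
#' @param report a [RecognitionReport-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRecognitionCSV <- function(report, path) {
  r <- report@rates
  groups <- unique(r$group)
  fams <- c("sampen", "energy", "combined")
  out <- data.frame(group = groups, stringsAsFactors = FALSE)
  for (fam in fams) {
    out[[fam]] <- vapply(groups, function(g) {
      sub <- r[r$group == g & r$feature_set == fam, ]
      sprintf("%.2f ± %.2f", sub$mean, sub$sd)
    }, "")
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
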