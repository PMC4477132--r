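#' Two-group rank-sum comparison of one feature
#'
#' Joint midranks (ties averaged) give each group's mean rank; the
#' Mann-Whitney statistic with normal approximation, tie correction and
#' continuity correction gives a two-sided p value. When every value is
#' identical the groups are indistinguishable: equal mean ranks and p = 1.
#'
#' @param a,b numeric vectors of the two groups' values.
#' @return list with `mean_rank_a`, `mean_rank_b`, `statistic`
#'   (Mann-Whitney U of group a) and `p_value`.
#' @examples
#' rankSumCompare(c(1, 2, 3), c(4, 5, 6))
#' @export
rankSumCompare <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  r <- rank(c(a, b))
  na <- length(a); nb <- length(b)
  mra <- mean(r[seq_len(na)])
  mrb <- mean(r[na + seq_len(nb)])
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (all(c(a, b) == c(a, b)[1])) {
    return(list(mean_rank_a = mra, mean_rank_b = mrb, statistic = U, p_value = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(mean_rank_a = mra, mean_rank_b = mrb,
       statistic = unname(wt$statistic), p_value = p)
}

#' Per-level rank-sum tables for both feature families
#'
#' Runs [rankSumCompare()] on each IMF level of the energy family (levels
#' 1-7) and of the sample-entropy family with the high-frequency
#' interference levels excluded (default IMF1-IMF2); the exclusion is
#' recorded in the result, not silently dropped. Group A is the CHD-like
#' group, B the normal-like group. No multiplicity adjustment is applied —
#' levels are reported individually.
#'
#' @param features a [PulseFeatureSet-class] containing both groups.
#' @param excludeSampenLevels integer levels excluded from the
#'   sample-entropy table.
#' @return named list of two [RankSumTable-class] objects, `energy` and
#'   `sampen`.
#' @export
featureRankTables <- function(features, excludeSampenLevels = c(1L, 2L)) {
  grp <- groupLabels(features)
  if (nlevels(droplevels(grp)) < 2)
    stop("configuration error: both groups must be present")
  ia <- grp == .group_levels[1]
  ib <- grp == .group_levels[2]
  one_family <- function(assay_name, levels_used, family) {
    m <- SummarizedExperiment::assay(features, assay_name)
    rows <- lapply(levels_used, function(lev) {
      cmp <- rankSumCompare(m[lev, ia], m[lev, ib])
      data.frame(level = lev, mean_rank_a = cmp$mean_rank_a,
                 mean_rank_b = cmp$mean_rank_b, statistic = cmp$statistic,
                 p_value = cmp$p_value)
    })
    new("RankSumTable", table = do.call(rbind, rows), featureFamily = family,
        excludedLevels = as.integer(setdiff(1:7, levels_used)),
        groupA = .group_levels[1], groupB = .group_levels[2],
        nA = sum(ia), nB = sum(ib))
  }
  list(energy = one_family("energy", 1:7, "energy"),
       sampen = one_family("sampen", setdiff(1:7, excludeSampenLevels), "sampen"))
}

setMethod("show", "RankSumTable", function(object) {
  cat(sprintf("Rank-sum comparison of IMF %s (%s n=%d vs %s n=%d)\n",
              object@featureFamily, object@groupA, object@nA,
              object@groupB, object@nB))
  if (length(object@excludedLevels))
    cat("  excluded levels:", paste(object@excludedLevels, collapse = ", "), "\n")
  tb <- object@table
  star <- ifelse(tb$p_value < 0.001, "***",
                 ifelse(tb$p_value < 0.01, "**",
                        ifelse(tb$p_value < 0.05, "*", "")))
  cat(sprintf("  IMF%-2d  meanRank A %8.2f  B %8.2f  p %.3g %s\n",
              tb$level, tb$mean_rank_a, tb$mean_rank_b, tb$p_value, star),
      sep = "")
})

#' Write a pair of rank-sum tables as CSV
#'
#' Mirrors a two-row-per-family layout: one row per group, one column per
#' analysed IMF level holding the mean rank, with `***` appended where
#' p < 0.001.
#'
#' @param tables list of [RankSumTable-class] as returned by
#'   [featureRankTables()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRankTableCSV <- function(tables, path) {
  rows <- lapply(tables, function(tb) {
    d <- tb@table
    lv <- paste0("IMF", d$level)
    star <- ifelse(d$p_value < 0.001, "***", "")
    a <- stats::setNames(sprintf("%.2f%s", d$mean_rank_a, star), lv)
    b <- stats::setNames(sprintf("%.2f%s", d$mean_rank_b, star), lv)
    out <- data.frame(family = tb@featureFamily,
                      group = c(tb@groupA, tb@groupB), stringsAsFactors = FALSE)
    cbind(out, rbind(as.data.frame(t(a)), as.data.frame(t(b))))
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) { r[setdiff(all_cols, names(r))] <- NA; r[all_cols] })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
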