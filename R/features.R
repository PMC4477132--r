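#' Discrete energy of one intrinsic mode function
#'
#' Discretizes the continuous-time energy integral of the squared mode as a
#' left Riemann sum, `sum(c^2) / fsHz`. Any consistent quadrature differs
#' only by a common factor that cancels under normalization.
#'
#' @param imf numeric vector (empty gives 0).
#' @param fsHz sampling rate (Hz).
#' @return nonnegative scalar.
#' @export
imfEnergy <- function(imf, fsHz) {
  if (!length(imf)) return(0)
  if (any(!is.finite(imf))) stop("imf contains non-finite samples")
  sum(imf^2) / fsHz
}

#' Normalized 7-level IMF energy vector
#'
#' Raw energies of IMF levels 1..7 (levels beyond the decomposition depth
#' zero-filled) divided by a total energy `E`. With
#' `denominator = "retained7"` (default) `E` sums the retained levels only,
#' so the normalized entries of a full 7-level decomposition sum to exactly
#' 1; `"all"` sums every extracted mode, the literal reading of the total
#' over all n modes.
#'
#' @param x an [IMFSet-class].
#' @param denominator `"retained7"` or `"all"`.
#' @param ... unused.
#' @return an [EnergyVector-class].
#' @rdname normalizedEnergy
#' @export
setMethod("normalizedEnergy", "IMFSet", function(x, denominator = c("retained7", "all"), ...) {
  denominator <- match.arg(denominator)
  k <- ncol(x@imfs)
  if (k < 1) stop("decomposition has no IMFs")
  all_e <- vapply(seq_len(k), function(i) imfEnergy(x@imfs[, i], x@fsHz), 0)
  raw <- numeric(7)
  present <- min(7L, k)
  raw[seq_len(present)] <- all_e[seq_len(present)]
  total <- if (denominator == "retained7") sum(raw) else sum(all_e)
  if (total == 0) stop("zero total energy")
  new("EnergyVector", raw = raw, normalized = raw / total,
      nLevelsPresent = as.integer(present))
})

#' Sample entropy of a series
#'
#' `SampEn(m, r, N) = -ln(A^m(r) / B^m(r))` where `B` and `A` are the
#' probabilities that two length-`m` (resp. `m + 1`) templates match under
#' the Chebyshev distance with strict tolerance `r`, self-matches excluded.
#' The tolerance is `rFraction` times the standard deviation of the series,
#' making the statistic exactly invariant to amplitude scaling. A constant
#' series is perfectly regular and returns 0. When no templates match at
#' either length the statistic is undefined: `NA` is returned with a
#' `reason` attribute and a message.
#'
#' @param series numeric vector, length >= m + 2.
#' @param m embedding dimension (template length).
#' @param rFraction tolerance as a fraction of `sd(series)`; 0.2 sits in
#'   the conventional 0.1-0.25 band.
#' @return scalar entropy in nats, or `NA`.
#' @examples
#' set.seed(1)
#' sampleEntropy(rnorm(300))            # irregular: high
#' sampleEntropy(sin(seq(0, 20, 0.05))) # regular: low
#' @export
sampleEntropy <- function(series, m = 2L, rFraction = 0.2) {
  series <- as.numeric(series)
  N <- length(series)
  if (N < m + 2) stop("degenerate input: need at least m + 2 samples")
  if (rFraction <= 0) stop("rFraction must be > 0")
  delta <- stats::sd(series)
  if (delta == 0) return(0)  # perfectly regular limit
  cnt <- .sampen_counts_cpp(series, as.integer(m), rFraction * delta)
  if (cnt$B == 0 || cnt$A == 0) {
    message(sprintf("sample entropy undefined (A = %d, B = %d matches); returning NA",
                    cnt$A, cnt$B))
    out <- NA_real_
    attr(out, "reason") <- if (cnt$B == 0) "no m-point matches" else "no (m+1)-point matches"
    return(out)
  }
  -log(cnt$A / cnt$B)
}

#' Per-level 7-entry sample-entropy vector
#'
#' Sample entropy of each IMF level 1..7. Each mode is evenly decimated to
#' at most `maxPoints` samples first (the pair count is quadratic in the
#' series length). The tolerance uses the standard deviation of the series
#' actually analysed — the decimated mode — so levels are commensurable
#' regardless of amplitude. Absent levels and undefined entropies are
#' stored as 0 and flagged, never dropped.
#'
#' @param x an [IMFSet-class].
#' @param m embedding dimension.
#' @param rFraction tolerance fraction of the per-series sd.
#' @param maxPoints decimation cap per mode.
#' @param ... unused.
#' @return a [SampEnVector-class].
#' @rdname sampenVector
#' @export
setMethod("sampenVector", "IMFSet", function(x, m = 2L, rFraction = 0.2,
                                             maxPoints = 5000L, ...) {
  values <- numeric(7)
  missing_mask <- rep(TRUE, 7)
  n_eff <- 0L
  k <- ncol(x@imfs)
  for (lev in seq_len(min(7L, k))) {
    series <- decimate_series(x@imfs[, lev], maxPoints)
    n_eff <- max(n_eff, length(series))
    v <- suppressMessages(sampleEntropy(series, m = m, rFraction = rFraction))
    if (is.na(v)) {
      values[lev] <- 0
    } else {
      values[lev] <- v
      missing_mask[lev] <- FALSE
    }
  }
  new("SampEnVector", values = values, m = as.integer(m),
      rFraction = rFraction, nEffective = as.integer(n_eff),
      missingMask = missing_mask)
})

setMethod("show", "SampEnVector", function(object) {
  cat(sprintf("SampEnVector (m = %d, r = %g sd, N <= %d):\n",
              object@m, object@rFraction, object@nEffective))
  v <- sprintf("%.3f%s", object@values, ifelse(object@missingMask, "*", ""))
  cat(" ", paste(sprintf("IMF%d=%s", 1:7, v), collapse = " "), "\n")
  if (any(object@missingMask)) cat("  (* zero-filled: level absent or entropy undefined)\n")
})

setMethod("show", "EnergyVector", function(object) {
  cat(sprintf("EnergyVector (%d of 7 levels present):\n", object@nLevelsPresent))
  cat("  normalized:", paste(sprintf("%.4f", object@normalized), collapse = " "), "\n")
})

#' Extract the full feature set of a list of recordings
#'
#' Runs EMD on every recording and assembles normalized IMF energies and
#' per-IMF sample entropies into a [PulseFeatureSet-class] (a
#' `SummarizedExperiment` with assays `energy` and `sampen`, 7 rows, one
#' column per subject). Recordings whose decomposition yields no IMFs are
#' dropped with a warning, never silently.
#'
#' @param recordings list of [PulseRecording-class].
#' @param sift a [SiftConfig-class].
#' @param m,rFraction,maxPoints sample-entropy settings, see
#'   [sampenVector()].
#' @param denominator energy normalization mode, see [normalizedEnergy()].
#' @return a [PulseFeatureSet-class].
#' @export
pulseFeatures <- function(recordings, sift = siftConfig(), m = 2L,
                          rFraction = 0.2, maxPoints = 5000L,
                          denominator = "retained7") {
  stopifnot(length(recordings) >= 1)
  cols <- lapply(recordings, function(rec) {
    dec <- emd(rec, sift)
    if (ncol(dec@imfs) == 0) return(NULL)
    ev <- normalizedEnergy(dec, denominator = denominator)
    sv <- sampenVector(dec, m = m, rFraction = rFraction, maxPoints = maxPoints)
    list(subject = rec@subjectId, group = rec@groupLabel,
         energy = ev@normalized, sampen = sv@values,
         n_imfs = ncol(dec@imfs), n_missing = sum(sv@missingMask),
         missing = sv@missingMask)
  })
  failed <- vapply(cols, is.null, TRUE)
  if (any(failed)) {
    warning(sprintf("%d recording(s) failed EMD and were dropped: %s",
                    sum(failed),
                    paste(vapply(recordings[failed], function(r) r@subjectId, ""),
                          collapse = ", ")))
    cols <- cols[!failed]
  }
  if (!length(cols)) stop("no recording produced a usable decomposition")
  energy <- vapply(cols, `[[`, numeric(7), "energy")
  sampen <- vapply(cols, `[[`, numeric(7), "sampen")
  rownames(energy) <- rownames(sampen) <- paste0("IMF", 1:7)
  subj <- vapply(cols, `[[`, "", "subject")
  colnames(energy) <- colnames(sampen) <- subj
  cd <- S4Vectors::DataFrame(
    subject_id = subj,
    group = factor(vapply(cols, `[[`, "", "group"), levels = .group_levels),
    n_imfs = vapply(cols, `[[`, 0L, "n_imfs"),
    n_sampen_missing = vapply(cols, `[[`, 0L, "n_missing"),
    sampen_missing_levels = vapply(cols, function(cc)
      paste(which(cc$missing), collapse = ","), ""))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(energy = energy, sampen = sampen), colData = cd)
  new("PulseFeatureSet", se)
}

#' @rdname accessors
#' @export
setMethod("groupLabels", "PulseFeatureSet", function(x)
  SummarizedExperiment::colData(x)$group)

#' Subjects-by-features matrix of a feature set
#'
#' @param x a [PulseFeatureSet-class].
#' @param family `"combined"` (E1..E7 then S1..S7), `"energy"` or
#'   `"sampen"`.
#' @param excludeSampenLevels integer levels of the sample-entropy family to
#'   drop from the matrix (e.g. `c(1, 2)` for the interference-prone
#'   high-frequency modes); default keeps all 7.
#' @param ... unused.
#' @return numeric matrix, one row per subject.
#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "PulseFeatureSet",
          function(x, family = c("combined", "energy", "sampen"),
                   excludeSampenLevels = integer(0), ...) {
  family <- match.arg(family)
  e <- t(SummarizedExperiment::assay(x, "energy"))
  s <- t(SummarizedExperiment::assay(x, "sampen"))
  colnames(e) <- paste0("E", 1:7)
  colnames(s) <- paste0("S", 1:7)
  if (length(excludeSampenLevels)) s <- s[, -excludeSampenLevels, drop = FALSE]
  switch(family,
         combined = cbind(e, s),
         energy = e,
         sampen = s)
})

#' Flat per-subject feature table
#'
#' One row per subject: `subject_id`, `group`, `E1..E7`, `S1..S7` and a
#' `flags` column listing zero-filled sample-entropy levels (empty when
#' none). Row order follows the input order.
#'
#' @param x a [PulseFeatureSet-class] or a list of
#'   [PulseRecording-class] (decomposed on the fly via [pulseFeatures()]).
#' @param ... passed on to [pulseFeatures()] for the list method.
#' @return a data.frame.
#' @rdname featureTable
#' @export
setMethod("featureTable", "PulseFeatureSet", function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  df <- data.frame(subject_id = cd$subject_id,
                   group = as.character(cd$group),
                   stringsAsFactors = FALSE)
  df <- cbind(df,
              as.data.frame(featureMatrix(x, "energy")),
              as.data.frame(featureMatrix(x, "sampen")))
  df$flags <- cd$sampen_missing_levels
  rownames(df) <- NULL
  df
})

#' @rdname featureTable
#' @export
setMethod("featureTable", "list", function(x, ...) {
  featureTable(pulseFeatures(x, ...))
})

#' Write a feature table as CSV
#'
#' @param features a [PulseFeatureSet-class] or feature-table data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(features, path) {
  df <- if (is(features, "PulseFeatureSet")) featureTable(features) else features
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
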