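#' Construct sifting/decomposition controls
#'
#' @param sdThreshold Cauchy-type stopping threshold: sifting of one mode
#'   stops once `sum((h_prev - h)^2) / sum(h_prev^2)` drops below it while
#'   the IMF conditions hold. 0.2 is the canonical choice.
#' @param maxSiftIters cap on sifting iterations per mode.
#' @param maxImfs cap on extracted modes (guards pathological inputs).
#' @param boundaryPolicy `"mirror"`: two extrema reflected across each end
#'   before envelope spline fitting.
#' @param minExtrema minimum number of maxima and of minima needed to fit
#'   envelopes; below it decomposition terminates.
#' @return a [SiftConfig-class].
#' @export
siftConfig <- function(sdThreshold = 0.2, maxSiftIters = 300L, maxImfs = 12L,
                       boundaryPolicy = "mirror", minExtrema = 2L) {
  cfg <- new("SiftConfig", sdThreshold = as.numeric(sdThreshold),
             maxSiftIters = as.integer(maxSiftIters),
             maxImfs = as.integer(maxImfs),
             boundaryPolicy = boundaryPolicy,
             minExtrema = as.integer(minExtrema))
  validObject(cfg)
  cfg
}

#' Locate strict local extrema
#'
#' Extrema are detected by sign changes of the first difference; a flat
#' plateau contributes a single extremum at its midpoint (rounded down).
#' Endpoints are never extrema.
#'
#' @param signal numeric vector, length >= 3.
#' @return list with integer vectors `maxima` and `minima` (1-based,
#'   strictly increasing).
#' @examples
#' findExtrema(c(0, 1, 0, -1, 0, 1, 0))
#' @export
findExtrema <- function(signal) {
  if (length(signal) < 3) stop("degenerate input: need at least 3 samples")
  .find_extrema_cpp(as.numeric(signal))
}

#' Count strict zero crossings
#'
#' Sign changes between consecutive samples; zero samples take the sign of
#' the next nonzero sample, so they never add a crossing of their own.
#'
#' @param signal numeric vector.
#' @return integer crossing count.
#' @export
zeroCrossings <- function(signal) .zero_crossings_cpp(as.numeric(signal))

#' Mean of the upper and lower cubic-spline envelopes
#'
#' Natural cubic splines through the maxima (upper envelope) and minima
#' (lower envelope) after mirror-extending two extrema across each end;
#' returns their pointwise mean. When fewer than `minExtrema` maxima or
#' minima exist the function returns `NULL` — the signal that sifting must
#' stop, not an error.
#'
#' @param signal numeric vector.
#' @param config a [SiftConfig-class].
#' @return numeric vector of the envelope mean, or `NULL`.
#' @export
envelopeMean <- function(signal, config = siftConfig()) {
  .envelope_mean_cpp(as.numeric(signal), config@minExtrema)
}

#' Test the intrinsic-mode-function conditions
#'
#' TRUE iff the number of extrema and the number of zero crossings differ
#' by at most one.
#'
#' @param candidate numeric vector, length >= 3.
#' @return logical scalar.
#' @examples
#' t <- seq(0, 4, by = 0.01)
#' isIMF(sin(2 * pi * t))        # TRUE
#' isIMF(sin(2 * pi * t) + 0.9)  # FALSE: extrema without zero crossings
#' @export
isIMF <- function(candidate) {
  if (length(candidate) < 3) stop("degenerate input: need at least 3 samples")
  .is_imf_cpp(as.numeric(candidate))
}

#' Sift one mode out of a signal
#'
#' Iterates `h <- h - envelopeMean(h)` until the Cauchy criterion
#' `SD = sum((h_prev - h)^2) / sum(h_prev^2) < sdThreshold` holds together
#' with the IMF conditions, the iteration cap is reached, or the extrema
#' are exhausted. Always returns the last iterate; the termination cause
#' and iteration count are attached as attributes `reason` and
#' `iterations`.
#'
#' @param signal numeric vector.
#' @param config a [SiftConfig-class].
#' @return numeric vector (the sifted mode candidate).
#' @export
sift <- function(signal, config = siftConfig()) {
  res <- .sift_cpp(as.numeric(signal), config@sdThreshold,
                   config@maxSiftIters, config@minExtrema)
  out <- res$h
  attr(out, "iterations") <- res$iterations
  attr(out, "reason") <- res$reason
  out
}

.emd_core <- function(samples, fs, config, subjectId = "unknown",
                      groupLabel = "unknown") {
  samples <- as.numeric(samples)
  n <- length(samples)
  empty <- function() new("IMFSet",
                          imfs = matrix(numeric(0), nrow = n, ncol = 0),
                          residual = samples, source = samples, fsHz = fs,
                          subjectId = subjectId, groupLabel = groupLabel)
  if (n < 8 || all(samples == samples[1])) return(empty())
  residual <- samples
  modes <- list()
  while (length(modes) < config@maxImfs) {
    ext <- .find_extrema_cpp(residual)
    if (length(ext$maxima) < config@minExtrema ||
        length(ext$minima) < config@minExtrema) break
    h <- .sift_cpp(residual, config@sdThreshold, config@maxSiftIters,
                   config@minExtrema)$h
    # accept only genuine IMFs; a failed candidate stays in the residual
    if (!.is_imf_cpp(h)) break
    modes[[length(modes) + 1L]] <- h
    residual <- residual - h
  }
  m <- if (length(modes)) do.call(cbind, modes) else matrix(numeric(0), nrow = n, ncol = 0)
  if (ncol(m)) colnames(m) <- paste0("IMF", seq_len(ncol(m)))
  new("IMFSet", imfs = m, residual = residual, source = samples, fsHz = fs,
      subjectId = subjectId, groupLabel = groupLabel)
}

#' Empirical mode decomposition
#'
#' Repeatedly sifts intrinsic mode functions out of the running residual
#' until the residual is monotone (fewer than `minExtrema` extrema of each
#' kind) or `maxImfs` is reached. Every accepted mode satisfies [isIMF()],
#' and the modes plus residual reconstruct the input to floating-point
#' accuracy (checked by the [IMFSet-class] validity).
#'
#' Constant or too-short input yields an empty decomposition whose residual
#' is the input itself.
#'
#' @param x a [PulseRecording-class] or numeric vector.
#' @param config a [SiftConfig-class].
#' @param fsHz sampling rate, required for the numeric method.
#' @param ... unused.
#' @return an [IMFSet-class].
#' @examples
#' cfg <- cohortConfig(groupLabel = "normal_like", durationS = 6, fsHz = 180,
#'                     seed = 3)
#' d <- emd(generateRecording(cfg, 1))
#' nIMF(d)
#' @rdname emd
#' @export
setMethod("emd", "PulseRecording", function(x, config = siftConfig(), ...) {
  .emd_core(x@samples, x@fsHz, config, x@subjectId, x@groupLabel)
})

#' @rdname emd
#' @export
setMethod("emd", "numeric", function(x, config = siftConfig(), fsHz = 1, ...) {
  .emd_core(x, fsHz, config)
})

#' Accessors for the package's S4 containers
#'
#' `imfs()` returns the mode matrix (one column per IMF),
#' `residualSignal()` the decomposition leftover, `nIMF()` the mode count,
#' `fsHz()` the sampling rate, `pulseSamples()` the raw signal and
#' `groupLabels()` the per-subject group factor of a feature set.
#'
#' @return the corresponding slot content.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setMethod("imfs", "IMFSet", function(x) x@imfs)

#' @rdname accessors
#' @export
setMethod("residualSignal", "IMFSet", function(x) x@residual)

#' @rdname accessors
#' @export
setMethod("nIMF", "IMFSet", function(x) ncol(x@imfs))

#' @rdname accessors
#' @export
setMethod("fsHz", "IMFSet", function(x) x@fsHz)

setMethod("show", "IMFSet", function(object) {
  cat(sprintf("IMFSet '%s' (%s): %d IMFs + residual over %d samples @ %g Hz\n",
              object@subjectId, object@groupLabel, ncol(object@imfs),
              length(object@source), object@fsHz))
})

#' Write an IMF matrix as CSV
#'
#' Columns `imf1..imfN,residual`, one row per sample.
#'
#' @param imfset an [IMFSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeIMFSetCSV <- function(imfset, path) {
  k <- ncol(imfset@imfs)
  df <- as.data.frame(if (k) imfset@imfs else matrix(numeric(0), nrow = length(imfset@residual), ncol = 0))
  if (k) names(df) <- paste0("imf", seq_len(k))
  df$residual <- imfset@residual
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
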