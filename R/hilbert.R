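#' Analytic-signal trace of one intrinsic mode function
#'
#' Constructs the analytic extension `z(t) = c(t) + i H[c](t)` by
#' single-sideband FFT, then takes instantaneous amplitude (modulus),
#' unwrapped phase (argument) and instantaneous frequency in Hz as the
#' phase derivative over `2 * pi` — central differences in the interior and
#' one-sided differences at the two edge samples.
#'
#' @param imf numeric vector, length >= 4.
#' @param fsHz sampling rate (Hz).
#' @return an [AnalyticTrace-class].
#' @examples
#' fs <- 720; t <- seq(0, 2, by = 1 / fs)
#' tr <- analyticTrace(2 * sin(2 * pi * 5 * t), fs)
#' summary(tr@instFreq[100:1200])   # ~5 Hz away from the edges
#' @export
analyticTrace <- function(imf, fsHz) {
  x <- as.numeric(imf)
  n <- length(x)
  if (n < 4) stop("degenerate input: need at least 4 samples")
  if (all(x == 0)) {
    return(new("AnalyticTrace", amplitude = numeric(n), phase = numeric(n),
               instFreq = numeric(n), fsHz = fsHz))
  }
  # analytic signal: zero the negative-frequency half of the spectrum
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  amplitude <- Mod(z)
  phase <- signal::unwrap(Arg(z))
  inst <- numeric(n)
  inst[2:(n - 1)] <- (phase[3:n] - phase[1:(n - 2)]) / 2
  inst[1] <- phase[2] - phase[1]
  inst[n] <- phase[n] - phase[n - 1]
  inst <- inst * fsHz / (2 * pi)
  new("AnalyticTrace", amplitude = amplitude, phase = phase,
      instFreq = inst, fsHz = fsHz)
}

#' Hilbert spectrum of a decomposition
#'
#' For each IMF, the squared instantaneous amplitude of every sample is
#' deposited into the frequency bin containing its instantaneous frequency
#' (bins span 0 to fs/2). Negative instantaneous frequencies — possible
#' numerically — are clipped into the first bin; frequencies at or above
#' fs/2 go into the last. Binning therefore conserves the total squared
#' amplitude mass exactly.
#'
#' @param x an [IMFSet-class].
#' @param nFreqBins number of uniform frequency bins.
#' @param ... unused.
#' @return a [HilbertSpectrum-class]; empty decompositions give an empty
#'   spectrum.
#' @rdname hilbertSpectrum
#' @export
setMethod("hilbertSpectrum", "IMFSet", function(x, nFreqBins = 64, ...) {
  fs <- x@fsHz
  n <- length(x@source)
  edges <- seq(0, fs / 2, length.out = nFreqBins + 1)
  if (ncol(x@imfs) == 0) {
    return(new("HilbertSpectrum", freqBins = edges, timeAxis = numeric(0),
               energy = matrix(numeric(0), nrow = nFreqBins, ncol = 0)))
  }
  grid <- matrix(0, nrow = nFreqBins, ncol = n)
  width <- (fs / 2) / nFreqBins
  for (k in seq_len(ncol(x@imfs))) {
    tr <- analyticTrace(x@imfs[, k], fs)
    bin <- floor(tr@instFreq / width) + 1L
    bin[bin < 1L] <- 1L            # clip negative instantaneous frequencies
    bin[bin > nFreqBins] <- nFreqBins
    e <- tr@amplitude^2
    for (i in seq_len(n)) grid[bin[i], i] <- grid[bin[i], i] + e[i]
  }
  new("HilbertSpectrum", freqBins = edges, timeAxis = (seq_len(n) - 1) / fs,
      energy = grid)
})

setMethod("show", "HilbertSpectrum", function(object) {
  cat(sprintf("HilbertSpectrum: %d freq bins x %d time samples, total energy %.4g\n",
              nrow(object@energy), ncol(object@energy), sum(object@energy)))
})

setMethod("show", "AnalyticTrace", function(object) {
  cat(sprintf("AnalyticTrace: %d samples @ %g Hz, mean amplitude %.4g\n",
              length(object@amplitude), object@fsHz, mean(object@amplitude)))
})

#' Write a Hilbert spectrum as long-format CSV
#'
#' Columns `time,freq,energy`; `freq` is the bin midpoint. Zero cells are
#' omitted.
#'
#' @param spectrum a [HilbertSpectrum-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpectrumCSV <- function(spectrum, path) {
  mid <- (head(spectrum@freqBins, -1) + spectrum@freqBins[-1]) / 2
  idx <- which(spectrum@energy > 0, arr.ind = TRUE)
  df <- data.frame(time = spectrum@timeAxis[idx[, 2]],
                   freq = mid[idx[, 1]],
                   energy = spectrum@energy[idx])
  df <- df[order(df$time, df$freq), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
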