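#' @import methods
#' @importFrom stats rnorm runif sd fft qnorm pnorm wilcox.test predict
#' @importFrom utils head read.csv write.csv
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @useDynLib pulseHHT, .registration = TRUE
NULL

.group_levels <- c("CHD_like", "normal_like")

#' CohortConfig: parameters of one synthetic pulse cohort
#'
#' Describes one cohort of quasi-periodic radial-pulse recordings: heart
#' rate, systolic and dicrotic wave geometry, broadband high-frequency
#' "complexity" content, baseline wander, measurement noise, a per-subject
#' narrowband resonance component, and acquisition settings. Identical
#' (config, seed) pairs regenerate bit-identical cohorts.
#'
#' @slot nSubjects number of subjects in the cohort.
#' @slot groupLabel `"CHD_like"` or `"normal_like"`.
#' @slot heartRateBpm length-2 numeric `(mean, sd)` in beats/min; the sd
#'   drives both subject-to-subject mean heart-rate variation and (at half
#'   weight) beat-to-beat period jitter, so sd = 0 yields exactly periodic
#'   signals.
#' @slot systolicAmplitude length-2 numeric `(mean, sd)` in arbitrary
#'   pressure units; the sd likewise splits into subject- and beat-level
#'   variation.
#' @slot dicroticRatio dicrotic-wave amplitude as a fraction of the systolic
#'   amplitude, in `[0, 1]`.
#' @slot dicroticDelay dicrotic-peak delay after the systolic peak as a
#'   fraction of the beat period, in `(0, 1)`.
#' @slot systolicWidth,dicroticWidth Gaussian bump widths (sd) as fractions
#'   of the beat period.
#' @slot hfComplexity amplitude (relative to the subject's systolic
#'   amplitude) of a broadband pink-noise component spanning `hfBand`.
#' @slot hfBand length-2 numeric frequency band (Hz) of the broadband
#'   component.
#' @slot baselineWanderAmp amplitude of a slow (< 0.5 Hz) sinusoidal
#'   baseline drift.
#' @slot noiseSd additive white measurement-noise standard deviation.
#' @slot resonanceAmp mean amplitude (relative to systolic amplitude) of a
#'   subject-specific narrowband oscillation whose frequency is drawn
#'   log-uniformly from `resonanceFreqRange`; 0 disables it.
#' @slot resonanceFreqRange length-2 numeric frequency range (Hz) for the
#'   subject-specific resonance.
#' @slot durationS recording duration in seconds.
#' @slot fsHz sampling rate in samples/second.
#' @slot seed integer master seed; subject `i` uses stream `seed + i`.
#' @name CohortConfig-class
#' @rdname CohortConfig-class
#' @exportClass CohortConfig
setClass("CohortConfig", representation(
  nSubjects = "integer",
  groupLabel = "character",
  heartRateBpm = "numeric",
  systolicAmplitude = "numeric",
  dicroticRatio = "numeric",
  dicroticDelay = "numeric",
  systolicWidth = "numeric",
  dicroticWidth = "numeric",
  hfComplexity = "numeric",
  hfBand = "numeric",
  baselineWanderAmp = "numeric",
  noiseSd = "numeric",
  resonanceAmp = "numeric",
  resonanceFreqRange = "numeric",
  durationS = "numeric",
  fsHz = "numeric",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  bad <- function(field, why) sprintf("invalid '%s': %s", field, why)
  if (length(object@nSubjects) != 1 || is.na(object@nSubjects) || object@nSubjects < 1)
    return(bad("nSubjects", "must be a single integer >= 1"))
  if (!object@groupLabel %in% .group_levels)
    return(bad("groupLabel", paste("must be one of", paste(.group_levels, collapse = ", "))))
  if (length(object@heartRateBpm) != 2 || object@heartRateBpm[1] < 30 || object@heartRateBpm[1] > 200)
    return(bad("heartRateBpm", "mean must lie in [30, 200] bpm"))
  if (object@heartRateBpm[2] < 0)
    return(bad("heartRateBpm", "sd must be >= 0"))
  if (length(object@systolicAmplitude) != 2 || object@systolicAmplitude[1] <= 0 || object@systolicAmplitude[2] < 0)
    return(bad("systolicAmplitude", "mean must be > 0 and sd >= 0"))
  if (object@dicroticRatio < 0 || object@dicroticRatio > 1)
    return(bad("dicroticRatio", "must lie in [0, 1]"))
  if (object@dicroticDelay <= 0 || object@dicroticDelay >= 1)
    return(bad("dicroticDelay", "must lie in (0, 1)"))
  if (object@systolicWidth <= 0 || object@dicroticWidth <= 0)
    return(bad("systolicWidth", "bump widths must be > 0"))
  if (object@hfComplexity < 0) return(bad("hfComplexity", "must be >= 0"))
  if (length(object@hfBand) != 2 || object@hfBand[1] <= 0 || diff(object@hfBand) <= 0)
    return(bad("hfBand", "must be an increasing positive (lo, hi) pair"))
  if (object@baselineWanderAmp < 0) return(bad("baselineWanderAmp", "must be >= 0"))
  if (object@noiseSd < 0) return(bad("noiseSd", "must be >= 0"))
  if (object@resonanceAmp < 0) return(bad("resonanceAmp", "must be >= 0"))
  if (length(object@resonanceFreqRange) != 2 || object@resonanceFreqRange[1] <= 0 ||
      diff(object@resonanceFreqRange) < 0)
    return(bad("resonanceFreqRange", "must be a nondecreasing positive (lo, hi) pair"))
  if (object@durationS <= 0) return(bad("durationS", "must be > 0"))
  if (object@fsHz <= 0) return(bad("fsHz", "must be > 0"))
  if (length(object@seed) != 1 || is.na(object@seed))
    return(bad("seed", "must be a single integer"))
  TRUE
})

#' PulseRecording: one subject's sampled pulse signal
#'
#' @slot samples numeric vector of pressure samples (arbitrary units).
#' @slot fsHz sampling rate (samples/second).
#' @slot subjectId subject identifier.
#' @slot groupLabel `"CHD_like"`, `"normal_like"` or `"unknown"`.
#' @name PulseRecording-class
#' @rdname PulseRecording-class
#' @exportClass PulseRecording
setClass("PulseRecording", representation(
  samples = "numeric",
  fsHz = "numeric",
  subjectId = "character",
  groupLabel = "character"
))

setValidity("PulseRecording", function(object) {
  if (length(object@fsHz) != 1 || object@fsHz <= 0) return("fsHz must be a single value > 0")
  if (any(!is.finite(object@samples))) return("samples must all be finite")
  if (!object@groupLabel %in% c(.group_levels, "unknown"))
    return("groupLabel must be CHD_like, normal_like or unknown")
  TRUE
})

#' SiftConfig: sifting and decomposition controls for EMD
#'
#' @slot sdThreshold Cauchy-type stopping threshold on the normalized
#'   squared change between consecutive sifting iterates.
#' @slot maxSiftIters maximum sifting iterations per mode.
#' @slot maxImfs maximum number of intrinsic mode functions to extract.
#' @slot boundaryPolicy envelope boundary handling; only `"mirror"`
#'   (reflection of two extrema across each end) is implemented.
#' @slot minExtrema minimum count of maxima and of minima required to fit
#'   envelopes; below it sifting (and decomposition) stops.
#' @name SiftConfig-class
#' @rdname SiftConfig-class
#' @exportClass SiftConfig
setClass("SiftConfig", representation(
  sdThreshold = "numeric",
  maxSiftIters = "integer",
  maxImfs = "integer",
  boundaryPolicy = "character",
  minExtrema = "integer"
))

setValidity("SiftConfig", function(object) {
  if (object@sdThreshold <= 0) return("sdThreshold must be > 0")
  if (object@maxSiftIters < 1) return("maxSiftIters must be >= 1")
  if (object@maxImfs < 1) return("maxImfs must be >= 1")
  if (!identical(object@boundaryPolicy, "mirror")) return("boundaryPolicy must be 'mirror'")
  if (object@minExtrema < 1) return("minExtrema must be >= 1")
  TRUE
})

#' IMFSet: intrinsic mode functions plus residual from one decomposition
#'
#' Columns of `imfs` are ordered from the highest-frequency mode (IMF1) to
#' the lowest. The decomposition is complete: the column sum plus the
#' residual reproduces the source signal to floating-point accuracy.
#'
#' @slot imfs numeric matrix, one column per IMF (may have zero columns).
#' @slot residual numeric vector, the monotone/low-extrema leftover.
#' @slot source the decomposed signal (kept so completeness is checkable).
#' @slot fsHz sampling rate of the source recording.
#' @slot subjectId,groupLabel provenance carried from the recording.
#' @name IMFSet-class
#' @rdname IMFSet-class
#' @exportClass IMFSet
setClass("IMFSet", representation(
  imfs = "matrix",
  residual = "numeric",
  source = "numeric",
  fsHz = "numeric",
  subjectId = "character",
  groupLabel = "character"
))

setValidity("IMFSet", function(object) {
  n <- length(object@source)
  if (length(object@residual) != n) return("residual length must equal source length")
  if (ncol(object@imfs) > 0 && nrow(object@imfs) != n)
    return("every IMF must have the source length")
  recon <- object@residual + if (ncol(object@imfs)) rowSums(object@imfs) else 0
  denom <- sqrt(sum(object@source^2))
  err <- sqrt(sum((recon - object@source)^2))
  if (denom > 0 && err / denom > 1e-9)
    return("IMFs + residual do not reconstruct the source within 1e-9 relative L2")
  if (denom == 0 && err > 1e-12) return("nonzero decomposition of a zero signal")
  TRUE
})

#' AnalyticTrace: instantaneous amplitude, phase and frequency of one IMF
#'
#' @slot amplitude nonnegative instantaneous amplitude (input units).
#' @slot phase unwrapped instantaneous phase (radians).
#' @slot instFreq instantaneous frequency (Hz), same length as the input;
#'   central differences of the unwrapped phase with one-sided differences
#'   at the two edge samples.
#' @slot fsHz sampling rate (Hz).
#' @name AnalyticTrace-class
#' @rdname AnalyticTrace-class
#' @exportClass AnalyticTrace
setClass("AnalyticTrace", representation(
  amplitude = "numeric",
  phase = "numeric",
  instFreq = "numeric",
  fsHz = "numeric"
))

setValidity("AnalyticTrace", function(object) {
  if (any(object@amplitude < 0)) return("amplitude must be nonnegative")
  if (length(object@phase) != length(object@amplitude) ||
      length(object@instFreq) != length(object@amplitude))
    return("amplitude, phase and instFreq must have equal length")
  if (length(object@phase) > 1 &&
      any(abs(diff(object@phase)) > pi + 1e-8))
    return("phase must be unwrapped (no jumps larger than pi)")
  TRUE
})

#' HilbertSpectrum: binned time-frequency energy distribution
#'
#' @slot freqBins frequency bin edges (Hz), length nbins + 1.
#' @slot timeAxis sample times (seconds).
#' @slot energy nonnegative matrix, frequency bins x time samples.
#' @name HilbertSpectrum-class
#' @rdname HilbertSpectrum-class
#' @exportClass HilbertSpectrum
setClass("HilbertSpectrum", representation(
  freqBins = "numeric",
  timeAxis = "numeric",
  energy = "matrix"
))

setValidity("HilbertSpectrum", function(object) {
  if (length(object@energy) && any(object@energy < 0)) return("energy must be nonnegative")
  if (length(object@energy) && nrow(object@energy) != length(object@freqBins) - 1)
    return("energy must have one row per frequency bin")
  TRUE
})

#' EnergyVector: per-level IMF energy of one recording
#'
#' Raw energies are discrete-time integrals of the squared mode; normalized
#' energies are shares of the total over the retained levels (default) or
#' over the full decomposition. Levels beyond the decomposition depth are
#' zero-filled.
#'
#' @slot raw length-7 nonnegative raw energies.
#' @slot normalized length-7 normalized energies.
#' @slot nLevelsPresent how many of the 7 levels the decomposition reached.
#' @name EnergyVector-class
#' @rdname EnergyVector-class
#' @exportClass EnergyVector
setClass("EnergyVector", representation(
  raw = "numeric",
  normalized = "numeric",
  nLevelsPresent = "integer"
))

setValidity("EnergyVector", function(object) {
  if (length(object@raw) != 7 || length(object@normalized) != 7)
    return("raw and normalized must have length 7")
  if (any(object@raw < 0)) return("raw energies must be nonnegative")
  TRUE
})

#' SampEnVector: per-level sample entropy of one recording
#'
#' @slot values length-7 sample entropies (nats); undefined or absent
#'   levels are stored as 0 and flagged in `missingMask`.
#' @slot m embedding dimension used.
#' @slot rFraction tolerance as a fraction of each series' sd.
#' @slot nEffective points used per level after decimation.
#' @slot missingMask length-7 logical; TRUE where the value is a zero-fill
#'   (level absent or entropy undefined), not a computed entropy.
#' @name SampEnVector-class
#' @rdname SampEnVector-class
#' @exportClass SampEnVector
setClass("SampEnVector", representation(
  values = "numeric",
  m = "integer",
  rFraction = "numeric",
  nEffective = "integer",
  missingMask = "logical"
))

setValidity("SampEnVector", function(object) {
  if (length(object@values) != 7 || length(object@missingMask) != 7)
    return("values and missingMask must have length 7")
  if (any(!is.finite(object@values))) return("values must be finite (zero-filled if undefined)")
  TRUE
})

#' PulseFeatureSet: subjects-by-features container for the pulse pipeline
#'
#' A [SummarizedExperiment::SummarizedExperiment] with two 7 x n assays,
#' `energy` (normalized IMF energies) and `sampen` (per-IMF sample
#' entropies), rows `IMF1..IMF7` and one column per subject. `colData`
#' carries `subject_id`, `group`, decomposition depth and missing-entropy
#' flags.
#'
#' @name PulseFeatureSet-class
#' @rdname PulseFeatureSet-class
#' @exportClass PulseFeatureSet
setClass("PulseFeatureSet", contains = "SummarizedExperiment")

setValidity("PulseFeatureSet", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("energy", "sampen") %in% a))
    return("assays 'energy' and 'sampen' are required")
  if (nrow(object) != 7) return("feature sets carry exactly 7 IMF levels")
  if (!all(c("subject_id", "group") %in% colnames(SummarizedExperiment::colData(object))))
    return("colData must contain subject_id and group")
  TRUE
})

#' RankSumTable: per-level two-group rank-sum comparison
#'
#' @slot table data.frame with one row per analysed IMF level: `level`,
#'   `mean_rank_a`, `mean_rank_b`, `statistic` (Mann-Whitney U for group A),
#'   `p_value`.
#' @slot featureFamily `"energy"` or `"sampen"`.
#' @slot excludedLevels levels deliberately left out of the analysis.
#' @slot groupA,groupB group labels; A is the first factor level.
#' @slot nA,nB group sizes.
#' @name RankSumTable-class
#' @rdname RankSumTable-class
#' @exportClass RankSumTable
setClass("RankSumTable", representation(
  table = "data.frame",
  featureFamily = "character",
  excludedLevels = "integer",
  groupA = "character",
  groupB = "character",
  nA = "integer",
  nB = "integer"
))

setValidity("RankSumTable", function(object) {
  need <- c("level", "mean_rank_a", "mean_rank_b", "statistic", "p_value")
  if (!all(need %in% names(object@table))) return("table is missing required columns")
  p <- object@table$p_value
  if (any(p < 0 | p > 1, na.rm = TRUE)) return("p values must lie in [0, 1]")
  TRUE
})

#' ForestConfig: random-forest training and evaluation controls
#'
#' @slot nTrees trees per forest.
#' @slot mtryRule feature-sampling rule; `"sqrt_mall"` takes
#'   `floor(sqrt(m_all))` candidate features per split.
#' @slot seed integer seed governing folds and tree growing.
#' @slot kFolds folds of the stratified cross-validation.
#' @slot nRepeats repeats of the cross-validation with distinct fold draws.
#' @name ForestConfig-class
#' @rdname ForestConfig-class
#' @exportClass ForestConfig
setClass("ForestConfig", representation(
  nTrees = "integer",
  mtryRule = "character",
  seed = "integer",
  kFolds = "integer",
  nRepeats = "integer"
))

setValidity("ForestConfig", function(object) {
  if (object@nTrees < 1) return("nTrees must be >= 1")
  if (!identical(object@mtryRule, "sqrt_mall")) return("mtryRule must be 'sqrt_mall'")
  if (object@kFolds < 2) return("kFolds must be >= 2")
  if (object@nRepeats < 1) return("nRepeats must be >= 1")
  TRUE
})

#' RecognitionReport: recognition rates per feature set
#'
#' @slot rates data.frame with columns `feature_set` (sampen, energy,
#'   combined), `group` (CHD_like, normal_like, average), `mean` and `sd`
#'   of the recognition rate in percent across folds x repeats. The
#'   `average` rows are pooled proportions over both groups, not means of
#'   the per-group rates.
#' @slot oob named numeric, out-of-bag accuracy (percent) per feature set
#'   from a single forest on the full data, for reference.
#' @slot nPerGroup named integer, subjects per group.
#' @slot config the [ForestConfig-class] used.
#' @name RecognitionReport-class
#' @rdname RecognitionReport-class
#' @exportClass RecognitionReport
setClass("RecognitionReport", representation(
  rates = "data.frame",
  oob = "numeric",
  nPerGroup = "integer",
  config = "ForestConfig"
))

setValidity("RecognitionReport", function(object) {
  r <- object@rates
  if (!all(c("feature_set", "group", "mean", "sd") %in% names(r)))
    return("rates is missing required columns")
  if (any(r$mean < 0 | r$mean > 100)) return("rates must lie in [0, 100] percent")
  TRUE
})
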