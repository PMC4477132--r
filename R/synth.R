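#' Construct a synthetic-cohort configuration
#'
#' Builds a validated [CohortConfig-class]. Defaults (chosen per group by
#' [defaultCohortConfigs()]) encode the two study cohorts: 225 CHD-like and
#' 117 normal-like subjects, 60 s recordings at 720 Hz. The two groups are
#' separated by design: normal-like subjects carry strong broadband
#' (pink-noise) complexity, spreading their mode energy evenly across IMF
#' levels and raising mid-level sample entropy, while CHD-like subjects are
#' more regular and concentrate energy in a subject-specific narrowband
#' resonance whose level varies from subject to subject.
#'
#' @param nSubjects subjects in the cohort.
#' @param groupLabel `"CHD_like"` or `"normal_like"`.
#' @param heartRateBpm numeric `(mean, sd)` heart rate in beats/min.
#' @param systolicAmplitude numeric `(mean, sd)` systolic peak amplitude.
#' @param dicroticRatio dicrotic amplitude as a fraction of systolic.
#' @param dicroticDelay dicrotic delay as a fraction of the beat period.
#' @param systolicWidth,dicroticWidth Gaussian bump sd as period fractions.
#' @param hfComplexity broadband component amplitude (fraction of systolic).
#' @param hfBand broadband component frequency band (Hz).
#' @param baselineWanderAmp slow-drift sinusoid amplitude.
#' @param noiseSd additive white-noise sd.
#' @param resonanceAmp subject-specific narrowband component mean amplitude
#'   (fraction of systolic); 0 disables it.
#' @param resonanceFreqRange frequency range (Hz) the per-subject resonance
#'   frequency is drawn from (log-uniform).
#' @param durationS recording length (seconds).
#' @param fsHz sampling rate (Hz).
#' @param seed master seed; subject `i` uses stream `seed + i`.
#' @return a [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(nSubjects = 3, groupLabel = "normal_like",
#'                     durationS = 5, fsHz = 180, seed = 7)
#' rec <- generateRecording(cfg, 1)
#' length(pulseSamples(rec))
#' @export
cohortConfig <- function(nSubjects = 1,
                         groupLabel = c("CHD_like", "normal_like"),
                         heartRateBpm = c(72, 8),
                         systolicAmplitude = c(1.0, 0.15),
                         dicroticRatio = 0.4,
                         dicroticDelay = 0.35,
                         systolicWidth = 0.07,
                         dicroticWidth = 0.11,
                         hfComplexity = 0.1,
                         hfBand = c(1, 100),
                         baselineWanderAmp = 0.1,
                         noiseSd = 0.01,
                         resonanceAmp = 0,
                         resonanceFreqRange = c(2, 40),
                         durationS = 60,
                         fsHz = 720,
                         seed = 1L) {
  groupLabel <- match.arg(groupLabel)
  cfg <- new("CohortConfig",
             nSubjects = as.integer(nSubjects),
             groupLabel = groupLabel,
             heartRateBpm = as.numeric(heartRateBpm),
             systolicAmplitude = as.numeric(systolicAmplitude),
             dicroticRatio = as.numeric(dicroticRatio),
             dicroticDelay = as.numeric(dicroticDelay),
             systolicWidth = as.numeric(systolicWidth),
             dicroticWidth = as.numeric(dicroticWidth),
             hfComplexity = as.numeric(hfComplexity),
             hfBand = as.numeric(hfBand),
             baselineWanderAmp = as.numeric(baselineWanderAmp),
             noiseSd = as.numeric(noiseSd),
             resonanceAmp = as.numeric(resonanceAmp),
             resonanceFreqRange = as.numeric(resonanceFreqRange),
             durationS = as.numeric(durationS),
             fsHz = as.numeric(fsHz),
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Default two-cohort study design
#'
#' Returns the pair of group configurations the package uses as its study
#' conditions: cohort sizes 225 (CHD-like) and 117 (normal-like), 60 s
#' recordings at 720 Hz. Normal-like subjects have higher broadband
#' complexity and beat variability; CHD-like subjects are more regular but
#' carry a subject-specific narrowband resonance that concentrates their
#' spectral energy at a level varying across subjects. Under this design
#' normal-like normalized IMF energies stochastically exceed CHD-like ones
#' at every retained level, and mid-level (IMF3-IMF6) sample entropy is
#' higher in the normal-like group.
#'
#' @param durationS,fsHz acquisition settings shared by both groups; shorter
#'   recordings keep simulation studies fast while leaving the effect
#'   structure unchanged.
#' @param seedChd,seedNormal master seeds of the two cohorts.
#' @param nChd,nNormal cohort sizes.
#' @param effectSize scales the group separation from 0 (identical
#'   configurations: both groups generated from the CHD-like parameter set)
#'   to 1 (full designed contrast); intermediate values interpolate the
#'   group-differing parameters linearly.
#' @return named list with elements `chd` and `normal`.
#' @export
defaultCohortConfigs <- function(durationS = 60, fsHz = 720,
                                 seedChd = 101L, seedNormal = 500202L,
                                 nChd = 225, nNormal = 117,
                                 effectSize = 1) {
  stopifnot(effectSize >= 0, effectSize <= 1)
  # CHD-like baseline parameter set
  chd <- list(hfComplexity = 0.15, dicroticRatio = 0.30, hrSd = 8,
              ampSd = 0.18, resonanceAmp = 1.2, sysW = 0.10, dicW = 0.14)
  # normal-like contrasts at full effect
  nrm <- list(hfComplexity = 0.40, dicroticRatio = 0.50, hrSd = 9,
              ampSd = 0.20, resonanceAmp = 0.25, sysW = 0.035, dicW = 0.055)
  # symmetric contrast scaling: both groups contract toward the midpoint as
  # effectSize drops, meeting at identical configurations at 0
  mixc <- function(field) {
    ctr <- (chd[[field]] + nrm[[field]]) / 2
    ctr + effectSize * (chd[[field]] - ctr)
  }
  mix <- function(field) {
    ctr <- (chd[[field]] + nrm[[field]]) / 2
    ctr + effectSize * (nrm[[field]] - ctr)
  }
  list(
    chd = cohortConfig(
      nSubjects = nChd, groupLabel = "CHD_like",
      heartRateBpm = c(72, mixc("hrSd")),
      systolicAmplitude = c(1.0, mixc("ampSd")),
      dicroticRatio = mixc("dicroticRatio"),
      systolicWidth = mixc("sysW"), dicroticWidth = mixc("dicW"),
      hfComplexity = mixc("hfComplexity"),
      hfBand = c(2, 180),
      resonanceAmp = mixc("resonanceAmp"),
      resonanceFreqRange = c(2 * (4.47 / 2)^(1 - effectSize), 150),
      noiseSd = 0.08,
      durationS = durationS, fsHz = fsHz, seed = seedChd),
    normal = cohortConfig(
      nSubjects = nNormal, groupLabel = "normal_like",
      heartRateBpm = c(72, mix("hrSd")),
      systolicAmplitude = c(1.0, mix("ampSd")),
      dicroticRatio = mix("dicroticRatio"),
      systolicWidth = mix("sysW"), dicroticWidth = mix("dicW"),
      hfComplexity = mix("hfComplexity"),
      hfBand = c(2, 180),
      resonanceAmp = mix("resonanceAmp"),
      resonanceFreqRange = c(10 * (4.47 / 10)^(1 - effectSize), 150),
      noiseSd = 0.08,
      durationS = durationS, fsHz = fsHz, seed = seedNormal)
  )
}

# Band-limited 1/f ("pink") noise via FFT shaping, unit variance.
pink_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  if (n < 4) return(w)
  W <- stats::fft(w)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)                      # fold to two-sided magnitudes
  g <- ifelse(f >= band[1] & f <= band[2], 1 / sqrt(pmax(f, band[1])), 0)
  y <- Re(stats::fft(W * g, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y <- y / s
  y
}

#' Generate one synthetic pulse recording
#'
#' Builds a quasi-periodic pressure waveform: per beat, a Gaussian systolic
#' bump plus a delayed, smaller dicrotic bump; beat periods and amplitudes
#' jitter around subject-level means; a slow (< 0.5 Hz) sinusoidal baseline
#' wander, a band-limited pink-noise complexity component, an optional
#' subject-specific narrowband resonance, and white measurement noise are
#' added. Deterministic given `(config@seed, subjectIndex)`.
#'
#' @param config a [CohortConfig-class].
#' @param subjectIndex 1-based subject index within the cohort.
#' @return a [PulseRecording-class].
#' @export
generateRecording <- function(config, subjectIndex = 1L) {
  validObject(config)
  stopifnot(subjectIndex >= 1)
  fs <- config@fsHz
  n <- round(config@durationS * fs)
  t <- (seq_len(n) - 1) / fs
  hr <- config@heartRateBpm
  amp <- config@systolicAmplitude

  with_local_seed(config@seed + subjectIndex, {
    # subject-level draws
    hr_subj <- min(200, max(30, stats::rnorm(1, hr[1], hr[2])))
    amp_subj <- max(0.05 * amp[1], stats::rnorm(1, amp[1], amp[2]))
    fr_lo <- config@resonanceFreqRange[1]
    fr_hi <- config@resonanceFreqRange[2]
    f_res <- exp(stats::runif(1, log(fr_lo), log(fr_hi)))
    a_res <- config@resonanceAmp * amp_subj * stats::rlnorm(1, 0, 0.8)
    phi_res <- stats::runif(1, 0, 2 * pi)
    f_bw <- stats::runif(1, 0.05, 0.45)
    phi_bw <- stats::runif(1, 0, 2 * pi)
    # subjects differ in how much broadband complexity they carry; the
    # log-normal spread makes the spectral profile idiosyncratic per subject
    hf_subj <- config@hfComplexity * stats::rlnorm(1, 0, 0.8)

    # beat train: period jitter derives from the heart-rate sd (half weight)
    Tm <- 60 / hr_subj
    period_sd <- 0.5 * 60 * hr[2] / hr[1]^2
    n_beats <- ceiling((config@durationS + 4 * Tm) / (0.5 * Tm))
    periods <- pmax(0.4 * Tm, stats::rnorm(n_beats, Tm, period_sd))
    onsets <- -Tm + c(0, cumsum(periods[-n_beats]))
    beat_amps <- pmax(0.05 * amp[1], stats::rnorm(n_beats, amp_subj, 0.5 * amp[2]))

    x <- numeric(n)
    for (b in seq_len(n_beats)) {
      P <- periods[b]; o <- onsets[b]
      if (o > config@durationS + P) break
      lo <- max(1L, floor((o - 0.2 * P) * fs) + 1L)
      hi <- min(n, ceiling((o + 1.4 * P) * fs) + 1L)
      if (lo > hi) next
      tt <- t[lo:hi]
      sys_peak <- o + 0.15 * P
      x[lo:hi] <- x[lo:hi] +
        beat_amps[b] * exp(-0.5 * ((tt - sys_peak) / (config@systolicWidth * P))^2) +
        beat_amps[b] * config@dicroticRatio *
          exp(-0.5 * ((tt - sys_peak - config@dicroticDelay * P) /
                        (config@dicroticWidth * P))^2)
    }

    x <- x + config@baselineWanderAmp * sin(2 * pi * f_bw * t + phi_bw)
    hf <- pink_noise(n, fs, config@hfBand)
    x <- x + hf_subj * amp_subj * hf
    x <- x + a_res * sin(2 * pi * f_res * t + phi_res)
    x <- x + config@noiseSd * stats::rnorm(n)

    prefix <- if (config@groupLabel == "CHD_like") "CHD" else "NRM"
    new("PulseRecording", samples = x, fsHz = fs,
        subjectId = sprintf("%s_%03d", prefix, subjectIndex),
        groupLabel = config@groupLabel)
  })
}

#' Generate two labelled cohorts of synthetic pulse recordings
#'
#' @param chdConfig,normalConfig [CohortConfig-class] objects for the two
#'   groups; defaults are the package's study design
#'   ([defaultCohortConfigs()]).
#' @return list of [PulseRecording-class], CHD-like subjects first.
#' @examples
#' cfgs <- defaultCohortConfigs(durationS = 4, fsHz = 180,
#'                              nChd = 2, nNormal = 2)
#' recs <- generateCohorts(cfgs$chd, cfgs$normal)
#' vapply(recs, function(r) r@groupLabel, "")
#' @export
generateCohorts <- function(chdConfig = defaultCohortConfigs()$chd,
                            normalConfig = defaultCohortConfigs()$normal) {
  validObject(chdConfig); validObject(normalConfig)
  if (chdConfig@groupLabel == normalConfig@groupLabel)
    stop("invalid 'groupLabel': the two cohort configs must label different groups")
  c(lapply(seq_len(chdConfig@nSubjects), function(i) generateRecording(chdConfig, i)),
    lapply(seq_len(normalConfig@nSubjects), function(i) generateRecording(normalConfig, i)))
}

#' Write / read a pulse recording as single-column CSV
#'
#' The file holds one `amplitude` column preceded by a comment line
#' `# fs_hz=<value>` carrying the sampling rate.
#'
#' @param recording a [PulseRecording-class].
#' @param path file path.
#' @return `writePulseCSV` returns `path` invisibly; `readPulseCSV` returns
#'   a [PulseRecording-class].
#' @export
writePulseCSV <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.10g", recording@fsHz), con)
  writeLines("amplitude", con)
  writeLines(format(recording@samples, digits = 17, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' @rdname writePulseCSV
#' @param subjectId,groupLabel metadata to attach on read (the CSV itself
#'   carries only the signal; cohort metadata lives in the manifest).
#' @export
readPulseCSV <- function(path, subjectId = "unknown", groupLabel = "unknown") {
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("#\\s*fs_hz=([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2) stop("missing '# fs_hz=' header comment in ", path)
  dat <- utils::read.csv(path, comment.char = "#")
  new("PulseRecording", samples = as.numeric(dat$amplitude),
      fsHz = as.numeric(m[2]), subjectId = subjectId, groupLabel = groupLabel)
}

#' Write a cohort of recordings plus manifest
#'
#' Writes one CSV per recording and a `manifest.csv` with columns
#' `subject_id,group_label,path`.
#'
#' @param recordings list of [PulseRecording-class].
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
writeCohortCSV <- function(recordings, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(recordings, function(r) {
    p <- file.path(dir, paste0(r@subjectId, ".csv"))
    writePulseCSV(r, p)
    data.frame(subject_id = r@subjectId, group_label = r@groupLabel,
               path = basename(p), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' @rdname writeCohortCSV
#' @param manifestPath path to a cohort `manifest.csv`.
#' @export
readCohortCSV <- function(manifestPath) {
  manifest <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  base <- dirname(manifestPath)
  lapply(seq_len(nrow(manifest)), function(i) {
    readPulseCSV(file.path(base, manifest$path[i]),
                 subjectId = manifest$subject_id[i],
                 groupLabel = manifest$group_label[i])
  })
}

#' @rdname accessors
#' @param x an object of one of the package's classes.
#' @export
setMethod("pulseSamples", "PulseRecording", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("fsHz", "PulseRecording", function(x) x@fsHz)

setMethod("show", "PulseRecording", function(object) {
  cat(sprintf("PulseRecording '%s' (%s): %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, object@groupLabel, length(object@samples),
              object@fsHz, length(object@samples) / object@fsHz))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d %s subjects, %.3g s @ %g Hz, seed %d\n",
              object@nSubjects, object@groupLabel, object@durationS,
              object@fsHz, object@seed))
  cat(sprintf("  HR %g±%g bpm, systolic %g±%g, dicrotic %g @ +%g period\n",
              object@heartRateBpm[1], object@heartRateBpm[2],
              object@systolicAmplitude[1], object@systolicAmplitude[2],
              object@dicroticRatio, object@dicroticDelay))
  cat(sprintf("  hf %g in [%g, %g] Hz, wander %g, noise %g, resonance %g in [%g, %g] Hz\n",
              object@hfComplexity, object@hfBand[1], object@hfBand[2],
              object@baselineWanderAmp, object@noiseSd, object@resonanceAmp,
              object@resonanceFreqRange[1], object@resonanceFreqRange[2]))
})
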