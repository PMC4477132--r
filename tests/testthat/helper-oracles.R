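# Independent oracles used to cross-check the package's optimized paths.

# Brute-force extrema scan: compare each interior point with its neighbours,
# collapsing flat plateaus to their midpoint (rounded down).
oracle_extrema <- function(x) {
  n <- length(x)
  maxima <- integer(0); minima <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L   # plateau [i, j]
    if (j <= n - 1L) {
      left <- x[i - 1L]; right <- x[j + 1L]
      mid <- (i + j) %/% 2L
      if (x[i] > left && x[i] > right) maxima <- c(maxima, mid)
      if (x[i] < left && x[i] < right) minima <- c(minima, mid)
    }
    i <- j + 1L
  }
  list(maxima = maxima, minima = minima)
}

# Envelope mean re-derived with R's own natural spline (stats::splinefun),
# applying the documented mirror rule: two extrema reflected across each end.
oracle_envelope_mean <- function(x, min_extrema = 2L) {
  ex <- oracle_extrema(x)
  if (length(ex$maxima) < min_extrema || length(ex$minima) < min_extrema)
    return(NULL)
  n <- length(x)
  mirror <- function(idx) {
    k <- min(2L, length(idx))
    t <- c(2 - rev(idx[seq_len(k)]), idx, 2 * n - rev(idx)[seq_len(k)])
    list(t = t, y = x[c(rev(idx[seq_len(k)]), idx, rev(idx)[seq_len(k)])])
  }
  up <- mirror(ex$maxima); lo <- mirror(ex$minima)
  fu <- stats::splinefun(up$t, up$y, method = "natural")
  fl <- stats::splinefun(lo$t, lo$y, method = "natural")
  (fu(seq_len(n)) + fl(seq_len(n))) / 2
}

# Naive transcription of the sample-entropy definition: per-template match
# probabilities under the Chebyshev distance with strict tolerance,
# self-matches excluded, averaged and combined as -ln(A/B).
oracle_sampen <- function(u, m, r) {
  N <- length(u)
  nv <- N - m
  Bi <- numeric(nv); Ai <- numeric(nv)
  js <- seq_len(nv)
  for (i in seq_len(nv)) {
    dm <- abs(u[i] - u[js])
    for (k in seq_len(m - 1)) dm <- pmax(dm, abs(u[i + k] - u[js + k]))
    dm[i] <- Inf                               # exclude the self-match
    Bi[i] <- sum(dm < r)
    dm1 <- pmax(dm, abs(u[i + m] - u[js + m]))
    Ai[i] <- sum(dm1 < r)
  }
  A <- sum(Ai); B <- sum(Bi)                   # common denominators cancel
  if (A == 0 || B == 0) return(list(value = NA_real_, A = A / 2, B = B / 2))
  list(value = -log(A / B), A = A / 2, B = B / 2)
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
oracle_exact_ranksum_p <- function(a, b) {
  na <- length(a); N <- na + length(b)
  r <- rank(c(a, b))
  obs <- sum(r[seq_len(na)])
  combs <- utils::combn(N, na)
  null_stats <- colSums(matrix(r[combs], nrow = na))
  mu <- na * (N + 1) / 2
  mean(abs(null_stats - mu) >= abs(obs - mu) - 1e-9)
}

# Small, fast cohort settings shared by several tests: short recordings with
# the default two-group effect structure.
tiny_cohorts <- function(n = 8, dur = 4, fs = 240, effectSize = 1) {
  defaultCohortConfigs(durationS = dur, fsHz = fs, nChd = n, nNormal = n,
                       effectSize = effectSize)
}
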