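# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user RNG.
with_local_seed <- function(seed, code) {
  seed <- as.integer(seed %% .Machine$integer.max)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Evenly decimate a series to at most max_points samples (stride subsampling;
# entropy estimation after EMD does not need an anti-alias stage).
decimate_series <- function(x, max_points) {
  n <- length(x)
  if (n <= max_points) return(x)
  stride <- ceiling(n / max_points)
  x[seq(1L, n, by = stride)]
}
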