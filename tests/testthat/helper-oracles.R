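# Brute-force reference implementations, kept deliberately independent of
# the package's vectorized code paths: plain loops over definitions.

# nearest-event lag: all-pairs minimization, ties to the earlier test event
oracle_nearest_lag <- function(reference, test) {
  vapply(reference, function(r) {
    if (!length(test)) return(NA_real_)
    d <- abs(test - r)
    best <- which(d == min(d))
    t_star <- min(test[best])   # earlier event wins ties
    t_star - r
  }, numeric(1))
}

# two-sided max dilation speed over usable samples, by explicit neighbor scan
oracle_speed <- function(time, diameter, ok) {
  idx <- which(ok)
  out <- rep(NA_real_, length(time))
  for (j in seq_along(idx)) {
    i <- idx[j]
    cand <- c()
    if (j > 1) {
      p <- idx[j - 1]
      cand <- c(cand, abs(diameter[i] - diameter[p]) / (time[i] - time[p]))
    }
    if (j < length(idx)) {
      nx <- idx[j + 1]
      cand <- c(cand, abs(diameter[nx] - diameter[i]) / (time[nx] - time[i]))
    }
    out[i] <- max(cand)
  }
  out
}

# median + k*MAD (unscaled) outlier flags on the oracle speeds
oracle_mad_flags <- function(time, diameter, ok, multiplier = 3) {
  sp <- oracle_speed(time, diameter, ok)
  spv <- sp[!is.na(sp)]
  med <- median(spv)
  madv <- median(abs(spv - med))
  if (madv == 0) return(rep(FALSE, length(time)))
  !is.na(sp) & sp > med + multiplier * madv
}

# sparsity rule by repeated explicit run scanning until stable
oracle_sparsity <- function(ok, dt_ms, max_island, flank_gap) {
  repeat {
    changed <- FALSE
    n <- length(ok)
    i <- 1
    while (i <= n) {
      if (ok[i]) {
        j <- i
        while (j < n && ok[j + 1]) j <- j + 1
        island_ms <- (j - i + 1) * dt_ms
        left_ms <- if (i == 1) Inf else {
          k <- i - 1; while (k > 1 && !ok[k - 1]) k <- k - 1
          (i - k) * dt_ms
        }
        right_ms <- if (j == n) Inf else {
          k <- j + 1; while (k < n && !ok[k + 1]) k <- k + 1
          (k - j) * dt_ms
        }
        if (island_ms < max_island && left_ms > flank_gap && right_ms > flank_gap) {
          ok[i:j] <- FALSE
          changed <- TRUE
        }
        i <- j + 1
      } else i <- i + 1
    }
    if (!changed) return(ok)
  }
}

# first derivative: explicit one-sided/central finite differences
oracle_derivative <- function(time, x) {
  n <- length(x)
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / (time[2] - time[1])
  v[n] <- (x[n] - x[n - 1]) / (time[n] - time[n - 1])
  for (i in seq_len(n - 2) + 1)
    v[i] <- (x[i + 1] - x[i - 1]) / (time[i + 1] - time[i - 1])
  v
}

# small fixture builders -----------------------------------------------------

make_trace <- function(n = 200, fs = 200, f = function(t) 5 + 0.1 * t,
                       valid = rep(TRUE, n)) {
  t <- seq(0, by = 1 / fs, length.out = n)
  d <- f(t)
  d[!valid] <- NA
  pupil_trace(t, d, valid)
}

random_masked_trace <- function(n = 400, fs = 200, p_invalid = 0.2) {
  t <- seq(0, by = 1 / fs, length.out = n)
  d <- 5 + cumsum(rnorm(n, 0, 0.01))
  valid <- runif(n) > p_invalid
  if (sum(valid) < 5) valid[sample.int(n, 5)] <- TRUE
  d[!valid] <- NA
  pupil_trace(t, d, valid)
}

quiet_config <- function(...) {
  # generator with every stochastic nuisance disabled; overrides via ...
  synthetic_config(noise_sd = 0, interference_amp = 0, quantization_sd = 0,
                   drift_amplitude = 0, artifact_gap_rate = 0,
                   artifact_spike_rate = 0, ...)
}

write_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
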