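#' Dilation velocity peak detection configuration
#'
#' Defaults follow the published detector: Savitzky-Golay smoothing with
#' window length 11 and polynomial order 3, a candidate threshold of 2.5
#' standard deviations on the first derivative, and 1500-ms non-maximal
#' suppression.
#'
#' @param sg_window Savitzky-Golay window length in samples (odd,
#'   greater than `sg_order`).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param threshold_sd derivative threshold in SD units (> 0).
#' @param nms_interval non-maximal suppression spacing, ms (>= 0).
#' @param threshold_center `"mean"` (default): threshold is
#'   mean + k x SD of the derivative over the analyzed segment;
#'   `"zero"`: k x SD around zero.
#' @return a list of class `peak_config`.
#' @export
peak_config <- function(sg_window = 11, sg_order = 3, threshold_sd = 2.5,
                        nms_interval = 1500,
                        threshold_center = c("mean", "zero")) {
  threshold_center <- match.arg(threshold_center)
  if (sg_window %% 2 != 1 || sg_window <= sg_order)
    stop("sg_window must be odd and greater than sg_order", call. = FALSE)
  if (threshold_sd <= 0) stop("threshold_sd must be > 0", call. = FALSE)
  if (nms_interval < 0) stop("nms_interval must be >= 0", call. = FALSE)
  structure(list(sg_window = sg_window, sg_order = sg_order,
                 threshold_sd = threshold_sd, nms_interval = nms_interval,
                 threshold_center = threshold_center),
            class = "peak_config")
}

#' Fill gaps and Savitzky-Golay smooth a preprocessed trace
#'
#' Interior unusable samples are linearly interpolated between their usable
#' neighbors; the filled core is then smoothed with the configured
#' Savitzky-Golay filter. Leading and trailing unusable runs are not
#' extrapolated and remain missing.
#'
#' @param trace a preprocessed [pupil_trace()].
#' @param config a [peak_config()].
#' @return list with `time` and `value` (smoothed diameter; `NA` outside the
#'   usable core).
#' @export
fill_and_smooth <- function(trace, config = peak_config()) {
  ok <- which(ok_mask(trace))
  if (length(ok) < config$sg_window)
    stop(sprintf("fewer usable samples (%d) than the smoothing window (%d)",
                 length(ok), config$sg_window), call. = FALSE)
  core <- ok[1]:ok[length(ok)]
  filled <- stats::approx(trace$time[ok], trace$diameter[ok],
                          xout = trace$time[core])$y
  smoothed <- signal::sgolayfilt(filled, p = config$sg_order,
                                 n = config$sg_window)
  value <- rep(NA_real_, n_samples(trace))
  value[core] <- smoothed
  list(time = trace$time, value = value)
}

#' First derivative of a smoothed series
#'
#' Central differences on interior samples, one-sided differences at the
#' ends of the usable core, divided by the actual sample spacing.
#'
#' @param series list with `time` and `value` (as from [fill_and_smooth()]).
#' @return list with `time` and `velocity` (units/s; `NA` outside the core).
#' @export
velocity <- function(series) {
  t <- series$time; x <- series$value
  n <- length(x)
  v <- rep(NA_real_, n)
  core <- which(!is.na(x))
  if (length(core) >= 2) {
    i0 <- core[1]; i1 <- core[length(core)]
    idx <- i0:i1
    m <- length(idx)
    xv <- x[idx]; tv <- t[idx]
    vi <- numeric(m)
    vi[1] <- (xv[2] - xv[1]) / (tv[2] - tv[1])
    vi[m] <- (xv[m] - xv[m - 1]) / (tv[m] - tv[m - 1])
    if (m > 2)
      vi[2:(m - 1)] <- (xv[3:m] - xv[1:(m - 2)]) / (tv[3:m] - tv[1:(m - 2)])
    v[idx] <- vi
  }
  list(time = t, velocity = v)
}

# strict local maxima with plateau handling: a flat plateau higher than both
# neighbors contributes its midpoint sample
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    if (i == 1 || i == k) next
    if (r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1])
      out <- c(out, starts[i] + (ends[i] - starts[i]) %/% 2L)
  }
  out
}

#' Detect dilation velocity peaks
#'
#' Candidates are strict local maxima of the derivative whose value exceeds
#' the threshold (mean + `threshold_sd` x SD of the derivative over the
#' analyzed segment). Non-maximal suppression then processes candidates in
#' descending derivative order, accepting a candidate only if it lies at
#' least `nms_interval` ms from every already-accepted peak.
#'
#' @param vel list with `time` and `velocity` (as from [velocity()]).
#' @param config a [peak_config()].
#' @return a data.frame of class `peak_train` with columns `time` and
#'   `velocity`, sorted by time; attribute `threshold` carries the cutoff.
#' @export
detect_velocity_peaks <- function(vel, config = peak_config()) {
  v <- vel$velocity; t <- vel$time
  seg <- !is.na(v)
  empty <- data.frame(time = numeric(0), velocity = numeric(0))
  class(empty) <- c("peak_train", "data.frame")
  if (!any(seg)) {
    warning("all-missing segment; no peaks", call. = FALSE)
    attr(empty, "threshold") <- NA_real_
    return(empty)
  }
  mu <- if (config$threshold_center == "mean") mean(v[seg]) else 0
  sdv <- stats::sd(v[seg])
  # an (up to rounding) constant derivative carries no peaks
  if (sdv < .Machine$double.eps^0.5 * max(1, abs(mu))) {
    attr(empty, "threshold") <- mu
    return(empty)
  }
  thr <- mu + config$threshold_sd * sdv
  cand <- .local_maxima(replace(v, !seg, -Inf))
  cand <- cand[v[cand] > thr]
  if (!length(cand)) {
    attr(empty, "threshold") <- thr
    return(empty)
  }
  ord <- cand[order(-v[cand], t[cand])]
  acc <- integer(0)
  min_gap <- config$nms_interval / 1000
  for (i in ord) {
    if (!length(acc) || all(abs(t[i] - t[acc]) >= min_gap)) acc <- c(acc, i)
  }
  acc <- sort(acc)
  out <- data.frame(time = t[acc], velocity = v[acc])
  class(out) <- c("peak_train", "data.frame")
  attr(out, "threshold") <- thr
  out
}

#' Count peaks within a phase window
#'
#' Half-open assignment: a peak exactly at the window end belongs to the
#' next phase.
#'
#' @param peaks a `peak_train` (or any data.frame with a `time` column).
#' @param window a [phase_window()].
#' @return integer count.
#' @export
peaks_per_phase <- function(peaks, window) {
  sum(peaks$time >= window$start & peaks$time < window$end)
}

#' Mean pupil size within a phase window
#'
#' Mean of the usable (valid or interpolated) diameter samples with
#' `start <= t < end`; `NA` with a warning when the phase holds no usable
#' sample.
#'
#' @param trace a preprocessed [pupil_trace()].
#' @param window a [phase_window()].
#' @return mean diameter (device units) or `NA`.
#' @export
mean_pupil_size_per_phase <- function(trace, window) {
  in_win <- trace$time >= window$start & trace$time < window$end
  use <- in_win & ok_mask(trace)
  if (!any(use)) {
    warning("no usable samples in phase window", call. = FALSE)
    return(NA_real_)
  }
  mean(trace$diameter[use])
}

#' Detect peaks for every trial of a participant
#'
#' The detector is run per trial (smoothing, derivative and the SD threshold
#' are computed over each trial's continuous segment).
#'
#' @param trace the participant's preprocessed [pupil_trace()].
#' @param schedule the participant's [default_schedule()] table.
#' @param config a [peak_config()].
#' @return data.frame with columns `trial`, `time`, `velocity`.
#' @export
detect_trial_peaks <- function(trace, schedule, config = peak_config()) {
  out <- lapply(unique(schedule$trial), function(tr) {
    rows <- schedule[schedule$trial == tr, ]
    win <- phase_window("baseline", min(rows$start), max(rows$end))
    seg <- segment_phase(trace, win)
    pk <- detect_velocity_peaks(velocity(fill_and_smooth(seg, config)), config)
    if (nrow(pk)) data.frame(trial = tr, time = pk$time, velocity = pk$velocity)
    else data.frame(trial = integer(0), time = numeric(0), velocity = numeric(0))
  })
  do.call(rbind, out)
}
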