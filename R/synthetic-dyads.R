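#' Configuration for the synthetic dyad generator
#'
#' Generates dyadic recordings with known ground truth: coupled blink point
#' processes, pupil traces with event-related dilations and injected sensor
#' artifacts, and fixation/saccade streams, on the study design of three
#' trials of three contiguous 30-s phases (baseline, audio, silence).
#'
#' Defaults encode the study conditions. Blink coupling is phase dependent
#' (attentional coupling is strongest at baseline, weakest while the
#' partners' goals diverge during audio). Dilation kinetics follow the
#' physiological anchor: the response begins around 800 ms after an arousal
#' event and peaks around 2 s. Measurement noise is modeled as bounded
#' device noise — a small periodic sensor-interference component plus
#' uniform quantization jitter — superimposed on slow Gaussian physiological
#' fluctuation (hippus band); bounded jitter is what video pupillometry
#' produces and is what gives the median + k*MAD dilation-speed rule a
#' meaningful, stable threshold.
#'
#' @param seed integer seed used by [assemble_dyad()] and
#'   [simulate_cohort()]; `NULL` leaves the RNG state untouched.
#' @param blink_rate_listener,blink_rate_observer Poisson rates (events/s)
#'   of the listener train and of the observer's independent (uncoupled)
#'   train. Observers blink less: their monitoring task suppresses blinking.
#' @param coupling_prob probability that a listener blink elicits a coupled
#'   observer blink; a scalar, or a named vector over phases
#'   (`baseline`, `audio`, `silence`).
#' @param coupling_dyad_sd SD of a per-dyad random shift of the coupling
#'   probabilities on the logit scale. Dyads differ substantially in how
#'   tightly they couple (in the study, dyad differences explained far more
#'   synchrony variance than the manipulations); 0 disables the
#'   heterogeneity.
#' @param coupling_lag_mean,coupling_lag_sd seconds; coupled observer blinks
#'   occur at listener onset + Normal(mean, sd) truncated to +/- 1.5 s.
#' @param blink_refractory_s minimum spacing between observer blinks;
#'   closer onsets are merged (physiological refractory period).
#' @param blink_dur_meanlog,blink_dur_sdlog log-normal blink duration
#'   parameters (seconds).
#' @param pupil_baseline mean pupil diameter (device units, mm assumed).
#' @param dilation_event_rate rate of planted arousal events (events/s),
#'   thinned to `dilation_min_sep` so individual responses stay resolvable.
#' @param dilation_min_sep minimum spacing between planted events, seconds.
#' @param dilation_onset_latency,dilation_peak_latency seconds after an
#'   event at which the dilation starts and peaks.
#' @param dilation_amplitude peak kernel amplitude, diameter units.
#' @param dilation_decay_tau exponential decay constant after the peak, s.
#' @param noise_sd SD of the smooth physiological noise, diameter units.
#' @param noise_corr_s correlation length (Gaussian kernel SD) of the
#'   physiological noise, seconds.
#' @param interference_amp,interference_freq amplitude (diameter units) and
#'   frequency (Hz) of the periodic sensor-interference component.
#' @param quantization_sd SD of the uniform quantization jitter.
#' @param drift_amplitude,drift_period slow sinusoidal baseline drift.
#' @param artifact_gap_rate rate (events/s) of tracking-loss gaps; gap
#'   durations are uniform on `gap_dur_range`.
#' @param gap_dur_range length-2 numeric, seconds.
#' @param artifact_spike_rate rate (events/s) of single-sample spikes of
#'   height `spike_amplitude`.
#' @param spike_amplitude diameter units.
#' @param fixation_median_ms named vector of per-phase median fixation
#'   durations (ms); fixations during the baseline cross are long, mutual
#'   gaze promotes active scanning with short fixations.
#' @param fixation_sdlog log-normal sdlog of fixation durations.
#' @param saccade_dur_ms saccade duration between fixations, ms.
#' @param sampling_rate Hz (default 200).
#' @param phase_length seconds per phase (default 30).
#' @param n_trials trials per recording (default 3).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = NULL,
                             blink_rate_listener = 0.25,
                             blink_rate_observer = 0.05,
                             coupling_prob = c(baseline = 0.4, audio = 0.1,
                                               silence = 0.25),
                             coupling_dyad_sd = 1.0,
                             coupling_lag_mean = 0.2,
                             coupling_lag_sd = 0.3,
                             blink_refractory_s = 0.1,
                             blink_dur_meanlog = log(0.12),
                             blink_dur_sdlog = 0.3,
                             pupil_baseline = 5.0,
                             dilation_event_rate = 0.06,
                             dilation_min_sep = 3.0,
                             dilation_onset_latency = 0.8,
                             dilation_peak_latency = 2.0,
                             dilation_amplitude = 0.5,
                             dilation_decay_tau = 3.0,
                             noise_sd = 0.05,
                             noise_corr_s = 0.8,
                             interference_amp = 0.015,
                             interference_freq = 47,
                             quantization_sd = 5e-4,
                             drift_amplitude = 0.1,
                             drift_period = 60,
                             artifact_gap_rate = 0.01,
                             gap_dur_range = c(0.08, 0.3),
                             artifact_spike_rate = 0.02,
                             spike_amplitude = 0.3,
                             fixation_median_ms = c(baseline = 2800,
                                                    audio = 650,
                                                    silence = 700),
                             fixation_sdlog = 0.4,
                             saccade_dur_ms = 30,
                             sampling_rate = 200,
                             phase_length = 30,
                             n_trials = 3) {
  cfg <- as.list(environment())
  rates <- c(cfg$blink_rate_listener, cfg$blink_rate_observer,
             cfg$dilation_event_rate, cfg$artifact_gap_rate,
             cfg$artifact_spike_rate)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (any(cfg$coupling_prob < 0 | cfg$coupling_prob > 1))
    stop("coupling_prob must lie in [0, 1]", call. = FALSE)
  if (cfg$coupling_dyad_sd < 0)
    stop("coupling_dyad_sd must be >= 0", call. = FALSE)
  if (cfg$dilation_peak_latency <= cfg$dilation_onset_latency)
    stop("dilation_peak_latency must exceed dilation_onset_latency", call. = FALSE)
  if (cfg$sampling_rate <= 0 || cfg$phase_length <= 0 || cfg$n_trials < 1)
    stop("invalid design parameters", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

# coupling probability for a vector of onset times, honoring per-phase values
.coupling_at <- function(config, onsets, schedule = NULL) {
  cp <- config$coupling_prob
  if (length(cp) == 1 || is.null(schedule)) return(rep(cp[[1]], length(onsets)))
  out <- rep(cp[[1]], length(onsets))
  for (i in seq_len(nrow(schedule))) {
    in_ph <- onsets >= schedule$start[i] & onsets < schedule$end[i]
    out[in_ph] <- cp[[schedule$phase[i]]]
  }
  out
}

# keep onsets spaced by at least the refractory period (earlier onset wins)
.refractory_merge <- function(onsets, refractory) {
  if (length(onsets) < 2) return(onsets)
  keep <- rep(TRUE, length(onsets))
  last <- onsets[1]
  for (i in seq_along(onsets)[-1]) {
    if (onsets[i] - last < refractory) keep[i] <- FALSE else last <- onsets[i]
  }
  onsets[keep]
}

# truncated normal lags via rejection; sd = 0 degenerates to the mean
.rtrunc_lag <- function(n, mean, sd, bound = 1.5) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[abs(x) <= bound])
  }
  out[seq_len(n)]
}

#' Generate coupled dyadic blink onset trains
#'
#' The listener train is homogeneous Poisson. Each listener blink
#' independently elicits a coupled observer blink with probability
#' `coupling_prob` at a truncated-normal lag; independent observer blinks
#' are superimposed as a second Poisson train. Observer onsets closer than
#' the refractory period are merged (the earlier onset is kept).
#'
#' @param config a [synthetic_config()].
#' @param duration recording length in seconds.
#' @param schedule optional [default_schedule()] table; enables per-phase
#'   coupling probabilities.
#' @param seed optional integer; if given, the RNG is seeded locally.
#' @return list with `listener` (sorted onsets), `observer` (sorted onsets)
#'   and `ground_truth`: data.frames labeling each onset (`coupled` flag for
#'   the listener train meaning "elicited a coupled partner blink"; `source`
#'   in `coupled`/`independent` for the observer train).
#' @export
generate_blink_trains <- function(config, duration, schedule = NULL,
                                  seed = config$seed) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  listener <- .refractory_merge(
    sort(stats::runif(stats::rpois(1, config$blink_rate_listener * duration),
                      0, duration)),
    config$blink_refractory_s)
  cp <- .coupling_at(config, listener, schedule)
  elicits <- stats::runif(length(listener)) < cp
  lags <- .rtrunc_lag(sum(elicits), config$coupling_lag_mean,
                      config$coupling_lag_sd)
  coupled <- listener[elicits] + lags
  coupled <- coupled[coupled >= 0 & coupled < duration]
  indep <- sort(stats::runif(stats::rpois(1, config$blink_rate_observer * duration),
                             0, duration))
  obs <- data.frame(onset = c(coupled, indep),
                    source = rep(c("coupled", "independent"),
                                 c(length(coupled), length(indep))))
  obs <- obs[order(obs$onset), , drop = FALSE]
  # refractory merge: drop onsets closer than the refractory period to the
  # previously kept onset
  if (nrow(obs) > 1) {
    keep <- rep(TRUE, nrow(obs))
    last <- obs$onset[1]
    for (i in seq_len(nrow(obs))[-1]) {
      if (obs$onset[i] - last < config$blink_refractory_s) keep[i] <- FALSE
      else last <- obs$onset[i]
    }
    obs <- obs[keep, , drop = FALSE]
  }
  rownames(obs) <- NULL
  list(listener = listener,
       observer = obs$onset,
       ground_truth = list(
         listener_blinks = data.frame(onset = listener, elicits_coupled = elicits),
         observer_blinks = obs))
}

#' Event-related pupil dilation kernel
#'
#' Zero before `onset_latency` after the event, raised-cosine rise to
#' `amplitude` at `peak_latency`, exponential decay afterwards. The steepest
#' rise (the dilation velocity peak) occurs at the midpoint of the rise,
#' `onset_latency + (peak_latency - onset_latency) / 2` after the event.
#'
#' @param t_rel time relative to the event, seconds (vectorized).
#' @param onset_latency,peak_latency,amplitude,decay_tau kernel parameters
#'   (see [synthetic_config()]).
#' @return kernel values, same length as `t_rel`.
#' @export
dilation_kernel <- function(t_rel, onset_latency = 0.8, peak_latency = 2.0,
                            amplitude = 0.5, decay_tau = 3.0) {
  out <- numeric(length(t_rel))
  rise <- t_rel >= onset_latency & t_rel <= peak_latency
  out[rise] <- amplitude / 2 *
    (1 - cos(pi * (t_rel[rise] - onset_latency) / (peak_latency - onset_latency)))
  dec <- t_rel > peak_latency
  out[dec] <- amplitude * exp(-(t_rel[dec] - peak_latency) / decay_tau)
  out
}

#' Latency of the steepest kernel rise
#'
#' Time after a planted event at which the dilation velocity of the
#' noiseless kernel is maximal; used to score recovered peaks against
#' ground truth.
#' @param config a [synthetic_config()].
#' @return seconds.
#' @export
steepest_rise_latency <- function(config) {
  config$dilation_onset_latency +
    (config$dilation_peak_latency - config$dilation_onset_latency) / 2
}

#' Generate planted dilation-event times
#'
#' Poisson candidates thinned to the configured minimum separation so each
#' event-related response stays resolvable.
#'
#' @param config a [synthetic_config()].
#' @param duration seconds.
#' @param seed optional integer seed.
#' @return sorted event times (seconds).
#' @export
generate_dilation_events <- function(config, duration, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_cand <- stats::rpois(1, config$dilation_event_rate * duration)
  cand <- sort(stats::runif(n_cand, 0, max(0, duration - config$dilation_peak_latency)))
  out <- numeric(0); last <- -Inf
  for (x in cand) {
    if (x - last >= config$dilation_min_sep) { out <- c(out, x); last <- x }
  }
  out
}

# smooth physiological noise: white Gaussian convolved with a Gaussian
# kernel of SD noise_corr_s, rescaled to the target SD
.smooth_noise <- function(n, sd_target, corr_s, dt) {
  if (sd_target == 0 || n < 2) return(numeric(n))
  m <- ceiling(4 * corr_s / dt)
  k <- stats::dnorm(seq(-m, m) * dt, sd = corr_s)
  x <- stats::filter(stats::rnorm(n + 2 * m), k / sum(k), sides = 2)
  x <- as.numeric(x[(m + 1):(m + n)])
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * sd_target / s
}

#' Generate a pupil trace with planted dilation events and artifacts
#'
#' The trace is baseline + slow drift + event-related dilation kernels +
#' physiological noise + bounded device noise. Artifacts are injected
#' afterwards: missing gaps (spans of invalid samples) and single-sample
#' spikes, both recorded in the ground truth.
#'
#' @param config a [synthetic_config()].
#' @param duration seconds.
#' @param event_times planted dilation-event times (seconds).
#' @param seed optional integer seed.
#' @param artifacts logical; inject gap/spike artifacts (default `TRUE`).
#' @return list with `trace` (a [pupil_trace()]) and `ground_truth`
#'   (`event_times`, `gaps` data.frame with `start`/`end` seconds, and
#'   `spike_times`).
#' @export
generate_pupil_trace <- function(config, duration, event_times = numeric(0),
                                 seed = NULL, artifacts = TRUE) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / config$sampling_rate
  time <- seq(0, duration - dt / 2, by = dt)
  n <- length(time)
  d <- rep(config$pupil_baseline, n)
  if (config$drift_amplitude > 0)
    d <- d + config$drift_amplitude * sin(2 * pi * time / config$drift_period)
  for (e in event_times)
    d <- d + dilation_kernel(time - e, config$dilation_onset_latency,
                             config$dilation_peak_latency,
                             config$dilation_amplitude,
                             config$dilation_decay_tau)
  d <- d + .smooth_noise(n, config$noise_sd, config$noise_corr_s, dt)
  if (config$interference_amp > 0)
    d <- d + config$interference_amp *
      sin(2 * pi * config$interference_freq * time + stats::runif(1, 0, 2 * pi))
  if (config$quantization_sd > 0)
    d <- d + stats::runif(n, -config$quantization_sd * sqrt(3),
                          config$quantization_sd * sqrt(3))
  valid <- rep(TRUE, n)
  gaps <- data.frame(start = numeric(0), end = numeric(0))
  spike_times <- numeric(0)
  if (artifacts) {
    gap_on <- sort(stats::runif(stats::rpois(1, config$artifact_gap_rate * duration),
                                0, duration - max(config$gap_dur_range)))
    gap_len <- stats::runif(length(gap_on), config$gap_dur_range[1],
                            config$gap_dur_range[2])
    gap_idx <- integer(0)
    for (g in seq_along(gap_on)) {
      i0 <- findInterval(gap_on[g], time) + 1L
      i1 <- min(n, i0 + round(gap_len[g] / dt) - 1L)
      if (i1 >= i0) {
        gap_idx <- c(gap_idx, i0:i1)
        gaps <- rbind(gaps, data.frame(start = time[i0], end = time[i1] + dt))
      }
    }
    valid[gap_idx] <- FALSE
    sp <- unique(findInterval(
      sort(stats::runif(stats::rpois(1, config$artifact_spike_rate * duration),
                        dt, duration - dt)), time) + 1L)
    sp <- setdiff(sp, gap_idx)
    sp <- sp[sp >= 1 & sp <= n]
    d[sp] <- d[sp] + config$spike_amplitude
    spike_times <- time[sp]
  }
  d[!valid] <- NA_real_
  list(trace = pupil_trace(time, d, valid),
       ground_truth = list(event_times = event_times, gaps = gaps,
                           spike_times = spike_times))
}

# alternating fixation/saccade tiling of the schedule's phases
.generate_fixations <- function(config, schedule) {
  onsets <- numeric(0); offsets <- numeric(0); kinds <- character(0)
  sacc_s <- config$saccade_dur_ms / 1000
  for (i in seq_len(nrow(schedule))) {
    t <- schedule$start[i]; end <- schedule$end[i]
    med <- config$fixation_median_ms[[schedule$phase[i]]] / 1000
    while (t < end - 0.02) {
      fdur <- stats::rlnorm(1, log(med), config$fixation_sdlog)
      f_end <- min(t + fdur, end - 1e-4)
      if (f_end - t >= 0.02) {
        onsets <- c(onsets, t); offsets <- c(offsets, f_end)
        kinds <- c(kinds, "fixation")
      }
      t <- f_end
      if (t >= end - 0.02) break
      s_end <- min(t + sacc_s, end - 1e-6)
      if (s_end - t >= 0.005) {
        onsets <- c(onsets, t); offsets <- c(offsets, s_end)
        kinds <- c(kinds, "saccade")
      }
      t <- s_end
    }
  }
  ocular_events(onsets, offsets, kinds)
}

# blink event intervals from onsets; durations log-normal, clipped to the
# trace span (onsets in the last sample interval are dropped)
.blink_events <- function(config, onsets, duration) {
  t_max <- duration - 1 / config$sampling_rate
  onsets <- onsets[onsets < t_max - 1e-3]
  if (!length(onsets))
    return(ocular_events(numeric(0), numeric(0), character(0)))
  dur <- stats::rlnorm(length(onsets), config$blink_dur_meanlog,
                       config$blink_dur_sdlog)
  offs <- pmin(onsets + dur, t_max)
  # a blink ends before the next one starts (events must not overlap)
  if (length(onsets) > 1)
    offs[-length(offs)] <- pmin(offs[-length(offs)], onsets[-1] - 1e-3)
  keep <- offs > onsets
  ocular_events(onsets[keep], offs[keep], "blink")
}

# invalidate trace samples during blink spans (device loses the pupil)
.apply_blink_gaps <- function(trace, blinks) {
  if (!nrow(blinks)) return(trace)
  v <- trace$valid; d <- trace$diameter
  for (i in seq_len(nrow(blinks))) {
    idx <- which(trace$time >= blinks$onset[i] & trace$time <= blinks$offset[i])
    v[idx] <- FALSE; d[idx] <- NA_real_
  }
  pupil_trace(trace$time, d, v, trace$interpolated, trace$trimmed)
}

#' Assemble a full synthetic dyad recording
#'
#' Builds both members' recordings on a common clock: the trial/phase
#' schedule (contexts permuted for counterbalancing), coupled blink trains
#' with per-phase coupling, pupil traces with planted dilation events and
#' artifacts (trace samples during blinks are invalid, as the device loses
#' the pupil), and fixation/saccade streams.
#'
#' @param config a [synthetic_config()].
#' @param dyad_id identifier string.
#' @param seed optional integer; defaults to `config$seed`.
#' @param with_pupil logical; `FALSE` skips pupil-trace synthesis (blink-only
#'   studies run much faster).
#' @param contexts optional explicit context order; default draws a random
#'   permutation (counterbalancing).
#' @return list with `dyad` (a [dyad_recording()]) and `ground_truth` (per
#'   member: blink labels, planted dilation events, artifact spans).
#' @export
assemble_dyad <- function(config, dyad_id = "dyad01", seed = config$seed,
                          with_pupil = TRUE, contexts = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(contexts))
    contexts <- sample(c("neutral", "negative", "positive"))
  schedule <- default_schedule(contexts, config$phase_length,
                               n_trials = config$n_trials)
  duration <- config$n_trials * 3 * config$phase_length
  # dyad-level coupling heterogeneity: one logit-scale shift for the pair
  if (config$coupling_dyad_sd > 0) {
    shift <- stats::rnorm(1, 0, config$coupling_dyad_sd)
    config$coupling_prob <- stats::plogis(stats::qlogis(config$coupling_prob) + shift)
  }
  trains <- generate_blink_trains(config, duration, schedule, seed = NULL)
  gt <- list(blinks = trains$ground_truth,
             coupling_prob = config$coupling_prob)

  members <- list()
  for (role in c("listener", "observer")) {
    onsets <- trains[[role]]
    blinks <- .blink_events(config, onsets, duration)
    if (with_pupil) {
      ev <- generate_dilation_events(config, duration)
      pt <- generate_pupil_trace(config, duration, ev)
      trace <- .apply_blink_gaps(pt$trace, blinks)
      gt[[role]] <- pt$ground_truth
    } else {
      trace <- pupil_trace(c(0, duration), rep(config$pupil_baseline, 2))
      gt[[role]] <- list(event_times = numeric(0),
                         gaps = data.frame(start = numeric(0), end = numeric(0)),
                         spike_times = numeric(0))
    }
    fixsac <- .generate_fixations(config, schedule)
    events <- ocular_events(c(blinks$onset, fixsac$onset),
                            c(blinks$offset, fixsac$offset),
                            c(blinks$kind, fixsac$kind))
    members[[role]] <- participant_recording(
      participant_id = paste0(dyad_id, "_", substr(role, 1, 1)),
      role = role, trace = trace, events = events, schedule = schedule)
  }
  list(dyad = dyad_recording(dyad_id, members$listener, members$observer),
       ground_truth = gt)
}

#' Simulate a cohort of dyads
#'
#' @param config a [synthetic_config()].
#' @param n_dyads number of dyads (the study analyzed 24).
#' @param seed integer master seed; per-dyad substreams are derived from it.
#' @param with_pupil see [assemble_dyad()].
#' @return list with `dyads` (list of [dyad_recording()]) and
#'   `ground_truths` (parallel list).
#' @export
simulate_cohort <- function(config, n_dyads = 24, seed = config$seed,
                            with_pupil = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1, n_dyads)
  dyads <- vector("list", n_dyads)
  gts <- vector("list", n_dyads)
  for (i in seq_len(n_dyads)) {
    res <- assemble_dyad(config, dyad_id = sprintf("dyad%02d", i),
                         seed = subseeds[i], with_pupil = with_pupil)
    dyads[[i]] <- res$dyad
    gts[[i]] <- res$ground_truth
  }
  list(dyads = dyads, ground_truths = gts)
}

#' Write a dyad recording to per-member delimited text files
#'
#' Emits, per member, `<id>_pupil.csv`, `<id>_events.csv` and a shared
#' `schedule.csv`, plus a `ground_truth.json` sidecar when ground truth is
#' supplied — the dialect [read_pupil_trace()] and [read_events()] consume.
#'
#' @param dyad a [dyad_recording()].
#' @param dir output directory (created if needed).
#' @param ground_truth optional ground-truth list from [assemble_dyad()].
#' @return `dir`, invisibly.
#' @export
write_dyad_files <- function(dyad, dir, ground_truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (role in c("listener", "observer")) {
    m <- dyad[[role]]
    write_pupil_trace(m$trace, file.path(dir, paste0(m$participant_id, "_pupil.csv")))
    write_events(m$events, file.path(dir, paste0(m$participant_id, "_events.csv")))
  }
  sched <- dyad$listener$schedule
  utils::write.table(sched, file.path(dir, "schedule.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(ground_truth))
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
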