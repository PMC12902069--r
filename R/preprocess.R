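#' Pupil preprocessing configuration
#'
#' Defaults are the published artifact-rejection parameters: blinks are
#' reconstructed by linear interpolation from 100 ms before to 150 ms after
#' each blink; saccades with a symmetric 75 ms buffer; dilation-speed
#' outliers beyond median + 3 x MAD are removed; 50 ms of data before and
#' after any gap longer than 75 ms is trimmed; valid islands shorter than
#' 50 ms flanked by gaps longer than 40 ms are removed; and a phase is
#' flagged for exclusion when more than 30% of its samples are missing.
#'
#' @param blink_pre,blink_post interpolation pads around blinks, ms.
#' @param saccade_buffer symmetric interpolation pad around saccades, ms.
#' @param mad_multiplier dilation-speed threshold multiplier (unitless).
#'   The MAD is unscaled (no normal-consistency factor): the rule is the
#'   literal median + k x MAD.
#' @param edge_pad,edge_min_gap gap-edge trimming: pad removed on each side
#'   (ms) of gaps strictly longer than `edge_min_gap` (ms).
#' @param sparsity_max_island,sparsity_flank_gap sparsity filter: valid
#'   islands strictly shorter than `sparsity_max_island` (ms) flanked on
#'   both sides by gaps strictly longer than `sparsity_flank_gap` (ms) are
#'   invalidated.
#' @param missing_exclusion_threshold fraction in (0, 1]; a phase is flagged
#'   when its missing fraction strictly exceeds it.
#' @param do_blink_interp,do_saccade_interp,do_mad,do_trim,do_sparsity
#'   stage switches; all stages run by default (reproducibility over the
#'   subjective visual-inspection gating sometimes used in practice).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(blink_pre = 100, blink_post = 150,
                              saccade_buffer = 75, mad_multiplier = 3,
                              edge_pad = 50, edge_min_gap = 75,
                              sparsity_max_island = 50, sparsity_flank_gap = 40,
                              missing_exclusion_threshold = 0.30,
                              do_blink_interp = TRUE, do_saccade_interp = TRUE,
                              do_mad = TRUE, do_trim = TRUE,
                              do_sparsity = TRUE) {
  cfg <- as.list(environment())
  durs <- c(cfg$blink_pre, cfg$blink_post, cfg$saccade_buffer, cfg$edge_pad,
            cfg$edge_min_gap, cfg$sparsity_max_island, cfg$sparsity_flank_gap)
  if (any(durs < 0)) stop("durations must be >= 0", call. = FALSE)
  if (cfg$mad_multiplier <= 0) stop("mad_multiplier must be > 0", call. = FALSE)
  if (cfg$missing_exclusion_threshold <= 0 || cfg$missing_exclusion_threshold > 1)
    stop("missing_exclusion_threshold must lie in (0, 1]", call. = FALSE)
  structure(cfg, class = "preprocess_config")
}

#' Reconstruct event spans by linear interpolation
#'
#' Samples from `pre` ms before each event onset to `post` ms after its
#' offset are replaced by the straight line joining the nearest usable
#' samples outside the padded span, and marked as interpolated (distinct
#' from originally valid). Spans touching the trace boundary, or lacking a
#' usable anchor on either side, are invalidated rather than extrapolated
#' (with a warning).
#'
#' @param trace a [pupil_trace()].
#' @param events an [ocular_events()] table (one kind; onset-sorted).
#' @param pre,post pads in milliseconds.
#' @return the reconstructed [pupil_trace()].
#' @export
interpolate_event_spans <- function(trace, events, pre, post) {
  if (!nrow(events)) return(trace)
  time <- trace$time; d <- trace$diameter
  valid <- trace$valid; interp <- trace$interpolated
  n <- length(time)
  for (i in seq_len(nrow(events))) {
    lo <- events$onset[i] - pre / 1000
    hi <- events$offset[i] + post / 1000
    span <- which(time >= lo & time <= hi)
    if (!length(span)) next
    ok <- valid | interp
    left <- span[1] - 1L
    while (left >= 1L && !ok[left]) left <- left - 1L
    right <- span[length(span)] + 1L
    while (right <= n && !ok[right]) right <- right + 1L
    if (left < 1L || right > n) {
      valid[span] <- FALSE; interp[span] <- FALSE; d[span] <- NA_real_
      warning(sprintf("event span [%g, %g] lacks an anchor; invalidated", lo, hi),
              call. = FALSE)
      next
    }
    w <- (time[span] - time[left]) / (time[right] - time[left])
    d[span] <- d[left] + w * (d[right] - d[left])
    valid[span] <- FALSE
    interp[span] <- TRUE
  }
  pupil_trace(time, d, valid, interp, trace$trimmed)
}

#' Two-sided dilation speed of a pupil trace
#'
#' Per usable sample, the larger of the absolute diameter change rates to
#' its previous and next usable samples (invalid neighbors are skipped;
#' endpoints use their single available neighbor).
#'
#' @param trace a [pupil_trace()] with at least 3 usable samples.
#' @return numeric vector, one speed (units/s) per sample; `NA` at unusable
#'   samples.
#' @export
dilation_speed <- function(trace) {
  ok <- which(ok_mask(trace))
  if (length(ok) < 3)
    stop("dilation_speed requires at least 3 usable samples", call. = FALSE)
  d <- trace$diameter[ok]; tt <- trace$time[ok]
  fwd <- abs(diff(d)) / diff(tt)
  m <- length(fwd)
  sp <- pmax(c(fwd[1], fwd), c(fwd, fwd[m]))
  out <- rep(NA_real_, n_samples(trace))
  out[ok] <- sp
  out
}

#' Remove dilation-speed outliers by the median + k x MAD rule
#'
#' Samples whose two-sided dilation speed strictly exceeds
#' `median(speed) + multiplier x MAD(speed)` are invalidated. The MAD is the
#' unscaled median absolute deviation over the usable samples of the segment
#' being processed. A degenerate segment (MAD = 0) flags nothing, with a
#' warning.
#'
#' @param trace a [pupil_trace()].
#' @param multiplier threshold multiplier (default 3).
#' @return the filtered [pupil_trace()].
#' @export
mad_speed_filter <- function(trace, multiplier = 3) {
  sp <- dilation_speed(trace)
  med <- stats::median(sp, na.rm = TRUE)
  madv <- stats::median(abs(sp - med), na.rm = TRUE)
  if (madv == 0) {
    warning("speed MAD is zero (degenerate segment); no samples flagged",
            call. = FALSE)
    return(trace)
  }
  flag <- !is.na(sp) & sp > med + multiplier * madv
  d <- trace$diameter; v <- trace$valid; interp <- trace$interpolated
  d[flag] <- NA_real_; v[flag] <- FALSE; interp[flag] <- FALSE
  pupil_trace(trace$time, d, v, interp, trace$trimmed)
}

# maximal runs of a logical vector: data.frame(start, end, value)
.runs <- function(x) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1L, end = end, value = r$values)
}

#' Trim data adjacent to long gaps
#'
#' For each maximal run of unusable samples strictly longer than `min_gap`
#' ms, `pad` ms of data preceding and following the run are invalidated
#' (edge artifacts around tracking losses). Samples removed here are marked
#' in the trace's `trimmed` mask, and trimming measures gap lengths on the
#' core (non-trimmed) gaps, so the operation is idempotent.
#'
#' @param trace a [pupil_trace()].
#' @param pad pad to remove on each side, ms (default 50).
#' @param min_gap minimum gap length to trigger trimming, ms (default 75).
#' @return the trimmed [pupil_trace()].
#' @export
trim_gap_edges <- function(trace, pad = 50, min_gap = 75) {
  n <- n_samples(trace)
  if (n == 0) return(trace)
  fs <- attr(trace, "sampling_rate")
  dt_ms <- 1000 / fs
  core_gap <- !ok_mask(trace) & !trace$trimmed
  runs <- .runs(core_gap)
  runs <- runs[runs$value & (runs$end - runs$start + 1L) * dt_ms > min_gap, ,
               drop = FALSE]
  if (!nrow(runs)) return(trace)
  pad_n <- round(pad / dt_ms)
  kill <- integer(0)
  for (i in seq_len(nrow(runs))) {
    if (runs$start[i] > 1L)
      kill <- c(kill, seq(max(1L, runs$start[i] - pad_n), runs$start[i] - 1L))
    if (runs$end[i] < n)
      kill <- c(kill, seq(runs$end[i] + 1L, min(n, runs$end[i] + pad_n)))
  }
  kill <- unique(kill)
  d <- trace$diameter; v <- trace$valid
  interp <- trace$interpolated; trm <- trace$trimmed
  newly <- setdiff(kill, which(!ok_mask(trace)))
  d[newly] <- NA_real_; v[newly] <- FALSE; interp[newly] <- FALSE
  trm[newly] <- TRUE
  pupil_trace(trace$time, d, v, interp, trm)
}

#' Remove short valid islands flanked by long gaps
#'
#' Maximal runs of usable samples strictly shorter than `max_island` ms
#' whose flanking unusable runs are BOTH strictly longer than `flank_gap` ms
#' are invalidated; runs at the trace boundaries count the boundary as an
#' infinite gap. The rule is applied to a fixed point (removing an island
#' can merge its neighboring gaps and qualify a further island), which makes
#' the operation idempotent.
#'
#' @param trace a [pupil_trace()].
#' @param max_island maximum island length, ms (default 50).
#' @param flank_gap minimum flanking-gap length, ms (default 40).
#' @return the filtered [pupil_trace()].
#' @export
sparsity_filter <- function(trace, max_island = 50, flank_gap = 40) {
  n <- n_samples(trace)
  if (n == 0) return(trace)
  fs <- attr(trace, "sampling_rate")
  dt_ms <- 1000 / fs
  d <- trace$diameter; v <- trace$valid; interp <- trace$interpolated
  repeat {
    ok <- v | interp
    runs <- .runs(ok)
    changed <- FALSE
    for (i in seq_len(nrow(runs))) {
      if (!runs$value[i]) next
      len_ms <- (runs$end[i] - runs$start[i] + 1L) * dt_ms
      if (len_ms >= max_island) next
      left_ms <- if (i == 1) Inf else (runs$end[i - 1] - runs$start[i - 1] + 1L) * dt_ms
      right_ms <- if (i == nrow(runs)) Inf else (runs$end[i + 1] - runs$start[i + 1] + 1L) * dt_ms
      if (left_ms > flank_gap && right_ms > flank_gap) {
        idx <- runs$start[i]:runs$end[i]
        d[idx] <- NA_real_; v[idx] <- FALSE; interp[idx] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pupil_trace(trace$time, d, v, interp, trace$trimmed)
}

#' Missing-data fraction of a phase
#'
#' Fraction of the expected samples (window length x sampling rate) that are
#' neither valid nor interpolated. A phase is flagged for exclusion when the
#' fraction strictly exceeds the configured threshold (a phase at exactly
#' the threshold is retained).
#'
#' @param trace a [pupil_trace()].
#' @param window a [phase_window()].
#' @return the missing fraction in `[0, 1]`.
#' @export
missing_fraction <- function(trace, window) {
  if (window$end <= window$start) stop("empty phase window", call. = FALSE)
  fs <- attr(trace, "sampling_rate")
  n_expected <- round((window$end - window$start) * fs)
  if (n_expected <= 0) stop("empty phase window", call. = FALSE)
  in_win <- trace$time >= window$start & trace$time < window$end
  n_ok <- sum(ok_mask(trace)[in_win])
  max(0, min(1, (n_expected - n_ok) / n_expected))
}

#' Run the full artifact-rejection chain
#'
#' Stages in their published order: blink interpolation (100/150 ms pads),
#' saccade interpolation (75 ms symmetric), dilation-speed MAD filtering,
#' gap-edge trimming, sparsity filtering. The speed median/MAD are computed
#' over the continuous recording passed in. Timestamps are never altered;
#' no stage after interpolation converts an unusable sample back to usable.
#'
#' @param trace a [pupil_trace()] (one continuous recording).
#' @param blink_events,saccade_events [ocular_events()] tables.
#' @param config a [preprocess_config()].
#' @param schedule optional [default_schedule()] table; when given, the
#'   report includes per-phase missing fractions and exclusion flags.
#' @return list with `trace` (cleaned) and `report` (a `preprocess_report`:
#'   per-stage counts of samples newly interpolated/invalidated, and the
#'   per-phase missing table when a schedule is supplied).
#' @export
preprocess_pipeline <- function(trace, blink_events, saccade_events, config,
                                schedule = NULL) {
  counts <- c(blink_interpolated = 0L, saccade_interpolated = 0L,
              mad_flagged = 0L, edge_trimmed = 0L, sparsity_removed = 0L)
  state <- function(tr) list(ok = ok_mask(tr), interp = tr$interpolated)
  s0 <- state(trace)

  if (config$do_blink_interp) {
    trace <- interpolate_event_spans(trace, blink_events,
                                     config$blink_pre, config$blink_post)
    s1 <- state(trace)
    counts["blink_interpolated"] <- sum(s1$interp & !s0$interp)
    s0 <- s1
  }
  if (config$do_saccade_interp) {
    trace <- interpolate_event_spans(trace, saccade_events,
                                     config$saccade_buffer, config$saccade_buffer)
    s1 <- state(trace)
    counts["saccade_interpolated"] <- sum(s1$interp & !s0$interp)
    s0 <- s1
  }
  if (config$do_mad) {
    trace <- mad_speed_filter(trace, config$mad_multiplier)
    s1 <- state(trace)
    counts["mad_flagged"] <- sum(s0$ok & !s1$ok)
    s0 <- s1
  }
  if (config$do_trim) {
    trace <- trim_gap_edges(trace, config$edge_pad, config$edge_min_gap)
    s1 <- state(trace)
    counts["edge_trimmed"] <- sum(s0$ok & !s1$ok)
    s0 <- s1
  }
  if (config$do_sparsity) {
    trace <- sparsity_filter(trace, config$sparsity_max_island,
                             config$sparsity_flank_gap)
    s1 <- state(trace)
    counts["sparsity_removed"] <- sum(s0$ok & !s1$ok)
  }

  phase_missing <- NULL
  if (!is.null(schedule)) {
    fracs <- vapply(schedule_windows(schedule),
                    function(w) missing_fraction(trace, w), numeric(1))
    phase_missing <- data.frame(trial = schedule$trial, phase = schedule$phase,
                                missing_fraction = fracs,
                                excluded = fracs > config$missing_exclusion_threshold)
  }
  report <- structure(list(counts = counts, phase_missing = phase_missing,
                           n_samples = n_samples(trace),
                           final_missing = sum(!ok_mask(trace))),
                      class = "preprocess_report")
  list(trace = trace, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report>\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %d samples\n", nm, x$counts[[nm]]))
  cat(sprintf("  final missing          %d of %d\n", x$final_missing, x$n_samples))
  if (!is.null(x$phase_missing) && any(x$phase_missing$excluded))
    cat("  ", sum(x$phase_missing$excluded), "phase(s) flagged for exclusion\n")
  invisible(x)
}

#' Preprocess one participant recording
#'
#' Convenience wrapper: runs [preprocess_pipeline()] on the participant's
#' trace with their device-reported blink and saccade events and their
#' schedule.
#'
#' @param participant a [participant_recording()].
#' @param config a [preprocess_config()].
#' @return list with `trace` and `report` (see [preprocess_pipeline()]).
#' @export
preprocess_participant <- function(participant, config = preprocess_config()) {
  preprocess_pipeline(participant$trace,
                      events_of_kind(participant$events, "blink"),
                      events_of_kind(participant$events, "saccade"),
                      config, schedule = participant$schedule)
}
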