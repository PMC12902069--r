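#' Count events of one kind within a phase
#'
#' Events are assigned to the phase containing their onset (half-open
#' window).
#'
#' @param events an [ocular_events()] table.
#' @param window a [phase_window()].
#' @param kind event kind to count.
#' @return integer count.
#' @export
count_events <- function(events, window, kind) {
  sum(events$kind == kind &
        events$onset >= window$start & events$onset < window$end)
}

#' Mean event duration within a phase
#'
#' Mean duration (ms) of the events of one kind whose onset falls in the
#' window. Durations are a property of the event: an event straddling the
#' phase boundary contributes its full duration. Zero matching events yield
#' `NA`, never 0.
#'
#' @param events an [ocular_events()] table.
#' @param window a [phase_window()].
#' @param kind event kind.
#' @return mean duration in ms, or `NA`.
#' @export
mean_event_duration <- function(events, window, kind) {
  sel <- events$kind == kind &
    events$onset >= window$start & events$onset < window$end
  if (!any(sel)) return(NA_real_)
  mean(events$duration_ms[sel])
}

.metric_measures <- c("n_fixations", "fixation_duration_ms", "n_blinks",
                      "blink_duration_ms", "n_peaks", "mean_pupil_size",
                      "missing_fraction")

# one participant's metric rows across trials x phases
.participant_metrics <- function(dyad_id, member, clean_trace, peaks) {
  sched <- member$schedule
  rows <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    win <- phase_window(sched$phase[i], sched$start[i], sched$end[i])
    trial_peaks <- peaks[peaks$trial == sched$trial[i], , drop = FALSE]
    vals <- c(
      n_fixations = count_events(member$events, win, "fixation"),
      fixation_duration_ms = mean_event_duration(member$events, win, "fixation"),
      n_blinks = count_events(member$events, win, "blink"),
      blink_duration_ms = mean_event_duration(member$events, win, "blink"),
      n_peaks = peaks_per_phase(trial_peaks, win),
      mean_pupil_size = suppressWarnings(mean_pupil_size_per_phase(clean_trace, win)),
      missing_fraction = missing_fraction(clean_trace, win)
    )
    rows[[i]] <- data.frame(
      dyad = dyad_id, participant = member$participant_id, role = member$role,
      trial = sched$trial[i], context = sched$context[i], phase = sched$phase[i],
      measure = names(vals), value = unname(vals))
  }
  do.call(rbind, rows)
}

#' Build the long-format metrics table for a cohort
#'
#' One row per participant x trial x phase x measure, with measures
#' `n_fixations`, `fixation_duration_ms`, `n_blinks`, `blink_duration_ms`,
#' `n_peaks`, `mean_pupil_size` and `missing_fraction`. For N dyads the
#' table holds N x 2 x trials x phases rows per measure.
#'
#' @param dyads list of [dyad_recording()] objects.
#' @param processed parallel list from [process_dyad()]: per dyad, per role,
#'   the cleaned trace and trial peak table.
#' @return data.frame in the metrics-table layout (see
#'   [write_metrics_table()]).
#' @export
build_metrics_table <- function(dyads, processed) {
  if (length(dyads) != length(processed))
    stop("dyads and processed lists differ in length", call. = FALSE)
  out <- vector("list", 2 * length(dyads))
  k <- 0
  for (i in seq_along(dyads)) {
    for (role in c("listener", "observer")) {
      p <- processed[[i]][[role]]
      if (is.null(p$trace) || is.null(p$peaks))
        stop(sprintf("missing processed data for %s of %s",
                     role, dyads[[i]]$dyad_id), call. = FALSE)
      k <- k + 1
      out[[k]] <- .participant_metrics(dyads[[i]]$dyad_id, dyads[[i]][[role]],
                                       p$trace, p$peaks)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  # integrity: every participant x trial x phase cell carries every measure
  cells <- unique(tab[, c("participant", "trial", "phase")])
  expected <- nrow(cells) * length(.metric_measures)
  if (nrow(tab) != expected)
    stop(sprintf("metrics table incomplete: %d rows, expected %d",
                 nrow(tab), expected), call. = FALSE)
  tab
}
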