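#' Construct a pupil-diameter time series
#'
#' A `pupil_trace` is a uniformly sampled (nominally 200 Hz) pupil-diameter
#' series with a per-sample validity mask. Invalid samples carry `NA`
#' diameter; the constructor never interpolates. A second mask tracks samples
#' that were reconstructed by interpolation during preprocessing, so that
#' "originally valid", "interpolated" and "missing" states stay distinct.
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing.
#' @param diameter numeric vector of pupil diameters (device units, mm
#'   assumed). `NA` marks missing samples.
#' @param valid logical mask of originally-valid samples. Defaults to
#'   `!is.na(diameter)`.
#' @param interpolated logical mask of samples reconstructed by
#'   interpolation. Defaults to all `FALSE`.
#' @param trimmed logical mask of samples invalidated by gap-edge trimming
#'   (kept distinct from core gaps so the trimming stage is idempotent).
#' @return an object of class `pupil_trace`: a list with elements `time`,
#'   `diameter`, `valid`, `interpolated`, `trimmed` and attribute
#'   `sampling_rate` (Hz, estimated from the median sample spacing).
#' @export
pupil_trace <- function(time, diameter, valid = !is.na(diameter),
                        interpolated = logical(length(time)),
                        trimmed = logical(length(time))) {
  time <- as.numeric(time)
  diameter <- as.numeric(diameter)
  valid <- as.logical(valid)
  interpolated <- as.logical(interpolated)
  trimmed <- as.logical(trimmed)
  n <- length(time)
  if (length(diameter) != n || length(valid) != n ||
      length(interpolated) != n || length(trimmed) != n)
    stop("time, diameter, valid, interpolated and trimmed must have equal length",
         call. = FALSE)
  if (n >= 2) {
    dt <- diff(time)
    bad <- which(dt <= 0)
    if (length(bad))
      stop(sprintf("timestamps not strictly increasing at index %d", bad[1] + 1L),
           call. = FALSE)
  }
  if (anyNA(valid)) stop("valid mask must not contain NA", call. = FALSE)
  if (any(valid & interpolated))
    stop("a sample cannot be both originally valid and interpolated", call. = FALSE)
  if (any(trimmed & (valid | interpolated)))
    stop("trimmed samples cannot be valid or interpolated", call. = FALSE)
  diameter[!valid & !interpolated] <- NA_real_
  if (any((valid | interpolated) & is.na(diameter)))
    stop("valid or interpolated samples must carry a diameter value", call. = FALSE)
  fs <- if (n >= 2) 1 / stats::median(diff(time)) else NA_real_
  structure(list(time = time, diameter = diameter, valid = valid,
                 interpolated = interpolated, trimmed = trimmed),
            sampling_rate = fs, class = "pupil_trace")
}

#' @export
print.pupil_trace <- function(x, ...) {
  n <- length(x$time)
  fs <- attr(x, "sampling_rate")
  cat(sprintf("<pupil_trace> %d samples, %.1f-%.1f s, ~%.0f Hz\n",
              n, if (n) min(x$time) else NA, if (n) max(x$time) else NA, fs))
  cat(sprintf("  valid: %d  interpolated: %d  missing: %d\n",
              sum(x$valid), sum(x$interpolated),
              sum(!x$valid & !x$interpolated)))
  invisible(x)
}

#' Number of samples in a pupil trace
#' @param trace a [pupil_trace()].
#' @return integer sample count.
#' @export
n_samples <- function(trace) length(trace$time)

#' Usable-sample mask (valid or interpolated)
#' @param trace a [pupil_trace()].
#' @return logical vector: samples carrying a usable diameter value.
#' @export
ok_mask <- function(trace) trace$valid | trace$interpolated

#' Sampling rate of a trace in Hz
#' @param trace a [pupil_trace()].
#' @return numeric, estimated from the median sample spacing.
#' @export
sampling_rate <- function(trace) attr(trace, "sampling_rate")

# delimiter by file extension: .csv -> comma, anything else -> tab
.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a pupil trace from a delimited text export
#'
#' Reads a CSV/TSV export (delimiter chosen by file extension) with one
#' timestamp column and one diameter column. Missing samples may be encoded
#' as empty fields or `NaN`/`NA`; they become invalid samples, never
#' interpolated.
#'
#' @param path file path to a delimited text file.
#' @param dialect named character vector mapping the canonical names `time`
#'   and `diameter` to the column names used in the file. The default covers
#'   the bundled synthetic exports; see [pupil_export_dialect()] for a
#'   Pupil Labs-style mapping.
#' @return a [pupil_trace()].
#' @export
read_pupil_trace <- function(path, dialect = c(time = "timestamp",
                                               diameter = "diameter")) {
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          check.names = FALSE, na.strings = c("NA", "NaN", ""))
  for (col in c("time", "diameter")) {
    if (!dialect[[col]] %in% names(df))
      stop(sprintf("required column '%s' (mapped from '%s') not found in %s",
                   dialect[[col]], col, path), call. = FALSE)
  }
  diameter <- df[[dialect[["diameter"]]]]
  n <- length(diameter)
  interp <- if ("interpolated" %in% names(df)) df$interpolated == 1 else logical(n)
  trimmed <- if ("trimmed" %in% names(df)) df$trimmed == 1 else logical(n)
  pupil_trace(time = df[[dialect[["time"]]]], diameter = diameter,
              valid = !is.na(diameter) & !interp, interpolated = interp,
              trimmed = trimmed)
}

#' Column-name map for Pupil Labs-style pupil exports
#'
#' Device exports name the columns `timestamp [s]` and
#' `pupil diameter left [mm]`; this returns the corresponding dialect map
#' for [read_pupil_trace()].
#' @return named character vector usable as the `dialect` argument.
#' @export
pupil_export_dialect <- function() {
  c(time = "timestamp [s]", diameter = "pupil diameter left [mm]")
}

#' Write a pupil trace to delimited text
#'
#' Timestamps are written with microsecond precision and diameters with
#' 9 decimal places so that a write/read round trip preserves the trace at
#' the stated precision. Invalid samples are written as empty diameter
#' fields; interpolated samples are flagged in an `interpolated` column so
#' the mask round-trips.
#'
#' @param trace a [pupil_trace()].
#' @param path output file path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_pupil_trace <- function(trace, path) {
  df <- data.frame(
    timestamp = sprintf("%.6f", trace$time),
    diameter = ifelse(ok_mask(trace), sprintf("%.9f", trace$diameter), ""),
    interpolated = as.integer(trace$interpolated),
    trimmed = as.integer(trace$trimmed)
  )
  utils::write.table(df, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Construct a table of ocular events
#'
#' Blink, fixation and saccade intervals reported by the eye tracker.
#' Events of one kind within one recording must be onset-sorted and
#' non-overlapping; durations are carried in milliseconds.
#'
#' @param onset,offset numeric vectors, seconds; `offset > onset` per row.
#' @param kind event kind: `"blink"`, `"fixation"` or `"saccade"`; either a
#'   single value recycled to all rows or one per row.
#' @return a data.frame of class `ocular_events` with columns `kind`,
#'   `onset`, `offset`, `duration_ms`, sorted by kind then onset.
#' @export
ocular_events <- function(onset, offset, kind) {
  onset <- as.numeric(onset)
  offset <- as.numeric(offset)
  if (length(offset) != length(onset))
    stop("onset and offset must have equal length", call. = FALSE)
  kind <- rep_len(as.character(kind), length(onset))
  bad_kind <- setdiff(unique(kind), c("blink", "fixation", "saccade"))
  if (length(bad_kind))
    stop("unknown event kind: ", paste(bad_kind, collapse = ", "), call. = FALSE)
  bad <- which(offset <= onset)
  if (length(bad))
    stop(sprintf("offset <= onset at row %d (onset=%g, offset=%g)",
                 bad[1], onset[bad[1]], offset[bad[1]]), call. = FALSE)
  df <- data.frame(kind = kind, onset = onset, offset = offset,
                   duration_ms = (offset - onset) * 1000)
  df <- df[order(df$kind, df$onset), , drop = FALSE]
  rownames(df) <- NULL
  for (k in unique(df$kind)) {
    sub <- df[df$kind == k, , drop = FALSE]
    if (nrow(sub) >= 2) {
      ov <- which(sub$onset[-1] < sub$offset[-nrow(sub)])
      if (length(ov))
        stop(sprintf("overlapping %s events at onset %g", k, sub$onset[ov[1] + 1]),
             call. = FALSE)
    }
  }
  class(df) <- c("ocular_events", "data.frame")
  df
}

#' Read an event table from delimited text
#'
#' @param path file path; delimiter chosen by extension.
#' @param kind event kind to assign (`"blink"`, `"fixation"`, `"saccade"`).
#'   If the file carries a `kind` column it is used instead.
#' @param dialect named character vector mapping `onset`/`offset` to the
#'   file's column names.
#' @return an [ocular_events()] table; an empty file yields an empty table
#'   with a warning.
#' @export
read_events <- function(path, kind,
                        dialect = c(onset = "onset", offset = "offset")) {
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          check.names = FALSE)
  if (nrow(df) == 0) {
    warning("no events in ", path, call. = FALSE)
    return(ocular_events(numeric(0), numeric(0), character(0)))
  }
  for (col in c("onset", "offset")) {
    if (!dialect[[col]] %in% names(df))
      stop(sprintf("required column '%s' not found in %s", dialect[[col]], path),
           call. = FALSE)
  }
  k <- if ("kind" %in% names(df)) df$kind else kind
  ocular_events(df[[dialect[["onset"]]]], df[[dialect[["offset"]]]], k)
}

#' Write an event table to delimited text
#' @param events an [ocular_events()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- data.frame(kind = events$kind,
                   onset = sprintf("%.6f", events$onset),
                   offset = sprintf("%.6f", events$offset))
  utils::write.table(df, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Subset events of one kind
#' @param events an [ocular_events()] table.
#' @param kind event kind to keep.
#' @return an `ocular_events` table, onset-sorted.
#' @export
events_of_kind <- function(events, kind) {
  out <- events[events$kind == kind, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' A labeled experimental phase window
#'
#' Phases are half-open intervals `[start, end)` on the recording clock.
#' Under the default schedule each trial holds three contiguous 30-s phases
#' in the order baseline, audio, silence.
#'
#' @param label `"baseline"`, `"audio"` or `"silence"`.
#' @param start,end seconds; `end > start`.
#' @return a list of class `phase_window`.
#' @export
phase_window <- function(label, start, end) {
  label <- match.arg(label, c("baseline", "audio", "silence"))
  if (!is.finite(start) || !is.finite(end) || end <= start)
    stop("phase window requires end > start", call. = FALSE)
  structure(list(label = label, start = start, end = end),
            class = "phase_window")
}

#' Build the trial/phase schedule of a recording
#'
#' Three trials, each a run of three contiguous 30-s phases
#' (baseline, audio, silence), with one emotional context per trial.
#'
#' @param contexts character vector of per-trial contexts in presentation
#'   order; a permutation of `c("neutral", "negative", "positive")` under the
#'   default design.
#' @param phase_length phase duration in seconds (default 30).
#' @param t0 start time of the first trial, seconds.
#' @param n_trials number of trials (default `length(contexts)`).
#' @return data.frame of class `phase_schedule` with columns `trial`,
#'   `context`, `order_code`, `phase`, `start`, `end`.
#' @export
default_schedule <- function(contexts = c("neutral", "negative", "positive"),
                             phase_length = 30, t0 = 0,
                             n_trials = length(contexts)) {
  contexts <- rep_len(contexts, n_trials)
  if (n_trials == 3 && !setequal(contexts, c("neutral", "negative", "positive")))
    stop("each context must appear exactly once per dyad", call. = FALSE)
  phases <- c("baseline", "audio", "silence")
  rows <- do.call(rbind, lapply(seq_len(n_trials), function(tr) {
    trial_start <- t0 + (tr - 1) * 3 * phase_length
    data.frame(trial = tr, context = contexts[tr],
               order_code = paste(toupper(substr(contexts, 1, 2)), collapse = "-"),
               phase = phases,
               start = trial_start + (0:2) * phase_length,
               end = trial_start + (1:3) * phase_length)
  }))
  rownames(rows) <- NULL
  class(rows) <- c("phase_schedule", "data.frame")
  rows
}

#' Phase windows of a schedule
#' @param schedule a [default_schedule()] table.
#' @return list of [phase_window()] objects, one per schedule row.
#' @export
schedule_windows <- function(schedule) {
  lapply(seq_len(nrow(schedule)), function(i)
    phase_window(schedule$phase[i], schedule$start[i], schedule$end[i]))
}

#' Restrict a trace or event table to one phase window
#'
#' Samples with `start <= t < end` are kept. Events are assigned by their
#' ONSET time: an event whose onset lies in the window belongs to the phase
#' even if it ends after the window (blink-synchrony windows are anchored on
#' onsets, so onset assignment keeps counting and synchrony consistent).
#'
#' @param x a [pupil_trace()] or [ocular_events()] table.
#' @param window a [phase_window()] (or any list with `start`/`end`).
#' @return an object of the same class restricted to the window.
#' @export
segment_phase <- function(x, window) UseMethod("segment_phase")

#' @export
segment_phase.pupil_trace <- function(x, window) {
  if (n_samples(x) == 0) stop("empty trace", call. = FALSE)
  if (window$start < min(x$time) - 1e-9 || window$end > max(x$time) + 1/attr(x, "sampling_rate") + 1e-9)
    stop(sprintf("phase window [%g, %g) outside recording span [%g, %g]",
                 window$start, window$end, min(x$time), max(x$time)),
         call. = FALSE)
  keep <- x$time >= window$start & x$time < window$end
  pupil_trace(x$time[keep], x$diameter[keep], x$valid[keep],
              x$interpolated[keep], x$trimmed[keep])
}

#' @export
segment_phase.ocular_events <- function(x, window) {
  keep <- x$onset >= window$start & x$onset < window$end
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' A single participant's recording
#'
#' @param participant_id identifier string.
#' @param role `"listener"` or `"observer"`.
#' @param trace a [pupil_trace()] (left eye).
#' @param events an [ocular_events()] table (blinks, fixations, saccades).
#' @param schedule a [default_schedule()] table.
#' @return a list of class `participant_recording`.
#' @export
participant_recording <- function(participant_id, role, trace, events, schedule) {
  role <- match.arg(role, c("listener", "observer"))
  if (nrow(events) > 0 && n_samples(trace) > 0) {
    span <- range(trace$time)
    if (any(events$onset < span[1] - 1e-9 | events$onset > span[2] + 1e-9))
      stop("event onsets outside recording span", call. = FALSE)
  }
  structure(list(participant_id = participant_id, role = role, eye = "left",
                 trace = trace, events = events, schedule = schedule),
            class = "participant_recording")
}

#' A dyad's paired recordings
#'
#' Both members must share an identical schedule (same phase boundaries on a
#' common clock).
#'
#' @param dyad_id identifier string.
#' @param listener,observer [participant_recording()] objects with the
#'   matching roles.
#' @return a list of class `dyad_recording`.
#' @export
dyad_recording <- function(dyad_id, listener, observer) {
  if (listener$role != "listener" || observer$role != "observer")
    stop("members must carry the listener and observer roles", call. = FALSE)
  a <- listener$schedule; b <- observer$schedule
  if (!isTRUE(all.equal(a$start, b$start)) || !isTRUE(all.equal(a$end, b$end)) ||
      !identical(a$phase, b$phase) || !identical(a$context, b$context))
    stop("dyad members must share an identical schedule", call. = FALSE)
  structure(list(dyad_id = dyad_id, listener = listener, observer = observer),
            class = "dyad_recording")
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf("<dyad_recording> %s: %d trials x 3 phases, %d + %d blinks\n",
              x$dyad_id, length(unique(x$listener$schedule$trial)),
              sum(x$listener$events$kind == "blink"),
              sum(x$observer$events$kind == "blink")))
  invisible(x)
}

.metrics_cols <- c("dyad", "participant", "role", "trial", "context",
                   "phase", "measure", "value")

#' Write the long-format metrics table
#'
#' Columns are written in the stable order dyad, participant, role, trial,
#' context, phase, measure, value. Duplicate (participant, trial, phase,
#' measure) keys are an integrity error.
#'
#' @param table data.frame with the metrics columns.
#' @param path output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(table, path) {
  missing_cols <- setdiff(.metrics_cols, names(table))
  if (length(missing_cols))
    stop("metrics table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  key <- paste(table$participant, table$trial, table$phase, table$measure)
  if (anyDuplicated(key))
    stop("duplicate (participant, trial, phase, measure) key: ",
         key[anyDuplicated(key)], call. = FALSE)
  out <- table[, .metrics_cols]
  out$value <- ifelse(is.na(out$value), "", sprintf("%.9g", out$value))
  utils::write.table(out, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a metrics table written by [write_metrics_table()]
#' @param path file path.
#' @return data.frame with the metrics columns.
#' @export
read_metrics_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          check.names = FALSE, na.strings = c("NA", ""),
                          colClasses = c(value = "numeric"))
  df[, .metrics_cols]
}
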