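#' Synchronization analysis configuration
#'
#' Windowed nearest-event synchronization for blink onsets or pupil dilation
#' velocity peaks. The analysis window is centered on each reference event:
#' 3 s total (+/- 1.5 s) for blinks, 5 s (+/- 2.5 s) for pupil peaks.
#'
#' @param modality `"blink"` or `"pupil_peak"`.
#' @param half_window half-width of the analysis window, seconds; defaults
#'   to 1.5 for blinks and 2.5 for pupil peaks.
#' @param reference_role which member's events anchor the windows
#'   (default `"listener"`).
#' @param denominator `"reference"` (default): the synchronization
#'   percentage is the share of the reference member's events in the phase
#'   with an in-window partner. `"pooled"`: both members' events enter the
#'   denominator and each is scored against the partner's train (sensitivity
#'   variant).
#' @param cross_phase logical; nearest-neighbor search in the test train may
#'   cross phase boundaries (windows are anchored on reference onsets, not
#'   clipped to phases). Default `TRUE`.
#' @return a list of class `sync_config`.
#' @export
sync_config <- function(modality = c("blink", "pupil_peak"),
                        half_window = NULL,
                        reference_role = c("listener", "observer"),
                        denominator = c("reference", "pooled"),
                        cross_phase = TRUE) {
  modality <- match.arg(modality)
  reference_role <- match.arg(reference_role)
  denominator <- match.arg(denominator)
  if (is.null(half_window))
    half_window <- if (modality == "blink") 1.5 else 2.5
  if (half_window <= 0) stop("half_window must be > 0", call. = FALSE)
  structure(list(modality = modality, half_window = half_window,
                 reference_role = reference_role, denominator = denominator,
                 cross_phase = cross_phase),
            class = "sync_config")
}

#' Signed lag from each reference event to its nearest test event
#'
#' For each reference onset r the lag is `t* - r`, where `t*` is the test
#' onset minimizing `|t - r|`. Matching is non-exclusive (a test event may
#' be the nearest neighbor of several reference events). Equidistant
#' earlier/later test events resolve to the EARLIER one (negative lag).
#'
#' @param reference sorted reference onsets, seconds (non-empty).
#' @param test sorted test onsets, seconds.
#' @return numeric vector of signed lags, one per reference event; all `NA`
#'   when the test train is empty.
#' @export
nearest_event_lag <- function(reference, test) {
  if (!length(reference))
    stop("reference train is empty", call. = FALSE)
  if (!length(test)) return(rep(NA_real_, length(reference)))
  i <- findInterval(reference, test)
  left <- ifelse(i >= 1, test[pmax(i, 1)], -Inf)
  right <- ifelse(i < length(test), test[pmin(i + 1, length(test))], Inf)
  dl <- reference - left
  dr <- right - reference
  ifelse(dl <= dr, left - reference, right - reference)
}

#' Windowed synchronization percentage
#'
#' 100 x (number of reference events whose nearest test event lies within
#' `half_window`, inclusive) / (number of reference events). Missing (with a
#' warning) when there are no reference events — never 0 or 100 by default.
#'
#' @param reference reference onsets within the phase, seconds.
#' @param test test onsets available for matching, seconds.
#' @param half_window window half-width, seconds.
#' @return percentage in `[0, 100]`, or `NA`.
#' @export
sync_percentage <- function(reference, test, half_window) {
  if (!length(reference)) {
    warning("no reference events in phase; synchronization undefined",
            call. = FALSE)
    return(NA_real_)
  }
  lags <- nearest_event_lag(reference, test)
  100 * mean(!is.na(lags) & abs(lags) <= half_window)
}

# event onsets of a member for the configured modality
.sync_onsets <- function(member, peaks, modality) {
  if (modality == "blink") events_of_kind(member$events, "blink")$onset
  else peaks$time
}

#' Per dyad x trial x phase synchronization table
#'
#' The reference member's events in each phase (onset assignment) are scored
#' against the test member's train; by default the test train is the whole
#' recording, so windows anchored near a phase edge may match a partner
#' event just across the boundary.
#'
#' @param dyads list of [dyad_recording()] objects.
#' @param config a [sync_config()].
#' @param peaks for `modality = "pupil_peak"`: a list parallel to `dyads`,
#'   each with `listener`/`observer` trial peak tables from
#'   [detect_trial_peaks()].
#' @return data.frame with columns `dyad`, `trial`, `context`, `phase`,
#'   `n_ref`, `n_test`, `sync_pct`; attribute `lags` holds the per-row lag
#'   vectors.
#' @export
dyad_sync_table <- function(dyads, config = sync_config("blink"),
                            peaks = NULL) {
  if (config$modality == "pupil_peak" &&
      (is.null(peaks) || length(peaks) != length(dyads)))
    stop("pupil_peak synchrony requires a peaks list parallel to dyads",
         call. = FALSE)
  ref_role <- config$reference_role
  test_role <- if (ref_role == "listener") "observer" else "listener"
  rows <- list(); lag_store <- list()
  for (i in seq_along(dyads)) {
    dy <- dyads[[i]]
    pk <- if (!is.null(peaks)) peaks[[i]] else list()
    ref_all <- .sync_onsets(dy[[ref_role]], pk[[ref_role]], config$modality)
    test_all <- .sync_onsets(dy[[test_role]], pk[[test_role]], config$modality)
    sched <- dy$listener$schedule
    for (j in seq_len(nrow(sched))) {
      lo <- sched$start[j]; hi <- sched$end[j]
      ref <- ref_all[ref_all >= lo & ref_all < hi]
      test_in <- test_all[test_all >= lo & test_all < hi]
      test_train <- if (config$cross_phase) test_all else test_in
      if (config$denominator == "reference") {
        pct <- suppressWarnings(sync_percentage(ref, test_train, config$half_window))
        lags <- if (length(ref)) nearest_event_lag(ref, test_train) else numeric(0)
      } else {
        ref_train_all <- if (config$cross_phase) ref_all else ref
        hits1 <- if (length(ref)) {
          l1 <- nearest_event_lag(ref, test_train)
          sum(!is.na(l1) & abs(l1) <= config$half_window)
        } else 0
        hits2 <- if (length(test_in)) {
          l2 <- nearest_event_lag(test_in, ref_train_all)
          sum(!is.na(l2) & abs(l2) <= config$half_window)
        } else 0
        denom <- length(ref) + length(test_in)
        pct <- if (denom == 0) NA_real_ else 100 * (hits1 + hits2) / denom
        lags <- if (length(ref)) nearest_event_lag(ref, test_train) else numeric(0)
      }
      rows[[length(rows) + 1]] <- data.frame(
        dyad = dy$dyad_id, trial = sched$trial[j], context = sched$context[j],
        phase = sched$phase[j], n_ref = length(ref), n_test = length(test_in),
        sync_pct = pct)
      lag_store[[length(lag_store) + 1]] <- lags
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "lags") <- lag_store
  out
}

#' Rank correlation between blink and pupil-peak synchrony, per phase
#'
#' Synchronization percentages are averaged over trials per dyad x phase for
#' each modality, then Spearman-correlated across dyads within each phase.
#'
#' @param blink_sync,peak_sync tables from [dyad_sync_table()].
#' @return data.frame with columns `phase`, `n`, `rho`, `p_value`; `NA`
#'   when fewer than 3 paired dyads are available.
#' @export
sync_cross_correlation <- function(blink_sync, peak_sync) {
  agg <- function(tab) stats::aggregate(sync_pct ~ dyad + phase, tab, mean,
                                        na.action = stats::na.omit)
  b <- agg(blink_sync); p <- agg(peak_sync)
  m <- merge(b, p, by = c("dyad", "phase"), suffixes = c("_blink", "_peak"))
  phases <- unique(blink_sync$phase)
  out <- lapply(phases, function(ph) {
    sub <- m[m$phase == ph & stats::complete.cases(m[, 3:4]), ]
    if (nrow(sub) < 3)
      return(data.frame(phase = ph, n = nrow(sub), rho = NA_real_,
                        p_value = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(sub$sync_pct_blink, sub$sync_pct_peak,
                      method = "spearman", exact = FALSE))
    data.frame(phase = ph, n = nrow(sub), rho = unname(ct$estimate),
               p_value = ct$p.value)
  })
  do.call(rbind, out)
}

#' Analytic chance level of the synchronization percentage
#'
#' For a homogeneous Poisson test train of rate `lambda` independent of the
#' reference train, the probability that a reference event finds a test
#' event within `+/- half_window` is `1 - exp(-2 * half_window * lambda)`,
#' so the expected synchronization percentage is 100 times that.
#'
#' @param lambda test-train rate, events/s.
#' @param half_window window half-width, seconds.
#' @return expected percentage.
#' @export
chance_sync_level <- function(lambda, half_window) {
  100 * (1 - exp(-2 * half_window * lambda))
}
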