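#' Default nested pipeline configuration
#'
#' Sections mirror the stage configurations ([synthetic_config()],
#' [preprocess_config()], [peak_config()], [sync_config()]) plus cohort size
#' and the master seed. Every default equals the published parameter where
#' one exists (interpolation pads 100/150 and 75 ms, median + 3 x MAD,
#' 50/75 ms edge trimming, 50/40 ms sparsity rule, 30% exclusion threshold,
#' Savitzky-Golay 11/3, 2.5 SD, 1500 ms NMS, +/- 1.5 s blink and +/- 2.5 s
#' pupil-peak windows).
#'
#' @return nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    seed = 1L,
    n_dyads = 24L,
    synthetic = unclass(synthetic_config()),
    preprocess = unclass(preprocess_config()),
    peaks = unclass(peak_config()),
    sync = list(blink_half_window = 1.5, pupil_half_window = 2.5,
                reference_role = "listener", denominator = "reference",
                cross_phase = TRUE)
  ), class = "pipeline_config")
}

# deep-merge user values into defaults, collecting unknown-key and type
# problems; numeric scalars may arrive as integers from YAML
.merge_config <- function(defaults, user, path = "", problems = NULL) {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      problems <- c(problems, sprintf("unknown key '%s'", full))
      next
    }
    dval <- defaults[[key]]
    uval <- user[[key]]
    if (is.list(dval) && !is.null(names(dval))) {
      if (!is.list(uval)) {
        problems <- c(problems, sprintf("'%s' must be a section", full))
        next
      }
      res <- .merge_config(dval, uval, full, problems)
      defaults[[key]] <- res$value
      problems <- res$problems
    } else {
      ok_type <- (is.numeric(dval) && is.numeric(uval)) ||
        (is.character(dval) && is.character(uval)) ||
        (is.logical(dval) && is.logical(uval)) ||
        is.null(dval)
      if (!ok_type) {
        problems <- c(problems, sprintf(
          "'%s' must be %s, got %s", full, class(dval)[1], class(uval)[1]))
      } else if (is.numeric(dval) && length(dval) > 1 && is.list(uval)) {
        problems <- c(problems, sprintf("'%s' must be a numeric vector", full))
      } else {
        if (!is.null(names(dval)) && is.null(names(uval)) &&
            length(uval) == length(dval)) names(uval) <- names(dval)
        defaults[[key]] <- uval
      }
    }
  }
  list(value = defaults, problems = problems)
}

#' Load and validate a pipeline configuration file
#'
#' Reads a YAML file, fills every unset key with its default, and rejects
#' unknown keys and type mismatches — listing all problems at once. An
#' empty (or missing `NULL`-content) file yields the full default
#' configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param quiet suppress the echo of effective values.
#' @return a validated `pipeline_config`.
#' @export
validate_config <- function(path = NULL, quiet = TRUE) {
  defaults <- default_pipeline_config()
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  res <- .merge_config(unclass(defaults), user)
  if (length(res$problems))
    stop("invalid configuration:\n  ",
         paste(res$problems, collapse = "\n  "), call. = FALSE)
  cfg <- structure(res$value, class = "pipeline_config")
  # re-validate through the stage constructors
  do.call(synthetic_config, cfg$synthetic[setdiff(names(cfg$synthetic), "seed")])
  do.call(preprocess_config, cfg$preprocess)
  do.call(peak_config, cfg$peaks)
  if (!quiet) utils::str(cfg)
  cfg
}

#' Preprocess and peak-detect both members of a dyad
#'
#' @param dyad a [dyad_recording()].
#' @param preprocess a [preprocess_config()].
#' @param peaks a [peak_config()].
#' @return list with `listener` and `observer`, each holding the cleaned
#'   `trace`, the preprocessing `report` and the trial `peaks` table.
#' @export
process_dyad <- function(dyad, preprocess = preprocess_config(),
                         peaks = peak_config()) {
  out <- list()
  for (role in c("listener", "observer")) {
    member <- dyad[[role]]
    pp <- preprocess_participant(member, preprocess)
    pk <- detect_trial_peaks(pp$trace, member$schedule, peaks)
    out[[role]] <- list(trace = pp$trace, report = pp$report, peaks = pk)
  }
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Stages: simulate -> preprocess -> peaks -> metrics -> sync (blinks and
#' pupil peaks) -> stats. Writes `metrics.csv`, `sync_blink.csv`,
#' `sync_pupil.csv`, `lmm_blink.txt`, `lmm_pupil.txt` and `manifest.json`
#' into `out_dir`. A given (config, seed) determines every output.
#'
#' @param config a `pipeline_config` (see [validate_config()]), or a path to
#'   a YAML configuration file.
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @param seed overrides `config$seed` when given.
#' @return (invisibly) list with `metrics`, `sync_blink`, `sync_pupil`,
#'   `lmm_blink`, `lmm_pupil`, `r2_blink`, `r2_pupil`, `contrasts_blink`,
#'   `cross_correlation`, `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL,
                         seed = NULL) {
  if (is.character(config)) config <- validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  syn_cfg <- do.call(synthetic_config, config$synthetic)
  pre_cfg <- do.call(preprocess_config, config$preprocess)
  pk_cfg <- do.call(peak_config, config$peaks)

  cohort <- .stage("simulate",
                   simulate_cohort(syn_cfg, config$n_dyads, seed = config$seed))
  processed <- .stage("preprocess+peaks",
                      lapply(cohort$dyads, process_dyad, preprocess = pre_cfg,
                             peaks = pk_cfg))
  metrics <- .stage("metrics", build_metrics_table(cohort$dyads, processed))

  peak_tables <- lapply(processed, function(p)
    list(listener = p$listener$peaks, observer = p$observer$peaks))
  sync_blink <- .stage("sync", dyad_sync_table(
    cohort$dyads,
    sync_config("blink", config$sync$blink_half_window,
                config$sync$reference_role, config$sync$denominator,
                config$sync$cross_phase)))
  sync_pupil <- .stage("sync", dyad_sync_table(
    cohort$dyads,
    sync_config("pupil_peak", config$sync$pupil_half_window,
                config$sync$reference_role, config$sync$denominator,
                config$sync$cross_phase),
    peaks = peak_tables))

  lmm_blink <- .stage("stats", fit_sync_lmm(sync_blink))
  lmm_pupil <- .stage("stats", fit_sync_lmm(sync_pupil))
  result <- list(
    metrics = metrics, sync_blink = sync_blink, sync_pupil = sync_pupil,
    lmm_blink = lmm_blink, lmm_pupil = lmm_pupil,
    r2_blink = r2_mixed(lmm_blink), r2_pupil = r2_mixed(lmm_pupil),
    contrasts_blink = phase_contrasts(lmm_blink),
    cross_correlation = sync_cross_correlation(sync_blink, sync_pupil))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metrics_table(metrics, file.path(out_dir, "metrics.csv"))
    utils::write.table(sync_blink, file.path(out_dir, "sync_blink.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    utils::write.table(sync_pupil, file.path(out_dir, "sync_pupil.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    for (mod in c("blink", "pupil")) {
      f <- file.path(out_dir, paste0("lmm_", mod, ".txt"))
      lm <- result[[paste0("lmm_", mod)]]
      r2 <- result[[paste0("r2_", mod)]]
      txt <- c(utils::capture.output(print(lm)),
               sprintf("marginal R2 = %.3f, conditional R2 = %.3f",
                       r2["marginal"], r2["conditional"]))
      writeLines(txt, f)
    }
    cfg_yaml <- yaml::as.yaml(unclass(config))
    tmp <- tempfile(); writeLines(cfg_yaml, tmp)
    manifest <- list(
      package_version = as.character(utils::packageVersion("dyadsync")),
      seed = config$seed,
      config_md5 = unname(tools::md5sum(tmp)),
      n_dyads = config$n_dyads,
      rows = list(metrics = nrow(metrics), sync_blink = nrow(sync_blink),
                  sync_pupil = nrow(sync_pupil)),
      outputs = as.list(tools::md5sum(file.path(
        out_dir, c("metrics.csv", "sync_blink.csv", "sync_pupil.csv"))))
    )
    unlink(tmp)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- manifest
  }
  invisible(result)
}
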