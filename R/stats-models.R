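#' Fit the synchronization linear mixed-effects model
#'
#' `sync_pct ~ phase * context + (1 | dyad)`, REML, with sum-to-zero
#' contrasts; term F-tests use the Satterthwaite degrees-of-freedom
#' approximation. Rows with missing response (phases where the reference
#' member produced no events) are dropped listwise. A singular fit (dyad
#' intercept variance collapsing to zero) is flagged, not an error.
#'
#' @param data data.frame with columns `dyad`, `phase`, `context` and the
#'   response.
#' @param response response column name (default `"sync_pct"`).
#' @return a list of class `lmm_result`: `model` (the `lmerModLmerTest`
#'   fit), `anova` (Satterthwaite type-III F-table), `sigma2_dyad`,
#'   `sigma2_res`, `singular`, `n_used`, `n_dropped`.
#' @export
fit_sync_lmm <- function(data, response = "sync_pct") {
  need <- c("dyad", "phase", "context", response)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  keep <- !is.na(data[[response]])
  df <- data[keep, , drop = FALSE]
  if (length(unique(df$dyad)) < 2)
    stop("need at least 2 dyads", call. = FALSE)
  df$dyad <- factor(df$dyad)
  df$phase <- factor(df$phase, levels = intersect(
    c("baseline", "audio", "silence"), unique(df$phase)))
  df$context <- factor(df$context)
  df$.y <- df[[response]]
  degenerate <- stats::var(df$.y) < 1e-12
  if (degenerate) {
    # a constant response carries no term variance: F = 0 by definition,
    # and the mixed-model machinery cannot factor the degenerate fit
    fit <- tryCatch(
      suppressWarnings(lme4::lmer(
        .y ~ phase * context + (1 | dyad), data = df, REML = TRUE,
        contrasts = list(phase = "contr.sum", context = "contr.sum"))),
      error = function(e) NULL)
    s2_dyad <- 0; s2_res <- 0
    an <- data.frame("Sum Sq" = 0, "Mean Sq" = 0, NumDF = c(2, 2, 4),
                     DenDF = NA, "F value" = 0, "Pr(>F)" = NA,
                     check.names = FALSE,
                     row.names = c("phase", "context", "phase:context"))
  } else {
    fit <- lmerTest::lmer(
      .y ~ phase * context + (1 | dyad), data = df, REML = TRUE,
      contrasts = list(phase = "contr.sum", context = "contr.sum"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2_dyad <- vc$vcov[vc$grp == "dyad"]
    s2_res <- vc$vcov[vc$grp == "Residual"]
    an <- suppressMessages(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  }
  structure(list(model = fit, anova = an,
                 sigma2_dyad = s2_dyad, sigma2_res = s2_res,
                 singular = degenerate || lme4::isSingular(fit),
                 degenerate = degenerate,
                 n_used = nrow(df), n_dropped = sum(!keep),
                 data = df),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("<lmm_result> sync ~ phase * context + (1 | dyad)\n")
  cat(sprintf("  n = %d (%d dropped), sigma2_dyad = %.3f, sigma2_res = %.3f%s\n",
              x$n_used, x$n_dropped, x$sigma2_dyad, x$sigma2_res,
              if (x$singular) " [singular]" else ""))
  print(x$anova)
  invisible(x)
}

#' Marginal and conditional R-squared of a mixed-model fit
#'
#' Variance decomposition for random-intercept models: with
#' `s2_f = var(fixed-effect linear predictor over the data)`,
#' marginal R2 = s2_f / (s2_f + s2_dyad + s2_res) is the share explained by
#' the experimental manipulations alone, and conditional
#' R2 = (s2_f + s2_dyad) / (s2_f + s2_dyad + s2_res) the share explained by
#' manipulations and dyad differences together. `s2_f` is computed from the
#' predictor values, not the coefficients, so the decomposition is invariant
#' to factor coding.
#'
#' @param result an [fit_sync_lmm()] result.
#' @return named numeric vector `c(marginal, conditional)`.
#' @export
r2_mixed <- function(result) {
  if (isTRUE(result$degenerate))
    stop("zero total variance; R2 undefined", call. = FALSE)
  pred <- stats::predict(result$model, re.form = NA)
  s2_f <- stats::var(pred)
  total <- s2_f + result$sigma2_dyad + result$sigma2_res
  if (total <= 0) stop("zero total variance; R2 undefined", call. = FALSE)
  c(marginal = s2_f / total,
    conditional = (s2_f + result$sigma2_dyad) / total)
}

#' Tukey-adjusted pairwise phase contrasts
#'
#' Estimated marginal means per phase (averaged over contexts) and all
#' pairwise phase differences with 95% confidence intervals and
#' Tukey-adjusted p-values.
#'
#' @param result an [fit_sync_lmm()] result.
#' @return list with `emmeans` (per-phase marginal means) and `contrasts`
#'   (estimate, SE, df, lower.CL, upper.CL, t.ratio, p.value per pair).
#' @export
phase_contrasts <- function(result) {
  if (isTRUE(result$degenerate)) {
    ph <- levels(result$data$phase)
    mu <- mean(result$data$.y)
    pairs <- t(utils::combn(ph, 2))
    return(list(
      emmeans = data.frame(phase = ph, emmean = mu, SE = 0),
      contrasts = data.frame(
        contrast = paste(pairs[, 1], "-", pairs[, 2]), estimate = 0, SE = 0,
        df = NA_real_, lower.CL = 0, upper.CL = 0, t.ratio = NA_real_,
        p.value = 1)))
  }
  emm <- suppressMessages(emmeans::emmeans(result$model, ~ phase))
  ct <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  list(emmeans = as.data.frame(emm),
       contrasts = merge(as.data.frame(stats::confint(ct)),
                         as.data.frame(ct)[, c("contrast", "t.ratio", "p.value")],
                         by = "contrast"))
}

#' Descriptive cell marginals of a metrics table
#'
#' Mean, SD and n per cell of the grouping factors, for one measure of the
#' long-format metrics table (the descriptive statistics the omnibus
#' analyses consume).
#'
#' @param table a metrics table (see [build_metrics_table()]).
#' @param measure measure name to summarize.
#' @param by character vector of grouping columns (default role and phase).
#' @return data.frame with the grouping columns plus `mean`, `sd`, `n`.
#' @export
descriptive_marginals <- function(table, measure, by = c("role", "phase")) {
  sub <- table[table$measure == measure, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for measure ", measure, call. = FALSE)
  groups <- sub[, by, drop = FALSE]
  key <- interaction(groups, drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    rows <- sub[key == k, ]
    vals <- rows$value[!is.na(rows$value)]
    cell <- rows[1, by, drop = FALSE]
    cell$mean <- if (length(vals)) mean(vals) else NA_real_
    cell$sd <- if (length(vals) >= 2) stats::sd(vals) else NA_real_
    cell$n <- length(vals)
    if (!length(vals))
      warning("empty cell ", k, call. = FALSE)
    cell
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a balanced synchronization table with known components
#'
#' Generates `sync_pct = phase mean + dyad intercept + residual` over a
#' balanced dyad x trial(context) x phase design — the generating model the
#' mixed-model recovery checks use, with every variance component known.
#'
#' @param n_dyads number of dyads.
#' @param phase_means named numeric vector over `baseline`, `audio`,
#'   `silence`.
#' @param sigma_dyad SD of the dyad random intercept.
#' @param sigma_res residual SD.
#' @param seed optional integer seed.
#' @return data.frame with columns `dyad`, `trial`, `context`, `phase`,
#'   `sync_pct`.
#' @export
simulate_sync_table <- function(n_dyads = 24,
                                phase_means = c(baseline = 40, audio = 25,
                                                silence = 31),
                                sigma_dyad = 15, sigma_res = 10,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  contexts <- c("neutral", "negative", "positive")
  phases <- c("baseline", "audio", "silence")
  grid <- expand.grid(phase = phases, trial = 1:3, dyad = seq_len(n_dyads),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$context <- contexts[grid$trial]
  grid$dyad <- sprintf("dyad%02d", grid$dyad)
  b <- stats::rnorm(n_dyads, 0, sigma_dyad)
  names(b) <- unique(grid$dyad)
  grid$sync_pct <- phase_means[grid$phase] + b[grid$dyad] +
    stats::rnorm(nrow(grid), 0, sigma_res)
  grid[, c("dyad", "trial", "context", "phase", "sync_pct")]
}
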