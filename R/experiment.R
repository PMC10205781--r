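# Replication engine: simulate n_reps cohorts, fit the five estimators on
# each, pool hazard ratios across replicates with percentile intervals.

MODEL_SET <- data.frame(
  key = c("conventional_adj", "two_stage_unadj", "two_stage_adj",
          "tsri_unadj", "tsri_adj"),
  method = c("conventional", "two_stage", "two_stage", "tsri", "tsri"),
  adjusted = c(TRUE, FALSE, TRUE, FALSE, TRUE),
  stringsAsFactors = FALSE
)

#' Run one scenario end to end
#'
#' Calibrates the scenario (unless `params` is supplied), simulates
#' `n_reps` independent cohorts, fits the five estimators on each
#' (conventional adjusted Cox; two-stage IV unadjusted/adjusted; 2SRI
#' unadjusted/adjusted), excludes replicates where any fit failed to
#' converge, and pools each model's hazard-ratio estimates into a point
#' estimate (arithmetic mean; geometric mean and median are also stored)
#' with a 2.5/97.5-percentile confidence interval.
#'
#' @param cfg A [scenario_config()].
#' @param params Optional pre-computed [calibrate_scenario()] result.
#' @param reps Optional override of `cfg$n_reps`.
#' @param calibration_n Calibration sample size, passed to
#'   [calibrate_scenario()] when `params` is `NULL`.
#' @param max_fail_frac Abort the scenario if more than this fraction of
#'   replicates has a non-converged fit (default 1%).
#' @param progress Emit a message every 100 replicates?
#' @return An object of class `scenario_summary`: a per-model table
#'   (`$models`, columns `model`, `method`, `adjusted`, `point_hr`,
#'   `ci_low`, `ci_high`, `geo_hr`, `median_hr`), the replicate-level HR
#'   matrix (`$estimates`), mean realized cohort marginals, counts of used
#'   and failed replicates, and the config and calibrated parameters.
#' @examples
#' cfg <- scenario_config(n_subjects = 500, n_reps = 5, true_hr = 2,
#'                        strength_c1 = 0, strength_c2 = 0)
#' run_scenario(cfg, calibration_n = 2e4)
#' @export
run_scenario <- function(cfg, params = NULL, reps = NULL,
                         calibration_n = 1e6, max_fail_frac = 0.01,
                         progress = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(params)) params <- calibrate_scenario(cfg, calibration_n)
  n_reps <- if (is.null(reps)) cfg$n_reps else as.integer(reps)

  hr <- matrix(NA_real_, n_reps, nrow(MODEL_SET),
               dimnames = list(NULL, MODEL_SET$key))
  log_hr <- hr
  ok <- matrix(FALSE, n_reps, nrow(MODEL_SET),
               dimnames = list(NULL, MODEL_SET$key))
  marg <- matrix(NA_real_, n_reps, 3,
                 dimnames = list(NULL, c("treat_prev", "outcome_incidence",
                                         "iv_or")))

  for (r in seq_len(n_reps)) {
    cohort <- simulate_cohort(cfg, params, rep_index = r)
    s <- cohort_summaries(cohort)
    marg[r, ] <- c(s$treat_prev, s$outcome_incidence, as.numeric(s$iv_or))
    for (m in seq_len(nrow(MODEL_SET))) {
      fit <- tryCatch(
        iv_coxph(cohort, method = MODEL_SET$method[m],
                 adjusted = MODEL_SET$adjusted[m]),
        error = function(e) NULL
      )
      if (!is.null(fit) && fit$converged && is.finite(fit$log_hr)) {
        hr[r, m] <- fit$hr
        log_hr[r, m] <- fit$log_hr
        ok[r, m] <- TRUE
      }
    }
    if (progress && r %% 100L == 0L)
      message(sprintf("  [%s HR=%g] replicate %d/%d", cfg$name, cfg$true_hr,
                      r, n_reps))
  }

  used <- rowSums(ok) == nrow(MODEL_SET)   # drop reps with any failed fit
  n_failed <- sum(!used)
  if (n_failed > max_fail_frac * n_reps)
    stop_invalid("scenario aborted: %d/%d replicates had non-converged fits",
                 n_failed, n_reps)

  pool <- do.call(rbind, lapply(seq_len(nrow(MODEL_SET)), function(m) {
    est <- summarize_estimates(hr[used, m])
    data.frame(
      model = MODEL_SET$key[m],
      method = MODEL_SET$method[m],
      adjusted = MODEL_SET$adjusted[m],
      point_hr = est$point,
      ci_low = est$ci_low,
      ci_high = est$ci_high,
      geo_hr = exp(mean(log_hr[used, m])),
      median_hr = stats::median(hr[used, m]),
      stringsAsFactors = FALSE
    )
  }))

  structure(list(
    scenario_name = cfg$name,
    true_hr = cfg$true_hr,
    models = pool,
    estimates = hr[used, , drop = FALSE],
    mean_treat_prev = mean(marg[, "treat_prev"]),
    mean_outcome_incidence = mean(marg[, "outcome_incidence"]),
    mean_iv_or = mean(marg[, "iv_or"]),
    n_reps_used = sum(used),
    n_failed = n_failed,
    config = cfg,
    params = params
  ), class = "scenario_summary")
}

#' Pool replicate-level hazard-ratio estimates
#'
#' Point estimate is the arithmetic mean; the interval is the empirical
#' 2.5th and 97.5th percentile with linear interpolation between order
#' statistics ([stats::quantile()] type 7).
#'
#' @param hrs Nonempty vector of finite positive HR estimates.
#' @return A list with `point`, `ci_low`, `ci_high`.
#' @examples
#' summarize_estimates(c(1, 1, 1, 1))
#' @export
summarize_estimates <- function(hrs) {
  if (length(hrs) == 0L) stop_invalid("no estimates to summarize")
  if (any(!is.finite(hrs) | hrs <= 0))
    stop_invalid("estimates must be finite and positive (filter failures upstream)")
  q <- stats::quantile(hrs, c(0.025, 0.975), names = FALSE, type = 7)
  list(point = mean(hrs), ci_low = q[1L], ci_high = q[2L])
}

#' @export
print.scenario_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Scenario '%s', true HR = %g: %d replicates used, %d failed\n",
              x$scenario_name, x$true_hr, x$n_reps_used, x$n_failed))
  cat(sprintf("  mean treat prev %.3f, outcome incidence %.3f, IV OR %.2f\n",
              x$mean_treat_prev, x$mean_outcome_incidence, x$mean_iv_or))
  tab <- x$models
  cat("  pooled hazard ratios (mean [2.5-97.5 percentile]):\n")
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("    %-17s %s  %.*f [%.*f-%.*f]\n", tab$model[i],
                if (tab$adjusted[i]) "adj  " else "unadj",
                digits, tab$point_hr[i], digits, tab$ci_low[i],
                digits, tab$ci_high[i]))
  }
  invisible(x)
}

#' @export
plot.scenario_summary <- function(x, ...) {
  tab <- x$models
  k <- nrow(tab)
  ylim <- range(tab$ci_low, tab$ci_high, x$true_hr)
  plot(seq_len(k), tab$point_hr, ylim = ylim, xaxt = "n", pch = 19,
       xlab = "", ylab = "pooled hazard ratio",
       main = sprintf("%s, true HR %g", x$scenario_name, x$true_hr), ...)
  graphics::arrows(seq_len(k), tab$ci_low, seq_len(k), tab$ci_high,
                   angle = 90, code = 3, length = 0.05)
  graphics::abline(h = x$true_hr, lty = 2, col = "grey40")
  graphics::axis(1, at = seq_len(k), labels = tab$model, las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' Assemble scenario summaries into a results table
#'
#' One row per (scenario, true HR), with realized marginals and each
#' model's pooled HR formatted as `"X.XX [lo-hi]"`; missing models render
#' `"NA"`.  When `csv_path` is given, a long-form machine-readable CSV
#' (one row per scenario x model) is written alongside.
#'
#' @param summaries A list of `scenario_summary` objects.
#' @param csv_path Optional path for the long-form CSV.
#' @return A data frame, one row per summary.
#' @export
build_results_table <- function(summaries, csv_path = NULL) {
  if (inherits(summaries, "scenario_summary")) summaries <- list(summaries)
  if (length(summaries) == 0L) stop_invalid("no summaries supplied")

  fmt <- function(tab, key) {
    i <- match(key, tab$model)
    if (is.na(i) || !is.finite(tab$point_hr[i])) return("NA")
    sprintf("%.2f [%.2f-%.2f]", tab$point_hr[i], tab$ci_low[i],
            tab$ci_high[i])
  }
  wide <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(
      scenario = s$scenario_name,
      strength_c1 = s$config$strength_c1,
      strength_c2 = s$config$strength_c2,
      treat_prev = round(s$mean_treat_prev, 2),
      outcome_incidence = round(s$mean_outcome_incidence, 2),
      iv_or = round(s$mean_iv_or, 2),
      true_hr = s$true_hr,
      conventional_adj = fmt(s$models, "conventional_adj"),
      two_stage_unadj = fmt(s$models, "two_stage_unadj"),
      two_stage_adj = fmt(s$models, "two_stage_adj"),
      tsri_unadj = fmt(s$models, "tsri_unadj"),
      tsri_adj = fmt(s$models, "tsri_adj"),
      stringsAsFactors = FALSE
    )
  }))

  if (!is.null(csv_path)) {
    long <- do.call(rbind, lapply(summaries, function(s) {
      cbind(
        data.frame(scenario = s$scenario_name, true_hr = s$true_hr,
                   stringsAsFactors = FALSE),
        s$models[, c("model", "adjusted", "point_hr", "ci_low", "ci_high")],
        data.frame(n_reps_used = s$n_reps_used, n_failed = s$n_failed,
                   mean_treat_prev = s$mean_treat_prev,
                   mean_outcome_incidence = s$mean_outcome_incidence,
                   mean_iv_or = s$mean_iv_or)
      )
    }))
    utils::write.csv(long, csv_path, row.names = FALSE, quote = FALSE)
  }
  wide
}
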