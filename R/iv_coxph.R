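#' Instrumental-variable Cox proportional-hazards estimators
#'
#' Fits one of the three estimators compared by the package to a single
#' simulated (or user-supplied) cohort:
#'
#' * `"conventional"` -- Cox regression of the outcome on the observed
#'   treatment (plus the measured confounder if `adjusted`), ignoring
#'   unmeasured confounding;
#' * `"two_stage"` -- two-stage IV: a linear first stage of treatment on
#'   the instrument, then a Cox second stage on the *predicted* treatment
#'   (two-stage predictor substitution);
#' * `"tsri"` -- two-stage residual inclusion: a Cox second stage on the
#'   observed treatment plus the first-stage residual as a control
#'   function; the reported effect is the coefficient on observed
#'   treatment.
#'
#' `adjusted = TRUE` enters the measured confounder `c1` in *both* stages
#' (for the IV estimators) or in the Cox model (conventional).  The
#' unmeasured confounder `c2` never enters any fitted model.
#'
#' @param cohort A data frame with columns `t_obs`, `event`, `x`, `z` and
#'   (if adjusted) `c1`, e.g. from [simulate_cohort()].
#' @param method `"conventional"`, `"two_stage"` or `"tsri"`.
#' @param adjusted Adjust for the measured confounder?
#' @return An object of class `iv_coxph` with components `model_label`,
#'   `adjusted`, `log_hr`, `se`, `hr` (`= exp(log_hr)`), `converged`,
#'   `coefficients`, `covariate_labels`, `first_stage` (for the IV
#'   methods) and the underlying `cox_fit`.
#' @examples
#' cfg <- scenario_config(n_subjects = 2000, true_hr = 2,
#'                        strength_c1 = 0, strength_c2 = 0)
#' par <- calibrate_scenario(cfg, calibration_n = 2e4)
#' coh <- simulate_cohort(cfg, par)
#' iv_coxph(coh, method = "two_stage", adjusted = FALSE)
#' @seealso [fit_first_stage()], [fit_cox_ph()], [run_scenario()]
#' @export
iv_coxph <- function(cohort,
                     method = c("conventional", "two_stage", "tsri"),
                     adjusted = TRUE) {
  method <- match.arg(method)
  first_stage <- NULL

  if (method == "conventional") {
    covs <- cbind(x = cohort$x)
  } else {
    first_stage <- fit_first_stage(cohort, adjusted = adjusted)
    if (method == "two_stage") {
      if (stats::sd(first_stage$fitted) < 1e-10)
        stop_invalid(paste("predicted treatment is constant: null or weak",
                           "instrument (first-stage z coefficient ~ 0)"))
      covs <- cbind(x_hat = first_stage$fitted)
    } else {
      if (sqrt(mean(first_stage$residuals^2)) < 1e-10)
        stop_invalid("first-stage residuals are (near) zero: treatment is deterministically explained")
      covs <- cbind(x = cohort$x, residual = first_stage$residuals)
    }
  }
  if (adjusted) covs <- cbind(covs, c1 = cohort$c1)

  fit <- fit_cox_ph(cohort$t_obs, cohort$event, covs)
  structure(list(
    model_label = method,
    adjusted = adjusted,
    log_hr = fit$log_hr,
    se = fit$se,
    hr = fit$hr,
    converged = fit$converged,
    coefficients = fit$coefficients,
    covariate_labels = fit$labels,
    first_stage = first_stage,
    cox_fit = fit,
    n = fit$n,
    n_events = fit$n_events
  ), class = "iv_coxph")
}

#' Conventional covariate-adjusted Cox model
#'
#' Convenience wrapper: `iv_coxph(cohort, "conventional", adjusted)`.
#' @inheritParams iv_coxph
#' @return An `iv_coxph` object.
#' @export
conventional_cox <- function(cohort, adjusted = TRUE) {
  iv_coxph(cohort, method = "conventional", adjusted = adjusted)
}

#' Two-stage IV estimator (linear first stage, Cox second stage)
#'
#' Convenience wrapper: `iv_coxph(cohort, "two_stage", adjusted)`.
#' @inheritParams iv_coxph
#' @return An `iv_coxph` object.
#' @export
two_stage_iv <- function(cohort, adjusted = TRUE) {
  iv_coxph(cohort, method = "two_stage", adjusted = adjusted)
}

#' Two-stage residual-inclusion (2SRI) estimator
#'
#' Convenience wrapper: `iv_coxph(cohort, "tsri", adjusted)`.
#' @inheritParams iv_coxph
#' @return An `iv_coxph` object.
#' @export
two_stage_residual_inclusion <- function(cohort, adjusted = TRUE) {
  iv_coxph(cohort, method = "tsri", adjusted = adjusted)
}

model_label_pretty <- c(
  conventional = "conventional Cox PH",
  two_stage = "two-stage IV (Cox second stage)",
  tsri = "two-stage residual inclusion (2SRI)"
)

#' @export
print.iv_coxph <- function(x, digits = 4, ...) {
  cat(sprintf("%s, %s\n", model_label_pretty[[x$model_label]],
              if (x$adjusted) "adjusted for measured confounder"
              else "unadjusted"))
  cat(sprintf("  treatment HR = %.*f (log HR %.*f, SE %.*f)%s\n",
              digits, x$hr, digits, x$log_hr, digits, x$se,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  covariates: %s; %d subjects, %d events\n",
              paste(x$covariate_labels, collapse = ", "), x$n, x$n_events))
  invisible(x)
}

#' @export
summary.iv_coxph <- function(object, conf_level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- cbind(
    coef = object$coefficients,
    `exp(coef)` = exp(object$coefficients),
    se = object$cox_fit$se_all,
    z = object$coefficients / object$cox_fit$se_all,
    `Pr(>|z|)` = 2 * stats::pnorm(-abs(object$coefficients /
                                         object$cox_fit$se_all))
  )
  out <- list(
    model_label = object$model_label,
    adjusted = object$adjusted,
    table = tab,
    hr = object$hr,
    hr_ci = exp(object$log_hr + c(-1, 1) * zq * object$se),
    conf_level = conf_level,
    converged = object$converged,
    n = object$n, n_events = object$n_events
  )
  class(out) <- "summary.iv_coxph"
  out
}

#' @export
print.summary.iv_coxph <- function(x, ...) {
  cat(sprintf("%s, %s (%d subjects, %d events)\n",
              model_label_pretty[[x$model_label]],
              if (x$adjusted) "adjusted" else "unadjusted", x$n, x$n_events))
  print(round(x$table, 4))
  cat(sprintf("treatment HR %.3f, %g%% Wald CI [%.3f, %.3f]%s\n",
              x$hr, 100 * x$conf_level, x$hr_ci[1], x$hr_ci[2],
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.iv_coxph <- function(object, ...) object$coefficients

#' @export
vcov.iv_coxph <- function(object, ...) {
  v <- as.matrix(object$cox_fit$var)
  dimnames(v) <- list(object$covariate_labels, object$covariate_labels)
  v
}

#' @export
confint.iv_coxph <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients
  se <- object$cox_fit$se_all
  ci <- cbind(est - zq * se, est + zq * se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
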