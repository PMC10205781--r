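# Scenario calibration.  The marginal quantities the scenarios prescribe
# (treatment prevalence, outcome incidence, instrument-treatment odds ratio)
# are not parameters of the generating model, so the model's intercepts are
# solved for by root-finding: conditional expectations of each target are
# computed over one large fixed-seed covariate sample, giving smooth
# monotone curves in the unknown, and Brent's method finds the root.
# Solving order: alpha0 for prevalence, alpha_z for the instrument odds
# ratio (alpha0 re-solved at every alpha_z), then lambda0 for incidence
# with the scenario's true treatment effect included.

#' Calibrate a scenario's nuisance parameters
#'
#' Solves the treatment-model intercept `alpha0`, the instrument
#' coefficient `alpha_z` and the baseline hazard `lambda0` so that the
#' scenario hits its target treatment prevalence, instrument--treatment
#' odds ratio and outcome incidence.  Confounder coefficients are fixed by
#' the scenario's strengths (identical in the treatment and hazard models);
#' the treatment log-hazard coefficient is `log(true_hr)` exactly.
#'
#' @param cfg A [scenario_config()].
#' @param calibration_n Size of the fixed-seed calibration covariate
#'   sample over which expectations are computed (default `1e6`).
#' @param tol_prev,tol_inc,tol_or Calibration tolerances for treatment
#'   prevalence, outcome incidence and the instrument odds ratio.
#' @return An object of class `calibrated_params`: coefficients of the
#'   treatment model (`alpha0`, `alpha_z`, `alpha_c1`, `alpha_c2`), of the
#'   hazard model (`lambda0`, `beta_x`, `gamma_c1`, `gamma_c2`), the
#'   achieved marginals measured on a realized calibration cohort, and the
#'   calibration seed.
#' @examples
#' cfg <- scenario_config(strength_c1 = 0, strength_c2 = 0,
#'                        target_treat_prev = 0.5)
#' par <- calibrate_scenario(cfg, calibration_n = 2e4)
#' abs(par$alpha0) < 0.05   # logistic symmetry
#' @export
calibrate_scenario <- function(cfg, calibration_n = 1e6,
                               tol_prev = 0.005, tol_inc = 0.01,
                               tol_or = 0.1) {
  stopifnot(inherits(cfg, "scenario_config"))
  sc <- strength_coefs(cfg)
  calibration_seed <- derive_seeds(cfg$base_seed, 1L)[1L]

  samp <- with_seed(calibration_seed, {
    cc <- generate_confounders(calibration_n, cfg$confounder_corr,
                               cfg$confounder_cutoff)
    z <- generate_instrument(calibration_n, cfg$iv_prevalence)
    list(c1 = cc$c1, c2 = cc$c2, z = z)
  })
  conf_lp <- sc["c1"] * samp$c1 + sc["c2"] * samp$c2

  expected_prev <- function(alpha0, alpha_z) {
    mean(cfg$iv_prevalence * expit(alpha0 + alpha_z + conf_lp) +
           (1 - cfg$iv_prevalence) * expit(alpha0 + conf_lp))
  }
  expected_or <- function(alpha0, alpha_z) {
    p1 <- mean(expit(alpha0 + alpha_z + conf_lp))
    p0 <- mean(expit(alpha0 + conf_lp))
    (p1 / (1 - p1)) / (p0 / (1 - p0))
  }
  solve_alpha0 <- function(alpha_z) {
    solve_root(function(a) expected_prev(a, alpha_z) - cfg$target_treat_prev,
               -5, 5, "treatment prevalence (alpha0)")
  }

  alpha_z <- if (abs(cfg$target_iv_or - 1) < 1e-12) 0 else {
    solve_root(function(az) {
      expected_or(solve_alpha0(az), az) - cfg$target_iv_or
    }, if (cfg$target_iv_or > 1) 1e-6 else -5,
       if (cfg$target_iv_or > 1) 5 else -1e-6,
       "instrument odds ratio (alpha_z)")
  }
  alpha0 <- solve_alpha0(alpha_z)

  if (abs(expected_prev(alpha0, alpha_z) - cfg$target_treat_prev) > tol_prev)
    stop_invalid("calibration failed to reach the treatment-prevalence target")
  if (abs(expected_or(alpha0, alpha_z) - cfg$target_iv_or) > tol_or)
    stop_invalid("calibration failed to reach the instrument-OR target")

  # expected incidence of the exponential event/censoring race truncated
  # at tau, marginal over the latent treatment status; Weibull shape k is
  # handled by working on the t^k scale, where both channels are
  # exponential and the horizon becomes tau^k
  beta_x <- log(cfg$true_hr)
  p_treat <- expit(alpha0 + alpha_z * samp$z + conf_lp)
  tau_k <- cfg$followup_horizon^cfg$weibull_shape
  race <- function(rate) {
    tot <- rate + cfg$censoring_rate
    rate / tot * (1 - exp(-tot * tau_k))
  }
  expected_inc <- function(lambda0) {
    base <- lambda0 * exp(conf_lp)
    mean(p_treat * race(base * exp(beta_x)) + (1 - p_treat) * race(base))
  }
  lambda0 <- solve_root(
    function(l) expected_inc(exp(l)) - cfg$target_outcome_incidence,
    log(1e-8), log(10), "outcome incidence (lambda0)")
  lambda0 <- exp(lambda0)
  if (abs(expected_inc(lambda0) - cfg$target_outcome_incidence) > tol_inc)
    stop_invalid("calibration failed to reach the outcome-incidence target")

  params <- structure(list(
    alpha0 = alpha0, alpha_z = alpha_z,
    alpha_c1 = unname(sc["c1"]), alpha_c2 = unname(sc["c2"]),
    lambda0 = lambda0, beta_x = beta_x,
    gamma_c1 = unname(sc["c1"]), gamma_c2 = unname(sc["c2"]),
    calibration_seed = calibration_seed,
    calibration_n = calibration_n
  ), class = "calibrated_params")

  # realized marginals on one drawn calibration cohort
  realized <- with_seed(calibration_seed + 1L, {
    x <- assign_treatment(samp$z, samp$c1, samp$c2, params)
    surv <- generate_survival(x, samp$c1, samp$c2, params, cfg)
    list(prev = mean(x), inc = mean(surv$event),
         or = odds_ratio_2x2(samp$z, x))
  })
  params$achieved_treat_prev <- realized$prev
  params$achieved_outcome_incidence <- realized$inc
  params$achieved_iv_or <- realized$or
  params
}

# Brent root-finding with bracket widening and a calibration-specific
# failure message naming the target.
solve_root <- function(f, lower, upper, what, max_widen = 8L) {
  fl <- f(lower); fu <- f(upper)
  k <- 0L
  while (is.finite(fl) && is.finite(fu) && fl * fu > 0 && k < max_widen) {
    span <- upper - lower
    lower <- lower - span
    upper <- upper + span
    fl <- f(lower); fu <- f(upper)
    k <- k + 1L
  }
  if (!is.finite(fl) || !is.finite(fu) || fl * fu > 0)
    stop_invalid("calibration bracket not found for %s", what)
  stats::uniroot(f, c(lower, upper), tol = 1e-9, maxiter = 200L)$root
}

#' @export
print.calibrated_params <- function(x, ...) {
  cat("Calibrated scenario parameters\n")
  cat(sprintf("  treatment model: alpha0 = %.4f, alpha_z = %.4f, alpha_c1 = %.3f, alpha_c2 = %.3f\n",
              x$alpha0, x$alpha_z, x$alpha_c1, x$alpha_c2))
  cat(sprintf("  hazard model: lambda0 = %.6f, beta_x = %.4f (HR %.3f), gamma_c1 = %.3f, gamma_c2 = %.3f\n",
              x$lambda0, x$beta_x, exp(x$beta_x), x$gamma_c1, x$gamma_c2))
  cat(sprintf("  achieved: treat prev %.4f, outcome incidence %.4f, IV OR %.3f\n",
              x$achieved_treat_prev, x$achieved_outcome_incidence,
              x$achieved_iv_or))
  cat(sprintf("  calibration: n = %g, seed = %d\n",
              x$calibration_n, x$calibration_seed))
  invisible(x)
}
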