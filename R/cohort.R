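# Cohort generators.  Each generator draws from R's global RNG stream;
# simulate_cohort() seeds that stream deterministically per replicate, so a
# (config, seed, rep_index) triple always reproduces the same cohort.

#' Generate the latent confounder pair
#'
#' Draws `(C1, L)` from a bivariate standard normal with correlation `rho`
#' and dichotomizes the second variate at `cutoff` to give the binary
#' confounder `C2 = 1(L > cutoff)`.  `C1` is the measured continuous
#' confounder; `C2` is unmeasured by every fitted model.
#'
#' @param n Number of subjects.
#' @param rho Correlation of the latent pair, in `[-1, 1]`.
#' @param cutoff Dichotomization threshold (default 0.4, giving
#'   `P(C2 = 1) = 1 - pnorm(0.4) ~ 0.345`).
#' @return A list with numeric vector `c1` and integer 0/1 vector `c2`.
#' @examples
#' set.seed(1)
#' cc <- generate_confounders(5, rho = 0.1)
#' @export
generate_confounders <- function(n, rho = 0.1, cutoff = 0.4) {
  if (!is_count(n)) stop_invalid("n must be a positive integer")
  if (!is.finite(rho) || abs(rho) > 1)
    stop_invalid("rho must lie in [-1, 1], got %s", format(rho))
  c1 <- stats::rnorm(n)
  latent <- rho * c1 + sqrt(1 - rho^2) * stats::rnorm(n)
  list(c1 = c1, c2 = as.integer(latent > cutoff))
}

#' Generate the binary instrument
#'
#' Independent Bernoulli draws, independent of the confounders (drawn from
#' a later segment of the replicate's RNG stream).
#'
#' @param n Number of subjects.
#' @param prev Instrument prevalence in `[0, 1]`.
#' @return Integer 0/1 vector of length `n`.
#' @export
generate_instrument <- function(n, prev = 0.40) {
  if (!is_count(n)) stop_invalid("n must be a positive integer")
  if (!is.numeric(prev) || length(prev) != 1L || is.na(prev) ||
      prev < 0 || prev > 1)
    stop_invalid("prev must lie in [0, 1]")
  as.integer(stats::runif(n) < prev)
}

#' Assign treatment from the logistic propensity model
#'
#' Treatment is Bernoulli with success probability
#' `expit(alpha0 + alpha_z z + alpha_c1 c1 + alpha_c2 c2)`.
#'
#' @param z,c1,c2 Instrument and confounder vectors of equal length.
#' @param params A `calibrated_params` object (or any list providing
#'   `alpha0`, `alpha_z`, `alpha_c1`, `alpha_c2`).
#' @return Integer 0/1 treatment vector.
#' @export
assign_treatment <- function(z, c1, c2, params) {
  n <- length(z)
  if (length(c1) != n || length(c2) != n)
    stop_invalid("z, c1, c2 must have equal length")
  lp <- params$alpha0 + params$alpha_z * z +
    params$alpha_c1 * c1 + params$alpha_c2 * c2
  bad <- which(!is.finite(lp))
  if (length(bad))
    stop_invalid("non-finite treatment linear predictor at index %d", bad[1L])
  as.integer(stats::runif(n) < expit(lp))
}

#' Generate observed follow-up times and event indicators
#'
#' Latent event times are Weibull with shape `cfg$weibull_shape` (1 =
#' exponential, constant hazard) and subject-specific rate
#' `lambda0 * exp(beta_x x + gamma_c1 c1 + gamma_c2 c2)`; latent censoring
#' times are Weibull with the same shape and rate `cfg$censoring_rate`
#' (infinite when the rate is 0).  Follow-up is truncated administratively
#' at `cfg$followup_horizon`.
#'
#' @param x,c1,c2 Treatment and confounder vectors of equal length.
#' @param params A `calibrated_params` object (needs `lambda0`, `beta_x`,
#'   `gamma_c1`, `gamma_c2`).
#' @param cfg The `scenario_config` (needs `censoring_rate`,
#'   `followup_horizon`, `weibull_shape`).
#' @return A list with numeric vector `t_obs` and integer 0/1 vector
#'   `event`.
#' @export
generate_survival <- function(x, c1, c2, params, cfg) {
  n <- length(x)
  if (length(c1) != n || length(c2) != n)
    stop_invalid("x, c1, c2 must have equal length")
  if (!is.finite(params$lambda0) || params$lambda0 <= 0)
    stop_invalid("lambda0 must be a positive rate, got %s",
                 format(params$lambda0))
  shape <- cfg$weibull_shape
  tau <- cfg$followup_horizon
  rate <- params$lambda0 *
    exp(params$beta_x * x + params$gamma_c1 * c1 + params$gamma_c2 * c2)
  t_event <- (stats::rexp(n) / rate)^(1 / shape)
  t_cens <- if (cfg$censoring_rate > 0) {
    (stats::rexp(n) / cfg$censoring_rate)^(1 / shape)
  } else {
    rep(Inf, n)
  }
  t_obs <- pmin(t_event, t_cens, tau)
  list(t_obs = t_obs, event = as.integer(t_event <= pmin(t_cens, tau)))
}

#' Simulate one calibrated cohort
#'
#' Composes the four generators under a per-replicate seed derived
#' deterministically from `cfg$base_seed` and `rep_index`, so replicates
#' are reproducible individually and mutually independent.
#'
#' @param cfg A `scenario_config`.
#' @param params The matching `calibrated_params` from
#'   [calibrate_scenario()].
#' @param rep_index Replicate number (1-based).
#' @return A `data.frame` of class `iv_cohort` with columns `z`, `c1`,
#'   `c2`, `x`, `t_obs`, `event` and attribute `rep_seed`.
#' @examples
#' cfg <- scenario_config(strength_c1 = 0, strength_c2 = 0, n_subjects = 200)
#' par <- calibrate_scenario(cfg, calibration_n = 1e4)
#' coh <- simulate_cohort(cfg, par, rep_index = 1)
#' head(coh)
#' @export
simulate_cohort <- function(cfg, params, rep_index = 1L) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is_count(rep_index)) stop_invalid("rep_index must be a positive integer")
  rep_seed <- derive_seeds(cfg$base_seed, rep_index + 1L)[rep_index + 1L]
  coh <- with_seed(rep_seed, {
    cc <- generate_confounders(cfg$n_subjects, cfg$confounder_corr,
                               cfg$confounder_cutoff)
    z <- generate_instrument(cfg$n_subjects, cfg$iv_prevalence)
    x <- assign_treatment(z, cc$c1, cc$c2, params)
    surv <- generate_survival(x, cc$c1, cc$c2, params, cfg)
    data.frame(z = z, c1 = cc$c1, c2 = cc$c2, x = x,
               t_obs = surv$t_obs, event = surv$event)
  })
  attr(coh, "rep_seed") <- rep_seed
  attr(coh, "scenario") <- cfg$name
  class(coh) <- c("iv_cohort", "data.frame")
  coh
}

#' Marginal summaries of one cohort
#'
#' @param cohort An `iv_cohort` (or any data frame with columns `z`, `x`,
#'   `event`).
#' @return A list with `treat_prev`, `outcome_incidence`, `iv_or` (2x2
#'   odds ratio between instrument and treatment) and
#'   `censor_rate_realized` (proportion censored).
#' @export
cohort_summaries <- function(cohort) {
  if (nrow(cohort) == 0L) stop_invalid("cohort is empty")
  list(
    treat_prev = mean(cohort$x),
    outcome_incidence = mean(cohort$event),
    iv_or = odds_ratio_2x2(cohort$z, cohort$x),
    censor_rate_realized = mean(cohort$event == 0)
  )
}

#' Write a cohort to a headered CSV
#'
#' Columns `z,c1,c2,x,t_obs,event`, one row per subject; intended for
#' debugging and cross-language checks.
#'
#' @param cohort An `iv_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, c("z", "c1", "c2", "x",
                                             "t_obs", "event")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
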