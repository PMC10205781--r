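#' Scenario configuration
#'
#' Bundles every user-facing setting of one simulation scenario: the cohort
#' size and replicate count, the true treatment hazard ratio, the strengths
#' of the measured (continuous, `C1`) and unmeasured (binary, `C2`)
#' confounders, and the marginal calibration targets (treatment prevalence,
#' outcome incidence, instrument prevalence and instrument--treatment odds
#' ratio).
#'
#' Confounder strengths are interpreted on the linear-predictor scale by
#' default: the same value is used as the coefficient of the confounder in
#' the treatment log-odds and in the log-hazard of the outcome.  With
#' `strength_scale = "ratio"` the strengths are read as odds/hazard ratios
#' instead, i.e. the coefficients become `log(strength)`.
#'
#' @param name Scenario label used in results tables.
#' @param n_subjects Cohort size per replicate.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param true_hr True treatment hazard ratio (conditional on both
#'   confounders); the treatment coefficient in the hazard is `log(true_hr)`.
#' @param strength_c1,strength_c2 Nonnegative confounder strengths for the
#'   measured and unmeasured confounder.
#' @param strength_scale `"linear-predictor"` (default) or `"ratio"`.
#' @param confounder_corr Correlation of the latent bivariate-normal
#'   confounder pair; values outside `[0, 0.2]` trigger a warning.
#' @param confounder_cutoff Dichotomization threshold producing the binary
#'   confounder from the second latent normal variate.
#' @param iv_prevalence Bernoulli prevalence of the binary instrument.
#' @param target_treat_prev Target marginal treatment prevalence.
#' @param target_outcome_incidence Target marginal outcome incidence over
#'   the follow-up horizon.
#' @param target_iv_or Target marginal odds ratio between instrument and
#'   treatment.
#' @param censoring_rate Exponential rate of the random-censoring channel
#'   (per unit time); `0` disables random censoring.
#' @param followup_horizon Administrative censoring time `tau`.
#' @param weibull_shape Shape of the event/censoring time distribution;
#'   `1` gives exponential times with a constant hazard.
#' @param base_seed Integer seed from which the calibration stream and all
#'   per-replicate streams are derived.
#' @return An object of class `scenario_config` (a named list).
#' @examples
#' cfg <- scenario_config(true_hr = 2, n_reps = 10)
#' cfg$true_hr
#' @seealso [scenario_preset()], [load_config()], [calibrate_scenario()]
#' @export
scenario_config <- function(name = "custom",
                            n_subjects = 10000L,
                            n_reps = 1000L,
                            true_hr = 1,
                            strength_c1 = 1.5,
                            strength_c2 = 2.0,
                            strength_scale = c("linear-predictor", "ratio"),
                            confounder_corr = 0.1,
                            confounder_cutoff = 0.4,
                            iv_prevalence = 0.40,
                            target_treat_prev = 0.24,
                            target_outcome_incidence = 0.09,
                            target_iv_or = 4.55,
                            censoring_rate = 0.03,
                            followup_horizon = 5,
                            weibull_shape = 1,
                            base_seed = 20230511L) {
  strength_scale <- match.arg(strength_scale)
  cfg <- list(
    name = as.character(name)[1L],
    n_subjects = as.integer(n_subjects),
    n_reps = as.integer(n_reps),
    true_hr = as.numeric(true_hr),
    strength_c1 = as.numeric(strength_c1),
    strength_c2 = as.numeric(strength_c2),
    strength_scale = strength_scale,
    confounder_corr = as.numeric(confounder_corr),
    confounder_cutoff = as.numeric(confounder_cutoff),
    iv_prevalence = as.numeric(iv_prevalence),
    target_treat_prev = as.numeric(target_treat_prev),
    target_outcome_incidence = as.numeric(target_outcome_incidence),
    target_iv_or = as.numeric(target_iv_or),
    censoring_rate = as.numeric(censoring_rate),
    followup_horizon = as.numeric(followup_horizon),
    weibull_shape = as.numeric(weibull_shape),
    base_seed = as.integer(base_seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)

  if (!is_count(cfg$n_subjects) || cfg$n_subjects < 2)
    add("n_subjects must be an integer >= 2")
  if (!is_count(cfg$n_reps)) add("n_reps must be a positive integer")
  if (!is.finite(cfg$true_hr) || cfg$true_hr <= 0)
    add("true_hr must be a positive real")
  if (!is.finite(cfg$strength_c1) || cfg$strength_c1 < 0)
    add("strength_c1 must be nonnegative")
  if (!is.finite(cfg$strength_c2) || cfg$strength_c2 < 0)
    add("strength_c2 must be nonnegative")
  if (cfg$strength_scale == "ratio" &&
      (cfg$strength_c1 <= 0 || cfg$strength_c2 <= 0))
    add("ratio-scale strengths must be strictly positive")
  if (!is.finite(cfg$confounder_corr) || abs(cfg$confounder_corr) > 1)
    add("confounder_corr must lie in [-1, 1]")
  for (f in c("iv_prevalence", "target_treat_prev",
              "target_outcome_incidence")) {
    if (!is_prob(cfg[[f]])) add(sprintf("%s must lie strictly in (0, 1)", f))
  }
  if (!is.finite(cfg$target_iv_or) || cfg$target_iv_or <= 0)
    add("target_iv_or must be a positive real")
  if (!is.finite(cfg$censoring_rate) || cfg$censoring_rate < 0)
    add("censoring_rate must be nonnegative")
  if (!is.finite(cfg$followup_horizon) || cfg$followup_horizon <= 0)
    add("followup_horizon must be a positive time")
  if (!is.finite(cfg$weibull_shape) || cfg$weibull_shape <= 0)
    add("weibull_shape must be positive")

  if (length(problems))
    stop_invalid("invalid scenario configuration:\n  - %s",
                 paste(problems, collapse = "\n  - "))

  if (is.finite(cfg$confounder_corr) &&
      (cfg$confounder_corr < 0 || cfg$confounder_corr > 0.2))
    warning("confounder_corr = ", cfg$confounder_corr,
            " is outside the usual [0, 0.2] range", call. = FALSE)
  cfg
}

# strengths -> (treatment, hazard) coefficients under the chosen scale
strength_coefs <- function(cfg) {
  if (cfg$strength_scale == "ratio") {
    c(c1 = log(cfg$strength_c1), c2 = log(cfg$strength_c2))
  } else {
    c(c1 = cfg$strength_c1, c2 = cfg$strength_c2)
  }
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario configuration:", x$name, "\n")
  cat(sprintf("  cohorts: %d subjects x %d replicates\n",
              x$n_subjects, x$n_reps))
  cat(sprintf("  true treatment HR: %g\n", x$true_hr))
  cat(sprintf("  confounder strengths (%s scale): C1 = %g (measured), C2 = %g (unmeasured)\n",
              x$strength_scale, x$strength_c1, x$strength_c2))
  cat(sprintf("  targets: treat prev %.3f, outcome incidence %.3f, IV OR %.2f\n",
              x$target_treat_prev, x$target_outcome_incidence, x$target_iv_or))
  cat(sprintf("  instrument prevalence %.2f; censoring rate %.3f; horizon %g\n",
              x$iv_prevalence, x$censoring_rate, x$followup_horizon))
  cat(sprintf("  base seed %d\n", x$base_seed))
  invisible(x)
}

#' Load scenario configurations from a YAML file
#'
#' A scenario file holds one scenario family; the fields mirror the
#' arguments of [scenario_config()].  `true_hr` may be a vector, in which
#' case `target_outcome_incidence` (and, if desired, `target_treat_prev`
#' and `target_iv_or`) may be vectors of the same length, matched
#' elementwise; scalars are recycled.  One `scenario_config` is returned
#' per true hazard ratio.
#'
#' @param path Path to a YAML scenario file.
#' @return A list of `scenario_config` objects.
#' @examples
#' cfgs <- load_config(system.file("presets", "moderate.yaml",
#'                                 package = "ivcoxsim"))
#' sapply(cfgs, `[[`, "true_hr")
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_invalid("unknown fields in %s: %s", path,
                 paste(unknown, collapse = ", "))
  hrs <- if (is.null(raw$true_hr)) 1 else unlist(raw$true_hr)
  vec_fields <- c("target_outcome_incidence", "target_treat_prev",
                  "target_iv_or")
  for (f in vec_fields) {
    v <- unlist(raw[[f]])
    if (!is.null(v) && length(v) != 1L && length(v) != length(hrs))
      stop_invalid("%s must have length 1 or length(true_hr) in %s", f, path)
  }
  lapply(seq_along(hrs), function(i) {
    args <- raw
    args$true_hr <- hrs[i]
    for (f in vec_fields) {
      v <- unlist(raw[[f]])
      if (!is.null(v)) args[[f]] <- v[min(i, length(v))]
    }
    do.call(scenario_config, args)
  })
}

#' Shipped scenario presets
#'
#' Three presets ship with the package, mirroring the weak
#' (C1 = 0.5, C2 = 1.0), moderate (C1 = 1.5, C2 = 2.0) and strong
#' (C1 = 2.5, C2 = 3.0) confounding scenarios, each with true hazard
#' ratios 1, 2 and 3 and per-HR outcome-incidence targets.
#'
#' @param name One of `"weak"`, `"moderate"`, `"strong"`.
#' @return A list of `scenario_config` objects (one per true HR).
#' @examples
#' presets <- scenario_preset("moderate")
#' presets[[3]]$true_hr
#' @export
scenario_preset <- function(name = c("moderate", "strong", "weak")) {
  name <- match.arg(name)
  path <- system.file("presets", paste0(name, ".yaml"),
                      package = "ivcoxsim", mustWork = TRUE)
  load_config(path)
}
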