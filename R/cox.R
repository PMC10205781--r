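#' Fit a Cox proportional-hazards model on a covariate matrix
#'
#' Thin wrapper around [survival::coxph()] (Efron tie handling, Newton
#' iterations capped at 100, relative tolerance 1e-9) that standardizes
#' the package's convergence policy: monotone partial likelihoods and
#' iteration-limit warnings are caught and reported as `converged = FALSE`
#' rather than errors, so the replication engine can exclude the fit.
#' The reported effect is the coefficient on the first covariate column.
#'
#' @param t_obs Nonnegative follow-up times.
#' @param event 0/1 event indicators (at least one event).
#' @param covariates Numeric matrix (or vector) of covariates; the first
#'   column carries the treatment-effect estimate.
#' @param labels Optional column labels (defaults to the matrix's).
#' @return An object of class `cox_fit`: `log_hr`, `se`, `hr`,
#'   `converged`, full coefficient vector `coefficients`, `var`,
#'   `n`, `n_events` and `labels`.
#' @examples
#' fit <- fit_cox_ph(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 0, 1, 0))
#' fit$hr
#' @export
fit_cox_ph <- function(t_obs, event, covariates, labels = NULL) {
  covariates <- as.matrix(covariates)
  if (is.null(labels)) labels <- colnames(covariates)
  if (is.null(labels)) labels <- paste0("v", seq_len(ncol(covariates)))
  colnames(covariates) <- labels
  if (any(t_obs < 0)) stop_invalid("negative follow-up times")
  if (!any(event == 1)) stop_invalid("no events: the Cox model carries no information")
  if (any(!is.finite(covariates))) stop_invalid("non-finite covariate values")

  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(t_obs, event) ~ covariates,
      ties = "efron",
      control = survival::coxph.control(iter.max = 100L, eps = 1e-9)
    ),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(fit$coefficients)
  se <- sqrt(diag(as.matrix(fit$var)))
  if (any(!is.finite(beta))) converged <- FALSE
  structure(list(
    log_hr = beta[1L],
    se = se[1L],
    hr = exp(beta[1L]),
    converged = converged,
    coefficients = stats::setNames(beta, labels),
    se_all = stats::setNames(se, labels),
    var = fit$var,
    loglik = fit$loglik,
    n = length(t_obs),
    n_events = sum(event == 1),
    labels = labels
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%d subjects, %d events)%s\n", x$n, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- cbind(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
               se = x$se_all)
  print(round(tab, 4))
  invisible(x)
}

#' Odds ratio from a 2x2 cross-tabulation
#'
#' Computes `(n11 * n00) / (n10 * n01)` for two binary vectors.  If any
#' cell is empty, the Haldane--Anscombe continuity correction (0.5 added
#' to every cell) is applied and the result carries the attribute
#' `continuity_corrected = TRUE`.
#'
#' @param z,x Binary (0/1) vectors of equal length, both nonconstant.
#' @return The odds ratio (positive scalar).
#' @examples
#' z <- rep(c(1, 1, 0, 0), c(10, 5, 2, 8))
#' x <- rep(c(1, 0, 1, 0), c(10, 5, 2, 8))
#' odds_ratio_2x2(z, x)  # 8
#' @export
odds_ratio_2x2 <- function(z, x) {
  if (length(z) != length(x)) stop_invalid("z and x must have equal length")
  if (length(unique(z)) < 2L || length(unique(x)) < 2L)
    stop_invalid("degenerate 2x2 table: z and x must both vary")
  n11 <- as.numeric(sum(z == 1 & x == 1))
  n10 <- as.numeric(sum(z == 1 & x == 0))
  n01 <- as.numeric(sum(z == 0 & x == 1))
  n00 <- as.numeric(sum(z == 0 & x == 0))
  corrected <- any(c(n11, n10, n01, n00) == 0L)
  if (corrected) {
    n11 <- n11 + 0.5; n10 <- n10 + 0.5; n01 <- n01 + 0.5; n00 <- n00 + 0.5
  }
  or <- (n11 * n00) / (n10 * n01)
  if (corrected) attr(or, "continuity_corrected") <- TRUE
  or
}
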