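#' Fit the first-stage linear regression of treatment on the instrument
#'
#' Ordinary least squares of the (binary) treatment on an intercept and
#' the instrument, plus the measured confounder when `adjusted = TRUE`.
#' A linear probability model is used deliberately: fitted values may lie
#' outside `[0, 1]` and are used as-is by the second stage.
#'
#' @param cohort An `iv_cohort` (or data frame with columns `x`, `z` and,
#'   if adjusted, `c1`).
#' @param adjusted Include the measured confounder `c1` in the design?
#' @return An object of class `first_stage_fit` with elements
#'   `coefficients`, `fitted`, `residuals` and `adjusted`.  By the normal
#'   equations, `fitted + residuals == x` and the residuals are orthogonal
#'   to every design column.
#' @examples
#' d <- data.frame(x = c(1, 0, 1, 0), z = c(1, 0, 0, 1))
#' fit_first_stage(d, adjusted = FALSE)$coefficients
#' @export
fit_first_stage <- function(cohort, adjusted = TRUE) {
  design <- cbind(`(Intercept)` = 1, z = cohort$z)
  if (adjusted) design <- cbind(design, c1 = cohort$c1)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1L):ncol(design)]]
    stop_invalid("first-stage design is collinear; offending column(s): %s",
                 paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qr_d, cohort$x)
  fitted <- drop(design %*% coefs)
  structure(list(
    coefficients = coefs,
    fitted = fitted,
    residuals = cohort$x - fitted,
    adjusted = adjusted
  ), class = "first_stage_fit")
}

#' @export
print.first_stage_fit <- function(x, ...) {
  cat("First-stage linear regression of treatment on",
      if (x$adjusted) "instrument + measured confounder" else "instrument",
      "\n")
  print(round(x$coefficients, 6))
  invisible(x)
}
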