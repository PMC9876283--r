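# TRIPOD-style calibration metrics for one model on one subgroup.

#' @keywords internal
effect_size_class <- function(r2) {
  if (is.na(r2)) return(NA_character_)
  if (r2 < 0.3) "none/very weak"
  else if (r2 < 0.5) "weak/low"
  else if (r2 <= 0.7) "moderate"
  else "high"
}

#' Fit the calibration regression of observed on predicted
#'
#' Ordinary least squares of the directly measured value on the model's
#' prediction.  The slope is the calibration slope (1 ideal) and the
#' intercept is the free-intercept calibration-in-the-large (0 ideal).
#' Reported alongside are the adjusted R-squared
#' `1 - (1 - R^2) (n - 1) / (n - 2)` (which may be negative), the root
#' mean squared residual of the fit, two-sided Wald p-values for slope
#' and intercept, the n >= 100 reliability flag, and an effect-size class
#' from the adjusted R-squared (< 0.3 none/very weak, 0.3-0.5 weak/low,
#' 0.5-0.7 moderate, > 0.7 high).
#'
#' @param observed,predicted Equal-length numeric vectors in the same
#'   unit; n >= 3 and `predicted` must not be constant.
#' @return Object of class `calibration_result` with fields `n`,
#'   `intercept`, `slope`, `c1` (= intercept), `c2` (= slope), `r2`,
#'   `r2_adj`, `rmse`, `p_slope`, `p_c1`, `reliable`,
#'   `effect_size_class`, `convention`.
#' @export
#' @examples
#' x <- rnorm(50, 50, 5)
#' fit_calibration(x, x)  # slope 1, intercept 0, rmse 0
fit_calibration <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    .stop("observed and predicted lengths differ")
  }
  keep <- is.finite(observed) & is.finite(predicted)
  observed <- observed[keep]
  predicted <- predicted[keep]
  n <- length(observed)
  if (n < 3) .stop("calibration fit needs at least 3 pairs")
  if (sd(predicted) == 0) {
    .stop("degenerate fit: predictions are constant")
  }
  fit <- lm(observed ~ predicted)
  # perfect fits trip summary.lm's reliability warning; degeneracy is
  # already handled above, so silence it
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  r2 <- sm$r.squared
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  out <- list(
    n = n,
    intercept = unname(cf["(Intercept)", "Estimate"]),
    slope = unname(cf["predicted", "Estimate"]),
    c1 = unname(cf["(Intercept)", "Estimate"]),
    c2 = unname(cf["predicted", "Estimate"]),
    r2 = r2,
    r2_adj = r2_adj,
    rmse = sqrt(mean(residuals(fit)^2)),
    p_slope = unname(cf["predicted", "Pr(>|t|)"]),
    p_c1 = unname(cf["(Intercept)", "Pr(>|t|)"]),
    reliable = n >= 100,
    effect_size_class = effect_size_class(r2_adj),
    convention = "free_intercept"
  )
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibration (n = %d%s): slope C2 = %.3f, intercept C1 = %.3f,\n  adj. R2 = %.3f (%s), RMSE = %.3f\n",
    x$n, if (x$reliable) "" else ", unreliable", x$c2, x$c1, x$r2_adj,
    x$effect_size_class, x$rmse
  ))
  invisible(x)
}

#' Calibration-in-the-large
#'
#' Two conventions are in circulation for calibration-in-the-large: the
#' difference of means, `mean(observed) - mean(predicted)`, and the free
#' intercept of the calibration regression of observed on predicted.
#' Both are zero for a perfectly calibrated model; they coincide only
#' when the calibration slope is 1.  The free-intercept convention is the
#' default here because it is the one whose magnitudes match tabulated
#' validation reports that pair it with a calibration slope; every result
#' carries its convention as an attribute.
#'
#' @param observed,predicted Numeric vectors in the same unit.
#' @param convention `"free_intercept"` (default) or
#'   `"mean_difference"`.
#' @return Numeric scalar with attribute `"convention"`.
#' @export
calibration_in_the_large <- function(observed, predicted,
                                     convention = c("free_intercept",
                                                    "mean_difference")) {
  convention <- match.arg(convention)
  value <- switch(convention,
    mean_difference = mean(observed) - mean(predicted),
    free_intercept = fit_calibration(observed, predicted)$c1
  )
  structure(value, convention = convention)
}

#' Paired mean difference between predicted and observed values
#'
#' Mean of `predicted - observed` (positive = overestimation) with a
#' two-sided t-based 95% confidence interval and p-value.  When the
#' differences have zero variance the t statistic is undefined: the CI
#' collapses to the point estimate and the p-value is reported as 1 when
#' the mean difference is exactly zero (perfect agreement) and `NA`
#' otherwise.
#'
#' @param observed,predicted Numeric vectors, n >= 2.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `mean_difference` with fields `n`,
#'   `mean_diff`, `ci_low`, `ci_high`, `p`.
#' @export
mean_difference <- function(observed, predicted, conf_level = 0.95) {
  if (length(observed) != length(predicted)) {
    .stop("observed and predicted lengths differ")
  }
  keep <- is.finite(observed) & is.finite(predicted)
  d <- (predicted - observed)[keep]
  n <- length(d)
  if (n < 2) .stop("mean difference needs at least 2 pairs")
  m <- mean(d)
  if (sd(d) == 0) {
    out <- list(n = n, mean_diff = m, ci_low = m, ci_high = m,
                p = if (m == 0) 1 else NA_real_)
  } else {
    tt <- t.test(d, conf.level = conf_level)
    out <- list(n = n, mean_diff = m,
                ci_low = unname(tt$conf.int[1]),
                ci_high = unname(tt$conf.int[2]),
                p = unname(tt$p.value))
  }
  class(out) <- "mean_difference"
  out
}

#' @export
print.mean_difference <- function(x, ...) {
  cat(sprintf("Mean difference (predicted - observed): %.3f [%.3f, %.3f], p = %s, n = %d\n",
              x$mean_diff, x$ci_low, x$ci_high, format.pval(x$p), x$n))
  invisible(x)
}
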