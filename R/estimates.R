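# S3 containers for the three kinds of estimate the AAF arithmetic consumes:
# proportions on [0,1], ratio measures (RR/OR/HR) with log- or linear-scale
# confidence intervals, and attributable-fraction components.

#' Default normal quantile for 95% intervals
#'
#' The package-wide default multiplier for two-sided 95% confidence and
#' uncertainty intervals, `z = 1.959964`. Every function taking a `z`
#' argument uses this value unless told otherwise.
#'
#' @return A positive scalar.
#' @export
default_z <- function() 1.959964

#' Proportion estimate with interval and linear-scale variance
#'
#' Represents a prevalence or proportion in `[0, 1]` — treatment coverage,
#' nonadherence prevalence, prevalence of current drinkers — together with
#' its 95% bounds and the linear-scale variance implied by them. The
#' confidence interval of a proportion is taken to be symmetric on the
#' linear scale, so `variance = ((upper - lower) / (2 z))^2` unless a
#' variance is supplied directly. A degenerate interval (`lower == upper
#' == value`) yields variance 0 and marks a quantity treated as fixed.
#'
#' @param value Point estimate, a fraction in `[0, 1]`.
#' @param lower,upper Interval bounds, fractions with
#'   `0 <= lower <= value <= upper <= 1`. Default to `value` (fixed
#'   quantity, zero variance).
#' @param variance Optional non-negative variance overriding the one
#'   derived from the interval.
#' @param z Normal quantile the interval corresponds to; see [default_z()].
#' @return An object of class `proportion_estimate`: a list with fields
#'   `value`, `lower`, `upper`, `variance`.
#' @seealso [ratio_estimate()], [variance_from_interval()]
#' @examples
#' proportion_estimate(0.401, 0.369, 0.433)  # nonadherence prevalence
#' proportion_estimate(0.246)                # fixed drinker prevalence
#' @export
proportion_estimate <- function(value, lower = value, upper = value,
                                variance = NULL, z = default_z()) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (!(lower >= 0 && lower <= value && value <= upper && upper <= 1)) {
    stop("proportion_estimate: need 0 <= lower <= value <= upper <= 1, got ",
         "lower = ", lower, ", value = ", value, ", upper = ", upper,
         call. = FALSE)
  }
  if (is.null(variance)) {
    variance <- variance_from_interval(value, lower, upper,
                                       scale = "normal", z = z)
  }
  if (variance < 0) stop("proportion_estimate: variance must be >= 0",
                         call. = FALSE)
  structure(list(value = value, lower = lower, upper = upper,
                 variance = variance),
            class = "proportion_estimate")
}

#' Ratio estimate (RR, OR or HR) with interval and derived variances
#'
#' Represents a published ratio measure together with its 95% interval and
#' the variance on the linear scale that the delta-method formulas consume.
#' Ratio intervals from regression models are symmetric on the log scale,
#' so by default (`scale_assumption = "log_normal"`) the log-scale variance
#' `Var[ln X] = ((ln upper - ln lower) / (2 z))^2` is computed first and
#' converted via `Var[X] = X^2 Var[ln X]`. With
#' `scale_assumption = "normal"` the interval is read as symmetric on the
#' linear scale.
#'
#' @param value Point estimate, `> 0`.
#' @param lower,upper Interval bounds with `0 < lower <= value <= upper`.
#'   Default to `value` (fixed ratio, zero variance).
#' @param variance Optional linear-scale variance overriding the derived one.
#' @param scale_assumption `"log_normal"` (default) or `"normal"`.
#' @param z Normal quantile of the interval; see [default_z()].
#' @return An object of class `ratio_estimate`: a list with fields `value`,
#'   `lower`, `upper`, `variance` (linear scale), `log_variance`
#'   (`Var[ln X]`) and `scale_assumption`.
#' @seealso [invert_ratio()], [odds_to_risk()]
#' @examples
#' # mortality hazard ratio, untreated vs treated
#' ratio_estimate(2.63, 1.92, 3.57)
#' @export
ratio_estimate <- function(value, lower = value, upper = value,
                           variance = NULL,
                           scale_assumption = c("log_normal", "normal"),
                           z = default_z()) {
  scale_assumption <- match.arg(scale_assumption)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (!(lower > 0 && lower <= value && value <= upper)) {
    stop("ratio_estimate: need 0 < lower <= value <= upper, got ",
         "lower = ", lower, ", value = ", value, ", upper = ", upper,
         call. = FALSE)
  }
  if (is.null(variance)) {
    variance <- variance_from_interval(value, lower, upper,
                                       scale = scale_assumption, z = z)
  }
  if (variance < 0) stop("ratio_estimate: variance must be >= 0",
                         call. = FALSE)
  log_variance <- if (scale_assumption == "log_normal") {
    ((log(upper) - log(lower)) / (2 * z))^2
  } else {
    # first-order transform of the linear-scale variance
    variance / value^2
  }
  structure(list(value = value, lower = lower, upper = upper,
                 variance = variance, log_variance = log_variance,
                 scale_assumption = scale_assumption),
            class = "ratio_estimate")
}

#' Attributable-fraction component with delta-method interval
#'
#' Holds one component of the stepwise AAF computation — `AdAF`, `NAAAF`,
#' `PDT`, the combined `AAF`, or a generic `AF` — with its delta-method
#' variance and a Wald-type uncertainty interval
#' `value +/- z * sqrt(variance)`. Intervals are deliberately not truncated
#' to `[0, 1]`: a lower bound below 0 signals a statistically
#' non-significant fraction.
#'
#' @param value Point estimate of the fraction.
#' @param variance Non-negative delta-method variance.
#' @param label One of `"AdAF"`, `"NAAAF"`, `"PDT"`, `"AAF"`, `"AF"`.
#' @param z Normal quantile for the interval; see [default_z()].
#' @return An object of class `fraction_estimate`: a list with fields
#'   `value`, `variance`, `ci_lower`, `ci_upper`, `label`.
#' @examples
#' fraction_estimate(0.46, 0.003, "AdAF")
#' @export
fraction_estimate <- function(value, variance, label, z = default_z()) {
  label <- match.arg(label, c("AdAF", "NAAAF", "PDT", "AAF", "AF"))
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (variance < 0) stop("fraction_estimate: variance must be >= 0",
                         call. = FALSE)
  half <- z * sqrt(variance)
  structure(list(value = value, variance = variance,
                 ci_lower = value - half, ci_upper = value + half,
                 label = label),
            class = "fraction_estimate")
}

#' @export
print.proportion_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("<proportion> %s [%s, %s]  var = %s\n",
              format(x$value, digits = digits),
              format(x$lower, digits = digits),
              format(x$upper, digits = digits),
              format(x$variance, digits = digits)))
  invisible(x)
}

#' @export
print.ratio_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("<ratio, %s> %s (%s to %s)  var = %s, var[ln] = %s\n",
              x$scale_assumption,
              format(x$value, digits = digits),
              format(x$lower, digits = digits),
              format(x$upper, digits = digits),
              format(x$variance, digits = digits),
              format(x$log_variance, digits = digits)))
  invisible(x)
}

#' @export
print.fraction_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("<%s> %s (95%% UI: %s, %s)  var = %s\n",
              x$label,
              format(x$value, digits = digits),
              format(x$ci_lower, digits = digits),
              format(x$ci_upper, digits = digits),
              format(x$variance, digits = digits)))
  invisible(x)
}
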