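# Transforms that turn published ratio measures and confidence intervals
# into the point-estimate + linear-scale-variance form the attributable
# fraction formulas consume.

#' Linear-scale variance from a confidence interval
#'
#' Recovers the variance of an estimate from its two-sided confidence
#' interval. Under `scale = "normal"` the interval is symmetric on the
#' linear scale and `Var[X] = ((upper - lower) / (2 z))^2`. Under
#' `scale = "log_normal"` the interval is symmetric on the log scale:
#' `Var[ln X] = ((ln upper - ln lower) / (2 z))^2` is computed first and
#' transformed to the linear scale through the first-order relation
#' `Var[X] ~= X^2 Var[ln X]`. When the published interval is asymmetric
#' around the point estimate on the assumed scale, the half-width is taken
#' as half the full interval width; the position of the point estimate
#' inside the interval does not enter.
#'
#' @param value Point estimate (used only under `log_normal`).
#' @param lower,upper Interval bounds, `lower <= upper`; both `> 0` under
#'   `log_normal`.
#' @param scale `"log_normal"` or `"normal"`.
#' @param z Normal quantile the interval corresponds to; see [default_z()].
#' @return The variance on the linear scale (a non-negative scalar).
#' @examples
#' # hazard ratio 2.63 (1.92 to 3.57), log-scale interval
#' variance_from_interval(2.63, 1.92, 3.57, "log_normal")
#' # proportion 0.401 (0.369 to 0.433), linear-scale interval
#' variance_from_interval(0.401, 0.369, 0.433, "normal")
#' @export
variance_from_interval <- function(value, lower, upper,
                                   scale = c("log_normal", "normal"),
                                   z = default_z()) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(lower), is.numeric(upper), z > 0)
  if (lower > upper) {
    stop("variance_from_interval: lower (", lower,
         ") exceeds upper (", upper, ")", call. = FALSE)
  }
  if (scale == "normal") {
    return(((upper - lower) / (2 * z))^2)
  }
  if (lower <= 0) {
    stop("variance_from_interval: bounds must be positive under the ",
         "log_normal assumption", call. = FALSE)
  }
  log_var <- ((log(upper) - log(lower)) / (2 * z))^2
  value^2 * log_var
}

#' Invert a ratio estimate
#'
#' Maps a ratio measure to its reciprocal, swapping the interval bounds:
#' a protective relative risk of adherence becomes the harmful relative
#' risk of nonadherence. The log-scale variance is invariant under
#' inversion (`Var[ln(1/X)] = Var[ln X]`), so the returned linear-scale
#' variance is `(1/value)^2 * Var[ln X]`. The operation is an involution:
#' inverting twice returns the original estimate.
#'
#' @param est A [ratio_estimate()].
#' @return A `ratio_estimate` for `1 / est`.
#' @examples
#' # mortality rate ratio treated vs untreated, 0.38 (0.28, 0.52),
#' # inverted to the hazard ratio for no treatment:
#' invert_ratio(ratio_estimate(0.38, 0.28, 0.52))
#' @export
invert_ratio <- function(est) {
  stopifnot(inherits(est, "ratio_estimate"))
  if (est$value <= 0) stop("invert_ratio: ratio must be positive",
                           call. = FALSE)
  value <- 1 / est$value
  out <- structure(list(value = value,
                        lower = 1 / est$upper,
                        upper = 1 / est$lower,
                        variance = value^2 * est$log_variance,
                        log_variance = est$log_variance,
                        scale_assumption = est$scale_assumption),
                   class = "ratio_estimate")
  out
}

#' Convert an odds ratio to a relative risk
#'
#' Applies the odds-to-risk conversion `RR = OR / ((1 - P) + P * OR)`,
#' where `P` is the baseline outcome prevalence (here: prevalence of
#' nonadherence among drinkers). The variance is propagated to first
#' order in both arguments:
#' `Var[RR] ~= D_P^2 Var[P] + D_OR^2 Var[OR]` with partial derivatives
#' `D_OR = (1 - P) / ((1 - P) + P OR)^2` and
#' `D_P = OR (1 - OR) / ((1 - P) + P OR)^2`.
#' For `OR > 1` the result satisfies `1 < RR <= OR`; for `OR < 1`,
#' `OR <= RR < 1`; `P = 0` is the rare-outcome limit where `RR = OR`.
#'
#' @param or_est A [ratio_estimate()] holding the odds ratio.
#' @param p A [proportion_estimate()] holding the baseline prevalence of
#'   the outcome.
#' @return A `ratio_estimate` holding the relative risk. Its interval is
#'   the Wald interval `RR +/- z sqrt(Var[RR])` truncated below at a tiny
#'   positive value, and its `scale_assumption` is `"normal"` (the
#'   propagated variance lives on the linear scale).
#' @param z Normal quantile used for the derived interval.
#' @examples
#' or_na <- invert_ratio(ratio_estimate(0.604, 0.531, 0.687))
#' odds_to_risk(or_na, proportion_estimate(0.401, 0.369, 0.433))
#' @export
odds_to_risk <- function(or_est, p, z = default_z()) {
  stopifnot(inherits(or_est, "ratio_estimate"),
            inherits(p, "proportion_estimate"))
  or <- or_est$value
  pp <- p$value
  if (or <= 0) stop("odds_to_risk: odds ratio must be positive",
                    call. = FALSE)
  denom <- (1 - pp) + pp * or
  rr <- or / denom
  d_or <- (1 - pp) / denom^2
  d_p <- or * (1 - or) / denom^2
  variance <- d_p^2 * p$variance + d_or^2 * or_est$variance
  half <- z * sqrt(variance)
  lower <- max(rr - half, .Machine$double.eps)
  upper <- max(rr + half, lower)
  structure(list(value = rr, lower = min(lower, rr), upper = max(upper, rr),
                 variance = variance, log_variance = variance / rr^2,
                 scale_assumption = "normal"),
            class = "ratio_estimate")
}

#' Exact variance of a product of independent variables
#'
#' For independent `X` and `Y`,
#' `Var[XY] = Var[X] Var[Y] + E[Y]^2 Var[X] + E[X]^2 Var[Y]`.
#' This identity is exact (not a Taylor approximation) and is the building
#' block for the variances of `AdAF`, `NAAAF` and the combined `AAF`.
#'
#' @param mean_x,mean_y Means of the two independent factors.
#' @param var_x,var_y Their variances, `>= 0`.
#' @return The variance of the product, a non-negative scalar, symmetric
#'   in `(x, y)`.
#' @examples
#' product_variance(0.5, 0.01, 0.2, 0.004)  # 0.00144
#' @export
product_variance <- function(mean_x, var_x, mean_y, var_y) {
  if (var_x < 0 || var_y < 0) {
    stop("product_variance: variances must be >= 0", call. = FALSE)
  }
  var_x * var_y + mean_y^2 * var_x + mean_x^2 * var_y
}

#' Assemble the risk-parameter set for the AAF chain
#'
#' Bundles the four epidemiological inputs the stepwise AAF needs:
#' the prevalence of nonadherence among treated patients (`p_na`), the
#' mortality risk ratio for nonadherence (`rr_na`), the risk ratio of
#' nonadherence for current drinkers versus abstainers (`rr_drink`), and
#' the mortality hazard ratio for people not on treatment
#' (`hr_nontreat`).
#'
#' @param p_na A [proportion_estimate()].
#' @param rr_na,rr_drink,hr_nontreat [ratio_estimate()] objects.
#' @return An object of class `risk_parameters` (a named list).
#' @seealso [load_parameters()] for the bundled set.
#' @export
risk_parameters <- function(p_na, rr_na, rr_drink, hr_nontreat) {
  args <- list(p_na = p_na, rr_na = rr_na, rr_drink = rr_drink,
               hr_nontreat = hr_nontreat)
  missing_ones <- names(args)[vapply(args, is.null, logical(1))]
  if (length(missing_ones)) {
    stop("risk_parameters: missing parameter(s): ",
         paste(missing_ones, collapse = ", "), call. = FALSE)
  }
  stopifnot(inherits(p_na, "proportion_estimate"),
            inherits(rr_na, "ratio_estimate"),
            inherits(rr_drink, "ratio_estimate"),
            inherits(hr_nontreat, "ratio_estimate"))
  structure(args, class = "risk_parameters")
}

#' Load a risk-parameter set
#'
#' Reads the four risk parameters from a JSON parameter file, or returns
#' the bundled set when `source` is the bundled dataset name
#' `"africa_gbd_2005"`. Each entry of the file's `parameters` array is
#' `{name, value, lower, upper, scale_assumption}` plus an optional
#' `unit` field (`"percent"` or `"fraction"`, default `"fraction"`) for
#' the proportion entry. Required names: `p_na`, `rr_na`, `rr_drink`,
#' `hr_nontreat`.
#'
#' The bundled set transcribes the published inputs: nonadherence
#' prevalence 40.1% (36.9% to 43.3%); risk ratio of nonadherence for
#' drinkers versus abstainers 1.82 (1.63 to 2.04); mortality risk ratio
#' for nonadherence 3.13 (1.95 to 5.05); mortality hazard ratio for no
#' treatment 2.63 (1.92 to 3.57).
#'
#' @param source `"africa_gbd_2005"` or a path to a JSON parameter file.
#' @param z Normal quantile the published intervals correspond to.
#' @return A [risk_parameters()] object.
#' @export
load_parameters <- function(source = "africa_gbd_2005", z = default_z()) {
  path <- if (identical(source, "africa_gbd_2005")) {
    system.file("extdata", "risk_parameters_africa_gbd_2005.json",
                package = "aafhiv", mustWork = TRUE)
  } else {
    if (!file.exists(source)) {
      stop("load_parameters: file not found: ", source, call. = FALSE)
    }
    source
  }
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(doc$parameters)) {
    stop("load_parameters: malformed parameter file (no 'parameters' array): ",
         path, call. = FALSE)
  }
  entries <- doc$parameters
  names(entries) <- vapply(entries, function(e) e$name %||% "", character(1))
  needed <- c("p_na", "rr_na", "rr_drink", "hr_nontreat")
  absent <- setdiff(needed, names(entries))
  if (length(absent)) {
    stop("load_parameters: missing parameter(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  get_num <- function(e, f) {
    v <- e[[f]]
    if (is.null(v) || !is.numeric(v)) {
      stop("load_parameters: parameter '", e$name, "' lacks numeric '",
           f, "'", call. = FALSE)
    }
    v
  }
  as_prop <- function(e) {
    s <- if (identical(e$unit, "percent")) 0.01 else 1
    proportion_estimate(get_num(e, "value") * s, get_num(e, "lower") * s,
                        get_num(e, "upper") * s, z = z)
  }
  as_ratio <- function(e) {
    ratio_estimate(get_num(e, "value"), get_num(e, "lower"),
                   get_num(e, "upper"),
                   scale_assumption = e$scale_assumption %||% "log_normal",
                   z = z)
  }
  risk_parameters(p_na = as_prop(entries$p_na),
                  rr_na = as_ratio(entries$rr_na),
                  rr_drink = as_ratio(entries$rr_drink),
                  hr_nontreat = as_ratio(entries$hr_nontreat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
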