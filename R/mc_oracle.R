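# Monte Carlo validation of the delta-method variances: sample the input
# parameters from their assumed distributions, push each draw through the
# deterministic AAF chain, and compare empirical moments and intervals
# with the analytic results.

#' Monte Carlo simulation settings
#'
#' @param seed Integer RNG seed. Mandatory: reproducibility of the
#'   validation runs is part of their contract, so no silent default is
#'   provided in the library API.
#' @param n_draws Number of parameter draws (default 200000). Fewer than
#'   1000 draws triggers a warning at comparison time but still runs.
#' @param proportion_model Sampling model for proportions:
#'   `"normal_truncated"` (normal on the linear scale truncated to
#'   `[0, 1]` and renormalised; the default, matching the linear-scale CI
#'   assumption) or `"beta_matched"` (beta with moment-matched mean and
#'   variance, for sensitivity analysis). Ratios are always sampled
#'   log-normally with log-mean `ln(value)` and log-SD `sqrt(Var[ln])`.
#' @return An object of class `mc_settings`.
#' @export
mc_settings <- function(seed, n_draws = 200000L,
                        proportion_model = c("normal_truncated",
                                             "beta_matched")) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("mc_settings: an explicit integer seed is required",
         call. = FALSE)
  }
  proportion_model <- match.arg(proportion_model)
  n_draws <- as.integer(n_draws)
  stopifnot(n_draws >= 1L)
  structure(list(seed = as.integer(seed), n_draws = n_draws,
                 proportion_model = proportion_model,
                 ratio_model = "log_normal"),
            class = "mc_settings")
}

draw_proportion <- function(p, n, model) {
  stopifnot(inherits(p, "proportion_estimate"))
  if (p$variance == 0) return(rep(p$value, n))
  s <- sqrt(p$variance)
  if (model == "normal_truncated") {
    # inverse-CDF sampling of the renormalised truncated normal
    plo <- stats::pnorm(0, p$value, s)
    phi <- stats::pnorm(1, p$value, s)
    stats::qnorm(stats::runif(n, plo, phi), p$value, s)
  } else {
    m <- p$value
    k <- m * (1 - m) / p$variance - 1
    if (k <= 0) {
      stop("draw_proportion: variance too large for a beta with mean ",
           m, call. = FALSE)
    }
    stats::rbeta(n, m * k, (1 - m) * k)
  }
}

draw_ratio <- function(r, n) {
  stopifnot(inherits(r, "ratio_estimate"))
  if (r$log_variance == 0) return(rep(r$value, n))
  stats::rlnorm(n, log(r$value), sqrt(r$log_variance))
}

#' Draw simulated risk-parameter sets
#'
#' Samples the four risk parameters independently from their assumed
#' distributions: ratios log-normally (log-mean `ln(value)`, log-SD
#' `sqrt(Var[ln])`), proportions per `settings$proportion_model`.
#' Parameters with zero variance yield constant columns. The RNG is
#' seeded from `settings$seed`, so identical settings give identical
#' draws.
#'
#' @param params A [risk_parameters()] set.
#' @param settings An [mc_settings()] object.
#' @return A numeric matrix with `settings$n_draws` rows and columns
#'   `p_na, rr_na, rr_drink, hr_nontreat`.
#' @export
draw_parameters <- function(params, settings) {
  stopifnot(inherits(params, "risk_parameters"),
            inherits(settings, "mc_settings"))
  set.seed(settings$seed)
  n <- settings$n_draws
  cbind(p_na = draw_proportion(params$p_na, n, settings$proportion_model),
        rr_na = draw_ratio(params$rr_na, n),
        rr_drink = draw_ratio(params$rr_drink, n),
        hr_nontreat = draw_ratio(params$hr_nontreat, n))
}

#' Monte Carlo AAF distribution for one stratum
#'
#' Draws all inputs — the four risk parameters plus the region's
#' treatment coverage and the stratum's drinker prevalence — and applies
#' the deterministic point-estimate chain
#' `AAF = AdAF * NAAAF * PDT` to every draw.
#'
#' @inheritParams compute_stratum
#' @param settings An [mc_settings()] object.
#' @return An object of class `mc_result`: a list with
#'   `empirical_mean`, `empirical_variance`, `percentile_interval`
#'   (2.5% and 97.5% quantiles), `level` (0.95), `n_effective` (draws
#'   surviving domain filters) and `draws` (the AAF sample).
#' @export
mc_aaf <- function(record, sex, age_band, params, settings) {
  stopifnot(inherits(record, "region_record"),
            inherits(settings, "mc_settings"))
  if (settings$n_draws < 1000L) {
    warning("mc_aaf: n_draws < 1000; empirical moments will be noisy")
  }
  m <- draw_parameters(params, settings)  # seeds the RNG
  n <- settings$n_draws
  p_treat <- draw_proportion(record$coverage, n, settings$proportion_model)
  p_drink <- draw_proportion(drinker_prevalence(record, sex, age_band),
                             n, settings$proportion_model)
  adaf <- attributable_fraction(m[, "p_na"], m[, "rr_na"])
  naaaf <- attributable_fraction(p_drink, m[, "rr_drink"])
  pdt <- p_treat / (p_treat + m[, "hr_nontreat"] * (1 - p_treat))
  aaf <- adaf * naaaf * pdt
  keep <- is.finite(aaf)
  aaf <- aaf[keep]
  structure(list(
    empirical_mean = mean(aaf),
    empirical_variance = if (length(aaf) > 1L) stats::var(aaf) else 0,
    percentile_interval = unname(stats::quantile(aaf, c(0.025, 0.975))),
    level = 0.95,
    n_effective = length(aaf),
    draws = aaf),
    class = "mc_result")
}

#' @export
print.mc_result <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<mc_result> mean %s  var %s  95%% percentile (%s, %s)  n = %d\n",
    format(x$empirical_mean, digits = digits),
    format(x$empirical_variance, digits = digits),
    format(x$percentile_interval[1], digits = digits),
    format(x$percentile_interval[2], digits = digits),
    x$n_effective))
  invisible(x)
}

#' Compare an analytic fraction estimate with its Monte Carlo oracle
#'
#' Reports the relative difference between the delta-method variance and
#' the empirical Monte Carlo variance, and between the Wald interval
#' width and the Monte Carlo 95% percentile interval width (relative to
#' the Monte Carlo quantities). The comparison passes when both are
#' within `rel_tol`.
#'
#' @param analytic A [fraction_estimate()].
#' @param mc An [mc_result()][mc_aaf] for the same stratum and
#'   parameters.
#' @param rel_tol Relative tolerance (default 0.10).
#' @param z Normal quantile defining the Wald width.
#' @return A list with `analytic_variance`, `mc_variance`,
#'   `rel_diff_variance`, `analytic_width`, `mc_width`,
#'   `rel_diff_width`, `pass_variance`, `pass_width`, `pass`.
#' @export
mc_compare <- function(analytic, mc, rel_tol = 0.10, z = default_z()) {
  stopifnot(inherits(analytic, "fraction_estimate"),
            inherits(mc, "mc_result"))
  rel <- function(a, b) {
    if (b == 0) return(if (a == 0) 0 else Inf)
    abs(a - b) / abs(b)
  }
  a_var <- analytic$variance
  m_var <- mc$empirical_variance
  a_w <- 2 * z * sqrt(a_var)
  m_w <- diff(mc$percentile_interval)
  dv <- rel(a_var, m_var)
  dw <- rel(a_w, m_w)
  list(analytic_variance = a_var, mc_variance = m_var,
       rel_diff_variance = dv,
       analytic_width = a_w, mc_width = m_w, rel_diff_width = dw,
       pass_variance = dv <= rel_tol, pass_width = dw <= rel_tol,
       pass = dv <= rel_tol && dw <= rel_tol)
}

#' Monte Carlo validation sweep over all strata
#'
#' Runs [compute_stratum()] and [mc_aaf()] for every region x sex x
#' age-band cell and compares the delta-method variance and Wald width
#' with the Monte Carlo oracle via [mc_compare()].
#'
#' @inheritParams compute_aaf_table
#' @param settings An [mc_settings()] object.
#' @param rel_tol Relative tolerance for the comparison (default 0.10).
#' @return A data frame with one row per stratum: `region, sex,
#'   age_band, analytic_variance, mc_variance, rel_diff,
#'   rel_diff_width, pass`.
#' @export
validate_mc <- function(records, params, settings, rel_tol = 0.10,
                        z = default_z()) {
  rows <- list()
  for (record in records) {
    for (sex in SEXES) {
      for (band in record$age_bands) {
        s <- compute_stratum(record, sex, band, params, z = z)
        mc <- mc_aaf(record, sex, band, params, settings)
        cmp <- mc_compare(s$aaf, mc, rel_tol = rel_tol, z = z)
        rows[[length(rows) + 1L]] <- data.frame(
          region = record$region, sex = sex, age_band = band,
          analytic_variance = cmp$analytic_variance,
          mc_variance = cmp$mc_variance,
          rel_diff = cmp$rel_diff_variance,
          rel_diff_width = cmp$rel_diff_width,
          pass = cmp$pass,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
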