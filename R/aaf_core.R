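# The stepwise alcohol-attributable fraction for HIV/AIDS mortality:
#   AAF = AdAF * NAAAF * PDT
# where AdAF is the fraction of deaths among treated patients attributable
# to nonadherence, NAAAF the fraction of nonadherence attributable to
# current drinking, and PDT the share of all HIV/AIDS deaths occurring
# among people on treatment.  Variances are propagated by the delta
# method (first/second-order Taylor expansion) assuming independent
# inputs.

#' Generic attributable fraction (Levin formula)
#'
#' `AF = P (RR - 1) / (P (RR - 1) + 1)` for exposure prevalence `P` and
#' relative risk `RR` of the exposed versus the unexposed. The `RR` may
#' come from risk ratios, hazard ratios, or converted odds ratios.
#'
#' @param p Exposure prevalence in `[0, 1]` (bare numeric).
#' @param rr Relative risk, `> 0` (bare numeric).
#' @return The attributable fraction, a scalar (vectorised over inputs).
#' @examples
#' attributable_fraction(0.401, 3.13)
#' @export
attributable_fraction <- function(p, rr) {
  stopifnot(all(p >= 0 & p <= 1), all(rr > 0))
  p * (rr - 1) / (p * (rr - 1) + 1)
}

af_with_variance <- function(p, rr, label, z) {
  stopifnot(inherits(p, "proportion_estimate"),
            inherits(rr, "ratio_estimate"))
  k <- 1 + p$value * (rr$value - 1)
  value <- p$value * (rr$value - 1) / k
  variance <- product_variance(p$value, p$variance,
                               rr$value, rr$variance) / k^4
  fraction_estimate(value, variance, label, z = z)
}

#' Adherence-attributable fraction of deaths (AdAF)
#'
#' The fraction of HIV/AIDS deaths among people on antiretroviral therapy
#' attributable to nonadherence (taking fewer than 95% of doses):
#' `AdAF = P_na (RR_na - 1) / (1 + P_na (RR_na - 1))`, algebraically
#' identical to the complement form
#' `(P_adher + P_na RR_na - 1) / (P_adher + P_na RR_na)` with
#' `P_adher = 1 - P_na`. The delta-method variance is
#' `Var[AdAF] ~= Var[P_na RR_na] / (1 + P_na (RR_na - 1))^4`, with
#' `Var[P_na RR_na]` the exact [product_variance()] of the independent
#' factors.
#'
#' @param p_na [proportion_estimate()] of nonadherence among treated
#'   patients.
#' @param rr_na [ratio_estimate()]: mortality risk ratio, nonadherent vs
#'   adherent.
#' @param z Normal quantile for the uncertainty interval.
#' @return A [fraction_estimate()] labelled `"AdAF"`.
#' @export
adherence_af <- function(p_na, rr_na, z = default_z()) {
  af_with_variance(p_na, rr_na, "AdAF", z)
}

#' Alcohol-attributable fraction of nonadherence (NAAAF)
#'
#' The fraction of nonadherence attributable to current drinking:
#' `NAAAF = P_drink (RR_drink - 1) / (1 + P_drink (RR_drink - 1))`, with
#' the same delta-method variance structure as [adherence_af()]. Drinker
#' prevalences without published bounds carry variance 0, in which case
#' only `Var[RR_drink]` contributes.
#'
#' @param p_drink [proportion_estimate()] of current drinkers among the
#'   treated population.
#' @param rr_drink [ratio_estimate()]: risk ratio of nonadherence,
#'   drinkers vs abstainers.
#' @param z Normal quantile for the uncertainty interval.
#' @return A [fraction_estimate()] labelled `"NAAAF"`.
#' @export
alcohol_nonadherence_af <- function(p_drink, rr_drink, z = default_z()) {
  af_with_variance(p_drink, rr_drink, "NAAAF", z)
}

#' Share of HIV/AIDS deaths occurring under treatment (PDT)
#'
#' Reconstructs the proportion of all HIV/AIDS deaths that occur among
#' people receiving antiretroviral therapy from treatment coverage and
#' the mortality hazard ratio of the untreated:
#' `PDT = P_treat / (P_treat + HR_nontreat (1 - P_treat))`.
#' The two-variable first-order variance is
#' `Var[PDT] ~= D_Ptreat^2 Var[P_treat] + D_HR^2 Var[HR_nontreat]` with
#' `D_Ptreat = HR / (P_treat + HR (1 - P_treat))^2` and
#' `D_HR = P_treat (1 - P_treat) / (P_treat + HR (1 - P_treat))^2`
#' (the partials enter squared, so their sign is immaterial).
#' `PDT` is strictly decreasing in `HR` for `P_treat` in `(0, 1)` and
#' equals `P_treat` at `HR = 1`.
#'
#' @param p_treat [proportion_estimate()] of people in need of therapy
#'   who receive it. `p_treat = 0` returns a zero fraction with a
#'   warning (no treated deaths, so the mediated AAF is 0).
#' @param hr_nontreat [ratio_estimate()]: mortality hazard ratio,
#'   untreated vs treated.
#' @param z Normal quantile for the uncertainty interval.
#' @return A [fraction_estimate()] labelled `"PDT"`.
#' @export
treated_death_share <- function(p_treat, hr_nontreat, z = default_z()) {
  stopifnot(inherits(p_treat, "proportion_estimate"),
            inherits(hr_nontreat, "ratio_estimate"))
  pt <- p_treat$value
  hr <- hr_nontreat$value
  if (pt == 0) {
    warning("treated_death_share: treatment coverage is 0; ",
            "no deaths occur under treatment and the mediated AAF is 0")
    return(fraction_estimate(0, 0, "PDT", z = z))
  }
  denom <- pt + hr * (1 - pt)
  value <- pt / denom
  d_ptreat <- hr / denom^2
  d_hr <- pt * (1 - pt) / denom^2
  variance <- d_ptreat^2 * p_treat$variance + d_hr^2 * hr_nontreat$variance
  fraction_estimate(value, variance, "PDT", z = z)
}

#' Mean mortality risk of the treated population
#'
#' On the arbitrary scale where an adherent treated patient has risk 1, a
#' nonadherent one has risk `RR_na`, so the treated population overall has
#' the adherence-weighted mean risk `1 + P_na (RR_na - 1)`. With the
#' bundled inputs (`P_na = 0.401`, `RR_na = 3.13`) this is 1.85.
#'
#' @param p_na Nonadherence prevalence, a bare fraction.
#' @param rr_na Mortality risk ratio for nonadherence, a bare ratio.
#' @return The mean relative risk of the treated population.
#' @examples
#' overall_treated_risk(0.401, 3.13)  # 1.85413
#' @export
overall_treated_risk <- function(p_na, rr_na) {
  stopifnot(p_na >= 0, p_na <= 1, rr_na > 0)
  1 + p_na * (rr_na - 1)
}

#' Mean mortality risk of the untreated population
#'
#' Continues the risk scale of [overall_treated_risk()]: the untreated
#' have `HR_nontreat` times the mean risk of the treated population,
#' i.e. `(1 + P_na (RR_na - 1)) * HR_nontreat`. With the bundled inputs
#' this is 4.88.
#'
#' @inheritParams overall_treated_risk
#' @param hr_nontreat Mortality hazard ratio, untreated vs treated.
#' @return The relative risk of the untreated population on the
#'   adherent-treated = 1 scale.
#' @examples
#' untreated_risk(0.401, 3.13, 2.63)  # 4.876
#' @export
untreated_risk <- function(p_na, rr_na, hr_nontreat) {
  stopifnot(hr_nontreat > 0)
  overall_treated_risk(p_na, rr_na) * hr_nontreat
}

#' Combine the three components into the final AAF
#'
#' `AAF = AdAF * NAAAF * PDT`. Under independence the variance follows
#' from applying the exact product-variance identity twice:
#' first to `AdAF * NAAAF`, then to that product and `PDT`. The interval
#' is Wald-type, `AAF +/- z sqrt(Var[AAF])`, not truncated to `[0, 1]`.
#'
#' @param adaf,naaaf,pdt [fraction_estimate()]s of the three components.
#' @param z Normal quantile for the uncertainty interval.
#' @return A [fraction_estimate()] labelled `"AAF"`.
#' @export
combine_aaf <- function(adaf, naaaf, pdt, z = default_z()) {
  stopifnot(inherits(adaf, "fraction_estimate"),
            inherits(naaaf, "fraction_estimate"),
            inherits(pdt, "fraction_estimate"))
  m12 <- adaf$value * naaaf$value
  v12 <- product_variance(adaf$value, adaf$variance,
                          naaaf$value, naaaf$variance)
  value <- m12 * pdt$value
  variance <- product_variance(m12, v12, pdt$value, pdt$variance)
  fraction_estimate(value, variance, "AAF", z = z)
}

#' Full AAF chain for one region/sex/age stratum
#'
#' Deterministic composition of [adherence_af()],
#' [alcohol_nonadherence_af()] (with the stratum's drinker prevalence),
#' [treated_death_share()] (with the region's coverage) and
#' [combine_aaf()]. `AdAF` and `PDT` do not depend on sex or age, so they
#' are identical across all strata of one region; only `NAAAF` varies.
#'
#' @param record A [region_record()].
#' @param sex `"men"` or `"women"`.
#' @param age_band Age-band label present in `record`.
#' @param params A [risk_parameters()] set.
#' @param z Normal quantile for the uncertainty intervals.
#' @return A list of class `aaf_stratum` with elements `region`, `sex`,
#'   `age_band`, `adaf`, `naaaf`, `pdt`, `aaf` (each a
#'   [fraction_estimate()]).
#' @examples
#' regions <- load_region_table("africa_gbd_2005")
#' params <- load_parameters("africa_gbd_2005")
#' compute_stratum(regions[["Sub-Saharan Africa, East"]], "men", "15-34",
#'                 params)
#' @export
compute_stratum <- function(record, sex, age_band, params,
                            z = default_z()) {
  stopifnot(inherits(record, "region_record"))
  if (!inherits(params, "risk_parameters")) {
    stop("compute_stratum: params must be a risk_parameters set ",
         "(see load_parameters())", call. = FALSE)
  }
  p_drink <- drinker_prevalence(record, sex, age_band)
  adaf <- adherence_af(params$p_na, params$rr_na, z = z)
  naaaf <- alcohol_nonadherence_af(p_drink, params$rr_drink, z = z)
  pdt <- treated_death_share(record$coverage, params$hr_nontreat, z = z)
  aaf <- combine_aaf(adaf, naaaf, pdt, z = z)
  structure(list(region = record$region, sex = sex, age_band = age_band,
                 adaf = adaf, naaaf = naaaf, pdt = pdt, aaf = aaf),
            class = "aaf_stratum")
}

#' @export
print.aaf_stratum <- function(x, ...) {
  cat(sprintf("<aaf_stratum> %s, %s, %s\n", x$region, x$sex, x$age_band))
  for (nm in c("adaf", "naaaf", "pdt", "aaf")) print(x[[nm]])
  invisible(x)
}

#' Stratified AAF results for a set of regions
#'
#' Runs [compute_stratum()] over every region x sex x age-band cell and
#' collects the results in one data frame (the bundled data yields
#' 5 regions x 2 sexes x 3 bands = 30 rows).
#'
#' @param records Named list of [region_record()]s, as returned by
#'   [load_region_table()].
#' @param params A [risk_parameters()] set.
#' @param z Normal quantile for the uncertainty intervals.
#' @param components If `TRUE` (default) include the `adaf`, `naaaf` and
#'   `pdt` columns alongside the AAF.
#' @return A data frame with columns `region, sex, age_band[, adaf,
#'   naaaf, pdt], aaf, aaf_variance, ci_lower, ci_upper`.
#' @export
compute_aaf_table <- function(records, params, z = default_z(),
                              components = TRUE) {
  stopifnot(length(records) > 0)
  rows <- list()
  for (record in records) {
    for (sex in SEXES) {
      for (band in record$age_bands) {
        s <- compute_stratum(record, sex, band, params, z = z)
        rows[[length(rows) + 1L]] <- data.frame(
          region = s$region, sex = s$sex, age_band = s$age_band,
          adaf = s$adaf$value, naaaf = s$naaaf$value, pdt = s$pdt$value,
          aaf = s$aaf$value, aaf_variance = s$aaf$variance,
          ci_lower = s$aaf$ci_lower, ci_upper = s$aaf$ci_upper,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!components) out <- out[setdiff(names(out),
                                      c("adaf", "naaaf", "pdt"))]
  rownames(out) <- NULL
  out
}
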