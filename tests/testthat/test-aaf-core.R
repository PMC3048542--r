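z <- default_z()

test_that("adherence_af equals the generic attributable-fraction formula", {
  set.seed(2311)
  for (i in 1:100) {
    p <- runif(1)
    rr <- exp(runif(1, -1, 2))
    got <- adherence_af(proportion_estimate(p),
                        ratio_estimate(rr))$value
    # complement-form oracle: (P_adher + P_na RR_na - 1)/(P_adher + P_na RR_na)
    oracle <- ((1 - p) + p * rr - 1) / ((1 - p) + p * rr)
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_equal(got, attributable_fraction(p, rr), tolerance = 1e-12)
  }
})

test_that("attributable fractions vanish without exposure or excess risk", {
  rr <- bundled_params$rr_na
  expect_equal(adherence_af(proportion_estimate(0), rr)$value, 0)
  expect_equal(adherence_af(proportion_estimate(0.4, 0.3, 0.5),
                            ratio_estimate(1))$value, 0)
  p0 <- alcohol_nonadherence_af(proportion_estimate(0),
                                bundled_params$rr_drink)
  expect_equal(p0$value, 0)
  expect_equal(p0$variance, 0)  # Var[P]=0 and P^2 Var[RR]=0 at P=0
})

test_that("the stepwise components match direct arithmetic on the bundled inputs", {
  adaf <- adherence_af(bundled_params$p_na, bundled_params$rr_na)
  denom <- 1 + 0.401 * (3.13 - 1)
  expect_equal(round(denom, 2), 1.85)
  expect_equal(adaf$value, 0.85413 / 1.85413, tolerance = 1e-10)
  expect_equal(adaf$variance,
               product_variance(0.401, bundled_params$p_na$variance,
                                3.13, bundled_params$rr_na$variance) /
                 denom^4)

  # current-drinker fraction, everyone drinking vs the East 15-34 cell
  expect_equal(alcohol_nonadherence_af(proportion_estimate(1),
                                       bundled_params$rr_drink)$value,
               0.82 / 1.82)
  naaaf <- alcohol_nonadherence_af(drinker_prevalence(east, "men", "15-34"),
                                   bundled_params$rr_drink)
  expect_equal(naaaf$value, 0.246 * 0.82 / (1 + 0.246 * 0.82))

  pdt <- treated_death_share(east$coverage, bundled_params$hr_nontreat)
  expect_equal(pdt$value, 0.1424 / (0.1424 + 2.63 * (1 - 0.1424)))
  expect_equal(round(pdt$value, 4), 0.0594)
  dd <- (0.1424 + 2.63 * (1 - 0.1424))^2
  expect_equal(pdt$variance,
               (2.63 / dd)^2 * east$coverage$variance +
                 (0.1424 * (1 - 0.1424) / dd)^2 *
                 bundled_params$hr_nontreat$variance)
})

test_that("treated_death_share honours its boundary and monotonicity laws", {
  hr <- bundled_params$hr_nontreat
  expect_equal(treated_death_share(proportion_estimate(1), hr)$value, 1)
  expect_equal(treated_death_share(proportion_estimate(0.37),
                                   ratio_estimate(1))$value, 0.37)
  expect_warning(
    p0 <- treated_death_share(proportion_estimate(0), hr), "coverage is 0")
  expect_equal(p0$value, 0)

  # strictly decreasing in HR at fixed coverage
  shares <- vapply(c(1, 1.5, 2.63, 5, 10), function(h)
    treated_death_share(proportion_estimate(0.2),
                        ratio_estimate(h))$value, numeric(1))
  expect_true(all(diff(shares) < 0))
})

test_that("the published risk scale chain is reproduced", {
  expect_equal(round(overall_treated_risk(0.401, 3.13), 2), 1.85)
  expect_equal(round(untreated_risk(0.401, 3.13, 2.63), 2), 4.88)
  expect_equal(overall_treated_risk(0, 7), 1)
  expect_equal(overall_treated_risk(1, 3.13), 3.13)
  expect_equal(untreated_risk(0, 3.13, 1), 1)
  expect_equal(untreated_risk(0, 3.13, 2.63), 2.63)
})

test_that("combine_aaf multiplies components and chains the product variance", {
  zero <- fraction_estimate(0, 0, "NAAAF")
  one <- fraction_estimate(1, 0, "AdAF")
  expect_equal(combine_aaf(one, zero, fraction_estimate(1, 0, "PDT"))$value, 0)
  expect_equal(combine_aaf(one, fraction_estimate(1, 0, "NAAAF"),
                           fraction_estimate(1, 0, "PDT"))$value, 1)

  adaf <- fraction_estimate(0.46, 0.008, "AdAF")
  naaaf <- fraction_estimate(0.17, 0.0003, "NAAAF")
  pdt <- fraction_estimate(0.06, 0.0001, "PDT")
  aaf <- combine_aaf(adaf, naaaf, pdt)
  v12 <- product_variance(0.46, 0.008, 0.17, 0.0003)
  expect_equal(aaf$value, 0.46 * 0.17 * 0.06)
  expect_equal(aaf$variance,
               product_variance(0.46 * 0.17, v12, 0.06, 0.0001))
  expect_equal(aaf$ci_upper - aaf$ci_lower, 2 * z * sqrt(aaf$variance))
})

test_that("compute_stratum chains the components for the East 15-34 men", {
  s <- compute_stratum(east, "men", "15-34", bundled_params)
  adaf_o <- 0.401 * 2.13 / (1 + 0.401 * 2.13)
  naaaf_o <- 0.246 * 0.82 / (1 + 0.246 * 0.82)
  pdt_o <- 0.1424 / (0.1424 + 2.63 * 0.8576)
  expect_equal(s$adaf$value, adaf_o)
  expect_equal(s$naaaf$value, naaaf_o)
  expect_equal(s$pdt$value, pdt_o)
  expect_equal(s$aaf$value, adaf_o * naaaf_o * pdt_o)
  expect_equal(round(s$aaf$value, 5), 0.00459)

  expect_error(compute_stratum(east, "men", "15-34", list()),
               "risk_parameters")
  expect_error(compute_stratum(east, "men", "90+", bundled_params),
               "age band")
})

test_that("AdAF and PDT are shared across strata of one region", {
  a <- compute_stratum(east, "men", "15-34", bundled_params)
  b <- compute_stratum(east, "women", "55+", bundled_params)
  expect_identical(a$adaf$value, b$adaf$value)
  expect_identical(a$pdt$value, b$pdt$value)
  expect_false(isTRUE(all.equal(a$naaaf$value, b$naaaf$value)))
})

test_that("fractions are monotone in prevalence and risk, and AAF <= components", {
  set.seed(555)
  af_val <- function(p, rr)
    adherence_af(proportion_estimate(p), ratio_estimate(rr))$value
  for (i in 1:20) {
    p <- runif(1, 0.05, 0.9); rr <- runif(1, 1.1, 5)
    expect_gt(af_val(p + 0.05, rr), af_val(p, rr))
    expect_gt(af_val(p, rr + 0.3), af_val(p, rr))
  }
  tab <- compute_aaf_table(bundled_regions, bundled_params)
  expect_true(all(tab$aaf <= pmin(tab$adaf, tab$naaaf, tab$pdt) + 1e-15))
})

test_that("zero input variances collapse every interval to the point", {
  params0 <- risk_parameters(
    p_na = proportion_estimate(0.401),
    rr_na = ratio_estimate(3.13),
    rr_drink = ratio_estimate(1.82),
    hr_nontreat = ratio_estimate(2.63))
  expect_error(
    region_record("pt", proportion_estimate(0.1424),
                  setNames(list(proportion_estimate(0.246)), "men|15-34")),
    "women")
  cells <- setNames(lapply(c(0.246, 0.1), proportion_estimate),
                    c("men|15-34", "women|15-34"))
  rec0 <- region_record("pt", proportion_estimate(0.1424), cells)
  s <- compute_stratum(rec0, "men", "15-34", params0)
  for (nm in c("adaf", "naaaf", "pdt", "aaf")) {
    expect_equal(s[[nm]]$variance, 0)
    expect_equal(s[[nm]]$ci_lower, s[[nm]]$value)
    expect_equal(s[[nm]]$ci_upper, s[[nm]]$value)
  }
})
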