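test_that("variance_from_interval matches direct evaluation on both scales", {
  z <- default_z()
  # log-scale interval of the no-treatment hazard ratio
  expect_equal(variance_from_interval(2.63, 1.92, 3.57, "log_normal"),
               2.63^2 * ((log(3.57) - log(1.92)) / (2 * z))^2)
  # linear-scale interval of the nonadherence prevalence
  expect_equal(variance_from_interval(0.401, 0.369, 0.433, "normal"),
               ((0.433 - 0.369) / (2 * z))^2)
  # degenerate interval on either scale
  expect_equal(variance_from_interval(2, 2, 2, "log_normal"), 0)
  expect_equal(variance_from_interval(2, 2, 2, "normal"), 0)

  expect_error(variance_from_interval(2, 3, 1, "normal"), "lower")
  expect_error(variance_from_interval(2, 0, 3, "log_normal"), "positive")
})

test_that("log-scale variance is identical for a ratio and its inverse", {
  v <- variance_from_interval(1, 0.28, 0.52, "log_normal") # value-free check
  expect_equal(((log(0.52) - log(0.28)) / (2 * default_z()))^2,
               ((log(1 / 0.28) - log(1 / 0.52)) / (2 * default_z()))^2)
  expect_equal(ratio_estimate(0.38, 0.28, 0.52)$log_variance,
               invert_ratio(ratio_estimate(0.38, 0.28, 0.52))$log_variance)
  expect_true(v >= 0)
})

test_that("invert_ratio recovers the published no-treatment hazard ratio", {
  inv <- invert_ratio(ratio_estimate(0.38, 0.28, 0.52))
  expect_equal(round(inv$value, 2), 2.63)
  expect_equal(round(inv$lower, 2), 1.92)
  expect_equal(round(inv$upper, 2), 3.57)
  expect_equal(inv$variance, (1 / 0.38)^2 * inv$log_variance)
})

test_that("invert_ratio is an involution and fixes the null ratio", {
  set.seed(41)
  for (i in 1:25) {
    lo <- runif(1, 0.2, 1.5)
    val <- lo * runif(1, 1, 2)
    hi <- val * runif(1, 1, 2)
    est <- ratio_estimate(val, lo, hi)
    twice <- invert_ratio(invert_ratio(est))
    expect_equal(twice$value, est$value, tolerance = 1e-12)
    expect_equal(twice$lower, est$lower, tolerance = 1e-12)
    expect_equal(twice$upper, est$upper, tolerance = 1e-12)
    expect_equal(twice$log_variance, est$log_variance, tolerance = 1e-12)
  }
  # ratio 1 with a log-symmetric interval is self-inverse
  one <- ratio_estimate(1, 1 / 1.3, 1.3)
  ione <- invert_ratio(one)
  expect_equal(ione$value, 1)
  expect_equal(ione$lower, one$lower, tolerance = 1e-12)
  expect_equal(ione$upper, one$upper, tolerance = 1e-12)
})

test_that("odds_to_risk implements the conversion and its propagation", {
  p_na <- proportion_estimate(0.401, 0.369, 0.433)

  # null association: RR = 1, D_P vanishes (OR(1-OR) = 0) and only
  # Var[OR] propagates through D_OR = (1-P)
  or1 <- ratio_estimate(1, 0.8, 1.25)
  rr1 <- odds_to_risk(or1, p_na)
  expect_equal(rr1$value, 1)
  expect_equal(rr1$variance, (1 - 0.401)^2 * or1$variance)

  # rare-outcome limit P = 0: RR = OR with Var[OR]
  or <- ratio_estimate(2.2, 1.7, 2.9)
  rr0 <- odds_to_risk(or, proportion_estimate(0))
  expect_equal(rr0$value, or$value)
  expect_equal(rr0$variance, or$variance)

  # nonadherence odds ratio for drinkers (inverse of the published
  # adherence OR 0.604) converted at the population nonadherence level
  or_na <- invert_ratio(ratio_estimate(0.604, 0.531, 0.687))
  rr <- odds_to_risk(or_na, p_na)
  oracle <- or_na$value / ((1 - 0.401) + 0.401 * or_na$value)
  expect_equal(rr$value, oracle)
  expect_equal(round(rr$value, 3), 1.311)
  d_or <- (1 - 0.401) / ((1 - 0.401) + 0.401 * or_na$value)^2
  d_p <- or_na$value * (1 - or_na$value) /
    ((1 - 0.401) + 0.401 * or_na$value)^2
  expect_equal(rr$variance,
               d_p^2 * p_na$variance + d_or^2 * or_na$variance)
})

test_that("odds_to_risk output lies strictly between 1 and OR", {
  set.seed(42)
  for (i in 1:50) {
    or_v <- exp(runif(1, -1.5, 1.5))
    if (abs(or_v - 1) < 0.05) next
    or <- ratio_estimate(or_v, or_v * 0.8, or_v * 1.25)
    p <- proportion_estimate(runif(1, 0.05, 0.95))
    rr <- odds_to_risk(or, p)$value
    if (or_v > 1) {
      expect_gt(rr, 1); expect_lt(rr, or_v)
    } else {
      expect_lt(rr, 1); expect_gt(rr, or_v)
    }
  }
})

test_that("product_variance is the exact product-of-independents variance", {
  expect_equal(product_variance(0.5, 0.01, 0.2, 0.004), 0.00144)
  expect_equal(product_variance(0.5, 0.01, 0.2, 0.004),
               product_variance(0.2, 0.004, 0.5, 0.01))  # symmetric
  expect_equal(product_variance(3, 0, 7, 0), 0)
  expect_error(product_variance(1, -0.1, 1, 0.1), ">= 0")

  # simulation oracle: empirical variance of X*Y for independent normals
  set.seed(90125)
  n <- 2e5
  for (pars in list(c(0.4, 0.02, 3.1, 0.6), c(1, 0.1, 1, 0.1),
                    c(0.15, 0.001, 2.6, 0.18))) {
    x <- rnorm(n, pars[1], sqrt(pars[2]))
    y <- rnorm(n, pars[3], sqrt(pars[4]))
    expect_equal(product_variance(pars[1], pars[2], pars[3], pars[4]),
                 var(x * y), tolerance = 0.03)
  }
})

test_that("load_parameters reads the bundled set and user files", {
  p <- bundled_params
  expect_s3_class(p, "risk_parameters")
  expect_equal(p$p_na$value, 0.401)
  expect_equal(p$rr_drink$value, 1.82)
  expect_equal(p$rr_na$value, 3.13)
  expect_equal(p$hr_nontreat$value, 2.63)
  expect_equal(p$hr_nontreat$scale_assumption, "log_normal")

  # user file round-trip
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(parameters = list(
    list(name = "p_na", value = 0.3, lower = 0.2, upper = 0.4,
         scale_assumption = "normal"),
    list(name = "rr_na", value = 2, lower = 1.5, upper = 2.7),
    list(name = "rr_drink", value = 1.5, lower = 1.2, upper = 1.9),
    list(name = "hr_nontreat", value = 3, lower = 2, upper = 4.5))),
    path, auto_unbox = TRUE, digits = NA)
  q <- load_parameters(path)
  expect_equal(q$p_na$value, 0.3)
  expect_equal(q$rr_na$scale_assumption, "log_normal")

  # missing parameter is named in the error
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(parameters = list(
    list(name = "p_na", value = 0.3, lower = 0.2, upper = 0.4))),
    bad, auto_unbox = TRUE)
  expect_error(load_parameters(bad), "rr_na")
  expect_error(load_parameters("/nonexistent/params.json"), "not found")
})
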