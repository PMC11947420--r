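test_that("liability thresholds match normal quantiles and a root-find oracle", {
  expect_equal(liability_threshold(0.025), 1.95996, tolerance = 1e-5)
  expect_equal(liability_threshold(0.5), 0)
  expect_equal(liability_threshold(0.40), 0.25335, tolerance = 1e-4)
  expect_equal(liability_threshold(0.025, variance = 2),
               sqrt(2) * qnorm(1 - 0.025))

  # oracle: numeric root-find of the normal CDF, 1e-9 agreement
  for (K in c(1e-4, 1e-3, 0.00625, 0.025, 0.1, 0.35, 0.5)) {
    root <- uniroot(function(t) pnorm(t, lower.tail = FALSE) - K,
                    c(-10, 10), tol = 1e-12)$root
    expect_equal(liability_threshold(K), root, tolerance = 1e-9)
  }
  # strictly decreasing in prevalence, monotone in variance
  ks <- seq(0.01, 0.49, by = 0.04)
  expect_true(all(diff(liability_threshold(ks)) < 0))
  expect_true(all(diff(liability_threshold(0.025, variance = c(1, 2, 3))) > 0))
  expect_error(liability_threshold(0), class = "varliab_domain_error")
  expect_error(liability_threshold(1), class = "varliab_domain_error")
})

test_that("truncated means match numeric integration and conserve the mean", {
  m <- truncated_liability_means(0.5)
  expect_equal(m$mean_affected, 0.79788, tolerance = 1e-5)
  expect_equal(m$mean_unaffected, -0.79788, tolerance = 1e-5)

  m2 <- truncated_liability_means(0.025)
  expect_equal(m2$mean_affected, 2.3378, tolerance = 1e-4)
  expect_equal(m2$mean_unaffected, -0.05994, tolerance = 1e-4)

  for (K in c(0.001, 0.00625, 0.025, 0.1, 0.35, 0.5, 0.8)) {
    oracle <- integrate_truncated_means(K)
    got <- truncated_liability_means(K)
    expect_equal(got$mean_affected, unname(oracle["mean_affected"]),
                 tolerance = 1e-7)
    expect_equal(got$mean_unaffected, unname(oracle["mean_unaffected"]),
                 tolerance = 1e-7)
    expect_equal(K * got$mean_affected + (1 - K) * got$mean_unaffected, 0,
                 tolerance = 1e-12)
  }
})

test_that("carrier penetrance is a Bayes inversion of the rate ratio", {
  expect_equal(carrier_penetrance(0.01, 0.01, 0.37), 0.37)
  expect_equal(carrier_penetrance(0.02, 0.01, 0.4, warn_rare = FALSE), 0.8 / 1.4)
  expect_equal(carrier_penetrance(0.05, 0, 0.025), 1)
  expect_error(carrier_penetrance(0, 0, 0.025), class = "varliab_domain_error")
  expect_warning(carrier_penetrance(0.5, 0.2, 0.025), "rare-carrier")
  # scale invariance in the rates
  expect_equal(carrier_penetrance(0.02, 0.01, 0.1, warn_rare = FALSE),
               carrier_penetrance(0.002, 0.001, 0.1))
})

test_that("liability effect is zero at equal rates, monotone, scale-invariant", {
  for (method in c("threshold_shift", "truncated_mixture")) {
    expect_equal(liability_effect(0.02, 0.02, 0.025, method = method), 0)
    z <- liability_effect(c(0.011, 0.013, 0.02, 0.05), 0.01, 0.025,
                          method = method)
    expect_true(all(diff(z) > 0))
    expect_equal(liability_effect(0.04, 0.02, 0.025, method = method),
                 liability_effect(0.004, 0.002, 0.025, method = method))
  }
})

test_that("the truncated-mixture convention reproduces its composed value", {
  # penetrance 4/7 at a 2-fold enrichment and prevalence 0.40, combined
  # with the truncated means at that prevalence
  z <- liability_effect(0.02, 0.01, 0.40, method = "truncated_mixture",
                        warn_rare = FALSE)
  expect_equal(z, 0.57143 * 0.96567 + 0.42857 * (-0.64378), tolerance = 3e-4)
  expect_equal(z, 0.27590, tolerance = 3e-4)
})

test_that("the threshold-shift estimator inverts an analytic carrier shift", {
  # carriers shifted by beta: penetrance is the upper tail at T - beta;
  # building rates from that penetrance must return exactly beta
  for (K in c(0.00625, 0.025, 0.35)) {
    for (beta in c(0.3, 0.6, 1.0)) {
      t <- qnorm(K, lower.tail = FALSE)
      pen <- pnorm(t - beta, lower.tail = FALSE)
      rate_cases <- pen / K
      rate_controls <- (1 - pen) / (1 - K)
      expect_equal(
        liability_effect(rate_cases, rate_controls, K, warn_rare = FALSE),
        beta, tolerance = 1e-10
      )
    }
  }
})

test_that("liability_from_ratio matches liability_effect and handles Inf", {
  rr <- c(0.5, 1, 2, 5)
  expect_equal(liability_from_ratio(rr, 0.025),
               liability_effect(rr, 1, 0.025, warn_rare = FALSE))
  expect_equal(liability_from_ratio(1, 0.1), 0)
  expect_true(is.infinite(liability_from_ratio(Inf, 0.025)))
})

test_that("standard errors derive from the exact-test p-value", {
  est <- se_and_ci(0.5, 0.05)
  expect_equal(est$se, 0.5 / qnorm(0.975), tolerance = 1e-6)
  expect_equal(est$ci_high - est$z, abs(est$z), tolerance = 1e-4)

  # round trip: the p implied by (z, se) reproduces the input p
  for (p in c(0.001, 0.05, 0.5)) {
    est <- se_and_ci(0.3, p)
    expect_equal(2 * pnorm(abs(est$z) / est$se, lower.tail = FALSE), p,
                 tolerance = 1e-10)
  }

  # published consistency check: a sex-difference z of 0.093 with CI upper
  # bound 0.20 implies se 0.0546 and p near the printed 0.087
  se_rec <- (0.20 - 0.093) / qnorm(0.975)
  p_rec <- 2 * pnorm(0.093 / se_rec, lower.tail = FALSE)
  expect_equal(p_rec, 0.089, tolerance = 0.01)
  expect_equal(p_rec, 0.087, tolerance = 0.05)

  expect_message(out <- se_and_ci(0.3, 1), "undefined")
  expect_true(is.na(out$se))
  expect_error(se_and_ci(0.3, 0), class = "varliab_domain_error")
  expect_error(se_and_ci(Inf, 0.5), class = "varliab_domain_error")
})

test_that("sex-difference contrasts subtract male from female estimates", {
  d0 <- sex_difference_liability(0.4, 0.1, 0.4, 0.1)
  expect_equal(d0$z_diff, 0)
  expect_equal(d0$p_value, 1)

  # antisymmetry
  d1 <- sex_difference_liability(0.66, 0.06, 0.53, 0.055)
  d2 <- sex_difference_liability(0.53, 0.055, 0.66, 0.06)
  expect_equal(d1$z_diff, -d2$z_diff)
  expect_equal(d1$p_value, d2$p_value)

  # reconstructed from published CIs: 0.66 (0.54-0.78) vs 0.53 (0.42-0.64)
  se_f <- (0.78 - 0.54) / (2 * qnorm(0.975))
  se_m <- (0.64 - 0.42) / (2 * qnorm(0.975))
  d <- sex_difference_liability(0.66, se_f, 0.53, se_m)
  expect_equal(d$z_diff, 0.13, tolerance = 1e-10)
  expect_gt(d$p_value, 0.05)
})

test_that("unequal-variance models rescale thresholds and reduce at ratio 1", {
  base <- unequal_variance_adjustment(prevalence_spec())
  expect_equal(base$threshold_raw, base$threshold_standardized)

  uv <- unequal_variance_adjustment(prevalence_spec(male_variance = 2))
  male <- uv[uv$sex == "male", ]
  expect_equal(male$threshold_raw, sqrt(2) * 1.95996, tolerance = 1e-4)
  expect_equal(male$threshold_standardized, 1.95996, tolerance = 1e-4)

  # thresholds monotone in variance at fixed prevalence
  raws <- sapply(c(1, 2, 3), function(v) {
    u <- unequal_variance_adjustment(prevalence_spec(male_variance = v))
    u$threshold_raw[u$sex == "male"]
  })
  expect_true(all(diff(raws) > 0))

  # with rates attached the standardized effects match liability_effect
  rates <- tibble::tibble(sex = c("female", "male"),
                          rate_cases = c(0.04, 0.04),
                          rate_controls = c(0.02, 0.02))
  uv2 <- unequal_variance_adjustment(prevalence_spec(male_variance = 2), rates)
  expect_equal(uv2$z_raw, sqrt(uv2$variance) * uv2$z_standardized)
  expect_equal(uv2$z_standardized[uv2$sex == "male"],
               liability_effect(0.04, 0.02, 0.025, warn_rare = FALSE))
})

test_that("milder sex ratios give female thresholds between the extremes", {
  t_male <- liability_threshold(0.025)
  t_f4 <- liability_threshold(female_prevalence_from_ratio(0.025, 4))
  for (ratio in c(3, 2)) {
    t_f <- liability_threshold(female_prevalence_from_ratio(0.025, ratio))
    expect_gt(t_f, t_male)
    expect_lt(t_f, t_f4)
  }
})
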