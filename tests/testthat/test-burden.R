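test_that("exact binomial p equals full enumeration", {
  expect_equal(exact_binom_p(50, 100, 0.5), 1)
  expect_equal(exact_binom_p(60, 100, 0.5), 0.05689, tolerance = 1e-4)
  expect_equal(exact_binom_p(0, 10, 0.5), 2 / 1024, tolerance = 1e-10)

  # oracle equivalence: every outcome for all trials <= 25
  for (p0 in c(0.1, 0.3, 0.5, 0.7)) {
    for (n in c(1, 2, 3, 5, 8, 13, 17, 21, 25)) {
      got <- exact_binom_p(0:n, n, p0)
      want <- vapply(0:n, enum_binom_p, numeric(1), trials = n, p0 = p0)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
  expect_error(exact_binom_p(1, 0, 0.5), class = "varliab_domain_error")
  expect_error(exact_binom_p(5, 3, 0.5), class = "varliab_domain_error")
})

test_that("de novo rate ratios carry exact tests and mapped CIs", {
  eq <- dnm_rate_ratio(20, 1000, 20, 1000)
  expect_equal(eq$ratio, 1)
  expect_equal(eq$p_value, 1)
  expect_lte(eq$ci_low, 1)
  expect_gte(eq$ci_high, 1)

  rr <- dnm_rate_ratio(30, 1000, 10, 1000)
  expect_equal(rr$ratio, 3)
  expect_equal(rr$p_value, enum_binom_p(30, 40, 0.5), tolerance = 1e-9)
  expect_equal(rr$expected_fraction, 0.5)

  # scale invariance: multiplying both denominators leaves the split test
  # unchanged
  big <- dnm_rate_ratio(30, 10000, 10, 10000)
  expect_equal(big$expected_fraction, rr$expected_fraction)
  expect_equal(big$p_value, rr$p_value)

  expect_warning(zc <- dnm_rate_ratio(5, 100, 0, 100), "infinite")
  expect_true(is.infinite(zc$ratio))
  expect_true(is.infinite(zc$ci_high))
  expect_error(dnm_rate_ratio(3, 0, 1, 10), class = "varliab_domain_error")
})

test_that("transmission tests compare transmitted alleles against one half", {
  t0 <- transmission_test(40, 40)
  expect_equal(t0$ratio, 1)
  expect_equal(t0$p_value, 1)

  t1 <- transmission_test(60, 40)
  expect_equal(t1$ratio, 1.5)
  expect_equal(t1$p_value, 0.05689, tolerance = 1e-4)

  # mirror: swapping transmitted/untransmitted inverts the ratio, same p
  t2 <- transmission_test(40, 60)
  expect_equal(t2$ratio, 1 / t1$ratio)
  expect_equal(t2$p_value, t1$p_value)
})

test_that("female-male contrasts use the female sample-size expectation", {
  prop <- sex_difference_observed(10, 40, 1000, 4000)
  expect_equal(prop$ratio, 1)
  expect_equal(prop$p_value, 1)

  d <- sex_difference_observed(40, 100, 4404, 17097)
  expect_equal(d$ratio, (40 / 4404) / (100 / 17097), tolerance = 1e-9)
  expect_equal(d$ratio, 1.553, tolerance = 1e-3)
  expect_equal(d$p_value, enum_binom_p(40, 140, 4404 / 21501),
               tolerance = 1e-9)

  # significance grows as counts scale at fixed rates
  p_seq <- vapply(c(1, 2, 4), function(k) {
    sex_difference_observed(40 * k, 100 * k, 4404, 17097)$p_value
  }, numeric(1))
  expect_true(all(diff(p_seq) < 0))
})

test_that("transmission sex contrast uses the parental-allele share", {
  even <- sex_difference_transmission(40, 100, 400, 1000)
  expect_equal(even$expected_fraction, 0.4)
  expect_equal(even$p_value, 1)

  d <- sex_difference_transmission(55, 100, 400, 1000)
  expect_equal(d$p_value, enum_binom_p(55, 100, 0.4), tolerance = 1e-9)
  expect_gte(d$expected_fraction, 0)
  expect_lte(d$expected_fraction, 1)
  expect_error(sex_difference_transmission(110, 100, 400, 1000),
               class = "varliab_domain_error")
})

test_that("parent-of-origin burden mirrors the rate-ratio mechanics", {
  eq <- parent_of_origin_burden(20, 1000, 20, 1000)
  expect_equal(eq$ratio, 1)

  d <- parent_of_origin_burden(230, 20000, 200, 20000)
  expect_equal(d$ratio, 1.15)
  expect_equal(d$p_value, enum_binom_p(230, 430, 0.5), tolerance = 1e-9)

  # symmetry: swapping parents inverts the ratio
  s <- parent_of_origin_burden(200, 20000, 230, 20000)
  expect_equal(s$ratio, 1 / d$ratio)
})

test_that("mutational-model expectations follow the diploid convention", {
  m <- mutational_model_test(rep(1e-6, 10), 31565, 1)
  expect_equal(m$expected, 2 * 31565 * 1e-5, tolerance = 1e-12)
  expect_equal(m$expected, 0.6313, tolerance = 1e-4)

  # observed equal to (integer) expected is unremarkable
  m2 <- mutational_model_test(rep(1e-5, 5), 10000, 1)
  expect_equal(m2$expected, 1)
  expect_gt(m2$p_value, 0.9)

  # linear in the trio count
  e <- vapply(c(1000, 2000, 4000), function(n) {
    mutational_model_test(rep(1e-6, 10), n, 0)$expected
  }, numeric(1))
  expect_equal(e[2] / e[1], 2)
  expect_equal(e[3] / e[1], 4)

  # diploid-convention rates drop the factor of two
  md <- mutational_model_test(rep(2e-6, 10), 31565, 1,
                              rate_convention = "diploid")
  expect_equal(md$expected, 31565 * 2e-5)

  expect_warning(z <- mutational_model_test(0, 100, 3), "zero")
  expect_equal(z$p_value, 0)
})

test_that("relative risks reproduce in-study arithmetic", {
  expect_equal(relative_risk(387, 1413, 1519, 6615), 1.193, tolerance = 1e-3)
  expect_equal(relative_risk(775, 2991, 2424, 10482), 1.120, tolerance = 1e-3)
  expect_equal(relative_risk(10, 100, 10, 100), 1)
  expect_error(relative_risk(1, 0, 1, 10), class = "varliab_domain_error")
})

test_that("burden_test dispatches by mode and ignores row order", {
  counts <- tibble::tibble(
    cohort = "c", sex = c("female", "male", "female", "male"),
    phenotype_group = "all",
    variant_class = "damaging_PTV",
    mode = c("de_novo", "de_novo", "transmitted_untransmitted",
             "transmitted_untransmitted"),
    events_case = c(30, 90, 60, 120),
    events_control = c(10, 40, 40, 100),
    n_case = c(1000, 3000, NA, NA),
    n_control = c(1000, 3000, NA, NA)
  )
  res <- burden_test(counts)
  expect_equal(res$ratio[1], 3)
  expect_equal(res$ratio[3], 1.5)
  expect_equal(res$p_value[3], 0.05689, tolerance = 1e-4)

  shuffled <- burden_test(counts[c(3, 1, 4, 2), ])
  merged <- merge(res, shuffled,
                  by = c("sex", "mode"), suffixes = c("", ".s"))
  expect_equal(merged$ratio, merged$ratio.s)
  expect_equal(merged$p_value, merged$p_value.s)

  # zero-event rows are reported as uninformative, not errors
  zero <- burden_test(tibble::tibble(
    cohort = "c", sex = "female", phenotype_group = "all",
    variant_class = "damaging_PTV", mode = "de_novo",
    events_case = 0, events_control = 0, n_case = 10, n_control = 10
  ))
  expect_equal(zero$p_value, 1)
  expect_true(is.na(zero$ratio))
})

test_that("rate-ratio CIs achieve near-nominal coverage in simulation", {
  # counts drawn directly from the Poisson sampling model at true ratios
  # 1 and 2; exact CIs must cover the truth in at least 93% of replicates
  set.seed(42)
  n_rep <- 1000
  for (true_ratio in c(1, 2)) {
    ec <- rpois(n_rep, 60 * true_ratio)
    eo <- rpois(n_rep, 60)
    keep <- ec + eo > 0 & eo > 0
    rr <- dnm_rate_ratio(ec[keep], 1000, eo[keep], 1000)
    covered <- rr$ci_low <= true_ratio & rr$ci_high >= true_ratio
    expect_gte(mean(covered), 0.93)
  }
  # transmission CIs, true transmitted:untransmitted ratio 1 and 2
  for (true_ratio in c(1, 2)) {
    tr <- rbinom(n_rep, 120, true_ratio / (1 + true_ratio))
    tt <- transmission_test(tr, 120 - tr)
    covered <- tt$ci_low <= true_ratio & tt$ci_high >= true_ratio
    expect_gte(mean(covered), 0.93)
  }
})
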