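# Independent oracles used across the suite. They deliberately avoid the
# package's code paths: the binomial oracle enumerates outcome
# probabilities directly, the truncated-mean oracle integrates numerically,
# and the matched-set oracle enumerates every possible draw.

# two-sided exact binomial p by full enumeration (minimum-likelihood rule)
enum_binom_p <- function(successes, trials, p0) {
  probs <- dbinom(0:trials, trials, p0)
  sum(probs[probs <= probs[successes + 1] * (1 + 1e-7)])
}

# truncated-normal means by numeric integration
integrate_truncated_means <- function(K) {
  t <- qnorm(K, lower.tail = FALSE)
  above <- integrate(function(x) x * dnorm(x), t, Inf, rel.tol = 1e-12)$value
  below <- integrate(function(x) x * dnorm(x), -Inf, t, rel.tol = 1e-12)$value
  c(mean_affected = above / K, mean_unaffected = below / (1 - K))
}

# exhaustive expectation of the matched-draw ratio: every target gene draws
# uniformly from its candidate set; enumerate the full product space
enum_expected_ratio <- function(candidate_counts_case, candidate_counts_ctrl,
                                scale = 1) {
  grids <- lapply(candidate_counts_case, seq_along)
  combos <- expand.grid(grids)
  ratios <- apply(combos, 1, function(ix) {
    cs <- sum(mapply(function(cc, i) cc[i], candidate_counts_case, ix))
    ct <- sum(mapply(function(cc, i) cc[i], candidate_counts_ctrl, ix))
    if (ct == 0) return(NA_real_)
    cs / ct * scale
  })
  mean(ratios, na.rm = TRUE)
}

# single-class simulation config used by recovery and calibration studies
recovery_config <- function(seed, n_families, beta,
                            rate = c(damaging_PTV = 0.02)) {
  simulation_config(
    n_families = n_families, seed = seed,
    dnm_rate = rate,
    effect_sizes = setNames(beta, names(rate)),
    inherited_allele_frequency = setNames(0, names(rate))
  )
}

# male-proband damaging-PTV de novo estimate from one simulated cohort:
# rate ratio with exact CI, mapped to the liability scale
male_ptv_recovery <- function(seed, n_families, beta) {
  co <- simulate_cohort(recovery_config(seed, n_families, beta),
                        detail = "counts")
  cc <- collapse_phenotype_groups(co$counts)
  cc <- cc[cc$mode == "de_novo" & cc$variant_class == "damaging_PTV" &
             cc$sex == "male", ]
  rr <- dnm_rate_ratio(cc$events_case, cc$n_case,
                       cc$events_control, cc$n_control)
  zz <- liability_from_ratio(c(rr$ci_low, rr$ratio, rr$ci_high), 0.025)
  tibble::tibble(z = zz[2], ci_low = zz[1], ci_high = zz[3],
                 p_value = rr$p_value)
}
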