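#' Liability threshold for a given prevalence
#'
#' Under the liability threshold model the trait corresponds to the upper
#' tail of a normal liability distribution; the threshold is the upper-tail
#' standard-normal quantile at the prevalence, scaled by the liability
#' standard deviation. A male autism prevalence of 2.5% places the
#' threshold at 1.96 standardized units; 0.625% in females places it at
#' about 2.50.
#'
#' @param prevalence Trait prevalence, proportion in (0,1). Vectorized.
#' @param variance Liability variance (default 1). The returned threshold is
#'   on the raw scale of that distribution; divide by `sqrt(variance)` for
#'   the standardized scale.
#' @return Numeric vector of thresholds in liability SD units.
#' @examples
#' liability_threshold(0.025)         # 1.96
#' liability_threshold(0.025, 2)      # sqrt(2) * 1.96
#' @export
liability_threshold <- function(prevalence, variance = 1) {
  check_proportion(prevalence, "prevalence")
  if (any(!is.finite(variance) | variance <= 0)) {
    stop_domain("`variance` must be positive")
  }
  sqrt(variance) * qnorm(prevalence, lower.tail = FALSE)
}

#' Mean liability of affected and unaffected individuals
#'
#' Truncated-normal identities for the standard liability model: with
#' prevalence K and threshold T, the mean liability of affected individuals
#' is phi(T)/K and that of unaffected individuals is -phi(T)/(1-K), so the
#' population mean is conserved at zero.
#'
#' @param prevalence Proportion in (0,1). Vectorized.
#' @return Tibble with columns `mean_affected`, `mean_unaffected` (SD units).
#' @examples
#' truncated_liability_means(0.5) # +/- 0.79788
#' @export
truncated_liability_means <- function(prevalence) {
  check_proportion(prevalence, "prevalence")
  t <- qnorm(prevalence, lower.tail = FALSE)
  tibble(
    mean_affected = dnorm(t) / prevalence,
    mean_unaffected = -dnorm(t) / (1 - prevalence)
  )
}

#' Penetrance of a variant class from case and control carrier rates
#'
#' Bayes inversion under the rare-carrier approximation: given per-sample
#' variant rates in affected individuals and in unaffected (or population)
#' controls, and the trait prevalence K, the probability of being affected
#' given carriage is `rate_cases * K / (rate_cases * K + rate_controls *
#' (1 - K))`. Carrier frequency is neglected in the normalization, which is
#' accurate for rates well below one variant per sample; a warning is
#' raised when either rate exceeds 0.1 unless `warn_rare = FALSE` (the
#' result depends only on the rate ratio, so pre-normalized rates are
#' acceptable inputs).
#'
#' @param rate_cases,rate_controls Variants per sample (nonnegative, not
#'   both zero). Vectorized.
#' @param prevalence Trait prevalence, proportion in (0,1).
#' @param warn_rare Warn when a rate exceeds 0.1 (default TRUE).
#' @return Numeric vector of penetrances in (0,1].
#' @examples
#' carrier_penetrance(2, 1, 0.4) # 0.8 / 1.4
#' @export
carrier_penetrance <- function(rate_cases, rate_controls, prevalence,
                               warn_rare = TRUE) {
  if (any(rate_cases < 0 | rate_controls < 0)) {
    stop_domain("carrier rates must be nonnegative")
  }
  if (any(rate_cases == 0 & rate_controls == 0)) {
    stop_domain("penetrance is undefined when both carrier rates are zero")
  }
  check_proportion(prevalence, "prevalence")
  if (warn_rare && any(pmax(rate_cases, rate_controls) > 0.1)) {
    warn(paste("carrier rate exceeds 0.1 per sample; the rare-carrier",
               "approximation may be inaccurate"))
  }
  rate_cases * prevalence /
    (rate_cases * prevalence + rate_controls * (1 - prevalence))
}

#' Liability-scale effect size of a variant class
#'
#' Converts an observed-scale enrichment (case versus control carrier
#' rates) into the mean liability shift conferred by the variant class, in
#' standard-deviation units of the sex-specific liability distribution.
#'
#' The default `"threshold_shift"` estimator inverts the threshold model:
#' carriers are taken to be normally distributed with unit variance around
#' a shifted mean, so the carrier penetrance p implies a shift
#' `z = T - qnorm(1 - p)` where T is the liability threshold. This
#' estimator is exactly consistent under the generative model used by
#' [simulate_cohort()]: the estimate converges to the simulated carrier
#' shift (see the methods vignette). The alternative
#' `"truncated_mixture"` convention reports the penetrance-weighted average
#' of the population truncated means,
#' `p * mean_affected + (1 - p) * mean_unaffected`; it preserves the sign
#' and ordering of effects but compresses their magnitude and is provided
#' for comparison with analyses that used it.
#'
#' Both estimators return 0 exactly when case and control rates are equal,
#' are strictly increasing in the rate ratio, and depend on the rates only
#' through their ratio.
#'
#' @inheritParams carrier_penetrance
#' @param variance Liability variance of the group (default 1). The return
#'   value is on the standardized (variance-1) scale; multiply by
#'   `sqrt(variance)` for the raw scale.
#' @param method Estimator convention; see Details.
#' @return Numeric vector of liability effects (standardized SD units).
#'   Infinite when `rate_controls` is zero (variant never seen in
#'   controls).
#' @examples
#' liability_effect(2, 1, 0.35) # ~0.43, cf. a 2-fold enrichment
#' @export
liability_effect <- function(rate_cases, rate_controls, prevalence,
                             variance = 1,
                             method = c("threshold_shift", "truncated_mixture"),
                             warn_rare = TRUE) {
  method <- arg_match(method)
  pen <- carrier_penetrance(rate_cases, rate_controls, prevalence,
                            warn_rare = warn_rare)
  if (method == "threshold_shift") {
    qnorm(prevalence, lower.tail = FALSE) - qnorm(pen, lower.tail = FALSE)
  } else {
    m <- truncated_liability_means(prevalence)
    pen * m$mean_affected + (1 - pen) * m$mean_unaffected
  }
}

#' Liability effect from a rate ratio
#'
#' The liability effect depends on the case/control rates only through
#' their ratio, so any rate-ratio quantity -- a point estimate or an exact
#' confidence bound from [dnm_rate_ratio()] or [transmission_test()] --
#' can be mapped directly to the liability scale. Because the mapping is
#' strictly increasing, transforming the bounds of an exact rate-ratio CI
#' yields an exact (asymmetric) CI for the liability effect; this is the
#' interval to use when calibrated coverage matters, e.g. in
#' parameter-recovery validation, whereas [se_and_ci()] reproduces the
#' symmetric Wald-from-p convention used for reported standard errors.
#'
#' @param ratio Rate ratio(s), positive (Inf allowed).
#' @inheritParams liability_effect
#' @return Numeric vector of liability effects (SD units).
#' @examples
#' rr <- dnm_rate_ratio(30, 1000, 10, 1000)
#' liability_from_ratio(c(rr$ci_low, rr$ratio, rr$ci_high), 0.025)
#' @export
liability_from_ratio <- function(ratio, prevalence,
                                 method = c("threshold_shift",
                                            "truncated_mixture")) {
  if (any(ratio < 0, na.rm = TRUE)) stop_domain("`ratio` must be nonnegative")
  liability_effect(ifelse(is.infinite(ratio), 1, ratio),
                   ifelse(is.infinite(ratio), 0, 1),
                   prevalence, method = method, warn_rare = FALSE)
}

#' Standard error and confidence interval from an exact-test p-value
#'
#' The liability pipeline derives the standard error of a liability
#' estimate from the two-sided p-value of the exact binomial count test on
#' which it is based, assuming Wald consistency: `se = |z| / q` where q is
#' the standard-normal two-sided quantile at p. The 95% CI is `z +/-
#' 1.96 se`. When p = 1 (or z = 0) the implied se is undefined and is
#' returned as `NA` with the CI suppressed.
#'
#' @param z Liability effect(s), SD units.
#' @param p_value Two-sided p-value(s) from the associated exact test,
#'   in (0,1].
#' @param prevalence_used Optional prevalence to carry through.
#' @param label Optional stratum descriptor to carry through.
#' @return Tibble with columns `z`, `se`, `ci_low`, `ci_high`, `p_value`
#'   (plus `prevalence_used`/`label` when given).
#' @examples
#' se_and_ci(0.5, 0.05) # se ~ 0.255, CI half-width ~ 0.5
#' @export
se_and_ci <- function(z, p_value, prevalence_used = NULL, label = NULL) {
  if (any(!is.finite(z))) stop_domain("`z` must be finite")
  if (any(p_value <= 0 | p_value > 1)) {
    stop_domain("`p_value` must be in (0, 1]")
  }
  q <- qnorm(p_value / 2, lower.tail = FALSE)
  se <- ifelse(q > 0 & z != 0, abs(z) / q, NA_real_)
  if (any(is.na(se))) {
    inform("se undefined at p = 1 or z = 0; reported as NA with CI suppressed")
  }
  out <- tibble(
    z = z,
    se = se,
    ci_low = z - z975() * se,
    ci_high = z + z975() * se,
    p_value = p_value
  )
  if (!is.null(prevalence_used)) out$prevalence_used <- prevalence_used
  if (!is.null(label)) out$label <- label
  out
}

#' Complete liability estimate for one stratum
#'
#' Convenience wrapper composing [liability_effect()] and [se_and_ci()].
#'
#' @inheritParams liability_effect
#' @inheritParams se_and_ci
#' @return Tibble with `z`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `prevalence_used` and `label`.
#' @export
liability_estimate <- function(rate_cases, rate_controls, prevalence,
                               p_value, label = NA_character_, variance = 1,
                               method = c("threshold_shift", "truncated_mixture"),
                               warn_rare = TRUE) {
  z <- liability_effect(rate_cases, rate_controls, prevalence,
                        variance = variance, method = method,
                        warn_rare = warn_rare)
  se_and_ci(z, p_value, prevalence_used = prevalence, label = label)
}

#' Sex difference of two liability estimates
#'
#' Contrast of female and male liability effects: `z_diff = z_f - z_m`,
#' `se_diff = sqrt(se_f^2 + se_m^2)`, with a two-sided normal p-value.
#' A positive difference means a larger effect size in females.
#'
#' @param z_f,z_m Liability effects per sex.
#' @param se_f,se_m Their standard errors (nonnegative).
#' @return Tibble with `z_diff`, `se_diff`, `ci_low`, `ci_high`, `p_value`.
#' @examples
#' sex_difference_liability(0.66, 0.061, 0.53, 0.056)
#' @export
sex_difference_liability <- function(z_f, se_f, z_m, se_m) {
  if (any(c(se_f, se_m) < 0, na.rm = TRUE)) {
    stop_domain("standard errors must be nonnegative")
  }
  z_diff <- z_f - z_m
  se_diff <- sqrt(se_f^2 + se_m^2)
  p <- ifelse(se_diff == 0,
              as.numeric(z_diff == 0) * 1,
              2 * pnorm(abs(z_diff) / se_diff, lower.tail = FALSE))
  p[se_diff == 0 & z_diff != 0] <- 0
  tibble(
    z_diff = z_diff,
    se_diff = se_diff,
    ci_low = z_diff - z975() * se_diff,
    ci_high = z_diff + z975() * se_diff,
    p_value = p
  )
}

#' Per-sex thresholds and liability effects under unequal variances
#'
#' Relaxes the equal-variance assumption of the standard different-threshold
#' model: each sex keeps its own prevalence but the male liability variance
#' may exceed the female variance (population analyses suggest 2-3x).
#' Thresholds and effects are reported both on each sex's raw scale and on
#' the standardized (variance-1) scale, so the sexes remain directly
#' comparable on the latter; with the female variance at 1 the standardized
#' scale is the female scale.
#'
#' @param spec A [prevalence_spec()] carrying per-sex prevalences and
#'   variances.
#' @param rates Optional tibble with columns `sex` ("female"/"male"),
#'   `rate_cases`, `rate_controls`; when given, liability effects are
#'   appended.
#' @param method Passed to [liability_effect()].
#' @return Tibble with one row per sex: `sex`, `prevalence`, `variance`,
#'   `threshold_standardized`, `threshold_raw`, and (with `rates`)
#'   `z_standardized`, `z_raw`.
#' @examples
#' unequal_variance_adjustment(prevalence_spec(male_variance = 2))
#' @export
unequal_variance_adjustment <- function(spec, rates = NULL,
                                        method = c("threshold_shift",
                                                   "truncated_mixture")) {
  stopifnot(inherits(spec, "prevalence_spec"))
  out <- tidy(spec) %>%
    select("sex", "prevalence", "variance",
           "threshold_standardized", "threshold_raw")
  if (!is.null(rates)) {
    out <- left_join(out, as_tibble(rates), by = "sex") %>%
      mutate(
        z_standardized = liability_effect(
          .data$rate_cases, .data$rate_controls, .data$prevalence,
          method = method, warn_rare = FALSE
        ),
        z_raw = sqrt(.data$variance) * .data$z_standardized
      )
  }
  out
}
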