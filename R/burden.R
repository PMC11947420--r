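#' Two-sided exact binomial p-value
#'
#' Exact two-sided test of `successes` out of `trials` against a null
#' success probability `p0`, using the minimum-likelihood convention (the
#' p-value sums the probabilities of all outcomes no more likely than the
#' one observed), as implemented by [stats::binom.test()]. Vectorized.
#'
#' @param successes,trials Nonnegative integer counts, `successes <= trials`,
#'   `trials > 0`.
#' @param p0 Null success probability in (0,1).
#' @return Numeric vector of p-values in (0,1].
#' @examples
#' exact_binom_p(60, 100, 0.5) # 0.0569
#' @export
exact_binom_p <- function(successes, trials, p0 = 0.5) {
  check_count(successes, "successes")
  check_count(trials, "trials")
  if (any(trials == 0)) stop_domain("`trials` must be positive")
  if (any(successes > trials)) stop_domain("`successes` cannot exceed `trials`")
  check_proportion(p0, "p0")
  mapply(function(s, t, p) binom.test(s, t, p)$p.value,
         successes, trials, p0)
}

# Clopper-Pearson interval on the case fraction of the event split,
# mapped to the ratio scale through f -> (f / (1 - f)) * scale.
rate_ratio_ci <- function(events_case, events_control, scale, conf = 0.95) {
  mapply(function(ec, eo, s) {
    ci <- binom.test(ec, ec + eo, conf.level = conf)$conf.int
    lo <- ci[1] / (1 - ci[1]) * s
    hi <- if (ci[2] >= 1) Inf else ci[2] / (1 - ci[2]) * s
    c(lo, hi)
  }, events_case, events_control, scale)
}

rate_ratio_result <- function(events_case, events_control, scale,
                              expected_fraction, cols = NULL) {
  if (any(events_case + events_control == 0)) {
    stop_domain("no events: the rate ratio is undefined at 0 total events")
  }
  if (any(events_control == 0)) {
    warn("zero control/untransmitted events: infinite ratio with one-sided CI")
  }
  ci <- rate_ratio_ci(events_case, events_control, scale)
  out <- tibble(
    ratio = ifelse(events_control == 0, Inf,
                   (events_case / events_control) * scale),
    ci_low = ci[1, ],
    ci_high = ci[2, ],
    p_value = exact_binom_p(events_case, events_case + events_control,
                            expected_fraction),
    expected_fraction = expected_fraction,
    n_events_total = events_case + events_control
  )
  if (!is.null(cols)) out <- dplyr::bind_cols(as_tibble(cols), out)
  out
}

#' De novo (or case-control) rate ratio with exact test
#'
#' Ratio of per-sample variant rates in cases (probands) versus controls
#' (siblings), tested with a two-sided exact binomial test of the case
#' share of all events against the sample-size expectation
#' `n_case / (n_case + n_control)`. The 95% CI is an exact
#' (Clopper-Pearson) interval on the case fraction mapped through
#' `f -> (f / (1 - f)) * (n_control / n_case)`.
#'
#' @param events_case,events_control Event counts. Vectorized.
#' @param n_case,n_control Sample denominators (positive).
#' @return Tibble with `ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `expected_fraction`, `n_events_total`.
#' @examples
#' dnm_rate_ratio(30, 1000, 10, 1000) # ratio 3
#' @export
dnm_rate_ratio <- function(events_case, n_case, events_control, n_control) {
  check_count(events_case, "events_case")
  check_count(events_control, "events_control")
  if (any(n_case <= 0 | n_control <= 0)) {
    stop_domain("sample denominators must be positive")
  }
  rate_ratio_result(events_case, events_control,
                    scale = n_control / n_case,
                    expected_fraction = n_case / (n_case + n_control))
}

#' Transmission disequilibrium of rare parental alleles
#'
#' Tests whether the fraction of parental rare alleles transmitted to the
#' probands differs from 0.5. The ratio is transmitted over untransmitted;
#' over-transmission gives a ratio above 1.
#'
#' @param transmitted,untransmitted Allele counts (total > 0). Vectorized.
#' @return Tibble as in [dnm_rate_ratio()]; `expected_fraction` is 0.5.
#' @examples
#' transmission_test(60, 40)
#' @export
transmission_test <- function(transmitted, untransmitted) {
  check_count(transmitted, "transmitted")
  check_count(untransmitted, "untransmitted")
  rate_ratio_result(transmitted, untransmitted, scale = 1,
                    expected_fraction = 0.5)
}

#' Female-versus-male event rate contrast (de novo mode)
#'
#' Direct comparison of autistic females and males: the fraction of all
#' events observed in females is tested against the fraction of individuals
#' that are female. A ratio above 1 indicates female excess.
#'
#' @param events_f,events_m Event counts per sex.
#' @param n_f,n_m Individual counts per sex.
#' @return Tibble as in [dnm_rate_ratio()].
#' @examples
#' sex_difference_observed(40, 100, 4404, 17097)
#' @export
sex_difference_observed <- function(events_f, events_m, n_f, n_m) {
  dnm_rate_ratio(events_f, n_f, events_m, n_m)
}

#' Female-versus-male transmission contrast
#'
#' The expected female share of transmitted alleles is the female share of
#' parental alleles; the observed female transmitted count is tested
#' against it. The reported ratio is the odds of the observed female share
#' relative to the expected share.
#'
#' @param transmitted_f Transmitted alleles in autistic females.
#' @param transmitted_total Transmitted alleles in all autistic individuals.
#' @param parental_alleles_f,parental_alleles_total Parental allele counts.
#' @return Tibble as in [dnm_rate_ratio()].
#' @export
sex_difference_transmission <- function(transmitted_f, transmitted_total,
                                        parental_alleles_f,
                                        parental_alleles_total) {
  check_count(transmitted_f, "transmitted_f")
  check_count(transmitted_total, "transmitted_total")
  if (any(parental_alleles_total <= 0) || any(parental_alleles_f < 0)) {
    stop_domain("parental allele totals must be positive")
  }
  if (any(transmitted_f > transmitted_total) ||
      any(parental_alleles_f > parental_alleles_total)) {
    stop_domain("totals must be at least the female components")
  }
  f0 <- parental_alleles_f / parental_alleles_total
  rate_ratio_result(transmitted_f, transmitted_total - transmitted_f,
                    scale = (1 - f0) / f0, expected_fraction = f0)
}

#' Maternal-versus-paternal burden of ultra-rare alleles
#'
#' Rate-ratio comparison of variant burden between mothers and fathers of
#' probands, with mothers in the case position; mechanics identical to
#' [dnm_rate_ratio()] with parent counts as denominators.
#'
#' @param events_mothers,events_fathers Variant counts per parent group.
#' @param n_mothers,n_fathers Parent counts.
#' @return Tibble as in [dnm_rate_ratio()].
#' @export
parent_of_origin_burden <- function(events_mothers, n_mothers,
                                    events_fathers, n_fathers) {
  dnm_rate_ratio(events_mothers, n_mothers, events_fathers, n_fathers)
}

#' Observed versus expected de novo counts under a mutational model
#'
#' Compares an observed de novo count in a gene set to the expectation from
#' per-gene mutation rates: `expected = 2 * n_trios * sum(rates)` for
#' per-haploid-generation rates (factor 1 for rates already on the diploid
#' scale), with a two-sided exact Poisson test.
#'
#' @param per_gene_rates Per-gene, per-generation mutation rates.
#' @param n_trios Number of trios.
#' @param observed Observed de novo count.
#' @param rate_convention `"haploid"` (default; expected = 2 mu n) or
#'   `"diploid"` (expected = mu n).
#' @return Tibble with `observed`, `expected`, `ratio`, `p_value`.
#' @examples
#' mutational_model_test(rep(1e-6, 10), 31565, 1)
#' @export
mutational_model_test <- function(per_gene_rates, n_trios, observed,
                                  rate_convention = c("haploid", "diploid")) {
  rate_convention <- arg_match(rate_convention)
  if (any(per_gene_rates < 0)) stop_domain("mutation rates must be nonnegative")
  if (n_trios <= 0) stop_domain("`n_trios` must be positive")
  check_count(observed, "observed")
  expected <- (if (rate_convention == "haploid") 2 else 1) *
    n_trios * sum(per_gene_rates)
  if (expected == 0) {
    p <- if (observed > 0) {
      warn("expected count is zero with observed > 0; p = 0 flagged")
      0
    } else 1
  } else {
    p <- poisson.test(observed, r = expected)$p.value
  }
  tibble(observed = observed, expected = expected,
         ratio = observed / expected, p_value = p)
}

#' Relative risk from two event/denominator pairs
#'
#' @param events_a,n_a Events and denominator in group a.
#' @param events_b,n_b Events and denominator in group b.
#' @return Numeric relative risk `(events_a/n_a) / (events_b/n_b)`.
#' @examples
#' relative_risk(387, 1413, 1519, 6615) # 1.19
#' @export
relative_risk <- function(events_a, n_a, events_b, n_b) {
  if (any(n_a <= 0 | n_b <= 0)) stop_domain("denominators must be positive")
  (events_a / n_a) / (events_b / n_b)
}

#' Run the mode-appropriate exact burden test on a stratum-count table
#'
#' Data-frame verb for tables of [tabulate_counts()]/[simulate_cohort()]
#' shape: one row per stratum with columns `mode` (`de_novo`,
#' `case_control`, `transmitted_untransmitted` or `parent_of_origin`),
#' `events_case`, `events_control` and, where applicable, `n_case`,
#' `n_control`. De novo, case-control and parent-of-origin rows are tested
#' with [dnm_rate_ratio()]; transmission rows with [transmission_test()].
#' Rows with zero total events get an NA ratio and p = 1.
#'
#' @param counts A stratum-count data frame.
#' @return The input with `ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `expected_fraction`, `n_events_total` columns appended.
#' @export
burden_test <- function(counts) {
  counts <- as_tibble(counts)
  stopifnot(all(c("mode", "events_case", "events_control") %in% names(counts)))
  res <- purrr::pmap(
    list(counts$mode, counts$events_case, counts$events_control,
         counts$n_case %||% rep(NA_real_, nrow(counts)),
         counts$n_control %||% rep(NA_real_, nrow(counts))),
    function(mode, ec, eo, nc, no) {
      if (ec + eo == 0) {
        return(tibble(ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p_value = 1, expected_fraction = NA_real_,
                      n_events_total = 0L))
      }
      if (mode == "transmitted_untransmitted") {
        transmission_test(ec, eo)
      } else {
        dnm_rate_ratio(ec, nc, eo, no)
      }
    }
  )
  dplyr::bind_cols(counts, dplyr::bind_rows(res))
}
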