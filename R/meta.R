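#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' Combines per-cohort estimates with weights `1/se^2`; the combined
#' estimate is the weighted average, the combined se is `1/sqrt(sum(w))`,
#' and the p-value is a two-sided normal test of the combined estimate
#' against zero. Inputs with missing or nonpositive se are dropped.
#'
#' @param data Data frame with one row per cohort.
#' @param estimate,se Columns holding the estimates (liability z or log
#'   rate ratio) and their standard errors (tidy-eval).
#' @return One-row tibble with `estimate`, `se`, `ci_low`, `ci_high`,
#'   `p_value`, `n_studies`.
#' @examples
#' ivw_meta(data.frame(x = c(1, 3), s = c(1, 1)), x, s)
#' @export
ivw_meta <- function(data, estimate, se) {
  x <- dplyr::pull(data, {{ estimate }})
  s <- dplyr::pull(data, {{ se }})
  keep <- is.finite(x) & is.finite(s) & s > 0
  if (!any(keep)) stop_domain("no inputs with a positive standard error")
  x <- x[keep]
  s <- s[keep]
  w <- 1 / s^2
  est <- sum(w * x) / sum(w)
  se_c <- 1 / sqrt(sum(w))
  tibble(
    estimate = est,
    se = se_c,
    ci_low = est - z975() * se_c,
    ci_high = est + z975() * se_c,
    p_value = 2 * pnorm(abs(est) / se_c, lower.tail = FALSE),
    n_studies = sum(keep)
  )
}

#' Meta-analyse rate ratios across cohorts
#'
#' Rate ratios are combined on the log scale with standard errors
#' reconstructed from the CI width, `(log(ci_high) - log(ci_low)) /
#' (2 * 1.96)`, then exponentiated for reporting.
#'
#' @param data Data frame with one row per cohort.
#' @param ratio,ci_low,ci_high Columns holding the ratio and its 95% CI.
#' @return One-row tibble with `ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `n_studies`.
#' @export
meta_rate_ratio <- function(data, ratio, ci_low, ci_high) {
  df <- tibble(
    lr = log(dplyr::pull(data, {{ ratio }})),
    se = (log(dplyr::pull(data, {{ ci_high }})) -
            log(dplyr::pull(data, {{ ci_low }}))) / (2 * z975())
  )
  m <- ivw_meta(df, .data$lr, .data$se)
  tibble(
    ratio = exp(m$estimate),
    ci_low = exp(m$ci_low),
    ci_high = exp(m$ci_high),
    p_value = m$p_value,
    n_studies = m$n_studies
  )
}

#' Bonferroni correction
#'
#' @param p p-value(s).
#' @param m Family size, at least 1.
#' @return `min(1, p * m)`, vectorized.
#' @examples
#' bonferroni(0.001, 54)
#' @export
bonferroni <- function(p, m) {
  if (any(m < 1)) stop_domain("`m` must be at least 1")
  pmin(1, p * m)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values via [stats::p.adjust()].
#'
#' @param ps Vector of p-values in (0,1].
#' @return Adjusted p-values, each no larger than its Bonferroni
#'   counterpart for the same family size.
#' @export
bh_fdr <- function(ps) {
  if (length(ps) == 0) return(numeric(0))
  if (any(ps <= 0 | ps > 1)) stop_domain("p-values must be in (0, 1]")
  p.adjust(ps, method = "BH")
}

#' Significance tier from raw, FDR and Bonferroni p-values
#'
#' `"***"` when the Bonferroni-corrected p is below 0.05, `"**"` when only
#' the FDR-adjusted p is, `"*"` when only the raw p is, `""` otherwise.
#' The inputs must satisfy `p_raw <= p_fdr <= p_bonf`.
#'
#' @param p_raw,p_fdr,p_bonf p-values (vectorized).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p_raw, p_fdr, p_bonf, alpha = 0.05) {
  eps <- 1e-12
  if (any(p_raw > p_fdr + eps | p_fdr > p_bonf + eps, na.rm = TRUE)) {
    stop_domain("expected p_raw <= p_fdr <= p_bonf")
  }
  dplyr::case_when(
    p_bonf < alpha ~ "***",
    p_fdr < alpha ~ "**",
    p_raw < alpha ~ "*",
    TRUE ~ ""
  )
}

#' Append multiplicity-adjusted p-values and tiers to a results table
#'
#' Adjusts the raw p-values within families: FDR is applied within each
#' family, Bonferroni uses `m` (defaulting to the family size). The
#' exome-wide family of the canonical analysis has 54 tests (3 sex
#' comparisons x 3 cohorts x 3 variant classes x 2 inheritance modes); the
#' two-phenotype-stratum family doubles it to 108.
#'
#' @param results Data frame with a raw p-value column.
#' @param p Column with raw p-values (tidy-eval; default `p_value`).
#' @param family Optional grouping column defining adjustment families.
#' @param m Bonferroni family size; defaults to the number of rows in each
#'   family.
#' @return `results` with `p_fdr`, `p_bonferroni`, `tier` appended.
#' @export
adjust_results <- function(results, p = p_value, family = NULL, m = NULL) {
  results <- as_tibble(results)
  fam <- if (quo_is_null(enquo(family))) {
    rep(1L, nrow(results))
  } else {
    dplyr::pull(results, {{ family }})
  }
  praw <- dplyr::pull(results, {{ p }})
  out <- results
  out$p_fdr <- NA_real_
  out$p_bonferroni <- NA_real_
  for (f in unique(fam)) {
    i <- which(fam == f)
    out$p_fdr[i] <- bh_fdr(praw[i])
    out$p_bonferroni[i] <- bonferroni(praw[i], m %||% length(i))
  }
  # Bonferroni with an explicit m larger than the family can fall below the
  # within-family FDR value; keep the tier ordering consistent.
  out$tier <- significance_tier(praw, pmin(out$p_fdr, out$p_bonferroni),
                                out$p_bonferroni)
  out
}
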