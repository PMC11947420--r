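#' Assign genes to covariate-matching strata
#'
#' Genes are matched on loss-of-function constraint (exact LOEUF decile),
#' sex-averaged brain expression, and coding-sequence length; the latter
#' two are binned into pool-wide quantile bins (quintiles by default).
#' Bins are computed on the full pool so target and candidate genes share
#' the same stratification.
#'
#' @param genes Gene table with `gene_id`, `loeuf_decile`,
#'   `brain_expression`, `cds_length`.
#' @param n_expression_bins,n_length_bins Number of quantile bins.
#' @return `genes` with `expression_bin`, `length_bin` and `stratum`
#'   columns appended.
#' @export
stratify_pool <- function(genes, n_expression_bins = 5, n_length_bins = 5) {
  g <- as_tibble(genes)
  if (nrow(g) == 0) stop_domain("empty gene pool")
  qbin <- function(x, k) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = k + 1),
                          na.rm = TRUE))
    if (length(br) < 2) return(rep(1L, length(x)))
    as.integer(cut(x, breaks = br, include.lowest = TRUE))
  }
  g %>%
    mutate(
      expression_bin = qbin(.data$brain_expression, n_expression_bins),
      length_bin = qbin(.data$cds_length, n_length_bins),
      stratum = paste(.data$loeuf_decile, .data$expression_bin,
                      .data$length_bin, sep = ":")
    )
}

# per-target-gene pool indices honouring the fallback chain:
# exact stratum -> same decile x expression bin -> same decile -> whole pool
match_candidates <- function(target, pool) {
  fallbacks <- 0L
  idx <- lapply(seq_len(nrow(target)), function(i) {
    j <- which(pool$stratum == target$stratum[i])
    if (!length(j)) {
      j <- which(pool$loeuf_decile == target$loeuf_decile[i] &
                   pool$expression_bin == target$expression_bin[i])
    }
    if (!length(j)) j <- which(pool$loeuf_decile == target$loeuf_decile[i])
    if (!length(j)) j <- seq_len(nrow(pool))
    if (!length(j)) stop_domain("empty matching pool")
    attr(j, "fallback") <- !any(pool$stratum == target$stratum[i])
    j
  })
  nf <- sum(vapply(idx, function(j) isTRUE(attr(j, "fallback")), logical(1)))
  if (nf > 0) {
    inform(sprintf("%d target gene(s) matched through a fallback stratum", nf))
  }
  idx
}

#' Draw one covariate-matched random gene set
#'
#' For each gene in the target set, one gene is drawn uniformly (with
#' replacement) from the candidate pool genes in the same stratum; a drawn
#' set may therefore repeat genes but reproduces the target's per-stratum
#' composition exactly. When a target stratum has no pool gene, the match
#' falls back to progressively coarser strata (same decile and expression
#' bin, then same decile), which is reported.
#'
#' @param genes Full gene table (target and pool together).
#' @param target_ids Gene ids of the target set.
#' @param seed Optional integer seed for reproducible draws.
#' @inheritParams stratify_pool
#' @return Tibble of drawn pool genes, one row per target gene.
#' @export
draw_matched_set <- function(genes, target_ids, seed = NULL,
                             n_expression_bins = 5, n_length_bins = 5) {
  if (!is.null(seed)) set.seed(seed)
  g <- stratify_pool(genes, n_expression_bins, n_length_bins)
  target <- filter(g, .data$gene_id %in% target_ids)
  pool <- filter(g, !.data$gene_id %in% target_ids)
  if (nrow(target) == 0) stop_domain("no target genes found in the gene table")
  cand <- match_candidates(target, pool)
  drawn <- vapply(cand, function(j) j[sample.int(length(j), 1)], integer(1))
  pool[drawn, ]
}

#' Permutation-averaged expected rate ratio for a gene set
#'
#' Builds the matched-gene-set null for a target set: `n_permutations`
#' matched random sets are drawn (with replacement) and the
#' mode-appropriate rate ratio is computed on each draw's summed per-gene
#' counts -- proband/sibling rate ratio in `de_novo` mode,
#' transmitted/untransmitted ratio in `transmission` mode. The average
#' ratio over permutations is the expected ratio for the target set, and
#' the permutation-mean per-sample case rate feeds excess-liability
#' estimation. Draws with a zero denominator are excluded from the
#' average; when more than 1% of draws are undefined the estimator falls
#' back to the ratio of summed numerators and denominators over all draws
#' (reported).
#'
#' @param genes Full gene table.
#' @param target_ids Target gene ids.
#' @param counts_by_gene Per-gene counts: `gene_id`, `events_case`,
#'   `events_control` (probands/siblings in de novo mode,
#'   transmitted/untransmitted in transmission mode).
#' @param mode `"de_novo"` or `"transmission"`.
#' @param n_case,n_control Sample denominators (de novo mode only).
#' @param n_permutations Number of matched draws (default 10,000).
#' @param seed Integer seed, recorded in the result.
#' @inheritParams stratify_pool
#' @return An object of class `matched_null_summary`: expected ratio,
#'   permutation-mean rates, empirical quantiles, permutation count, seed.
#' @export
expected_ratio <- function(genes, target_ids, counts_by_gene,
                           mode = c("de_novo", "transmission"),
                           n_case = NULL, n_control = NULL,
                           n_permutations = 10000, seed = 1,
                           n_expression_bins = 5, n_length_bins = 5) {
  mode <- arg_match(mode)
  if (mode == "de_novo" && (is.null(n_case) || is.null(n_control))) {
    stop_domain("de_novo mode needs `n_case` and `n_control`")
  }
  set.seed(seed)
  g <- stratify_pool(genes, n_expression_bins, n_length_bins)
  target <- filter(g, .data$gene_id %in% target_ids)
  pool <- filter(g, !.data$gene_id %in% target_ids)
  cnt <- as_tibble(counts_by_gene)
  pool_case <- cnt$events_case[match(pool$gene_id, cnt$gene_id)]
  pool_ctrl <- cnt$events_control[match(pool$gene_id, cnt$gene_id)]
  pool_case[is.na(pool_case)] <- 0
  pool_ctrl[is.na(pool_ctrl)] <- 0

  cand <- match_candidates(target, pool)
  k <- length(cand)
  draw_idx <- matrix(0L, nrow = n_permutations, ncol = k)
  for (i in seq_len(k)) {
    j <- cand[[i]]
    draw_idx[, i] <- j[sample.int(length(j), n_permutations, replace = TRUE)]
  }
  case_sums <- rowSums(matrix(pool_case[draw_idx], nrow = n_permutations))
  ctrl_sums <- rowSums(matrix(pool_ctrl[draw_idx], nrow = n_permutations))

  scale <- if (mode == "de_novo") n_control / n_case else 1
  ratios <- (case_sums / ctrl_sums) * scale
  defined <- is.finite(ratios)
  if (!any(defined) && sum(ctrl_sums) == 0) {
    stop_domain("all permutation draws have zero denominators")
  }
  frac_undef <- mean(!defined)
  if (frac_undef > 0.01) {
    inform(sprintf(
      "%.1f%% of draws undefined; using ratio-of-sums fallback estimator",
      100 * frac_undef))
    exp_ratio <- (sum(case_sums) / sum(ctrl_sums)) * scale
  } else {
    exp_ratio <- mean(ratios[defined])
  }
  denom_case <- if (mode == "de_novo") n_case else 1
  denom_ctrl <- if (mode == "de_novo") n_control else 1
  structure(
    list(
      expected_ratio = exp_ratio,
      n_permutations = n_permutations,
      permutation_mean_case_rate = mean(case_sums) / denom_case,
      permutation_mean_control_rate = mean(ctrl_sums) / denom_ctrl,
      quantiles = quantile(ratios[defined],
                           c(0.025, 0.25, 0.5, 0.75, 0.975)),
      fraction_undefined = frac_undef,
      mode = mode,
      n_case = n_case,
      n_control = n_control,
      seed = seed
    ),
    class = "matched_null_summary"
  )
}

#' @export
print.matched_null_summary <- function(x, ...) {
  cat("<matched_null_summary>\n")
  cat(sprintf("  mode: %s; permutations: %d (seed %s)\n",
              x$mode, x$n_permutations, format(x$seed)))
  cat(sprintf("  expected ratio: %.4f (%.1f%% draws undefined)\n",
              x$expected_ratio, 100 * x$fraction_undefined))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.matched_null_summary <- function(x, ...) {
  tibble(
    mode = x$mode,
    expected_ratio = x$expected_ratio,
    permutation_mean_case_rate = x$permutation_mean_case_rate,
    permutation_mean_control_rate = x$permutation_mean_control_rate,
    n_permutations = x$n_permutations,
    fraction_undefined = x$fraction_undefined,
    seed = x$seed
  )
}

#' Exact test of a gene set's burden against its matched-null expectation
#'
#' Repeats the exome-wide exact binomial test with the null fraction
#' recentred so that the null rate ratio equals the permutation-averaged
#' expected ratio R: in de novo mode the expected case fraction becomes
#' `R n_case / (R n_case + n_control)`, in transmission mode `R / (1 +
#' R)`. With R = 1 this reduces exactly to the exome-wide test.
#'
#' @param events_case,events_control Observed counts on the target set.
#' @param null A `matched_null_summary` from [expected_ratio()].
#' @param n_case,n_control Sample denominators (default those recorded in
#'   `null`).
#' @return Tibble as in [dnm_rate_ratio()].
#' @export
test_vs_expected <- function(events_case, events_control, null,
                             n_case = NULL, n_control = NULL) {
  stopifnot(inherits(null, "matched_null_summary"))
  R <- null$expected_ratio
  if (!is.finite(R)) stop_domain("expected ratio is not finite")
  if (null$mode == "de_novo") {
    n_case <- n_case %||% null$n_case
    n_control <- n_control %||% null$n_control
    f0 <- R * n_case / (R * n_case + n_control)
    scale <- n_control / n_case
  } else {
    f0 <- R / (1 + R)
    scale <- 1
  }
  rate_ratio_result(events_case, events_control, scale = scale,
                    expected_fraction = f0)
}

#' Liability of a gene set in excess of matched genes
#'
#' Estimates the liability attributable to a gene set beyond what is
#' expected for genes of similar constraint, brain expression and length:
#' the control rate in the liability conversion is replaced by the
#' permutation-mean case rate of matched random sets, so a set whose
#' observed rate equals its matched expectation gets zero excess
#' liability.
#'
#' @param rate_observed Observed per-sample case rate on the target set
#'   (de novo mode) or transmitted/untransmitted-style rate (transmission
#'   mode).
#' @param null A `matched_null_summary`.
#' @param prevalence Trait prevalence for the group under study.
#' @param p_value Optional exact-test p-value (e.g. from
#'   [test_vs_expected()]) to complete the estimate with se and CI.
#' @param label Optional stratum label.
#' @inheritParams liability_effect
#' @return Tibble: `z` alone, or a full liability estimate when `p_value`
#'   is given.
#' @export
excess_liability <- function(rate_observed, null, prevalence,
                             p_value = NULL, label = NA_character_,
                             method = c("threshold_shift",
                                        "truncated_mixture")) {
  stopifnot(inherits(null, "matched_null_summary"))
  ref <- null$permutation_mean_case_rate
  if (!is.finite(ref) || ref <= 0) {
    stop_domain("permutation mean rate must be positive")
  }
  z <- liability_effect(rate_observed, ref, prevalence, method = method,
                        warn_rare = FALSE)
  if (is.null(p_value)) {
    tibble(z = z, prevalence_used = prevalence, label = label)
  } else {
    se_and_ci(z, p_value, prevalence_used = prevalence, label = label)
  }
}
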