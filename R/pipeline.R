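#' Configuration of the end-to-end analysis recipe
#'
#' Collects every tunable of the canonical analysis in one place:
#' population prevalences, classification thresholds, the phenotype
#' stratification scheme, the multiplicity family size, and the
#' permutation settings for gene-set nulls.
#'
#' @param prevalence A [prevalence_spec()].
#' @param classification A [classification_config()].
#' @param scheme Phenotype stratification scheme
#'   (see [phenotype_stratify()]) or `NULL` to analyse all probands as one
#'   group.
#' @param m_family Bonferroni family size (54 for the exome-wide family:
#'   3 sex comparisons x 3 cohorts x 3 variant classes x 2 inheritance
#'   modes; 108 for the two-phenotype-stratum family).
#' @param n_permutations,seed Matched gene-set permutation settings.
#' @param liability_method Estimator passed to [liability_effect()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(prevalence = prevalence_spec(),
                            classification = classification_config(),
                            scheme = "spark_motor_cognitive",
                            m_family = 54,
                            n_permutations = 10000,
                            seed = 1,
                            liability_method = "threshold_shift") {
  structure(list(prevalence = prevalence, classification = classification,
                 scheme = scheme, m_family = m_family,
                 n_permutations = n_permutations, seed = seed,
                 liability_method = liability_method),
            class = "pipeline_config")
}

# prevalence to use for a (sex, phenotype_group) stratum: subgroup scaling
# by the observed classified proportions, NA for unclassified strata
stratum_prevalences <- function(persons, spec) {
  probands <- persons %>% filter(.data$role == "proband")
  base <- c(female = spec$female_prevalence, male = spec$male_prevalence)
  groups <- unique(probands$phenotype_group)
  purrr::map_dfr(c("female", "male"), function(s) {
    purrr::map_dfr(groups, function(g) {
      K <- base[[s]]
      if (g %in% c("impaired", "not_impaired")) {
        cls <- probands %>%
          filter(.data$sex == s,
                 .data$phenotype_group %in% c("impaired", "not_impaired"))
        prop <- mean(cls$phenotype_group == "impaired")
        sub <- subgroup_prevalence(K, prop)
        K <- if (g == "impaired") sub$featured else sub$complement
      } else if (g == "unclassified") {
        K <- NA_real_
      }
      tibble(sex = s, phenotype_group = g, prevalence_used = K)
    })
  })
}

#' Run the canonical analysis recipe on raw tables
#'
#' Sequences the full pipeline: genotype/rarity filtering and variant
#' classification, phenotype stratification, stratum counting, exact
#' burden/transmission tests, liability conversion with
#' phenotype-scaled sex-specific prevalences, per-stratum female-male
#' liability contrasts, cross-cohort inverse-variance meta-analysis (when
#' several cohorts are present), and tiered multiplicity adjustment. A
#' rerun with the same inputs and configuration is deterministic.
#'
#' @param variants Variant table (one row per variant call; see
#'   [classify_variants()] for required columns).
#' @param persons Person table.
#' @param genes Gene metadata table.
#' @param config A [pipeline_config()].
#' @param cohort Cohort label when `variants` holds a single cohort; to
#'   analyse several cohorts, bind their count tables and pass them to the
#'   lower-level verbs directly.
#' @return An object of class `varliab_pipeline` with elements `results`
#'   (one row per stratum x test, with ratio, CI, raw/FDR/Bonferroni p,
#'   tier, and liability z/se/CI), `sex_differences`, `counts`, and a
#'   reproducibility `manifest`.
#' @export
run_pipeline <- function(variants, persons, genes,
                         config = pipeline_config(), cohort = "cohort") {
  persons <- as_tibble(persons)
  if (!is.null(config$scheme)) {
    persons <- phenotype_stratify(persons, config$scheme)
  }
  classified <- classify_variants(variants, genes, config$classification)
  pass_geno <- genotype_pass(classified)
  pass_rare <- rarity_pass(classified, config$classification$rarity_mode)
  counts <- tabulate_counts(classified, persons, config$classification,
                            cohort = cohort)
  prevs <- stratum_prevalences(persons, config$prevalence)

  results <- burden_test(counts) %>%
    left_join(prevs, by = c("sex", "phenotype_group")) %>%
    mutate(
      rate_cases = if_else(.data$mode == "transmitted_untransmitted",
                           .data$events_case /
                             pmax(1, .data$events_case + .data$events_control),
                           .data$events_case / .data$n_case),
      rate_controls = if_else(.data$mode == "transmitted_untransmitted",
                              .data$events_control /
                                pmax(1, .data$events_case + .data$events_control),
                              .data$events_control / .data$n_control),
      z = if_else(
        is.na(.data$prevalence_used) | .data$rate_controls <= 0 |
          .data$rate_cases <= 0,
        NA_real_,
        liability_effect(pmax(.data$rate_cases, 1e-12),
                         pmax(.data$rate_controls, 1e-12),
                         if_else(is.na(.data$prevalence_used), 0.5,
                                 .data$prevalence_used),
                         method = config$liability_method,
                         warn_rare = FALSE))
    )
  q <- qnorm(results$p_value / 2, lower.tail = FALSE)
  results$z_se <- if_else(is.na(results$z) | results$z == 0 | q <= 0,
                          NA_real_, abs(results$z) / q)
  results$z_ci_low <- results$z - z975() * results$z_se
  results$z_ci_high <- results$z + z975() * results$z_se
  results <- adjust_results(results, p = .data$p_value,
                            m = config$m_family)

  sex_diff <- results %>%
    filter(!is.na(.data$z), !is.na(.data$z_se)) %>%
    select("cohort", "phenotype_group", "variant_class", "mode", "sex",
           "z", "z_se") %>%
    tidyr::pivot_wider(names_from = "sex", values_from = c("z", "z_se")) %>%
    filter(!is.na(.data$z_female), !is.na(.data$z_male))
  sex_diff <- dplyr::bind_cols(
    select(sex_diff, "cohort", "phenotype_group", "variant_class", "mode"),
    sex_difference_liability(sex_diff$z_female, sex_diff$z_se_female,
                             sex_diff$z_male, sex_diff$z_se_male)
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("varliab")),
    config_hash = rlang::hash(config),
    seed = config$seed,
    cohort = cohort,
    attrition = tibble(
      filter = c("input_variants", "genotype_pass", "rarity_pass",
                 "both_filters"),
      n = c(length(pass_geno), sum(pass_geno), sum(pass_rare),
            sum(pass_geno & pass_rare))
    )
  )
  structure(list(results = results, sex_differences = sex_diff,
                 counts = counts, manifest = manifest),
            class = "varliab_pipeline")
}

#' @export
print.varliab_pipeline <- function(x, ...) {
  cat("<varliab_pipeline>\n")
  cat(sprintf("  %d result rows (%s), %d sex-difference contrasts\n",
              nrow(x$results), x$manifest$cohort, nrow(x$sex_differences)))
  sig <- sum(x$results$tier != "", na.rm = TRUE)
  cat(sprintf("  %d stratum-test(s) significant before correction\n", sig))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.varliab_pipeline <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.varliab_pipeline <- function(x, ...) {
  tibble(
    n_tests = nrow(x$results),
    n_significant_raw = sum(x$results$p_value < 0.05, na.rm = TRUE),
    n_significant_bonferroni = sum(x$results$tier == "***", na.rm = TRUE),
    config_hash = x$manifest$config_hash
  )
}

#' Write pipeline outputs as tab-delimited files
#'
#' Writes `results.tsv`, `sex_differences.tsv`, `counts.tsv` and a
#' `manifest.tsv` (attrition log plus run metadata) into a directory.
#' Outputs are plain text; a rerun with the same inputs writes identical
#' bytes.
#'
#' @param x A `varliab_pipeline`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "varliab_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(x$results, "results.tsv")
  tsv(x$sex_differences, "sex_differences.tsv")
  tsv(x$counts, "counts.tsv")
  meta <- x$manifest$attrition
  meta <- bind_rows(meta, tibble(
    filter = c("package_version", "config_hash", "seed", "cohort"),
    n = NA_integer_
  ))
  meta$value <- c(rep(NA_character_, nrow(x$manifest$attrition)),
                  x$manifest$package_version, x$manifest$config_hash,
                  as.character(x$manifest$seed), x$manifest$cohort)
  tsv(meta, "manifest.tsv")
  invisible(dir)
}
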