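#' Variant classification configuration
#'
#' Thresholds for damaging-variant classification and rarity filtering.
#' The strict (default) configuration calls a PTV damaging when its gene
#' lies in the most LoF-intolerant LOEUF decile and a missense variant
#' damaging at MPC >= 2; relaxed sensitivity configurations widen these to
#' deciles 2-3 and MPC >= 1.
#'
#' @param ptv_decile_max Highest LOEUF decile still counted as damaging for
#'   PTVs (1 strict; 2 or 3 relaxed).
#' @param mpc_threshold Minimum MPC for damaging missense (2 strict, 1
#'   relaxed).
#' @param rarity_mode One of `"rare_0.1pct"` (cohort and gnomAD MAF <
#'   0.1%), `"ultra_rare_duo"` (single family, absent from gnomAD),
#'   `"ultra_rare_casecontrol"` (AF < 0.005%).
#' @return An object of class `classification_config`.
#' @export
classification_config <- function(ptv_decile_max = 1, mpc_threshold = 2,
                                  rarity_mode = c("rare_0.1pct",
                                                  "ultra_rare_duo",
                                                  "ultra_rare_casecontrol")) {
  rarity_mode <- arg_match(rarity_mode)
  if (!ptv_decile_max %in% 1:10) stop_domain("`ptv_decile_max` must be 1..10")
  if (mpc_threshold <= 0) stop_domain("`mpc_threshold` must be positive")
  structure(list(ptv_decile_max = ptv_decile_max,
                 mpc_threshold = mpc_threshold,
                 rarity_mode = rarity_mode),
            class = "classification_config")
}

#' Genotype-level quality filter
#'
#' A genotype passes when read depth, genotype quality and variant allele
#' fraction all meet the inclusive thresholds DP >= 10, GQ >= 10 and
#' VAF >= 0.25 (the exclusions are phrased strictly, so the boundaries
#' pass). Missing metrics fail closed with a warning.
#'
#' @param variants Data frame with columns `dp`, `gq`, `vaf`.
#' @return Logical vector, one element per row.
#' @export
genotype_pass <- function(variants) {
  v <- as_tibble(variants)
  miss <- is.na(v$dp) | is.na(v$gq) | is.na(v$vaf)
  if (any(miss)) {
    warn(sprintf("%d genotype(s) with missing DP/GQ/VAF fail closed",
                 sum(miss)))
  }
  !miss & v$dp >= 10 & v$gq >= 10 & v$vaf >= 0.25
}

#' Rarity filter
#'
#' Three tiers: `rare_0.1pct` requires cohort AF < 0.1% and gnomAD AF
#' missing or < 0.1%; `ultra_rare_duo` requires the allele in exactly one
#' family and absent from gnomAD; `ultra_rare_casecontrol` requires cohort
#' AF < 0.005% (strict).
#'
#' @param variants Data frame with `af_cohort`, `af_gnomad`,
#'   `n_families_with_allele` columns.
#' @param mode Rarity tier (see [classification_config()]).
#' @return Logical vector.
#' @export
rarity_pass <- function(variants, mode = c("rare_0.1pct", "ultra_rare_duo",
                                           "ultra_rare_casecontrol")) {
  mode <- arg_match(mode)
  v <- as_tibble(variants)
  switch(mode,
    rare_0.1pct = v$af_cohort < 0.001 &
      (is.na(v$af_gnomad) | v$af_gnomad < 0.001),
    ultra_rare_duo = v$n_families_with_allele == 1 &
      (is.na(v$af_gnomad) | v$af_gnomad == 0),
    ultra_rare_casecontrol = v$af_cohort < 0.00005
  )
}

#' Classify variants into damaging/synonymous/other classes
#'
#' Joins gene constraint onto the variant table and applies the
#' classification rules: a PTV is `damaging_PTV` when its gene's LOEUF
#' decile is at most `ptv_decile_max`; a missense variant is
#' `damaging_missense` when its MPC is at least `mpc_threshold` (in any
#' gene); synonymous variants pass through; everything else (including
#' variants in genes absent from the gene table, which are warned about)
#' is `other`.
#'
#' @param variants Variant data frame with `gene_id`, `consequence`
#'   (`PTV`/`missense`/`synonymous`/`other`) and `mpc` columns.
#' @param genes Gene metadata with `gene_id` and `loeuf_decile`.
#' @param config A [classification_config()].
#' @return `variants` with a `variant_class` column appended.
#' @export
classify_variants <- function(variants, genes,
                              config = classification_config()) {
  v <- as_tibble(variants) %>%
    left_join(select(as_tibble(genes), "gene_id", "loeuf_decile"),
              by = "gene_id")
  unknown <- is.na(v$loeuf_decile)
  if (any(unknown & v$consequence == "PTV")) {
    warn(sprintf("%d PTV(s) in genes absent from the gene table -> 'other'",
                 sum(unknown & v$consequence == "PTV")))
  }
  v %>%
    mutate(variant_class = case_when(
      .data$consequence == "PTV" & !is.na(.data$loeuf_decile) &
        .data$loeuf_decile <= config$ptv_decile_max ~ "damaging_PTV",
      .data$consequence == "missense" & !is.na(.data$mpc) &
        .data$mpc >= config$mpc_threshold ~ "damaging_missense",
      .data$consequence == "synonymous" ~ "synonymous",
      TRUE ~ "other"
    )) %>%
    select(-"loeuf_decile")
}

#' Greedy maximal-unrelated sample selection
#'
#' Prunes a relatedness graph by repeatedly removing the individual with
#' the most remaining relatives until no related pair is left. Ties on
#' degree are broken by removing a male before a female (preferentially
#' retaining females), then by lexicographic id. The retained set induces
#' an edgeless graph, and rerunning on it is the identity.
#'
#' @param relatedness_pairs Two-column data frame (or matrix) of related id
#'   pairs.
#' @param persons Person table with `person_id` and `sex` columns.
#' @return Character vector of retained person ids.
#' @export
max_unrelated <- function(relatedness_pairs, persons) {
  persons <- as_tibble(persons)
  ids <- persons$person_id
  sex <- setNames(persons$sex, ids)
  pairs <- as.data.frame(relatedness_pairs)
  if (nrow(pairs) == 0) return(ids)
  a <- as.character(pairs[[1]])
  b <- as.character(pairs[[2]])
  if (!all(c(a, b) %in% ids)) {
    stop_domain("relatedness pairs reference unknown person ids")
  }
  alive <- rep(TRUE, length(a))
  removed <- character(0)
  repeat {
    if (!any(alive)) break
    deg <- table(c(a[alive], b[alive]))
    top <- names(deg)[deg == max(deg)]
    # remove a male first, then the lexicographically smallest id
    males <- top[sex[top] == "male"]
    pick <- if (length(males)) sort(males)[1] else sort(top)[1]
    removed <- c(removed, pick)
    alive <- alive & a != pick & b != pick
  }
  setdiff(ids, removed)
}

#' Assign phenotype strata to probands
#'
#' Two schemes mirror the cohorts' phenotype availability. The
#' `asc_cognitive` scheme distinguishes probands with cognitive impairment
#' (IQ below the cutoff or an explicit impairment flag) from everyone else
#' (no impairment or unknown status, which the ASC data cannot separate).
#' The `spark_motor_cognitive` scheme forms three groups: `impaired` (IQ
#' below the cutoff, cognitive impairment, or motor delay), `not_impaired`
#' (explicit "no" on the reported conditions and no qualifying IQ), and
#' `unclassified` (missing information). Non-probands get `NA`.
#'
#' @param persons Person table (`person_id`, `role`, `iq`,
#'   `cognitive_impairment`, `motor_delay`).
#' @param scheme Stratification scheme.
#' @param iq_cutoff IQ threshold; defaults to 80 for the SPARK-style
#'   scheme and 70 for the ASC-style scheme.
#' @return `persons` with a `phenotype_group` column appended.
#' @export
phenotype_stratify <- function(persons,
                               scheme = c("spark_motor_cognitive",
                                          "asc_cognitive"),
                               iq_cutoff = NULL) {
  scheme <- arg_match(scheme)
  iq_cutoff <- iq_cutoff %||% if (scheme == "spark_motor_cognitive") 80 else 70
  p <- as_tibble(persons)
  low_iq <- !is.na(p$iq) & p$iq < iq_cutoff
  cog <- p$cognitive_impairment
  if (scheme == "asc_cognitive") {
    grp <- if_else(low_iq | (!is.na(cog) & cog == "yes"),
                   "impaired", "not_impaired_or_unknown")
  } else {
    motor <- p$motor_delay
    impaired <- low_iq |
      (!is.na(cog) & cog == "yes") | (!is.na(motor) & motor == "yes")
    not_impaired <- !impaired &
      !is.na(cog) & cog == "no" & !is.na(motor) & motor == "no"
    grp <- case_when(impaired ~ "impaired",
                     not_impaired ~ "not_impaired",
                     TRUE ~ "unclassified")
  }
  p$phenotype_group <- if_else(p$role == "proband", grp, NA_character_)
  p
}

#' Collapse phenotype groups in a stratum-count table
#'
#' Aggregates burden counts over phenotype groups within sex, class and
#' mode. Proband-side quantities are summed; in de novo mode the
#' sibling-side counts are shared across the phenotype groups of a sex
#' (every group is compared with the same siblings) and are therefore
#' taken once, not summed.
#'
#' @param counts A burden-count table with a `phenotype_group` column.
#' @return The collapsed table with `phenotype_group = "all"`.
#' @export
collapse_phenotype_groups <- function(counts) {
  as_tibble(counts) %>%
    group_by(.data$cohort, .data$sex, .data$variant_class, .data$mode) %>%
    summarise(
      events_case = sum(.data$events_case),
      events_control = if (.data$mode[1] == "de_novo") {
        .data$events_control[1]
      } else {
        sum(.data$events_control)
      },
      n_case = sum(.data$n_case),
      n_control = .data$n_control[1],
      .groups = "drop"
    ) %>%
    mutate(phenotype_group = "all") %>%
    select("cohort", "sex", "phenotype_group", "variant_class", "mode",
           "events_case", "events_control", "n_case", "n_control")
}

variant_class_levels <- function() {
  c("damaging_PTV", "damaging_missense", "synonymous", "other")
}

#' Aggregate classified variants into stratum-level burden counts
#'
#' Turns per-variant records (already classified; see
#' [classify_variants()]) and per-person records into the stratum-count
#' table consumed by [burden_test()]. Genotype and rarity filters are
#' applied first. De novo events are counted per child and attributed to
#' probands (`events_case`) or siblings (`events_control`) within each
#' proband sex and phenotype group (the sibling counts of a sex serve as
#' the control for every phenotype group of that sex, as siblings carry no
#' phenotype stratum). Transmission events count transmitted alleles in
#' probands against their untransmitted complements. Strata are completed
#' with zero rows over sex x phenotype group x variant class.
#'
#' @param variants Classified variant table (with `variant_class`).
#' @param persons Person table; a `phenotype_group` column (from
#'   [phenotype_stratify()]) is used when present, otherwise all probands
#'   form one `"all"` group.
#' @param config A [classification_config()] (supplies the rarity mode).
#' @param cohort Cohort label for the output rows.
#' @return A burden-count tibble with columns `cohort`, `sex`,
#'   `phenotype_group`, `variant_class`, `mode`, `events_case`,
#'   `events_control`, `n_case`, `n_control`.
#' @export
tabulate_counts <- function(variants, persons,
                            config = classification_config(),
                            cohort = "cohort") {
  v <- as_tibble(variants)
  p <- as_tibble(persons)
  if (!"variant_class" %in% names(v)) {
    stop_domain("variants must carry `variant_class`; run classify_variants()")
  }
  if (!"phenotype_group" %in% names(p)) {
    p$phenotype_group <- if_else(p$role == "proband", "all", NA_character_)
  }
  v <- v[genotype_pass(v) & rarity_pass(v, config$rarity_mode), ]
  orphan <- !v$child_id %in% p$person_id
  if (any(orphan)) {
    warn(sprintf("%d variant row(s) reference unknown persons; dropped",
                 sum(orphan)))
    v <- v[!orphan, ]
  }
  v <- left_join(v,
                 select(p, child_id = "person_id", "sex", "role",
                        "phenotype_group"),
                 by = "child_id")

  groups <- sort(unique(p$phenotype_group[p$role == "proband"]))
  frame <- tidyr::expand_grid(
    sex = c("female", "male"),
    phenotype_group = groups,
    variant_class = variant_class_levels()
  )
  n_by <- function(role) {
    p %>%
      filter(.data$role == !!role) %>%
      count(.data$sex, name = "n")
  }
  n_prob <- p %>%
    filter(.data$role == "proband") %>%
    count(.data$sex, .data$phenotype_group, name = "n_case")
  n_sib <- n_by("sibling") %>% rename(n_control = "n")

  # --- de novo mode ---
  dn <- v %>% filter(.data$inheritance == "de_novo")
  case_dn <- dn %>%
    filter(.data$role == "proband") %>%
    count(.data$sex, .data$phenotype_group, .data$variant_class,
          name = "events_case")
  ctrl_dn <- dn %>%
    filter(.data$role == "sibling") %>%
    count(.data$sex, .data$variant_class, name = "events_control")
  de_novo <- frame %>%
    left_join(case_dn, by = c("sex", "phenotype_group", "variant_class")) %>%
    left_join(ctrl_dn, by = c("sex", "variant_class")) %>%
    left_join(n_prob, by = c("sex", "phenotype_group")) %>%
    left_join(n_sib, by = "sex") %>%
    mutate(mode = "de_novo",
           across(c("events_case", "events_control", "n_case", "n_control"),
                  ~ tidyr::replace_na(.x, 0L)))

  # --- transmission mode (proband alleles only) ---
  tr <- v %>%
    filter(.data$role == "proband",
           grepl("^(transmitted|untransmitted)_", .data$inheritance)) %>%
    mutate(side = if_else(grepl("^transmitted_", .data$inheritance),
                          "events_case", "events_control"))
  trans <- frame %>%
    left_join(
      tr %>%
        count(.data$sex, .data$phenotype_group, .data$variant_class,
              .data$side) %>%
        tidyr::pivot_wider(names_from = "side", values_from = "n",
                           values_fill = 0L),
      by = c("sex", "phenotype_group", "variant_class")
    ) %>%
    mutate(mode = "transmitted_untransmitted",
           across(any_of(c("events_case", "events_control")),
                  ~ tidyr::replace_na(.x, 0L)),
           n_case = NA_integer_, n_control = NA_integer_)
  for (col in c("events_case", "events_control")) {
    if (!col %in% names(trans)) trans[[col]] <- 0L
  }

  bind_rows(de_novo, trans) %>%
    mutate(cohort = cohort) %>%
    select("cohort", "sex", "phenotype_group", "variant_class", "mode",
           "events_case", "events_control", "n_case", "n_control") %>%
    arrange(.data$mode, .data$sex, .data$phenotype_group,
            .data$variant_class)
}
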