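#' Configuration of the trio-cohort generative model
#'
#' Parameters of the liability-threshold generative model used to emulate
#' family cohorts ascertained through an affected proband. Background
#' liability is normal with sex-specific variance; each carried damaging
#' variant adds its class effect size to the liability; a child is
#' affected when the liability exceeds the sex-specific threshold implied
#' by the configured prevalences, and has co-occurring motor/cognitive
#' impairment when it exceeds a second, higher threshold calibrated so the
#' impairment fraction among affected probands matches the configured
#' within-trait prevalences.
#'
#' Defaults encode the canonical study conditions: male prevalence 2.5%
#' with a 4:1 male:female ratio, unit variances, roughly 0.02 damaging
#' protein-truncating de novo mutations per child exome-wide with larger
#' totals for less damaging classes, and impairment prevalences of 0.35 in
#' male and 0.40 in female probands.
#'
#' @param n_families Number of ascertained families (or cases, in
#'   case-control mode).
#' @param male_prevalence,sex_ratio,female_prevalence,male_variance,female_variance
#'   Population parameters; see [prevalence_spec()].
#' @param n_genes Number of protein-coding genes carrying variants.
#' @param dnm_rate Named per-child expected de novo counts per variant
#'   class (diploid totals, i.e. `2 * sum(mu)` over genes).
#' @param effect_sizes Named liability shift per carried variant, SD units,
#'   per class.
#' @param inherited_allele_frequency Named per-gene, per-haplotype
#'   population allele frequency per class.
#' @param impairment_prevalence Named (female/male) prevalence of
#'   co-occurring impairment among affected probands.
#' @param impairment_model `"shared_axis"` (second threshold on the autism
#'   liability axis; default) or `"correlated"` (a second liability axis
#'   correlated with the first).
#' @param impairment_correlation Correlation of the second axis
#'   (`"correlated"` model only).
#' @param ascertainment `"proband_trio"` (default), `"duo"` (one sequenced
#'   parent) or `"case_control"`.
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   configuration.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_families = 1000,
    male_prevalence = 0.025,
    sex_ratio = 4,
    female_prevalence = NULL,
    male_variance = 1,
    female_variance = 1,
    n_genes = 400,
    dnm_rate = c(damaging_PTV = 0.02, damaging_missense = 0.05,
                 synonymous = 0.30, other = 0.60),
    effect_sizes = c(damaging_PTV = 0.6, damaging_missense = 0.3,
                     synonymous = 0, other = 0),
    inherited_allele_frequency = c(damaging_PTV = 5e-5,
                                   damaging_missense = 2e-4,
                                   synonymous = 1e-3, other = 2e-3),
    impairment_prevalence = c(female = 0.40, male = 0.35),
    impairment_model = c("shared_axis", "correlated"),
    impairment_correlation = 0.7,
    ascertainment = c("proband_trio", "duo", "case_control"),
    seed = 1) {
  impairment_model <- arg_match(impairment_model)
  ascertainment <- arg_match(ascertainment)
  cls <- variant_class_levels()
  fill <- function(x, default = 0) {
    out <- setNames(rep(default, length(cls)), cls)
    out[names(x)] <- x
    out
  }
  if (any(dnm_rate < 0) || any(inherited_allele_frequency < 0)) {
    stop_domain("rates and allele frequencies must be nonnegative")
  }
  if (any(!is.finite(effect_sizes))) stop_domain("effect sizes must be finite")
  check_proportion(impairment_prevalence, "impairment_prevalence")
  structure(
    list(
      n_families = n_families,
      male_prevalence = male_prevalence,
      sex_ratio = sex_ratio,
      female_prevalence = female_prevalence,
      male_variance = male_variance,
      female_variance = female_variance,
      n_genes = n_genes,
      dnm_rate = fill(dnm_rate),
      effect_sizes = fill(effect_sizes),
      inherited_allele_frequency = fill(inherited_allele_frequency),
      impairment_prevalence = impairment_prevalence[c("female", "male")],
      impairment_model = impairment_model,
      impairment_correlation = impairment_correlation,
      ascertainment = ascertainment,
      seed = seed
    ),
    class = "simulation_config"
  )
}

sim_prevalences <- function(cfg) {
  spec <- prevalence_spec(cfg$male_prevalence, cfg$sex_ratio,
                          cfg$female_prevalence,
                          male_variance = cfg$male_variance,
                          female_variance = cfg$female_variance)
  list(
    K = c(female = spec$female_prevalence, male = spec$male_prevalence),
    sigma = sqrt(c(female = cfg$female_variance, male = cfg$male_variance))
  )
}

# impairment threshold on the second axis for the correlated model:
# solve P(L2 > t2 | L1 > t1) = target for standard bivariate normal rho
correlated_threshold <- function(t1_std, rho, target) {
  K <- pnorm(t1_std, lower.tail = FALSE)
  joint <- function(t2) {
    stats::integrate(function(x) {
      dnorm(x) * pnorm((t2 - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE)
    }, t1_std, Inf, rel.tol = 1e-9)$value
  }
  stats::uniroot(function(t2) joint(t2) / K - target, c(-8, 8),
                 tol = 1e-9)$root
}

# distribution of the total variant-induced liability shift per child:
# per-class counts are Poisson (de novo plus expected carried inherited
# alleles); classes with zero effect do not shift liability
sim_shift_distribution <- function(cfg) {
  lam_inh <- 2 * cfg$n_genes * cfg$inherited_allele_frequency
  lam <- cfg$dnm_rate + lam_inh
  active <- which(cfg$effect_sizes != 0 & lam > 0)
  s <- 0
  w <- 1
  for (i in active) {
    nmax <- stats::qpois(1 - 1e-12, lam[i]) + 2
    pk <- stats::dpois(0:nmax, lam[i])
    s <- as.vector(outer(s, cfg$effect_sizes[i] * (0:nmax), `+`))
    w <- as.vector(outer(w, pk, `*`))
  }
  list(s = s, w = w)
}

# threshold t with P(N(0, sigma^2) + shift > t) = target under the
# compound shift distribution, so configured prevalences are realized
# exactly in the population
calibrated_threshold <- function(target, sigma, shift) {
  base <- sigma * qnorm(target, lower.tail = FALSE)
  if (length(shift$s) == 1) return(base)
  p_above <- function(t) {
    sum(shift$w * pnorm((t - shift$s) / sigma, lower.tail = FALSE))
  }
  stats::uniroot(function(t) p_above(t) - target,
                 c(base - 1e-9, base + max(shift$s) + 1), tol = 1e-10)$root
}

sim_thresholds <- function(cfg) {
  pv <- sim_prevalences(cfg)
  shift <- sim_shift_distribution(cfg)
  sexes <- c("female", "male")
  t1 <- vapply(sexes, function(s) {
    calibrated_threshold(pv$K[[s]], pv$sigma[[s]], shift)
  }, numeric(1))
  if (cfg$impairment_model == "shared_axis") {
    t2 <- vapply(sexes, function(s) {
      calibrated_threshold(cfg$impairment_prevalence[[s]] * pv$K[[s]],
                           pv$sigma[[s]], shift)
    }, numeric(1))
  } else {
    # correlated second axis: threshold from the background bivariate
    # normal (variant shifts on the first axis are ignored here)
    t2 <- vapply(sexes, function(s) {
      correlated_threshold(t1[s] / pv$sigma[[s]], cfg$impairment_correlation,
                           cfg$impairment_prevalence[[s]])
    }, numeric(1))
  }
  list(K = pv$K, sigma = pv$sigma, autism = t1, impairment = t2)
}

# Draw n children. `parents` is a list of per-parent allele-count matrices
# (n x class); when NULL, new parents are drawn. Returns all per-child
# quantities needed for bookkeeping.
sim_draw_children <- function(n, cfg, th, parents = NULL) {
  cls <- variant_class_levels()
  nC <- length(cls)
  draw_mat <- function(f) {
    matrix(f(n * nC), nrow = n, dimnames = list(NULL, cls))
  }
  q <- cfg$inherited_allele_frequency
  # draw a per-class matrix, skipping all-zero classes cheaply
  class_mat <- function(f, active) {
    m <- matrix(0L, nrow = n, ncol = nC, dimnames = list(NULL, cls))
    for (i in which(active)) m[, i] <- f(i)
    m
  }
  draw_parent <- function() {
    class_mat(function(i) rbinom(n, 2 * cfg$n_genes, q[i]), q > 0)
  }
  if (is.null(parents)) {
    parents <- if (cfg$ascertainment == "case_control") NULL else {
      list(mother = draw_parent(), father = draw_parent())
    }
  }
  if (is.null(parents)) {
    carried <- draw_parent()
    trans_mo <- trans_fa <- NULL
  } else {
    halve <- function(p) {
      class_mat(function(i) rbinom(n, p[, i], 0.5), colSums(p) > 0)
    }
    trans_mo <- halve(parents$mother)
    trans_fa <- halve(parents$father)
    carried <- trans_mo + trans_fa
  }
  dnm <- class_mat(function(i) rpois(n, cfg$dnm_rate[i]), cfg$dnm_rate > 0)
  male <- runif(n) < 0.5
  sex <- if_else(male, "male", "female")
  pick <- function(v) if_else(male, v[["male"]], v[["female"]])
  shift <- as.vector((dnm + carried) %*% cfg$effect_sizes)
  sig <- pick(th$sigma)
  liability <- rnorm(n) * sig + shift
  affected <- liability > pick(th$autism)
  if (cfg$impairment_model == "shared_axis") {
    impaired <- liability > pick(th$impairment)
  } else {
    rho <- cfg$impairment_correlation
    l2 <- rho * liability / sig + sqrt(1 - rho^2) * rnorm(n)
    impaired <- l2 > pick(th$impairment)
  }
  list(sex = sex, liability = liability, affected = affected,
       impaired = impaired, dnm = dnm, carried = carried,
       trans_mo = trans_mo, trans_fa = trans_fa, parents = parents)
}

sub_children <- function(d, keep) {
  list(
    sex = d$sex[keep], liability = d$liability[keep],
    affected = d$affected[keep], impaired = d$impaired[keep],
    dnm = d$dnm[keep, , drop = FALSE],
    carried = d$carried[keep, , drop = FALSE],
    trans_mo = if (!is.null(d$trans_mo)) d$trans_mo[keep, , drop = FALSE],
    trans_fa = if (!is.null(d$trans_fa)) d$trans_fa[keep, , drop = FALSE],
    parents = if (!is.null(d$parents)) {
      list(mother = d$parents$mother[keep, , drop = FALSE],
           father = d$parents$father[keep, , drop = FALSE])
    }
  )
}

bind_children <- function(a, b) {
  if (is.null(a)) return(b)
  list(
    sex = c(a$sex, b$sex), liability = c(a$liability, b$liability),
    affected = c(a$affected, b$affected), impaired = c(a$impaired, b$impaired),
    dnm = rbind(a$dnm, b$dnm), carried = rbind(a$carried, b$carried),
    trans_mo = if (!is.null(a$trans_mo)) rbind(a$trans_mo, b$trans_mo),
    trans_fa = if (!is.null(a$trans_fa)) rbind(a$trans_fa, b$trans_fa),
    parents = if (!is.null(a$parents)) {
      list(mother = rbind(a$parents$mother, b$parents$mother),
           father = rbind(a$parents$father, b$parents$father))
    }
  )
}

#' Simulate an ascertained family cohort under the liability model
#'
#' Generates a cohort of families retained because they contain an
#' affected proband. Parental rare alleles are drawn from per-gene
#' population frequencies and transmitted Mendelianly; de novo events per
#' class are Poisson; child liability is sex-specific normal background
#' plus the summed class effects of carried damaging variants; diagnosis
#' and co-occurring impairment are threshold crossings (see
#' [simulation_config()]). Ascertainment is by rejection sampling of
#' children until `n_families` probands are found, after which one
#' non-autistic sibling per family is generated (trio mode). The whole
#' cohort is deterministic given the configuration (including its seed).
#'
#' @param cfg A [simulation_config()].
#' @param detail `"tables"` (default) emits full person/variant/gene
#'   tables for the QC-and-counting pipeline plus a truth record;
#'   `"counts"` skips table construction and returns stratum counts only
#'   (useful for replicated calibration studies).
#' @return An object of class `simulated_cohort` with elements `counts`
#'   (stratum-level burden counts), `truth` (thresholds, effect sizes,
#'   per-person latent liabilities), `config`, and -- in `"tables"` mode --
#'   `persons`, `variants`, `genes`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_families = 50, seed = 7))
#' cohort$counts
#' @export
simulate_cohort <- function(cfg, detail = c("tables", "counts")) {
  detail <- arg_match(detail)
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  th <- sim_thresholds(cfg)
  n <- cfg$n_families

  # accumulate affected probands by batch rejection
  pbar <- mean(pnorm(th$autism / th$sigma, lower.tail = FALSE))
  probands <- if (n == 0) sim_draw_children(0, cfg, th) else NULL
  got <- 0L
  for (iter in seq_len(if (n == 0) 0 else 60)) {
    if (got >= n) break
    batch <- min(5e6, ceiling((n - got) / max(pbar, 1e-8) * 1.2) + 100)
    d <- sim_draw_children(batch, cfg, th)
    hit <- which(d$affected)
    if (length(hit)) {
      probands <- bind_children(probands, sub_children(d, hit))
      got <- got + length(hit)
    }
  }
  if (got < n) {
    abort("ascertainment infeasible: too few affected children after bounded retries",
          class = "varliab_simulation_error")
  }
  probands <- sub_children(probands, seq_len(n))

  # one non-autistic sibling per family, same parents (family modes only)
  siblings <- NULL
  if (cfg$ascertainment != "case_control") {
    siblings <- sim_draw_children(n, cfg, th, parents = probands$parents)
    for (iter in seq_len(100)) {
      bad <- which(siblings$affected)
      if (!length(bad)) break
      redo <- sim_draw_children(length(bad), cfg, th,
                                parents = list(
                                  mother = probands$parents$mother[bad, , drop = FALSE],
                                  father = probands$parents$father[bad, , drop = FALSE]))
      for (f in c("sex", "liability", "affected", "impaired")) {
        siblings[[f]][bad] <- redo[[f]]
      }
      for (f in c("dnm", "carried", "trans_mo", "trans_fa")) {
        siblings[[f]][bad, ] <- redo[[f]]
      }
    }
    if (any(siblings$affected)) {
      abort("could not draw non-autistic siblings", class = "varliab_simulation_error")
    }
  } else {
    # unaffected controls, matched in number
    controls <- NULL
    got <- 0L
    for (iter in seq_len(60)) {
      if (got >= n) break
      d <- sim_draw_children(ceiling((n - got) * 1.1) + 50, cfg, th)
      hit <- which(!d$affected)
      controls <- bind_children(controls, sub_children(d, hit))
      got <- got + length(hit)
    }
    siblings <- sub_children(controls, seq_len(n))
  }

  counts <- sim_counts(cfg, probands, siblings)
  truth <- sim_truth(cfg, th, probands, siblings)
  out <- list(counts = counts, truth = truth, config = cfg,
              persons = NULL, variants = NULL, genes = NULL)
  if (detail == "tables") {
    genes <- make_gene_table(cfg$n_genes, dnm_rate = cfg$dnm_rate)
    tabs <- sim_tables(cfg, probands, siblings, genes)
    out$persons <- tabs$persons
    out$variants <- tabs$variants
    out$genes <- genes
  }
  structure(out, class = "simulated_cohort")
}

# stratum counts from the simulator's internal bookkeeping (independent of
# the emitted variant rows)
sim_counts <- function(cfg, probands, siblings) {
  cls <- variant_class_levels()
  grp <- function(imp) if_else(imp, "impaired", "not_impaired")
  frame <- tidyr::expand_grid(sex = c("female", "male"),
                              phenotype_group = c("impaired", "not_impaired"),
                              variant_class = cls)
  sum_by <- function(mat, sex, group) {
    df <- as_tibble(mat)
    df$sex <- sex
    df$phenotype_group <- group
    df %>%
      tidyr::pivot_longer(all_of(cls), names_to = "variant_class",
                          values_to = "k") %>%
      group_by(.data$sex, .data$phenotype_group, .data$variant_class) %>%
      summarise(events = sum(.data$k), .groups = "drop")
  }
  n_prob <- tibble(sex = probands$sex, phenotype_group = grp(probands$impaired)) %>%
    count(.data$sex, .data$phenotype_group, name = "n_case")
  n_sib <- tibble(sex = siblings$sex) %>% count(.data$sex, name = "n_control")

  case_dn <- sum_by(probands$dnm, probands$sex, grp(probands$impaired)) %>%
    rename(events_case = "events")
  ctrl_dn <- sum_by(siblings$dnm, siblings$sex, "all") %>%
    group_by(.data$sex, .data$variant_class) %>%
    summarise(events_control = sum(.data$events), .groups = "drop")
  mode_cc <- cfg$ascertainment == "case_control"
  if (mode_cc) {
    case_dn <- sum_by(probands$dnm + probands$carried, probands$sex,
                      grp(probands$impaired)) %>%
      rename(events_case = "events")
    ctrl_dn <- sum_by(siblings$dnm + siblings$carried, siblings$sex, "all") %>%
      group_by(.data$sex, .data$variant_class) %>%
      summarise(events_control = sum(.data$events), .groups = "drop")
  }
  de_novo <- frame %>%
    left_join(case_dn, by = c("sex", "phenotype_group", "variant_class")) %>%
    left_join(ctrl_dn, by = c("sex", "variant_class")) %>%
    left_join(n_prob, by = c("sex", "phenotype_group")) %>%
    left_join(n_sib, by = "sex") %>%
    mutate(mode = if (mode_cc) "case_control" else "de_novo",
           across(c("events_case", "events_control", "n_case", "n_control"),
                  ~ tidyr::replace_na(as.numeric(.x), 0)))

  out <- de_novo
  if (!mode_cc) {
    # transmission: proband transmitted vs untransmitted alleles
    trans_obs <- probands$trans_mo +
      if (cfg$ascertainment == "duo") 0 else probands$trans_fa
    par_obs <- probands$parents$mother +
      if (cfg$ascertainment == "duo") 0 else probands$parents$father
    untrans <- par_obs - trans_obs
    tr_case <- sum_by(trans_obs, probands$sex, grp(probands$impaired)) %>%
      rename(events_case = "events")
    tr_ctrl <- sum_by(untrans, probands$sex, grp(probands$impaired)) %>%
      rename(events_control = "events")
    trans <- frame %>%
      left_join(tr_case, by = c("sex", "phenotype_group", "variant_class")) %>%
      left_join(tr_ctrl, by = c("sex", "phenotype_group", "variant_class")) %>%
      mutate(mode = "transmitted_untransmitted",
             n_case = NA_real_, n_control = NA_real_,
             across(c("events_case", "events_control"),
                    ~ tidyr::replace_na(as.numeric(.x), 0)))
    out <- bind_rows(de_novo, trans)
  }
  out %>%
    mutate(cohort = "simulated") %>%
    select("cohort", "sex", "phenotype_group", "variant_class", "mode",
           "events_case", "events_control", "n_case", "n_control") %>%
    arrange(.data$mode, .data$sex, .data$phenotype_group, .data$variant_class)
}

sim_truth <- function(cfg, th, probands, siblings) {
  fam <- sprintf("fam%05d", seq_along(probands$sex))
  list(
    effect_sizes = cfg$effect_sizes,
    thresholds = tibble(
      sex = c("female", "male"),
      prevalence = th$K[c("female", "male")],
      autism_threshold = th$autism[c("female", "male")],
      impairment_threshold = th$impairment[c("female", "male")]
    ),
    liabilities = bind_rows(
      tibble(person_id = paste0(fam, "_p"), family_id = fam,
             role = "proband", sex = probands$sex,
             liability = probands$liability, affected = probands$affected,
             impaired = probands$impaired),
      tibble(person_id = paste0(fam, "_s"), family_id = fam,
             role = if (cfg$ascertainment == "case_control") "control" else "sibling",
             sex = siblings$sex, liability = siblings$liability,
             affected = siblings$affected, impaired = siblings$impaired)
    )
  )
}

#' Synthetic gene metadata table
#'
#' Builds the per-gene annotation consumed by classification and matched
#' gene-set resampling: LOEUF deciles in equal blocks, log-normal
#' sex-averaged brain expression and coding length, per-class mutation
#' rates proportional to coding length and scaled so the class totals
#' match the configured per-child de novo rates, and random gene-set
#' membership flags. Entirely synthetic; not derived from any real gene
#' annotation.
#'
#' @param n_genes Number of genes.
#' @param dnm_rate Named per-child de novo totals per class (see
#'   [simulation_config()]).
#' @param seed Optional seed (when used standalone; [simulate_cohort()]
#'   manages the RNG itself).
#' @return Tibble with `gene_id`, `loeuf_decile`, `brain_expression`,
#'   `cds_length`, mutation-rate and flag columns.
#' @export
make_gene_table <- function(n_genes,
                            dnm_rate = c(damaging_PTV = 0.02,
                                         damaging_missense = 0.05,
                                         synonymous = 0.30, other = 0.60),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  decile <- sort(rep(1:10, length.out = n_genes))
  len <- pmax(300, round(exp(rnorm(n_genes, 7.3, 0.5))))
  expr <- exp(rnorm(n_genes, 2, 1))
  d1 <- decile == 1
  rate_for <- function(total, subset) {
    w <- ifelse(subset, len, 0)
    if (sum(w) == 0) return(rep(0, n_genes))
    total / 2 * w / sum(w)   # per-haploid-generation rates
  }
  sfari <- d1 & runif(n_genes) < 0.5
  sfari[!d1] <- runif(sum(!d1)) < 0.02
  tibble(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    loeuf_decile = decile,
    brain_expression = expr,
    cds_length = len,
    mutation_rate_ptv = rate_for(dnm_rate[["damaging_PTV"]], d1),
    mutation_rate_missense = rate_for(dnm_rate[["damaging_missense"]],
                                      rep(TRUE, n_genes)),
    mutation_rate_synonymous = rate_for(dnm_rate[["synonymous"]],
                                        rep(TRUE, n_genes)),
    sfari = sfari,
    sfari_loeuf1 = sfari & d1,
    fetal_male_biased = runif(n_genes) < 0.03,
    fetal_female_biased = runif(n_genes) < 0.02,
    adult_male_biased = runif(n_genes) < 0.1,
    adult_female_biased = runif(n_genes) < 0.1
  )
}

# person and variant tables for the QC pipeline
sim_tables <- function(cfg, probands, siblings, genes) {
  n <- length(probands$sex)
  fam <- sprintf("fam%05d", seq_len(n))
  cls <- variant_class_levels()
  yesno <- function(x) if_else(x, "yes", "no")

  persons <- bind_rows(
    tibble(person_id = paste0(fam, "_p"), family_id = fam,
           sex = probands$sex, role = "proband", autism = TRUE,
           cognitive_impairment = yesno(probands$impaired),
           motor_delay = "no", iq = NA_integer_),
    if (cfg$ascertainment != "case_control") {
      tibble(person_id = paste0(fam, "_s"), family_id = fam,
             sex = siblings$sex, role = "sibling", autism = FALSE,
             cognitive_impairment = yesno(siblings$impaired),
             motor_delay = "no", iq = NA_integer_)
    } else {
      tibble(person_id = paste0(fam, "_c"), family_id = fam,
             sex = siblings$sex, role = "sibling", autism = FALSE,
             cognitive_impairment = yesno(siblings$impaired),
             motor_delay = "no", iq = NA_integer_)
    },
    if (cfg$ascertainment %in% c("proband_trio", "duo")) {
      tibble(person_id = paste0(fam, "_mo"), family_id = fam,
             sex = "female", role = "mother", autism = FALSE,
             cognitive_impairment = "no", motor_delay = "no",
             iq = NA_integer_)
    },
    if (cfg$ascertainment == "proband_trio") {
      tibble(person_id = paste0(fam, "_fa"), family_id = fam,
             sex = "male", role = "father", autism = FALSE,
             cognitive_impairment = "no", motor_delay = "no",
             iq = NA_integer_)
    }
  )

  # gene samplers per class (candidate genes and rate weights)
  samplers <- list(
    damaging_PTV = list(idx = which(genes$loeuf_decile == 1),
                        w = genes$mutation_rate_ptv[genes$loeuf_decile == 1]),
    damaging_missense = list(idx = seq_len(nrow(genes)),
                             w = genes$mutation_rate_missense),
    synonymous = list(idx = seq_len(nrow(genes)),
                      w = genes$mutation_rate_synonymous),
    other = list(idx = seq_len(nrow(genes)),
                 w = genes$mutation_rate_missense)
  )
  draw_gene <- function(class, k) {
    s <- samplers[[class]]
    genes$gene_id[s$idx[sample.int(length(s$idx), k, replace = TRUE,
                                   prob = s$w)]]
  }
  consequence_of <- function(class, k) {
    switch(class,
           damaging_PTV = rep("PTV", k),
           damaging_missense = rep("missense", k),
           synonymous = rep("synonymous", k),
           other = rep("missense", k))
  }
  mpc_of <- function(class, k) {
    switch(class,
           damaging_PTV = rep(NA_real_, k),
           damaging_missense = round(runif(k, 2, 3.5), 2),
           synonymous = rep(NA_real_, k),
           other = round(runif(k, 0, 0.9), 2))
  }
  mk_rows <- function(count_mat, child_ids, family_ids, inheritance) {
    parts <- lapply(cls, function(cl) {
      k_per <- count_mat[, cl]
      tot <- sum(k_per)
      if (tot == 0) return(NULL)
      i <- rep(seq_along(k_per), k_per)
      tibble(
        family_id = family_ids[i],
        child_id = child_ids[i],
        gene_id = draw_gene(cl, tot),
        consequence = consequence_of(cl, tot),
        mpc = mpc_of(cl, tot),
        inheritance = inheritance,
        af_cohort = round(runif(tot, 0, 9e-4), 6),
        af_gnomad = NA_real_,
        n_families_with_allele = 1L,
        dp = 10L + rpois(tot, 30),
        gq = 99L,
        vaf = round(pmin(0.7, pmax(0.3, rnorm(tot, 0.5, 0.05))), 3)
      )
    })
    bind_rows(parts)
  }

  p_id <- paste0(fam, "_p")
  s_id <- paste0(fam, if (cfg$ascertainment == "case_control") "_c" else "_s")
  pieces <- list(
    mk_rows(probands$dnm, p_id, fam, "de_novo"),
    mk_rows(siblings$dnm, s_id, fam, "de_novo")
  )
  if (cfg$ascertainment != "case_control") {
    pieces <- c(pieces, list(
      mk_rows(probands$trans_mo, p_id, fam, "transmitted_mother"),
      mk_rows(probands$parents$mother - probands$trans_mo, p_id, fam,
              "untransmitted_mother"),
      mk_rows(siblings$trans_mo, s_id, fam, "transmitted_mother")
    ))
    if (cfg$ascertainment == "proband_trio") {
      pieces <- c(pieces, list(
        mk_rows(probands$trans_fa, p_id, fam, "transmitted_father"),
        mk_rows(probands$parents$father - probands$trans_fa, p_id, fam,
                "untransmitted_father"),
        mk_rows(siblings$trans_fa, s_id, fam, "transmitted_father")
      ))
    }
  } else {
    pieces <- c(pieces, list(
      mk_rows(probands$carried, p_id, fam, "unknown"),
      mk_rows(siblings$carried, s_id, fam, "unknown")
    ))
  }
  schema <- tibble(
    family_id = character(0), child_id = character(0),
    gene_id = character(0), consequence = character(0), mpc = numeric(0),
    inheritance = character(0), af_cohort = numeric(0),
    af_gnomad = numeric(0), n_families_with_allele = integer(0),
    dp = integer(0), gq = integer(0), vaf = numeric(0)
  )
  variants <- bind_rows(c(list(schema), pieces))
  list(persons = persons, variants = variants)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("<simulated_cohort>\n")
  cat(sprintf("  %d families (%s ascertainment), seed %s\n",
              x$config$n_families, x$config$ascertainment,
              format(x$config$seed)))
  n_ev <- sum(x$counts$events_case + x$counts$events_control)
  cat(sprintf("  %d stratum rows, %d events total\n", nrow(x$counts), n_ev))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.simulated_cohort <- function(x, ...) x$counts

#' @exportS3Method generics::glance
glance.simulated_cohort <- function(x, ...) {
  tibble(
    n_families = x$config$n_families,
    ascertainment = x$config$ascertainment,
    prop_male_probands = mean(x$truth$liabilities$sex[
      x$truth$liabilities$role == "proband"] == "male"),
    prop_impaired_probands = mean(x$truth$liabilities$impaired[
      x$truth$liabilities$role == "proband"]),
    seed = x$config$seed
  )
}

#' Burden-count and per-gene count tables of a simulated cohort
#'
#' Emits the analysis-ready tables: the stratum-level burden counts (from
#' the simulator's internal bookkeeping, so they agree exactly with
#' [tabulate_counts()] applied to the emitted person/variant tables) and
#' per-gene counts by mode for gene-set analyses (tables mode only).
#'
#' @param cohort A `simulated_cohort`.
#' @return List with `burden_counts` and (in tables mode) `gene_counts`.
#' @export
emit_count_tables <- function(cohort) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  out <- list(burden_counts = cohort$counts, gene_counts = NULL)
  if (!is.null(cohort$variants)) {
    v <- cohort$variants %>%
      left_join(select(cohort$persons, child_id = "person_id", "role"),
                by = "child_id")
    dn <- v %>%
      filter(.data$inheritance == "de_novo") %>%
      mutate(side = if_else(.data$role == "proband",
                            "events_case", "events_control"),
             mode = "de_novo")
    tr <- v %>%
      filter(.data$role == "proband",
             grepl("transmitted_", .data$inheritance)) %>%
      mutate(side = if_else(grepl("^transmitted_", .data$inheritance),
                            "events_case", "events_control"),
             mode = "transmitted_untransmitted")
    out$gene_counts <- bind_rows(dn, tr) %>%
      count(.data$gene_id, .data$consequence, .data$mode, .data$side) %>%
      tidyr::pivot_wider(names_from = "side", values_from = "n",
                         values_fill = 0L)
    for (col in c("events_case", "events_control")) {
      if (!col %in% names(out$gene_counts)) out$gene_counts[[col]] <- 0L
    }
  }
  out
}

#' Analytic female:male carrier-rate ratio among probands
#'
#' Computes, by numeric summation over the generative model, the expected
#' ratio of per-proband de novo carrier rates of one variant class in
#' female versus male probands. Under the different-threshold model this
#' ratio is 1 at zero effect size and grows with the carrier shift: the
#' higher female threshold enriches ascertained females for carriers. The
#' calculation assumes the focal class is the only one with a nonzero
#' effect (other classes are ignored, with a note, if configured
#' otherwise).
#'
#' @param cfg A [simulation_config()].
#' @param class Focal variant class.
#' @param max_count Truncation of the carried-count sums.
#' @return The female:male expected de novo rate ratio among probands.
#' @export
expected_sex_ratio_of_carriers <- function(cfg, class = "damaging_PTV",
                                           max_count = 12) {
  stopifnot(inherits(cfg, "simulation_config"))
  others <- setdiff(variant_class_levels(), class)
  if (any(cfg$effect_sizes[others] != 0)) {
    inform("nonzero effects in non-focal classes are ignored by the analytic ratio")
  }
  th <- sim_thresholds(cfg)
  beta <- cfg$effect_sizes[[class]]
  lam_d <- cfg$dnm_rate[[class]]
  n_par_hap <- if (cfg$ascertainment == "proband_trio") 4 else 2
  lam_i <- n_par_hap * cfg$n_genes * cfg$inherited_allele_frequency[[class]] / 2
  grid <- expand.grid(d = 0:max_count, i = 0:max_count)
  w <- stats::dpois(grid$d, lam_d) * stats::dpois(grid$i, lam_i)
  rate_sex <- function(sex) {
    p_aff <- pnorm((th$autism[[sex]] - beta * (grid$d + grid$i)) /
                     th$sigma[[sex]], lower.tail = FALSE)
    sum(grid$d * w * p_aff) / sum(w * p_aff)
  }
  rate_sex("female") / rate_sex("male")
}
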