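mk_variant <- function(dp = 40, gq = 99, vaf = 0.5, af_cohort = 5e-4,
                       af_gnomad = NA_real_, n_families_with_allele = 1L,
                       consequence = "PTV", mpc = NA_real_,
                       gene_id = "g00001", child_id = "fam00001_p",
                       family_id = "fam00001",
                       inheritance = "de_novo") {
  tibble::tibble(family_id = family_id, child_id = child_id,
                 gene_id = gene_id, consequence = consequence, mpc = mpc,
                 inheritance = inheritance, af_cohort = af_cohort,
                 af_gnomad = af_gnomad,
                 n_families_with_allele = n_families_with_allele,
                 dp = dp, gq = gq, vaf = vaf)
}

test_that("genotype filters are inclusive at the stated boundaries", {
  expect_true(genotype_pass(mk_variant(dp = 30, gq = 60, vaf = 0.5)))
  expect_false(genotype_pass(mk_variant(dp = 9, gq = 60, vaf = 0.5)))
  expect_true(genotype_pass(mk_variant(dp = 10, gq = 10, vaf = 0.25)))
  expect_false(genotype_pass(mk_variant(gq = 9)))
  expect_false(genotype_pass(mk_variant(vaf = 0.24)))
  expect_warning(res <- genotype_pass(mk_variant(dp = NA)), "fail closed")
  expect_false(res)
})

test_that("rarity tiers follow their frequency definitions", {
  expect_true(rarity_pass(mk_variant(af_cohort = 5e-4, af_gnomad = 2e-4),
                          "rare_0.1pct"))
  expect_false(rarity_pass(mk_variant(af_cohort = 2e-3), "rare_0.1pct"))
  expect_true(rarity_pass(mk_variant(af_gnomad = NA), "rare_0.1pct"))
  expect_false(rarity_pass(mk_variant(af_gnomad = 5e-3), "rare_0.1pct"))

  expect_true(rarity_pass(mk_variant(n_families_with_allele = 1L),
                          "ultra_rare_duo"))
  expect_false(rarity_pass(mk_variant(n_families_with_allele = 2L),
                           "ultra_rare_duo"))
  expect_false(rarity_pass(mk_variant(af_gnomad = 1e-5), "ultra_rare_duo"))

  expect_true(rarity_pass(mk_variant(af_cohort = 4e-5),
                          "ultra_rare_casecontrol"))
  # the boundary is a strict inequality
  expect_false(rarity_pass(mk_variant(af_cohort = 5e-5),
                           "ultra_rare_casecontrol"))
})

test_that("variant classification honours constraint deciles and MPC", {
  genes <- tibble::tibble(gene_id = paste0("g", 1:4),
                          loeuf_decile = c(1, 2, 4, 10))
  v <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g1", "g1", "g1", "gX"),
    consequence = c("PTV", "PTV", "PTV", "missense", "missense",
                    "synonymous", "PTV"),
    mpc = c(NA, NA, NA, 2.0, 1.2, NA, NA)
  )
  expect_warning(strict <- classify_variants(v, genes), "absent")
  expect_equal(strict$variant_class,
               c("damaging_PTV", "other", "other", "damaging_missense",
                 "other", "synonymous", "other"))

  relaxed <- suppressWarnings(classify_variants(
    v, genes, classification_config(ptv_decile_max = 3, mpc_threshold = 1)))
  expect_equal(relaxed$variant_class[2], "damaging_PTV")
  expect_equal(relaxed$variant_class[3], "other")
  expect_equal(relaxed$variant_class[5], "damaging_missense")

  # strict damaging calls are a subset of relaxed ones
  strict_dmg <- strict$variant_class %in% c("damaging_PTV", "damaging_missense")
  relaxed_dmg <- relaxed$variant_class %in% c("damaging_PTV", "damaging_missense")
  expect_true(all(!strict_dmg | relaxed_dmg))

  # idempotent and order-independent
  again <- suppressWarnings(classify_variants(strict, genes))
  expect_equal(again$variant_class, strict$variant_class)
  shuf <- suppressWarnings(classify_variants(v[7:1, ], genes))
  expect_equal(shuf$variant_class, rev(strict$variant_class))
})

test_that("greedy unrelated pruning retains females preferentially", {
  persons <- tibble::tibble(
    person_id = c("aF", "bM", "cM", "dF", "eM"),
    sex = c("female", "male", "male", "female", "male"),
    role = "proband"
  )
  # no edges: everyone is retained
  expect_setequal(max_unrelated(data.frame(a = character(0),
                                           b = character(0)), persons),
                  persons$person_id)

  # one male-female pair: the female survives
  kept <- max_unrelated(data.frame(a = "aF", b = "bM"), persons)
  expect_true("aF" %in% kept)
  expect_false("bM" %in% kept)

  # triangle with two males and one female: only the female survives
  tri <- data.frame(a = c("aF", "aF", "bM"), b = c("bM", "cM", "cM"))
  kept_tri <- max_unrelated(tri, persons)
  expect_true("aF" %in% kept_tri)
  expect_false(any(c("bM", "cM") %in% kept_tri))

  # output induces an edgeless graph and rerunning is the identity
  pairs <- data.frame(a = c("aF", "bM", "cM", "dF"),
                      b = c("bM", "cM", "dF", "eM"))
  kept2 <- max_unrelated(pairs, persons)
  live <- pairs[pairs$a %in% kept2 & pairs$b %in% kept2, ]
  expect_equal(nrow(live), 0)
  again <- max_unrelated(pairs[pairs$a %in% kept2 & pairs$b %in% kept2, ],
                         persons[persons$person_id %in% kept2, ])
  expect_setequal(again, kept2)

  expect_error(max_unrelated(data.frame(a = "zz", b = "aF"), persons),
               class = "varliab_domain_error")
})

test_that("phenotype stratification distinguishes impairment schemes", {
  persons <- tibble::tibble(
    person_id = paste0("p", 1:6),
    family_id = paste0("f", 1:6),
    sex = "male", role = c(rep("proband", 5), "sibling"),
    autism = c(rep(TRUE, 5), FALSE),
    cognitive_impairment = c("no", "yes", NA, "no", "no", "no"),
    motor_delay = c("no", "no", NA, "no", "yes", "no"),
    iq = c(79L, NA, NA, 100L, NA, NA)
  )
  spark <- phenotype_stratify(persons, "spark_motor_cognitive")
  expect_equal(spark$phenotype_group[1], "impaired")       # IQ 79 < 80
  expect_equal(spark$phenotype_group[2], "impaired")       # reported diagnosis
  expect_equal(spark$phenotype_group[3], "unclassified")   # all unknown
  expect_equal(spark$phenotype_group[4], "not_impaired")   # explicit no, IQ 100
  expect_equal(spark$phenotype_group[5], "impaired")       # motor delay
  expect_true(is.na(spark$phenotype_group[6]))             # sibling

  asc <- phenotype_stratify(persons, "asc_cognitive")
  expect_equal(asc$phenotype_group[1], "not_impaired_or_unknown") # IQ 79 >= 70
  expect_equal(asc$phenotype_group[3], "not_impaired_or_unknown")
  asc80 <- phenotype_stratify(persons, "asc_cognitive", iq_cutoff = 80)
  expect_equal(asc80$phenotype_group[1], "impaired")
})

test_that("stratum counting conserves totals and completes empty strata", {
  persons <- tibble::tibble(
    person_id = c("f1_p", "f1_s", "f2_p", "f2_s"),
    family_id = c("f1", "f1", "f2", "f2"),
    sex = c("female", "female", "female", "male"),
    role = c("proband", "sibling", "proband", "sibling"),
    autism = c(TRUE, FALSE, TRUE, FALSE),
    cognitive_impairment = "no", motor_delay = "no", iq = NA_integer_
  )
  empty <- mk_variant()[0, ]
  empty$variant_class <- character(0)
  zero <- tabulate_counts(empty, persons)
  expect_true(all(zero$events_case == 0))
  expect_true(all(zero$events_control == 0))
  expect_equal(nrow(zero), 2 * 1 * 4 * 2)  # sex x group x class x mode

  v <- dplyr::bind_rows(
    mk_variant(child_id = "f1_p", family_id = "f1"),
    mk_variant(child_id = "f1_p", family_id = "f1"),
    mk_variant(child_id = "f2_p", family_id = "f2"),
    mk_variant(child_id = "f1_s", family_id = "f1",
               consequence = "synonymous"),
    mk_variant(child_id = "f1_p", family_id = "f1",
               inheritance = "transmitted_mother"),
    mk_variant(child_id = "f1_p", family_id = "f1",
               inheritance = "untransmitted_father")
  )
  genes <- tibble::tibble(gene_id = "g00001", loeuf_decile = 1)
  cl <- classify_variants(v, genes)
  counts <- tabulate_counts(cl, persons)

  # 3 de novo damaging PTVs in 2 female probands
  dn <- counts[counts$mode == "de_novo" & counts$sex == "female" &
                 counts$variant_class == "damaging_PTV", ]
  expect_equal(dn$events_case, 3)
  expect_equal(dn$n_case, 2)
  syn <- counts[counts$mode == "de_novo" & counts$sex == "female" &
                  counts$variant_class == "synonymous", ]
  expect_equal(syn$events_control, 1)

  # conservation: total de novo events equal the passing de novo rows
  dn_all <- counts[counts$mode == "de_novo", ]
  expect_equal(sum(dn_all$events_case) +
                 sum(dn_all$events_control[!duplicated(
                   paste(dn_all$sex, dn_all$variant_class))]),
               sum(cl$inheritance == "de_novo"))
  tr_all <- counts[counts$mode == "transmitted_untransmitted", ]
  expect_equal(sum(tr_all$events_case) + sum(tr_all$events_control), 2)

  # orphan variant rows are warned about and dropped
  orphan <- mk_variant(child_id = "nobody")
  orphan$variant_class <- "damaging_PTV"
  expect_warning(tabulate_counts(dplyr::bind_rows(cl, orphan), persons),
                 "unknown persons")
})

test_that("phenotype-group collapsing keeps shared controls single-counted", {
  counts <- tibble::tibble(
    cohort = "c", sex = "male",
    phenotype_group = c("impaired", "not_impaired", "impaired",
                        "not_impaired"),
    variant_class = "damaging_PTV",
    mode = c("de_novo", "de_novo", "transmitted_untransmitted",
             "transmitted_untransmitted"),
    events_case = c(10, 20, 8, 12),
    events_control = c(50, 50, 7, 11),
    n_case = c(100, 300, NA, NA),
    n_control = c(400, 400, NA, NA)
  )
  col <- collapse_phenotype_groups(counts)
  dn <- col[col$mode == "de_novo", ]
  expect_equal(dn$events_case, 30)
  expect_equal(dn$events_control, 50)   # same siblings, counted once
  expect_equal(dn$n_case, 400)
  expect_equal(dn$n_control, 400)
  tr <- col[col$mode == "transmitted_untransmitted", ]
  expect_equal(tr$events_case, 20)
  expect_equal(tr$events_control, 18)   # proband alleles sum across groups
})
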