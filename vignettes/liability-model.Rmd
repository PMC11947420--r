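---
title: "Liability-scale effect sizes of rare variants: models, estimators, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-scale effect sizes of rare variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(varliab)
```

## The different-threshold liability model

`varliab` works under the classical liability threshold model: a latent
predisposition L, the sum of many additive genetic and non-genetic
contributions, is normally distributed in the population, and an
individual is affected when L exceeds a threshold set by the trait
prevalence, `T = Φ⁻¹(1 − K)` on the standardized scale. A sex
difference in prevalence is modelled as a difference in thresholds: with
a male prevalence of 2.5% (1 in 40) and a 4:1 male:female ratio, the
male threshold is 1.96 SD and the female threshold about 2.50 SD
(`liability_threshold()`, `prevalence_spec()`). The same machinery
applies to any dichotomous trait defined on the liability axis: for
co-occurring motor/cognitive impairment *among* autistic probands, with
within-trait prevalences of 0.35 (males) and 0.40 (females), the
thresholds are about 0.39 and 0.25 SD.

Two standard relaxations are provided. Phenotype strata scale the
sex-specific prevalence by the observed within-trait proportion
(`subgroup_prevalence()`: e.g. 23% × 2.5% ≈ 0.58% for
autism-with-cognitive-impairment in males), with the complement
assigned to the remaining stratum so the two sum to the parent
prevalence. An unequal-variance variant
(`unequal_variance_adjustment()`) lets the male liability variance
exceed the female variance (population analyses suggest a factor of
2–3); thresholds and effects are then reported both on each sex's raw
scale and rescaled to the standardized (variance-1, i.e. female) scale
so the sexes stay comparable.

## From observed enrichment to liability effect size

The observed-scale result of a burden analysis is a rate ratio: variants
per proband over variants per sibling (de novo), or transmitted over
untransmitted parental alleles (inherited), tested against its
sample-size expectation with a two-sided exact binomial test
(minimum-likelihood convention, `exact_binom_p()`; this is
`stats::binom.test()`'s rule, which the test suite verifies against full
enumeration). Exact Clopper–Pearson intervals on the event split are
mapped to the ratio scale through `f ↦ (f/(1−f))·(n_control/n_case)`.

Converting enrichment to the liability scale proceeds in two steps.
First, Bayes inversion under the rare-carrier approximation gives the
carrier penetrance `p = rK / (rK + r̃(1−K))` from the case and control
rates r, r̃ (`carrier_penetrance()`; the approximation neglects carrier
frequency in the normalization and is flagged for rates above 0.1 per
sample). Second, the penetrance is mapped to a mean carrier shift.
Here a genuine design choice exists, and the package makes it
explicitly:

- **Threshold inversion (default).** If carriers are normal with unit
  variance around a shifted mean, penetrance p implies the shift
  `Z = T − Φ⁻¹(1 − p)` (`liability_effect(method = "threshold_shift")`).
  This estimator is exactly consistent under the package's own
  generative model: the parameter-recovery studies below confirm that
  it converges to the simulated carrier shift. It also reproduces, from
  an observed ≈2-fold enrichment at prevalences 0.40/0.35, effect sizes
  in the 0.39–0.45 SD range.
- **Truncated-means mixture (alternative).** The penetrance-weighted
  average of the population truncated means,
  `Z = p·φ(T)/K − (1−p)·φ(T)/(1−K)`
  (`method = "truncated_mixture"`), treats carriers as population
  members reallocated between the affected and unaffected tails. It
  preserves sign, ordering and the zero at equal rates, but compresses
  magnitudes (a 2-fold enrichment at K = 0.40 maps to ≈0.28 SD rather
  than ≈0.43) and does not recover a simulated shift; it is retained
  for comparison with analyses that used it.

Both estimators are zero exactly at rate ratio 1, strictly increasing in
the ratio, and invariant to rescaling both rates.

### Uncertainty conventions

Reported standard errors follow the convention of deriving se from the
exact-test p-value, `se = |Z|/Φ⁻¹(1 − p/2)`, with symmetric 95% CIs
(`se_and_ci()`); at p = 1 (or Z = 0) the implied se is undefined and is
returned as missing with the CI suppressed. This convention is
Wald-consistent near the null but uses the null-variance scale, so at
strong enrichment it understates the sampling spread. Because the
penetrance-to-liability mapping is strictly monotone in the rate ratio,
an exact asymmetric CI is available for free by transforming the
endpoints of the exact rate-ratio CI (`liability_from_ratio()`); the
package's calibration studies use this interval, and it is the one to
prefer when coverage matters. Sex differences are
`Z_f − Z_m` with `se = sqrt(se_f² + se_m²)` and a two-sided normal
p-value (`sex_difference_liability()`).

## Meta-analysis and multiplicity

Cohorts are combined by fixed-effect inverse-variance weighting
(`ivw_meta()`), rate ratios on the log scale with se reconstructed from
the CI width (`meta_rate_ratio()`); no heterogeneity statistics are
computed. Multiplicity uses two tiers on top of the raw p:
Benjamini–Hochberg FDR within the declared family and Bonferroni with a
configurable family size (`adjust_results()`). The canonical exome-wide
family has 54 tests — 3 sex comparisons × 3 cohorts × 3 variant
classes × 2 inheritance modes; the two-phenotype-stratum analyses use
108. The 108 is inferred from corrected values consistent with the
printed arithmetic (e.g. 0.0080 × 108 ≈ 0.86) rather than stated
anywhere, which is why it is a configuration value and not a constant.
Tiers `***`/`**`/`*` mark significance after Bonferroni, after FDR, or
only before correction.

## Matched gene-set nulls

Gene-set burden is judged against covariate-matched random sets rather
than the exome-wide expectation. Genes are stratified by exact LOEUF
decile and pool-wide quantile bins of sex-averaged brain expression and
coding length; the bin count is not dictated by anything external, so
the package defaults to quintiles and exposes the knob. For each of
10,000 draws (default), every target gene is replaced by a uniform draw
with replacement from its stratum; a stratum with no candidates falls
back to same-decile-and-expression-bin, then same-decile matching, with
a note. The draw-averaged rate ratio becomes the null ratio of a
recentred exact test (`test_vs_expected()`: expected case fraction
`R·n_case/(R·n_case + n_control)` in de novo mode, `R/(1+R)` for
transmission; at R = 1 this is exactly the exome-wide test), and the
draw-averaged case rate replaces the sibling rate in the liability
conversion to give the set's *excess* liability
(`excess_liability()`). Draws with empty denominators are dropped from
the average; if they exceed 1% of draws the estimator switches to the
ratio of summed numerators and denominators, and says so. All draws are
Mersenne–Twister with a recorded seed, so null summaries are exactly
reproducible.

## QC, classification and counting

The classification rules are thresholds on annotations the input tables
already carry: PTVs are damaging in genes within the most-constrained
LOEUF decile (deciles 2–3 as relaxed sensitivity settings), missense
variants at MPC ≥ 2 (≥ 1 relaxed), synonymous passes through, and
everything else — including variants in genes missing from the gene
table — is `other`. Genotypes pass at DP ≥ 10, GQ ≥ 10 and VAF ≥ 0.25;
the published exclusions are phrased as strict inequalities, so the
boundaries pass. Rarity tiers: cohort and gnomAD MAF < 0.1%;
single-family and absent from gnomAD (duo analyses); AF < 0.005%
(case-control). Relatedness pruning is the greedy
remove-highest-degree loop with ties broken by removing a male before a
female and then by lexicographic id, so reruns are deterministic and
females are preferentially retained. Phenotype stratification supports
the two schemes the cohorts allow: impaired versus
not-impaired-or-unknown (IQ cutoff 70 by default, exposed as a
parameter because the source definitions mix an IQ rule with ontology
codes), and a three-way impaired / explicitly-not-impaired /
unclassified split that also counts motor delay (IQ cutoff 80).
`tabulate_counts()` then aggregates to one row per sex × phenotype
group × variant class × mode, sharing each sex's sibling counts across
that sex's phenotype groups; `collapse_phenotype_groups()` undoes the
stratification without double-counting those shared controls.

## The cohort simulator

`simulate_cohort()` exists so that every estimator in the package can be
checked by parameter recovery. Its defaults are the study conditions:
male prevalence 2.5%, sex ratio 4:1, unit variances, one non-autistic
sibling per ascertained family, impairment prevalences 0.40/0.35 among
female/male probands, about 0.02 damaging-PTV de novo events per child
with larger totals for milder classes (0.05 damaging missense, 0.30
synonymous, 0.60 other — typical exome-wide de novo yields), and
carrier shifts of 0.6 SD (damaging PTV) and 0.3 SD (damaging missense).
Parental rare alleles are drawn per gene from class-specific population
frequencies and transmitted Mendelianly; de novo counts are Poisson;
the child's liability is its sex's normal background plus the summed
class shifts of carried variants.

Two calibration details matter. First, thresholds are computed against
the *compound* liability distribution (normal background convolved with
the Poisson variant shifts), not the background alone, so the
configured prevalences are realized exactly in the simulated population
rather than being inflated by the variant mass. Second, co-occurring
impairment is by default a second, higher threshold on the same axis,
calibrated the same way so the configured impairment fractions among
probands are hit; because nothing in the source material commits to a
mechanism, an alternative correlated-second-axis model
(`impairment_model = "correlated"`) is provided, with its threshold
solved from the background bivariate normal.

Ascertainment is rejection sampling of children until the requested
number of affected probands is found (batched and vectorized; a bounded
retry budget turns infeasible configurations into an error instead of a
hang). Conditioning is on proband status only, so estimator inputs are
unaffected by the batching strategy. `detail = "counts"` skips the
person/variant table construction for replicated studies; the tables
mode emits exactly the inputs the QC-and-counting pipeline consumes,
and the stratum counts it reports come from independent internal
bookkeeping, which the suite checks agrees with `tabulate_counts()` row
for row. The emitted gene table (`make_gene_table()`) is entirely
synthetic — deciles in blocks, log-normal expression and length,
length-proportional mutation rates scaled to the configured class
totals.

What the simulator does **not** emulate: linkage disequilibrium and
genomic coordinates, sex-chromosome inheritance, annotation error,
genetic-ancestry structure, variable genotype quality (all emitted
genotypes pass QC), multi-child families, or assortative ascertainment
beyond the affected proband. Passing recovery tests therefore validate
the estimators under the model's own assumptions; they say nothing
about robustness to, e.g., stratification artefacts in real cohorts.

## Validation studies and problem sizes

The package's statistical claims are established by three simulation
studies, run both in the test suite and by `scripts/acceptance.R`:

- **Parameter recovery.** 200 cohorts of 20,000 families with a single
  damaging-PTV class at a 0.6-SD carrier shift; the male-proband
  liability estimate with its exact transformed CI covers the true
  shift in well over 90% of replicates, and the mean estimate is
  unbiased to within a few hundredths of a SD. Smaller-cohort sweeps
  across shifts of 0.3, 0.6 and 1.0 SD behave the same way.
- **Null calibration.** 500 null cohorts of 1,000 families (no variant
  effects) yield 2,000 independent stratum tests; the exact test's
  rejection rate at the 5% level is consistent with nominal within
  binomial Monte-Carlo error.
- **The signature prediction.** Under the different-threshold model,
  highly penetrant variants are relatively more frequent in female
  probands. Cohorts of 25,000 families at shifts of 0.5 and 1.0 SD show
  a female:male damaging-DNM rate ratio above 1 that grows with the
  shift and matches the analytic ratio from numeric integration
  (`expected_sex_ratio_of_carriers()`), while the female-minus-male
  liability difference stays centred at zero — the observed-scale sex
  difference is a threshold artefact, not an effect-size difference.

These sizes were chosen to give each check comfortable Monte-Carlo
resolution on a single CPU; they are configuration, not constants, and
scale freely.

## Numerical choices and degenerate inputs

- Prevalences are proportions internally; percent-scaled inputs are the
  caller's responsibility to convert (helpers print percent only in
  reporting).
- Zero control or untransmitted counts give an infinite ratio with a
  one-sided CI and a warning — the exact test remains valid, so no
  continuity correction is applied.
- Zero total events give p = 1 and a missing ratio in `burden_test()`.
- `se_and_ci()` errors at p ≤ 0 and returns missing se at p = 1;
  p-values can underflow to zero at extreme enrichment, in which case
  the exact transformed CI is the usable interval.
- Quantile bins with tied breaks collapse; a covariate with a single
  value yields one bin.
- Mutation-rate tables are per-haploid-generation by default
  (`expected = 2μn`); a `rate_convention` flag switches to diploid
  rates.
- Parent-of-origin denominators are parent counts, not allele counts.
- Transmission CIs condition on transmitted + untransmitted totals; the
  alternative (conditioning on all parental alleles) is not offered.

## Known limitations

Heritability estimation, polygenic scores, non-normal liability
distributions, random-effects meta-analysis, gene-level association
(TADA-style) and X/Y-chromosome analyses are out of scope. The
rare-carrier approximation degrades for variant classes approaching one
event per sample. The Wald-from-p standard errors undercover at strong
enrichment (use the transformed exact CIs). Real-data ingestion expects
pre-annotated tab-delimited tables; VCF parsing is deliberately not
provided.
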