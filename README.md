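# varliab

Rare protein-coding variants — de novo protein-truncating and damaging
missense mutations in particular — are strongly enriched in autistic
individuals, and more so in autistic females than males. Whether that
observed-scale sex difference reflects genuinely sex-biased effect sizes
or simply the different diagnostic thresholds implied by the ~4:1
male:female prevalence ratio is a question about the **liability scale**,
not the observed scale. `varliab` implements the full analysis toolkit
for answering it from stratified variant-count data:

- exact-binomial burden tests on de novo, transmitted/untransmitted, and
  case-control counts, with exact rate-ratio confidence intervals;
- conversion of observed enrichment into liability-scale effect sizes
  under sex-specific liability threshold models, including
  phenotype-scaled prevalences (autism with/without co-occurring
  cognitive or motor impairment) and unequal-variance variants;
- covariate-matched random gene-set permutation nulls (LOEUF decile,
  brain expression, coding length) with excess-liability estimation;
- inverse-variance fixed-effect meta-analysis and tiered
  Bonferroni/FDR multiplicity adjustment;
- variant classification, genotype/rarity QC, phenotype stratification,
  greedy maximal-unrelated pruning, and stratum counting;
- a generative trio-cohort simulator under the same liability model, so
  every estimator can be validated by parameter recovery without access
  to controlled individual-level data.

It is written for statistical geneticists and epidemiologists working
with family-based rare-variant cohorts; all user-facing functions take
data frames and return tibbles, so analyses compose with the pipe.

## The model

A latent liability L is standard normal in the population of each sex.
With sex-specific prevalence K the diagnostic threshold is
`T = Φ⁻¹(1 − K)`: 1.96 SD for a male prevalence of 2.5%, about 2.50 SD
for the 0.625% female prevalence implied by a 4:1 ratio. For a variant
class with per-sample rates `r` in affected and `r̃` in unaffected
individuals, the penetrance under the rare-carrier approximation is

    p = r·K / (r·K + r̃·(1 − K))

and the mean liability shift conferred by the class (the effect size Z,
in SD units) is obtained by threshold inversion,

    Z = T − Φ⁻¹(1 − p),

so equal rates give Z = 0 and the estimate depends on the rates only
through their ratio. Standard errors follow the Wald-from-p convention
`se = |Z| / Φ⁻¹(1 − p_binomial/2)` for compatibility with reported
values; exact asymmetric CIs obtained by transforming the rate-ratio CI
through the monotone mapping are available via `liability_from_ratio()`
and are what the package's calibration studies use. Sex differences are
`Z_f − Z_m` with variances added. The methods vignette
(`vignettes/liability-model.Rmd`) derives and motivates all of this.

## Worked example

Female probands versus female siblings, de novo damaging PTVs, with
counts at the scale of a large trio cohort:

```r
library(varliab)

spec <- prevalence_spec(male_prevalence = 0.025, sex_ratio = 4)
tidy(spec)
#>   sex    prevalence variance threshold_standardized threshold_raw
#> 1 female    0.00625        1                   2.50          2.50
#> 2 male      0.025          1                   1.96          1.96

rr <- dnm_rate_ratio(events_case = 214, n_case = 4404,
                     events_control = 60, n_control = 4707)
rr
#>   ratio ci_low ci_high  p_value expected_fraction n_events_total
#> 1  3.81   2.85    5.16 9.03e-24             0.483            274

liability_estimate(rate_cases = 214 / 4404, rate_controls = 60 / 4707,
                   prevalence = spec$female_prevalence,
                   p_value = rr$p_value)
#>       z     se ci_low ci_high  p_value prevalence_used
#> 1 0.510 0.0507  0.410   0.609 9.03e-24         0.00625
```

A 3.8-fold enrichment of damaging PTVs in female probands translates to
about half a standard deviation of liability — far below the ~2.5-SD
female threshold, i.e. these variants alone cannot account for a
diagnosis.

The same machinery runs end-to-end on simulated cohorts:

```r
cohort <- simulate_cohort(simulation_config(n_families = 2000, seed = 42))
glance(cohort)
#>   n_families ascertainment prop_male_probands prop_impaired_probands seed
#> 1       2000 proband_trio               0.794                  0.362   42

res <- run_pipeline(cohort$variants, cohort$persons, cohort$genes,
                    config = pipeline_config(m_family = 54))
res
#> <varliab_pipeline>
#>   32 result rows (simulated), 15 sex-difference contrasts
#>   17 stratum-test(s) significant before correction

dplyr::filter(tidy(res), mode == "de_novo",
              variant_class == "damaging_PTV", sex == "male") |>
  dplyr::select(phenotype_group, events_case, events_control,
                ratio, p_value, z, tier)
#>   phenotype_group events_case events_control ratio  p_value     z tier
#> 1 impaired                 55             26  3.77 7.72e-09 0.528 ***
#> 2 not_impaired             63             26  2.43 7.60e-05 0.369 ***
```

The simulator's default damaging-PTV carrier shift is 0.6 SD; the
pipeline recovers liability effects of that order from the ascertained
counts, larger in the impaired stratum where the scaled prevalence is
lower. `autoplot()` on a pipeline result draws the liability forest
plot; on a simulated cohort it shows the latent liabilities against the
sex thresholds.

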