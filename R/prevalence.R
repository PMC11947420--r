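#' Sex-specific prevalence specification
#'
#' Bundles the population parameters of the different-threshold liability
#' model: the male prevalence, the male:female prevalence ratio (or an
#' explicit female prevalence), per-sex liability variances, and optional
#' within-sex subgroup proportions used to scale prevalences for phenotype
#' strata (e.g. the fraction of autistic probands with cognitive impairment).
#'
#' The defaults encode an autism population prevalence of 2.5% in males
#' (1 in 40) with a 4:1 male-to-female prevalence ratio and unit liability
#' variance in both sexes.
#'
#' @param male_prevalence Trait prevalence in males, a proportion in (0,1).
#' @param sex_ratio Male:female prevalence ratio, a positive real. Ignored
#'   when `female_prevalence` is given directly.
#' @param female_prevalence Optional explicit female prevalence.
#' @param male_variance,female_variance Liability variances per sex
#'   (default 1: the standard equal-variance model).
#' @param subgroup_proportion_male,subgroup_proportion_female Optional
#'   proportions in (0,1] of affected individuals of each sex carrying a
#'   phenotypic feature; used by [subgroup_prevalence()]-style scaling.
#' @return An object of class `prevalence_spec`.
#' @examples
#' spec <- prevalence_spec(male_prevalence = 0.025, sex_ratio = 4)
#' tidy(spec)
#' @export
prevalence_spec <- function(male_prevalence = 0.025, sex_ratio = 4,
                            female_prevalence = NULL,
                            male_variance = 1, female_variance = 1,
                            subgroup_proportion_male = NULL,
                            subgroup_proportion_female = NULL) {
  check_proportion(male_prevalence, "male_prevalence")
  if (is.null(female_prevalence)) {
    female_prevalence <- female_prevalence_from_ratio(male_prevalence, sex_ratio)
  } else {
    check_proportion(female_prevalence, "female_prevalence")
    sex_ratio <- male_prevalence / female_prevalence
  }
  if (!is.finite(male_variance) || male_variance <= 0 ||
      !is.finite(female_variance) || female_variance <= 0) {
    stop_domain("liability variances must be positive")
  }
  for (p in c(subgroup_proportion_male, subgroup_proportion_female)) {
    if (!is.null(p)) check_proportion(p, "subgroup proportion", open_high = FALSE)
  }
  structure(
    list(
      male_prevalence = male_prevalence,
      female_prevalence = female_prevalence,
      male_to_female_ratio = sex_ratio,
      male_variance = male_variance,
      female_variance = female_variance,
      subgroup_proportion_male = subgroup_proportion_male,
      subgroup_proportion_female = subgroup_proportion_female
    ),
    class = "prevalence_spec"
  )
}

#' @export
print.prevalence_spec <- function(x, ...) {
  cat("<prevalence_spec>\n")
  cat(sprintf("  male:   K = %.5g (variance %.3g)\n",
              x$male_prevalence, x$male_variance))
  cat(sprintf("  female: K = %.5g (variance %.3g, ratio %.3g:1)\n",
              x$female_prevalence, x$male_to_female_ratio, x$female_variance))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.prevalence_spec <- function(x, ...) {
  tibble(
    sex = c("female", "male"),
    prevalence = c(x$female_prevalence, x$male_prevalence),
    variance = c(x$female_variance, x$male_variance),
    threshold_standardized = qnorm(c(x$female_prevalence, x$male_prevalence),
                                   lower.tail = FALSE),
    threshold_raw = sqrt(c(x$female_variance, x$male_variance)) *
      qnorm(c(x$female_prevalence, x$male_prevalence), lower.tail = FALSE),
    subgroup_proportion = c(
      x$subgroup_proportion_female %||% NA_real_,
      x$subgroup_proportion_male %||% NA_real_
    )
  )
}

#' Female prevalence from the male prevalence and the sex ratio
#'
#' With a male:female prevalence ratio of r, the female prevalence is the
#' male prevalence divided by r (e.g. 2.5% / 4 = 0.625%).
#'
#' @param male_prevalence Proportion in (0,1).
#' @param ratio Male:female prevalence ratio, positive.
#' @return The female prevalence, a proportion.
#' @examples
#' female_prevalence_from_ratio(0.025, 4) # 0.00625
#' @export
female_prevalence_from_ratio <- function(male_prevalence, ratio) {
  check_proportion(male_prevalence, "male_prevalence")
  if (any(!is.finite(ratio) | ratio <= 0)) {
    stop_domain("`ratio` must be a positive real")
  }
  out <- male_prevalence / ratio
  check_proportion(out, "derived female prevalence")
  out
}

#' Scale a sex-specific prevalence into phenotype subgroups
#'
#' Splits a sex-specific trait prevalence into the prevalence of the trait
#' *with* a co-occurring feature (the product of the prevalence and the
#' observed within-trait feature proportion) and the complementary
#' prevalence *without* it, so the two subgroup prevalences sum to the
#' parent prevalence. This is how phenotype-stratified liability analyses
#' obtain, e.g., a prevalence of autism-with-cognitive-impairment of
#' 0.58% in males from 23% x 2.5%.
#'
#' @param sex_prevalence Parent prevalence, proportion in (0,1].
#' @param proportion_with_feature Observed fraction of affected individuals
#'   with the feature, proportion in (0,1].
#' @return A tibble with columns `featured` and `complement` (one row per
#'   input element).
#' @examples
#' subgroup_prevalence(0.025, 0.23) # featured ~ 0.58%
#' @export
subgroup_prevalence <- function(sex_prevalence, proportion_with_feature) {
  check_proportion(sex_prevalence, "sex_prevalence", open_high = FALSE)
  check_proportion(proportion_with_feature, "proportion_with_feature",
                   open_high = FALSE)
  featured <- sex_prevalence * proportion_with_feature
  tibble(featured = featured, complement = sex_prevalence - featured)
}
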