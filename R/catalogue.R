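#' The catalogue of reported models
#'
#' Declarative specifications of the seventeen Bayesian mixed-effects
#' models of the analysis: five within-culture UK models, five
#' within-culture Japanese models, and seven cross-culture models. Accuracy
#' models use dummy coding with reference levels non-autistic (group), UK
#' (culture) and mental (condition); mean-jerk models JPUK.4-6 are fit to
#' the z-standardised per-animation mean jerk; the jerk-variability model
#' JPUK.7 is fit to the per-cell-per-word CV with a random intercept for
#' word. Models with a jerk-difference covariate use random intercepts for
#' subject and animation and random slopes varying by subject; the pure
#' group models use random intercepts and slopes for both subject and
#' animation.
#'
#' @param jerk_prior c(mean, sd) of the informative normal prior on the
#'   jerk-difference slope (zero-centred priors everywhere else). The
#'   default centre of -2.5 score units per SD encodes the negative
#'   movement-similarity effect found in earlier work with this task; both
#'   numbers are configuration parameters, not estimates.
#' @param slopes "main" (default) gives random slopes for main-effect
#'   predictor columns; "full" for every fixed-effect column.
#' @param accuracy_priors,jerk_priors,cv_priors [prior_set()]s for the
#'   three response scales.
#' @return Named list of 17 [model_spec()]s.
#' @export
model_catalogue <- function(jerk_prior = c(mean = -2.5, sd = 1.5),
                            slopes = "main",
                            accuracy_priors = prior_set(coef_scale = 10,
                                                        intercept_scale = 50,
                                                        sd_scale = 5),
                            jerk_priors = prior_set(coef_scale = 2.5,
                                                    intercept_scale = 2.5,
                                                    sd_scale = 2.5),
                            cv_priors = prior_set(coef_scale = 2.5,
                                                  intercept_scale = 2.5,
                                                  sd_scale = 2.5)) {
  inf <- list(z_jerk_difference = unname(jerk_prior))
  jd_priors <- prior_set(coef_scale = accuracy_priors$coef_scale,
                         intercept_scale = accuracy_priors$intercept_scale,
                         sd_scale = accuracy_priors$sd_scale,
                         informative = inf)
  zcov <- c(z_jerk_difference = "jerk_difference")

  both_re <- list(
    list(group = "observer_id", intercept = TRUE, slopes = slopes),
    list(group = "animation_id", intercept = TRUE, slopes = slopes))
  subj_slope_re <- list(
    list(group = "observer_id", intercept = TRUE, slopes = slopes),
    list(group = "animation_id", intercept = TRUE, slopes = "none"))
  gen_re <- list(
    list(group = "generator_id", intercept = TRUE, slopes = c("group")))

  uk <- list(observer_culture = "UK", generator_culture = "UK")
  jp <- list(observer_culture = "JP", generator_culture = "JP")
  mental <- list(condition = "mental")

  specs <- list(
    UK.1 = model_spec("UK.1", "accuracy",
                      "generator_group * observer_group",
                      filter = c(uk, mental), random = both_re,
                      priors = accuracy_priors),
    UK.2 = model_spec("UK.2", "accuracy",
                      "generator_group * observer_group * condition",
                      filter = uk, random = both_re,
                      priors = accuracy_priors),
    UK.3 = model_spec("UK.3", "accuracy",
                      "z_jerk_difference * condition",
                      filter = uk, random = subj_slope_re,
                      priors = jd_priors, z_covariates = zcov),
    UK.4 = model_spec("UK.4", "accuracy",
                      "z_jerk_difference * condition * observer_group",
                      filter = uk, random = subj_slope_re,
                      priors = jd_priors, z_covariates = zcov),
    UK.5 = model_spec("UK.5", "accuracy",
                      "z_jerk_difference * condition * generator_group",
                      filter = uk, random = subj_slope_re,
                      priors = jd_priors, z_covariates = zcov),
    JP.1 = model_spec("JP.1", "accuracy",
                      "generator_group * observer_group",
                      filter = c(jp, mental), random = both_re,
                      priors = accuracy_priors),
    JP.2 = model_spec("JP.2", "accuracy",
                      "generator_group * observer_group * condition",
                      filter = jp, random = both_re,
                      priors = accuracy_priors),
    JP.3 = model_spec("JP.3", "accuracy",
                      "z_jerk_difference * condition",
                      filter = jp, random = subj_slope_re,
                      priors = jd_priors, z_covariates = zcov),
    JP.4 = model_spec("JP.4", "accuracy",
                      "z_jerk_difference * condition * observer_group",
                      filter = jp, random = subj_slope_re,
                      priors = jd_priors, z_covariates = zcov),
    JP.5 = model_spec("JP.5", "accuracy",
                      "z_jerk_difference * condition * generator_group",
                      filter = jp, random = subj_slope_re,
                      priors = jd_priors, z_covariates = zcov),
    JPUK.1 = model_spec("JPUK.1", "accuracy",
                        "z_jerk_difference * condition * observer_culture",
                        random = subj_slope_re,
                        priors = jd_priors, z_covariates = zcov),
    JPUK.2 = model_spec("JPUK.2", "accuracy",
                        paste("z_jerk_difference * condition *",
                              "observer_culture * observer_group"),
                        random = subj_slope_re,
                        priors = jd_priors, z_covariates = zcov),
    JPUK.3 = model_spec("JPUK.3", "accuracy",
                        "condition * observer_culture * generator_culture",
                        filter = list(observer_group = "aut",
                                      generator_group = "aut"),
                        random = both_re, priors = accuracy_priors),
    JPUK.4 = model_spec("JPUK.4", "z_mean_jerk", "group",
                        data = "animations", random = gen_re,
                        priors = jerk_priors),
    JPUK.5 = model_spec("JPUK.5", "z_mean_jerk", "group * word",
                        data = "animations", random = gen_re,
                        priors = jerk_priors),
    JPUK.6 = model_spec("JPUK.6", "z_mean_jerk", "group * word * culture",
                        data = "animations", random = gen_re,
                        priors = jerk_priors),
    JPUK.7 = model_spec("JPUK.7", "cv", "group * culture",
                        data = "cv",
                        random = list(list(group = "word", intercept = TRUE,
                                           slopes = "none")),
                        priors = cv_priors)
  )
  specs
}

#' Reduced model used for parameter-recovery simulations
#'
#' Mirrors the generative model of [simulate_ratings()]: generator group x
#' observer group on mental-state trials, random intercepts for subject and
#' animation and a generator-group slope by subject.
#'
#' @param priors Priors (accuracy scale).
#' @return A [model_spec()].
#' @export
recovery_model_spec <- function(priors = prior_set(coef_scale = 10,
                                                   intercept_scale = 50,
                                                   sd_scale = 5)) {
  model_spec("recovery", "accuracy", "generator_group * observer_group",
             filter = list(condition = "mental"),
             random = list(
               list(group = "observer_id", intercept = TRUE,
                    slopes = c("generator_group")),
               list(group = "animation_id", intercept = TRUE,
                    slopes = "none")),
             priors = priors)
}
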