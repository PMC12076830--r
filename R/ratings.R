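#' Ground-truth effect structure for simulated ratings
#'
#' Parameters of the generative model for latent trial accuracy (target
#' rating minus mean non-target rating, score units on the -100..100
#' scale):
#'
#' accuracy = baseline
#'          + beta_generator_group  * [generator autistic]
#'          + beta_observer_group   * [observer autistic]
#'          + beta_interaction      * [both autistic]
#'          + beta_mental_state     * [condition non-mental]
#'          + beta_jerk_difference  * z(jerk difference)
#'          + subject intercept + subject slope on generator group
#'          + animation intercept + residual
#'
#' The default effect sizes reflect the magnitudes the analysis is designed
#' to detect: an own-group advantage of non-autistic observers for
#' non-autistic-generated animations (negative generator-group effect) and
#' a negative jerk-difference (movement-similarity) slope.
#'
#' @param baseline_accuracy Intercept, score units.
#' @param beta_generator_group,beta_observer_group,beta_interaction Fixed
#'   group effects (dummy coding, reference non-autistic), score units.
#' @param beta_mental_state Effect of the non-mental condition vs mental.
#' @param beta_jerk_difference Slope per SD of jerk difference.
#' @param sd_subject_intercept,sd_animation_intercept,sd_subject_slopes
#'   Random-effect SDs, score units.
#' @param sd_residual Trial-level residual SD.
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(baseline_accuracy = 20,
                        beta_generator_group = -8,
                        beta_observer_group = -3,
                        beta_interaction = 3,
                        beta_mental_state = -5,
                        beta_jerk_difference = -2,
                        sd_subject_intercept = 8,
                        sd_animation_intercept = 6,
                        sd_subject_slopes = 3,
                        sd_residual = 15) {
  sds <- c(sd_subject_intercept, sd_animation_intercept, sd_subject_slopes,
           sd_residual)
  if (any(sds < 0)) stop_config("random-effect and residual sds must be >= 0")
  structure(as.list(environment()), class = "effect_spec")
}

#' Simulate visual-analogue ratings for assembled sessions
#'
#' Draws each trial's latent accuracy from the generative model in
#' [effect_spec()], then constructs six 0-100 ratings so that the accuracy
#' statistic (target minus mean non-target) recovers the latent value
#' exactly before clipping: the target word gets `50 + accuracy/2`, every
#' non-target `50 - accuracy/2`.
#'
#' @param sessions Output of [assemble_rating_sessions()].
#' @param animations The `animation_set` rated.
#' @param design The `study_design`.
#' @param effects An [effect_spec()].
#' @param kinematics List with `animation_jerk` (animation_id, mean_jerk)
#'   and `observer_jerk` (participant_id, word, mean_jerk) as produced by
#'   [kinematic_summaries()] and [observer_word_jerk()].
#' @param seed RNG seed; defaults to the study's rating stream.
#' @return Data frame of rating trials: `observer_id, animation_id` plus one
#'   0-100 column per word. The latent trial table (with the injected
#'   accuracy and covariates) is attached as attribute `"latent"`.
#' @export
simulate_ratings <- function(sessions, animations, design, effects,
                             kinematics, seed = NULL) {
  stopifnot(inherits(effects, "effect_spec"),
            inherits(design, "study_design"))
  if (is.null(seed)) seed <- derive_seed(design$config$seed, "ratings")
  anims <- animations$animations
  unknown <- setdiff(sessions$animation_id, anims$animation_id)
  if (length(unknown))
    stop_config("unknown animation_id in sessions: %s",
                paste(utils::head(unknown, 3), collapse = ", "))

  parts <- design$participants
  tr <- merge(sessions,
              anims[, c("animation_id", "generator_id", "condition")],
              by = c("animation_id", "generator_id"))
  tr <- merge(tr, stats::setNames(parts, c("observer_id", "observer_culture",
                                           "observer_group")),
              by = "observer_id")
  tr <- merge(tr, stats::setNames(parts, c("generator_id",
                                           "generator_culture",
                                           "generator_group")),
              by = "generator_id")

  jd <- jerk_difference_table(kinematics$observer_jerk,
                              kinematics$animation_jerk, tr)
  tr <- merge(tr, jd, by = c("observer_id", "animation_id", "word"))
  tr <- tr[order(tr$observer_id, tr$animation_id), ]

  with_seed(seed, {
    obs_ids <- sort(unique(tr$observer_id))
    anim_ids <- sort(unique(tr$animation_id))
    u_subj <- stats::setNames(
      stats::rnorm(length(obs_ids), 0, effects$sd_subject_intercept), obs_ids)
    u_anim <- stats::setNames(
      stats::rnorm(length(anim_ids), 0, effects$sd_animation_intercept),
      anim_ids)
    u_slope <- stats::setNames(
      stats::rnorm(length(obs_ids), 0, effects$sd_subject_slopes), obs_ids)

    gen_aut <- as.integer(tr$generator_group == "aut")
    obs_aut <- as.integer(tr$observer_group == "aut")
    non_mental <- as.integer(tr$condition == "non_mental")

    latent <- effects$baseline_accuracy +
      effects$beta_generator_group * gen_aut +
      effects$beta_observer_group * obs_aut +
      effects$beta_interaction * gen_aut * obs_aut +
      effects$beta_mental_state * non_mental +
      effects$beta_jerk_difference * tr$z_jerk_difference +
      u_subj[tr$observer_id] + u_anim[tr$animation_id] +
      u_slope[tr$observer_id] * gen_aut +
      stats::rnorm(nrow(tr), 0, effects$sd_residual)
    latent <- unname(latent)

    words <- design$words$word
    ratings <- matrix(rep(50 - latent / 2, length(words)),
                      ncol = length(words),
                      dimnames = list(NULL, words))
    for (w in words) {
      hit <- tr$word == w
      ratings[hit, w] <- 50 + latent[hit] / 2
    }
    ratings <- pmin(pmax(ratings, 0), 100)

    out <- data.frame(observer_id = tr$observer_id,
                      animation_id = tr$animation_id,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(ratings))
    tr$latent_accuracy <- latent
    attr(out, "latent") <- tr
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Runs every generation-phase stage in order (design, trajectories,
#' sessions, kinematic summaries, ratings), each on its own seed stream
#' derived from the study seed, so identical seeds give byte-identical
#' studies.
#'
#' @param config A [design_config()].
#' @param effects An [effect_spec()].
#' @param profiles A [kinematic_profiles()] object.
#' @return List of class `synthetic_study` with the design, animation set,
#'   sessions, kinematic tables and rating trials.
#' @export
simulate_study <- function(config = design_config(),
                           effects = effect_spec(),
                           profiles = kinematic_profiles()) {
  design <- make_design(config)
  animations <- simulate_generation_phase(design, profiles)
  sessions <- assemble_rating_sessions(design, animations)
  kin <- list(animation_jerk = kinematic_summaries(animations),
              observer_jerk = observer_word_jerk(animations))
  ratings <- simulate_ratings(sessions, animations, design, effects, kin)
  structure(list(design = design, animations = animations,
                 sessions = sessions, kinematics = kin, ratings = ratings,
                 effects = effects),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d participants, %d animations, %d rating trials\n",
    nrow(x$design$participants), nrow(x$animations$animations),
    nrow(x$ratings)))
  invisible(x)
}
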