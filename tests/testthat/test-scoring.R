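words6 <- default_words()$word

test_that("trial accuracy reproduces hand-computed cases", {
  r <- setNames(c(100, 0, 0, 0, 0, 0), words6)
  expect_equal(trial_accuracy(r, "arguing"), 100)
  expect_equal(trial_accuracy(setNames(rep(37, 6), words6), "teasing"), 0)
  r2 <- setNames(c(80, 10, 20, 30, 40, 50), words6)
  expect_equal(trial_accuracy(r2, "arguing"), 50)
  # target a, uniform non-targets b: accuracy = a - b
  r3 <- setNames(c(70, rep(15, 5)), words6)
  expect_equal(trial_accuracy(r3, "arguing"), 55)
  # adding a constant to all ratings leaves accuracy unchanged
  expect_equal(trial_accuracy(r2 + 7, "arguing"),
               trial_accuracy(r2, "arguing"))
})

test_that("trial accuracy validates its input", {
  r <- setNames(c(80, 10, 20, 30, 40, 50), words6)
  expect_error(trial_accuracy(r, "waltzing"), "not among")
  r[2] <- 250
  expect_error(trial_accuracy(r, "arguing"), "0, 100")
  expect_error(trial_accuracy(r[1:5], "arguing"), "6 values")
})

test_that("noise-free synthetic ratings recover the latent accuracy
           exactly", {
  eff <- effect_spec(baseline_accuracy = 18, beta_generator_group = -8,
                     beta_observer_group = -3, beta_interaction = 3,
                     beta_mental_state = -5, beta_jerk_difference = -2,
                     sd_subject_intercept = 0, sd_animation_intercept = 0,
                     sd_subject_slopes = 0, sd_residual = 0)
  study <- small_study(seed = 19, effects = eff)
  latent <- attr(study$ratings, "latent")
  scored <- score_trials(study$ratings, study$animations,
                         study$design$participants)
  m <- merge(scored, latent[, c("observer_id", "animation_id",
                                "latent_accuracy")],
             by = c("observer_id", "animation_id"))
  expect_equal(m$accuracy, m$latent_accuracy, tolerance = 1e-9)
})

test_that("scored accuracy equals the latent value wherever no clipping
           occurred", {
  study <- small_study()
  latent <- attr(study$ratings, "latent")
  scored <- score_trials(study$ratings, study$animations,
                         study$design$participants)
  m <- merge(scored, latent[, c("observer_id", "animation_id",
                                "latent_accuracy")],
             by = c("observer_id", "animation_id"))
  ok <- abs(m$latent_accuracy) <= 100
  expect_gt(mean(ok), 0.95)
  expect_equal(m$accuracy[ok], m$latent_accuracy[ok], tolerance = 1e-9)
})

test_that("ratings honour the 0-100 clipping contract", {
  eff <- effect_spec(baseline_accuracy = 90, sd_residual = 60)
  study <- small_study(seed = 23, effects = eff)
  r <- as.matrix(study$ratings[, words6])
  expect_true(all(r >= 0 & r <= 100))
})

test_that("the model table is a lossless one-row-per-trial join", {
  study <- small_study()
  tabs <- small_tables()
  expect_equal(nrow(tabs$trials), nrow(study$sessions))
  expect_equal(nrow(tabs$trials),
               nrow(study$design$participants) * 48)
  mental <- tabs$trials[tabs$trials$condition == "mental", ]
  expect_equal(nrow(mental), nrow(tabs$trials) / 2)
  key <- paste(tabs$trials$observer_id, tabs$trials$animation_id)
  expect_false(anyDuplicated(key) > 0)

  # orphaned keys error
  acc <- score_trials(study$ratings, study$animations,
                      study$design$participants)
  jd <- jerk_difference_table(study$kinematics$observer_jerk,
                              study$kinematics$animation_jerk,
                              study$sessions)
  expect_error(build_model_table(acc[-1, ], jd,
                                 study$design$participants),
               "unmatched trial keys")
})

test_that("degenerate effect spec gives constant latent accuracy and a
           large injected effect moves cell means accordingly", {
  eff0 <- effect_spec(baseline_accuracy = 12, beta_generator_group = 0,
                      beta_observer_group = 0, beta_interaction = 0,
                      beta_mental_state = 0, beta_jerk_difference = 0,
                      sd_subject_intercept = 0, sd_animation_intercept = 0,
                      sd_subject_slopes = 0, sd_residual = 0)
  study0 <- small_study(seed = 31, effects = eff0)
  latent0 <- attr(study0$ratings, "latent")
  expect_equal(latent0$latent_accuracy, rep(12, nrow(latent0)),
               tolerance = 1e-12)

  # naive cell-mean difference recovers the injected generator-group
  # effect within Monte-Carlo error (> 5000 trials)
  eff <- effect_spec(beta_generator_group = -8, beta_interaction = 0)
  study <- simulate_study(design_config(n_per_cell = 9, seed = 37),
                          eff, small_profiles())
  latent <- attr(study$ratings, "latent")
  expect_gt(nrow(latent), 5000)
  # per-observer generator-group difference: subject effects cancel, and
  # with a zero interaction the effect is common to all observers
  d_o <- tapply(seq_len(nrow(latent)), latent$observer_id, function(i) {
    g <- latent$generator_group[i] == "aut"
    mean(latent$latent_accuracy[i][g]) -
      mean(latent$latent_accuracy[i][!g])
  })
  n_anim_per_group <- length(unique(latent$animation_id)) / 2
  # observer-level scatter plus the shared animation-level component
  se <- sqrt(var(d_o) / length(d_o) + 2 * 6^2 / n_anim_per_group)
  expect_lt(abs(mean(d_o) - (-8)), 3 * se)
})
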