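test_that("the crossed design has balanced culture x group cells", {
  d <- make_design(design_config(n_per_cell = 15))
  expect_equal(nrow(d$participants), 60)
  cells <- table(d$participants$culture, d$participants$group)
  expect_true(all(cells == 15))
  expect_false(anyDuplicated(d$participants$participant_id) > 0)

  w <- d$words
  expect_equal(nrow(w), 6)
  expect_equal(as.vector(table(w$condition)), c(3, 3))
})

test_that("identical seeds give identical designs and studies", {
  d1 <- make_design(design_config(n_per_cell = 3, seed = 42))
  d2 <- make_design(design_config(n_per_cell = 3, seed = 42))
  expect_identical(d1, d2)

  s1 <- simulate_study(small_config(seed = 11), profiles = small_profiles())
  s2 <- simulate_study(small_config(seed = 11), profiles = small_profiles())
  expect_identical(s1$ratings, s2$ratings)
  expect_identical(s1$animations$trajectories, s2$animations$trajectories)
  expect_identical(s1$sessions, s2$sessions)
})

test_that("invalid word lists are rejected", {
  five <- default_words()[1:5, ]
  expect_error(design_config(words = five), "6 distinct words")
  unbal <- default_words()
  unbal$condition <- c("mental", "mental", "mental", "mental",
                       "non_mental", "non_mental")
  expect_error(design_config(words = unbal), "balanced")
  expect_error(design_config(n_per_cell = 0), "positive")
})

test_that("rating sessions are balanced over word x generator cells and
           exclude the observer's own animations", {
  study <- small_study()
  sess <- study$sessions
  cfg <- study$design$config
  anims <- merge(sess, study$animations$animations,
                 by = c("animation_id", "generator_id", "word"))
  anims <- merge(anims,
                 setNames(study$design$participants,
                          c("generator_id", "generator_culture",
                            "generator_group")),
                 by = "generator_id")

  per_obs <- table(sess$observer_id)
  expect_true(all(per_obs == 6 * 2 * 2 * cfg$animations_per_cell))

  counts <- table(anims$observer_id, anims$word,
                  anims$generator_culture, anims$generator_group)
  expect_true(all(counts == cfg$animations_per_cell))

  expect_false(any(anims$observer_id == anims$generator_id))
})

test_that("pool exhaustion raises an error naming the deficient cell", {
  cfg <- design_config(n_per_cell = 4, animations_per_cell = 6, seed = 1)
  d <- make_design(cfg)
  a <- simulate_generation_phase(d, small_profiles())
  expect_error(assemble_rating_sessions(d, a), "pool exhausted.*available")
})

test_that("generation phase yields one animation per participant x word", {
  study <- small_study()
  a <- study$animations$animations
  expect_equal(nrow(a), nrow(study$design$participants) * 6)
  expect_true(all(table(a$generator_id) == 6))
  expect_identical(sort(unique(a$word)), sort(default_words()$word))
  # condition is consistent with the word's triad
  m <- merge(a, default_words(), by = "word")
  expect_true(all(as.character(m$condition.x) == as.character(m$condition.y)))
})

test_that("missing cell profiles are a configuration error", {
  d <- make_design(small_config())
  prof <- small_profiles()
  prof[["UK.aut"]] <- NULL
  expect_error(simulate_generation_phase(d, prof), "UK.aut")
})
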