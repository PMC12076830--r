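test_that("finite-difference derivatives vanish for constant and
           sub-cubic polynomial trajectories", {
  const <- analytic_trajectory(function(t) rep(0.4, length(t)))
  for (k in 1:3) {
    d <- differentiate(const, order = k)
    expect_lt(max(abs(d$dx)), 1e-9)
    expect_lt(max(abs(d$dy)), 1e-9)
  }
  quad <- analytic_trajectory(function(t) 0.1 * t^2)
  j <- differentiate(quad, order = 3)
  expect_lt(max(abs(j$dx)), 1e-6)
})

test_that("jerk of x(t) = t^3 matches the analytic third derivative", {
  cub <- analytic_trajectory(function(t) t^3 / 8, duration = 2)
  j <- differentiate(cub, order = 3)
  j1 <- j[j$triangle_id == 1, ]
  # d3/dt3 (t^3/8) = 6/8
  expect_true(all(abs(j1$dx - 6 / 8) / (6 / 8) < 1e-3))
  # derivative series shrinks by 2 samples per order
  expect_equal(nrow(j1), 120 - 6)
})

test_that("finite-difference jerk error shrinks as the sampling rate
           grows", {
  err_at <- function(rate) {
    tr <- analytic_trajectory(function(t) 0.2 * sin(2 * pi * t),
                              duration = 2, rate = rate)
    j <- differentiate(tr, order = 3)
    j1 <- j[j$triangle_id == 1, ]
    truth <- -0.2 * (2 * pi)^3 * cos(2 * pi * j1$t)
    max(abs(j1$dx - truth))
  }
  errs <- vapply(c(30, 60, 120), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("mean jerk averages the two triangles and respects rigid
           motion and scaling", {
  # triangle 1 with constant jerk magnitude 6 (x = t^3), triangle 2 static
  cub <- analytic_trajectory(function(t) t^3, duration = 2)
  expect_equal(mean_jerk(cub), 3, tolerance = 1e-6)

  set.seed(9)
  tr <- simulate_trajectory(trajectory_params(duration = 2,
                                              n_submovements = 4), 60)
  shifted <- tr
  shifted$x <- shifted$x + 0.1
  shifted$y <- shifted$y - 0.07
  expect_equal(mean_jerk(shifted), mean_jerk(tr), tolerance = 1e-9)

  scaled <- tr
  scaled$x <- scaled$x * 2
  scaled$y <- scaled$y * 2
  expect_equal(mean_jerk(scaled), 2 * mean_jerk(tr), tolerance = 1e-9)
})

test_that("differentiate validates sampling and sample count", {
  tr <- analytic_trajectory(function(t) t, duration = 2)
  bad <- tr
  bad$t[5] <- bad$t[5] + 0.01
  expect_error(differentiate(bad, 3), "non-uniform")
  short <- tr[tr$t < 3 / 60, ]
  expect_error(differentiate(short, 3), "too few samples")
})

test_that("jerk differences follow the absolute-difference contract", {
  own <- data.frame(participant_id = c("p1", "p1"), word = c("arguing",
                                                             "dancing"),
                    mean_jerk = c(5, 2))
  anim <- data.frame(animation_id = c("a1", "a2"), mean_jerk = c(2, 2))
  sess <- data.frame(observer_id = "p1", animation_id = c("a1", "a2"),
                     word = c("arguing", "dancing"))
  jd <- jerk_difference_table(own, anim, sess)
  expect_equal(sort(jd$jerk_difference), c(0, 3))

  # swapping own and animation jerk leaves the magnitude unchanged
  own2 <- own; own2$mean_jerk <- c(2, 2)
  anim2 <- anim; anim2$mean_jerk <- c(5, 2)
  jd2 <- jerk_difference_table(own2, anim2, sess)
  expect_equal(jd2$jerk_difference, jd$jerk_difference)

  expect_error(
    jerk_difference_table(own[1, ], anim, sess),
    "missing own-animation jerk")
})

test_that("jerk-difference table covers every trial and standardises to
           mean 0, sd 1", {
  study <- small_study()
  jd <- jerk_difference_table(study$kinematics$observer_jerk,
                              study$kinematics$animation_jerk,
                              study$sessions)
  expect_equal(nrow(jd), nrow(study$sessions))
  expect_true(all(jd$jerk_difference >= 0))
  expect_lt(abs(mean(jd$z_jerk_difference)), 1e-9)
  expect_lt(abs(sd(jd$z_jerk_difference) - 1), 1e-9)
})

test_that("jerk CV reproduces hand-computed cases and the per-cell
           record count", {
  mk_set <- function(jerks) {
    n <- length(jerks)
    anims <- data.frame(
      animation_id = paste0("a", 1:n),
      generator_id = paste0("p", 1:n),
      word = "arguing", condition = "mental")
    parts <- data.frame(participant_id = paste0("p", 1:n),
                        culture = "UK", group = "aut")
    aset <- structure(list(animations = anims), class = "animation_set")
    jerk_cv(data.frame(animation_id = paste0("a", 1:n), mean_jerk = jerks),
            aset, parts)
  }
  expect_equal(mk_set(c(1, 3))$cv, sqrt(2) / 2, tolerance = 1e-9)
  expect_equal(mk_set(c(4, 4, 4))$cv, 0)
  expect_error(mk_set(1), "fewer than 2")

  study <- small_study()
  cv <- jerk_cv(study$kinematics$animation_jerk, study$animations,
                study$design$participants)
  expect_equal(nrow(cv), 24)
  expect_true(all(table(cv$culture, cv$group) == 6))
  expect_true(all(cv$cv >= 0))
})
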