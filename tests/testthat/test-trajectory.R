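test_that("trajectories have the configured sample count and spacing", {
  p <- trajectory_params(duration = 2, n_submovements = 3)
  set.seed(1)
  tr <- simulate_trajectory(p, sampling_rate = 60)
  expect_equal(sum(tr$triangle_id == 1), 120)
  expect_equal(sum(tr$triangle_id == 2), 120)
  dt <- diff(tr$t[tr$triangle_id == 1])
  expect_equal(dt, rep(1 / 60, 119), tolerance = 1e-12)
  expect_true(all(tr$x >= 0 & tr$x <= 1 & tr$y >= 0 & tr$y <= 1))
})

test_that("too-short trajectories are rejected", {
  expect_error(simulate_trajectory(trajectory_params(duration = 0.1), 60),
               "too short")
})

test_that("a single noise-free submovement is smooth with a bell-shaped
           speed profile", {
  p <- trajectory_params(duration = 2, n_submovements = 1,
                         submovement_amplitude_sd = 0.2, noise_sd = 0)
  set.seed(3)
  tr <- simulate_trajectory(p, 60)
  v <- differentiate(tr, order = 1)
  v1 <- v[v$triangle_id == 1, ]
  speed <- sqrt(v1$dx^2 + v1$dy^2)
  # near-zero speed at both ends, maximum in the interior
  expect_lt(speed[1], max(speed) / 10)
  expect_lt(speed[length(speed)], max(speed) / 10)
  expect_gt(which.max(speed) / length(speed), 0.2)
  expect_lt(which.max(speed) / length(speed), 0.8)
  expect_true(is.finite(mean_jerk(tr)))
})

test_that("mean jerk is non-decreasing in submovement count", {
  levels <- c(3, 6, 12)
  mean_by_level <- vapply(levels, function(ns) {
    set.seed(100 + ns)
    mean(replicate(40, {
      p <- trajectory_params(duration = 2, n_submovements = ns,
                             submovement_amplitude_sd = 0.15)
      mean_jerk(simulate_trajectory(p, 60))
    }))
  }, numeric(1))
  expect_true(all(diff(mean_by_level) > 0))
})

test_that("cell dispersion controls between-generator jerk variability", {
  cv_for <- function(disp_ukaut, seed) {
    cfg <- design_config(n_per_cell = 6, seed = seed)
    d <- make_design(cfg)
    prof <- small_profiles(dispersion = c(UK.aut = disp_ukaut,
                                          UK.non_aut = 0.2, JP.aut = 0.2,
                                          JP.non_aut = 0.2))
    a <- simulate_generation_phase(d, prof)
    cv <- jerk_cv(kinematic_summaries(a), a, d$participants)
    c(ukaut = mean(cv$cv[cv$culture == "UK" & cv$group == "aut"]),
      uknon = mean(cv$cv[cv$culture == "UK" & cv$group == "non_aut"]))
  }
  # doubled spread in the UK-autistic cell: higher CV than UK non-autistic
  # in the clear majority of replicates
  res <- vapply(1:5, function(s) cv_for(0.6, s), numeric(2))
  expect_gte(sum(res["ukaut", ] > res["uknon", ]), 4)
})

test_that("zero dispersion makes a cell's generators kinematically
           homogeneous relative to a dispersed cell", {
  cfg <- design_config(n_per_cell = 8, seed = 5)
  d <- make_design(cfg)
  prof <- small_profiles(dispersion = c(UK.aut = 0.8, UK.non_aut = 0,
                                        JP.aut = 0, JP.non_aut = 0))
  a <- simulate_generation_phase(d, prof)
  kj <- kinematic_summaries(a)
  cv <- jerk_cv(kj, a, d$participants)
  expect_gt(mean(cv$cv[cv$culture == "UK" & cv$group == "aut"]),
            mean(cv$cv[cv$culture == "UK" & cv$group == "non_aut"]))
})
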