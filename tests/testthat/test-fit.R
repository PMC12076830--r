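# Minimal spec helpers for fitting arbitrary data frames
flat_spec <- function(fixed, response = "y", priors = prior_set(
                        coef_scale = 10, intercept_scale = 10, sd_scale = 5))
  model_spec("flat", response, fixed, random = list(), priors = priors)

test_that("the intercept-only posterior matches the conjugate
           normal-normal closed form", {
  set.seed(101)
  n <- 500
  y <- rnorm(n, 5, 1)
  tab <- data.frame(y = y)
  fit <- fit_model(flat_spec("1"), tab, tiny_settings())
  draws <- fit$draws[, "(Intercept)"]

  # normal-normal posterior mean with the residual sd profiled at sd(y)
  s2 <- var(y)
  post_mean <- (sum(y) / s2) / (n / s2 + 1 / 10^2)
  mcse <- sd(draws) / sqrt(unname(coda::effectiveSize(
    coda::as.mcmc(draws))))
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse + 1e-3)
  expect_lt(abs(mean(draws) - post_mean), 0.05)
})

test_that("refitting with identical settings is bit-identical", {
  tab <- small_tables()$cv
  spec <- model_catalogue()$JPUK.7
  f1 <- suppressWarnings(fit_model(spec, tab, tiny_settings(seed = 3)))
  f2 <- suppressWarnings(fit_model(spec, tab, tiny_settings(seed = 3)))
  expect_identical(f1$draws, f2$draws)
  expect_identical(posterior_table(f1), posterior_table(f2))
})

test_that("posterior summaries follow their definitions", {
  const <- rep(3.2, 1000)
  s <- summarise_effect(const)
  expect_equal(s$e_mu, 3.2)
  expect_equal(s$cri_low, 3.2)
  expect_equal(s$cri_high, 3.2)

  set.seed(5)
  sym <- rnorm(20000)
  s2 <- summarise_effect(sym)
  expect_lt(abs(s2$p_negative - 0.5), 0.02)
  expect_equal(s2$p_negative + s2$p_positive, 1)
  expect_true(s2$cri_low <= s2$e_mu && s2$e_mu <= s2$cri_high)

  fit <- suppressWarnings(fit_model(model_catalogue()$JPUK.7,
                                    small_tables()$cv, tiny_settings()))
  expect_error(summarise_effect(fit, "not_a_term"), "unknown term")
})

test_that("posterior contrasts reduce to coefficients and to per-draw
           arithmetic", {
  tab <- small_tables()$trials
  spec_main <- model_spec("m", "accuracy",
                          "generator_group + observer_group",
                          random = list())
  fit <- suppressWarnings(fit_model(spec_main, tab, tiny_settings()))

  # identity contrast
  c0 <- posterior_contrast(fit, list(generator_group = "aut"),
                           list(generator_group = "aut"))
  expect_equal(c0$e_mu, 0)
  expect_equal(c0$cri_low, 0)
  expect_equal(c0$cri_high, 0)

  # in a dummy-coded main-effects model, level2 - level1 is the coefficient
  cg <- posterior_contrast(fit, list(generator_group = "aut"),
                           list(generator_group = "non_aut"))
  cf <- summarise_effect(fit, "generator_groupaut")
  expect_equal(cg$e_mu, cf$e_mu, tolerance = 1e-12)
  expect_equal(cg$cri_low, cf$cri_low, tolerance = 1e-12)

  # brute-force oracle under an interaction model: per-draw computation
  # straight from the coefficient draws
  spec_int <- model_spec("mi", "accuracy",
                         "generator_group * observer_group",
                         random = list())
  fit2 <- suppressWarnings(fit_model(spec_int, tab, tiny_settings()))
  got <- posterior_contrast(fit2, list(generator_group = "aut",
                                       observer_group = "aut"),
                            list(generator_group = "non_aut"))
  d <- fit2$draws
  cell_a <- d[, "(Intercept)"] + d[, "generator_groupaut"] +
    d[, "observer_groupaut"] + d[, "generator_groupaut:observer_groupaut"]
  cell_b <- d[, "(Intercept)"] + 0.5 * d[, "observer_groupaut"]
  manual <- summarise_effect(cell_a - cell_b)
  expect_equal(got$e_mu, manual$e_mu, tolerance = 1e-12)
  expect_equal(got$p_negative, manual$p_negative)

  expect_error(posterior_contrast(fit, list(generator_group = "bogus")),
               "absent from factor")
})

test_that("convergence diagnostics are attached and flag high Rhat", {
  fit <- fit_model(flat_spec("1"), data.frame(y = rnorm(100)),
                   tiny_settings())
  expect_true(all(c("(Intercept)", "sigma") %in%
                    names(fit$diagnostics$rhat)))
  expect_true(is.na(fit$diagnostics$divergent_transition_count))
  expect_true(all(fit$diagnostics$rhat < 1.05, na.rm = TRUE))
})
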