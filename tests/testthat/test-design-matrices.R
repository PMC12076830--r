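test_that("dummy and deviation codings follow their definitions", {
  tab <- small_tables()$trials
  spec <- model_spec("m", "accuracy",
                     "generator_group * observer_group",
                     random = list())
  dm <- build_design_matrices(spec, tab)
  X <- dm$X
  ref <- dm$data$generator_group == "non_aut" &
    dm$data$observer_group == "non_aut"
  expect_true(all(X[ref, c("generator_groupaut", "observer_groupaut",
                           "generator_groupaut:observer_groupaut")] == 0))
  # interaction column is the elementwise product, 1 only when both
  # factors are at their non-reference level
  expect_equal(X[, "generator_groupaut:observer_groupaut"],
               X[, "generator_groupaut"] * X[, "observer_groupaut"])

  wspec <- model_spec("w", "z_mean_jerk", "word", data = "animations",
                      random = list())
  wdm <- build_design_matrices(wspec, small_tables()$animations)
  wcols <- grep("^word", colnames(wdm$X), value = TRUE)
  expect_length(wcols, 5)
  lev <- levels(wdm$data$word)
  rows <- wdm$X[match(lev, as.character(wdm$data$word)), wcols]
  # deviation contrast: columns sum to 0 over the levels, omitted level -1
  expect_equal(unname(colSums(rows)), rep(0, 5))
  expect_equal(unname(rows[length(lev), ]), rep(-1, 5))
})

test_that("covariates are re-standardised within the filtered subset", {
  tab <- small_tables()$trials
  spec <- model_spec("m", "accuracy", "z_jerk_difference",
                     filter = list(observer_culture = "UK",
                                   condition = "mental"),
                     random = list(),
                     z_covariates = c(z_jerk_difference = "jerk_difference"))
  dm <- build_design_matrices(spec, tab)
  z <- dm$data$z_jerk_difference
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
  expect_true(all(as.character(dm$data$observer_culture) == "UK"))
})

test_that("the catalogue declares all seventeen reported models", {
  cat <- model_catalogue()
  expect_length(cat, 17)
  expect_setequal(names(cat),
                  c(paste0("UK.", 1:5), paste0("JP.", 1:5),
                    paste0("JPUK.", 1:7)))

  tab <- small_tables()$trials
  dm <- build_design_matrices(cat$UK.1, tab)
  expect_true(all(as.character(dm$data$condition) == "mental"))
  expect_true(all(as.character(dm$data$observer_culture) == "UK"))
  expect_true(all(as.character(dm$data$generator_culture) == "UK"))

  # JPUK.7: group x culture on jerk variability, random intercept for word
  j7 <- cat$JPUK.7
  expect_equal(j7$response, "cv")
  expect_match(j7$fixed, "group \\* culture")
  expect_equal(j7$random[[1]]$group, "word")
  dm7 <- build_design_matrices(j7, small_tables()$cv)
  expect_true("groupaut:cultureJP" %in% colnames(dm7$X))
  expect_equal(length(dm7$random[[1]]$levels), 6)

  # the informative jerk-difference prior is carried by the jerk models
  expect_equal(cat$UK.3$priors$informative$z_jerk_difference, c(-2.5, 1.5))
  expect_null(cat$UK.1$priors$informative$z_jerk_difference)
})

test_that("misdeclared models fail loudly", {
  tab <- small_tables()$trials
  bad <- model_spec("b", "accuracy", "nonexistent_column", random = list())
  expect_error(build_design_matrices(bad, tab), "absent from table")
  bad2 <- model_spec("b2", "accuracy", "generator_group",
                     filter = list(observer_culture = "FR"), random = list())
  expect_error(build_design_matrices(bad2, tab), "no rows")
})
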