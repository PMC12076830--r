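# Shared small fixtures, built in code. The small study uses 4 participants
# per cell, 2 rated animations per word x generator cell (48 trials per
# observer) and 4-second trajectories to keep the suite fast.

small_config <- function(seed = 7, n_per_cell = 4, animations_per_cell = 2) {
  design_config(n_per_cell = n_per_cell,
                animations_per_cell = animations_per_cell, seed = seed)
}

small_profiles <- function(...) kinematic_profiles(duration = 4, ...)

.study_cache <- new.env(parent = emptyenv())

small_study <- function(seed = 7, effects = effect_spec()) {
  key <- paste0("s", seed, "_", paste(unlist(effects), collapse = "_"))
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- simulate_study(small_config(seed), effects,
                                          small_profiles())
  .study_cache[[key]]
}

small_tables <- function(seed = 7) {
  key <- paste0("t", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- animent:::canonical_tables(small_study(seed))
  .study_cache[[key]]
}

tiny_settings <- function(seed = 1)
  mcmc_settings(chains = 2, iterations = 1500, warmup = 500, adapt = 300,
                seed = seed)

# Disguise a synthetic study's CSVs as externally named deposited files
# (renamed columns, recoded factor levels) to exercise mapping-driven
# ingestion.
ingestion_fixture <- function(dir, study = small_study(),
                              mangle = identity) {
  paths <- write_study(study, dir)
  anims <- read.csv(paths[["animations"]])
  anims <- merge(anims, read.csv(paths[["kinematics"]]), by = "animation_id")
  names(anims) <- c("vid", "maker", "target", "cond", "jerkval")
  anims$cond <- ifelse(anims$cond == "mental", "ToM", "GD")
  write.csv(anims, file.path(dir, "videos.csv"), row.names = FALSE)
  parts <- read.csv(paths[["participants"]])
  names(parts) <- c("pid", "country", "dx")
  parts$dx <- ifelse(parts$dx == "aut", "ASD", "TD")
  write.csv(parts, file.path(dir, "people.csv"), row.names = FALSE)
  ratings <- mangle(read.csv(paths[["ratings"]], check.names = FALSE))
  write.csv(ratings, file.path(dir, "responses.csv"), row.names = FALSE)
  list(study = study,
       paths = list(ratings = file.path(dir, "responses.csv"),
                    participants = file.path(dir, "people.csv"),
                    animations = file.path(dir, "videos.csv")))
}

ingestion_mapping <- function() {
  words <- default_words()$word
  list(
    ratings = setNames(c("observer_id", "animation_id", words),
                       c("observer_id", "animation_id", words)),
    participants = c(participant_id = "pid", culture = "country",
                     group = "dx"),
    animations = c(animation_id = "vid", generator_id = "maker",
                   word = "target", condition = "cond",
                   mean_jerk = "jerkval"),
    levels = list(group = c(ASD = "aut", TD = "non_aut"),
                  condition = c(ToM = "mental", GD = "non_mental")))
}

# Deterministic two-triangle trajectory from analytic coordinate functions
# fx(t), fy(t) (triangle 2 static), for finite-difference oracles.
analytic_trajectory <- function(fx, fy = function(t) rep(0.5, length(t)),
                                duration = 2, rate = 60) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  out <- rbind(
    data.frame(animation_id = "a", t = t, triangle_id = 1,
               x = fx(t), y = fy(t)),
    data.frame(animation_id = "a", t = t, triangle_id = 2,
               x = 0.5, y = 0.5))
  attr(out, "sampling_rate") <- rate
  out
}
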