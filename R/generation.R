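#' Per-cell kinematic profiles for the generation phase
#'
#' Each culture x group cell gets a profile governing its generators'
#' movement kinematics: the mean submovement count (jerk level) and a
#' between-generator dispersion on the log scale. A participant's personal
#' submovement count is `round(mean_submovements * exp(N(0, dispersion)))`,
#' so `dispersion = 0` makes all generators of a cell kinematically
#' identical in expectation, while a larger dispersion inflates the
#' between-generator coefficient of variation of mean jerk in that cell.
#'
#' The default profiles emulate the study conditions the analysis targets:
#' all four cells share the same expected jerk level, and the UK autistic
#' cell has elevated between-generator dispersion, raising that cell's
#' jerk coefficient of variation by roughly 0.4 over the ~0.6 baseline of
#' the other cells.
#'
#' @param mean_submovements Expected submovement count per animation.
#' @param dispersion Named numeric: log-scale between-generator dispersion
#'   per cell (`UK.aut`, `UK.non_aut`, `JP.aut`, `JP.non_aut`).
#' @param duration,amplitude_sd,noise_sd Shared trajectory settings.
#' @return Named list of per-cell profile lists, class `kinematic_profiles`.
#' @export
kinematic_profiles <- function(mean_submovements = 12,
                               dispersion = c(UK.aut = 0.4, UK.non_aut = 0.25,
                                              JP.aut = 0.25, JP.non_aut = 0.25),
                               duration = 8,
                               amplitude_sd = 0.15,
                               noise_sd = 0) {
  cells <- as.vector(outer(CULTURE_LEVELS, GROUP_LEVELS, cell_key))
  if (!all(cells %in% names(dispersion)))
    stop_config("dispersion must name all cells: %s",
                paste(setdiff(cells, names(dispersion)), collapse = ", "))
  profiles <- lapply(cells, function(cell) {
    list(mean_submovements = mean_submovements,
         dispersion = unname(dispersion[[cell]]),
         duration = duration,
         amplitude_sd = amplitude_sd,
         noise_sd = noise_sd)
  })
  names(profiles) <- cells
  structure(profiles, class = "kinematic_profiles")
}

#' Construct an animation set from its component tables
#'
#' Used when re-assembling a study from written artefacts (e.g. the CSV
#' files of an earlier pipeline stage).
#'
#' @param animations Data frame `animation_id, generator_id, word,
#'   condition`.
#' @param trajectories Long-format trajectory data frame (may be `NULL`
#'   when only metadata-level operations are needed).
#' @param sampling_rate Hz.
#' @return An `animation_set`.
#' @export
animation_set <- function(animations, trajectories = NULL,
                          sampling_rate = 60) {
  need <- c("animation_id", "generator_id", "word", "condition")
  if (!all(need %in% names(animations)))
    stop_config("animations must have columns: %s", paste(need, collapse = ", "))
  animations$condition <- canon_condition(animations$condition)
  if (!is.null(trajectories) &&
      !all(c("animation_id", "t", "triangle_id", "x", "y") %in%
           names(trajectories)))
    stop_config("trajectories must be in long format")
  structure(list(animations = as.data.frame(animations),
                 trajectories = trajectories,
                 sampling_rate = sampling_rate),
            class = "animation_set")
}

#' Simulate the animation-generation phase
#'
#' Every participant generates one animation per word (6 each). Personal
#' jerk levels are drawn from the participant's cell profile, so
#' between-generator jerk dispersion is controllable cell by cell.
#'
#' @param design A [make_design()] result.
#' @param profiles A [kinematic_profiles()] object covering all four cells.
#' @param seed RNG seed; defaults to the study's trajectory stream.
#' @return An `animation_set`: list with `animations` (animation_id,
#'   generator_id, word, condition) and `trajectories` (long format, all
#'   animations), plus the sampling rate.
#' @export
simulate_generation_phase <- function(design,
                                      profiles = kinematic_profiles(),
                                      seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  cells <- unique(cell_key(design$participants$culture,
                           design$participants$group))
  missing <- setdiff(cells, names(profiles))
  if (length(missing))
    stop_config("missing kinematic profile for cell(s): %s",
                paste(missing, collapse = ", "))
  if (is.null(seed)) seed <- derive_seed(design$config$seed, "trajectories")
  rate <- design$config$sampling_rate

  with_seed(seed, {
    parts <- design$participants
    rows <- list(); trajs <- list(); k <- 0L
    for (i in seq_len(nrow(parts))) {
      prof <- profiles[[cell_key(parts$culture[i], parts$group[i])]]
      n_sub <- max(1L, as.integer(round(
        prof$mean_submovements * exp(stats::rnorm(1, 0, prof$dispersion)))))
      params <- trajectory_params(duration = prof$duration,
                                  n_submovements = n_sub,
                                  submovement_amplitude_sd = prof$amplitude_sd,
                                  noise_sd = prof$noise_sd)
      for (w in seq_len(nrow(design$words))) {
        k <- k + 1L
        id <- sprintf("A%04d_%s_%s", k, parts$participant_id[i],
                      design$words$word[w])
        rows[[k]] <- data.frame(
          animation_id = id,
          generator_id = parts$participant_id[i],
          word = design$words$word[w],
          condition = as.character(design$words$condition[w]),
          stringsAsFactors = FALSE
        )
        trajs[[k]] <- simulate_trajectory(params, rate, id)
      }
    }
    animations <- do.call(rbind, rows)
    animations$condition <- canon_condition(animations$condition)
    structure(list(animations = animations,
                   trajectories = do.call(rbind, trajs),
                   sampling_rate = rate),
              class = "animation_set")
  })
}

#' @export
print.animation_set <- function(x, ...) {
  cat(sprintf("animation_set: %d animations, %d trajectory samples, %g Hz\n",
              nrow(x$animations), nrow(x$trajectories), x$sampling_rate))
  invisible(x)
}
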