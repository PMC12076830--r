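#' Write a synthetic study to plain-text CSV artefacts
#'
#' Files: `participants.csv` (participant_id, culture, group),
#' `animations.csv` (animation_id, generator_id, word, condition),
#' `sessions.csv`, `ratings.csv` (observer_id, animation_id, one 0-100
#' column per word), `kinematics.csv` (animation_id, mean_jerk),
#' `observer_jerk.csv`, and optionally the long-format `trajectories.csv`
#' (animation_id, t, triangle_id, x, y).
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @param trajectories Also write the (large) trajectory file?
#' @return Invisibly, the named vector of file paths written.
#' @export
write_study <- function(study, dir, trajectories = FALSE) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    participants = "participants.csv", animations = "animations.csv",
    sessions = "sessions.csv", ratings = "ratings.csv",
    kinematics = "kinematics.csv", observer_jerk = "observer_jerk.csv")
  tabs <- list(
    participants = study$design$participants,
    animations = study$animations$animations,
    sessions = study$sessions,
    ratings = study$ratings,
    kinematics = study$kinematics$animation_jerk,
    observer_jerk = study$kinematics$observer_jerk)
  if (trajectories) {
    files["trajectories"] <- "trajectories.csv"
    tabs$trajectories <- study$animations$trajectories
  }
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  for (nm in names(tabs))
    utils::write.csv(tabs[[nm]], paths[[nm]], row.names = FALSE)
  invisible(paths)
}

rename_by_mapping <- function(df, mapping, file, required) {
  missing_cols <- setdiff(unname(mapping), names(df))
  if (length(missing_cols))
    stop_config("%s: mapped columns absent from file: %s", file,
                paste(missing_cols, collapse = ", "))
  missing_sem <- setdiff(required, names(mapping))
  if (length(missing_sem))
    stop_config("%s: mapping omits required column(s): %s", file,
                paste(missing_sem, collapse = ", "))
  out <- df[, unname(mapping), drop = FALSE]
  names(out) <- names(mapping)
  out
}

recode_levels <- function(x, map) {
  if (is.null(map)) return(as.character(x))
  x <- as.character(x)
  unname(ifelse(x %in% names(map), map[x], x))
}

#' Ingest deposited (real-data) CSV files into the canonical model table
#'
#' The layout and column names of deposited data files are not hard-coded:
#' a mapping config declares, per file, which source column carries each
#' semantic column, plus optional level recodings for culture, group and
#' condition. Rows with ratings outside 0-100 are flagged and dropped, with
#' counts reported in the attached validation report.
#'
#' @param paths Named list of file paths: `ratings`, `participants`,
#'   `animations` (animation metadata; include a `mean_jerk` column to
#'   enable jerk-difference covariates).
#' @param mapping Named list of named character vectors
#'   (`semantic = source`) per file; optional `levels` entry with recode
#'   maps, e.g. `list(group = c(ASD = "aut", TD = "non_aut"))`.
#' @return A `model_table` (see [build_model_table()]) with a `"validation"`
#'   attribute listing flagged rows.
#' @export
ingest_real_data <- function(paths, mapping) {
  for (f in c("ratings", "participants", "animations"))
    if (is.null(paths[[f]]) || !file.exists(paths[[f]]))
      stop_config("missing input file: %s", f)

  parts <- rename_by_mapping(
    utils::read.csv(paths$participants, stringsAsFactors = FALSE),
    mapping$participants, "participants",
    c("participant_id", "culture", "group"))
  parts$culture <- recode_levels(parts$culture, mapping$levels$culture)
  parts$group <- recode_levels(parts$group, mapping$levels$group)
  if (!all(parts$culture %in% CULTURE_LEVELS))
    stop_config("unrecognised culture levels: %s",
                paste(setdiff(parts$culture, CULTURE_LEVELS), collapse = ", "))
  if (!all(parts$group %in% GROUP_LEVELS))
    stop_config("unrecognised group levels: %s",
                paste(setdiff(parts$group, GROUP_LEVELS), collapse = ", "))
  parts$culture <- canon_culture(parts$culture)
  parts$group <- canon_group(parts$group)

  anims_raw <- utils::read.csv(paths$animations, stringsAsFactors = FALSE)
  has_jerk <- "mean_jerk" %in% names(mapping$animations)
  anims <- rename_by_mapping(
    anims_raw, mapping$animations, "animations",
    c("animation_id", "generator_id", "word", "condition"))
  anims$condition <- recode_levels(anims$condition, mapping$levels$condition)
  anims$condition <- canon_condition(anims$condition)

  ratings_raw <- utils::read.csv(paths$ratings, stringsAsFactors = FALSE)
  words <- sort(unique(anims$word))
  rmap <- mapping$ratings
  ratings <- rename_by_mapping(ratings_raw, rmap, "ratings",
                               c("observer_id", "animation_id", words))

  rmat <- as.matrix(ratings[, words])
  bad <- rowSums(is.na(rmat) | rmat < 0 | rmat > 100) > 0
  validation <- list(n_rows = nrow(ratings), n_flagged = sum(bad),
                     flagged_rows = which(bad))
  ratings <- ratings[!bad, , drop = FALSE]
  if (!nrow(ratings)) stop_config("no valid rating rows after validation")

  aset <- structure(list(animations = anims, trajectories = NULL,
                         sampling_rate = NA_real_),
                    class = "animation_set")
  acc <- score_trials(ratings, aset, parts)

  if (has_jerk) {
    kin <- data.frame(animation_id = anims$animation_id,
                      mean_jerk = anims$mean_jerk)
    own <- merge(anims[, c("animation_id", "generator_id", "word")], kin,
                 by = "animation_id")
    own <- stats::setNames(own[, c("generator_id", "word", "mean_jerk")],
                           c("participant_id", "word", "mean_jerk"))
    jd <- jerk_difference_table(own, kin, acc)
  } else {
    jd <- acc[, c("observer_id", "animation_id", "word")]
    jd$jerk_difference <- NA_real_
    jd$z_jerk_difference <- NA_real_
  }
  out <- build_model_table(acc, jd, parts)
  attr(out, "validation") <- validation
  out
}
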