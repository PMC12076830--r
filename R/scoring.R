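#' Trial accuracy statistic
#'
#' Accuracy is the rating for the target word minus the mean rating of the
#' five non-target words, so it ranges from -100 to 100: positive values
#' mean the target was discriminated from the distractor words, values near
#' zero or below mean confusion between scales.
#'
#' @param ratings Named numeric vector of six 0-100 ratings (names are the
#'   words).
#' @param target_word The word the rated animation depicted.
#' @return Accuracy score in \[-100, 100\].
#' @export
trial_accuracy <- function(ratings, target_word) {
  if (length(ratings) != 6 || is.null(names(ratings)))
    stop_config("ratings must be a named vector of 6 values")
  if (!target_word %in% names(ratings))
    stop_config("target word '%s' not among the rated words", target_word)
  if (anyNA(ratings) || any(ratings < 0 | ratings > 100))
    stop_config("ratings must lie in [0, 100]")
  unname(ratings[[target_word]] - mean(ratings[names(ratings) != target_word]))
}

#' Score all rating trials of a study
#'
#' @param ratings Rating-trial data frame (`observer_id, animation_id` plus
#'   one column per word) as written by [simulate_ratings()].
#' @param animations An `animation_set` (supplies each animation's target
#'   word and condition).
#' @param participants Participant roster.
#' @return Data frame of accuracy records: observer/generator factors,
#'   target word, condition and accuracy, one row per trial.
#' @export
score_trials <- function(ratings, animations, participants) {
  anims <- animations$animations
  words <- intersect(names(ratings), anims$word)
  if (length(words) != 6)
    stop_config("expected 6 word columns in ratings, found %d", length(words))
  rmat <- as.matrix(ratings[, words])
  if (anyNA(rmat) || any(rmat < 0 | rmat > 100))
    stop_config("ratings must lie in [0, 100]")
  tab <- merge(ratings[, c("observer_id", "animation_id")],
               anims[, c("animation_id", "generator_id", "word", "condition")],
               by = "animation_id", sort = FALSE)
  tab <- tab[match(paste(ratings$observer_id, ratings$animation_id),
                   paste(tab$observer_id, tab$animation_id)), ]
  idx <- cbind(seq_len(nrow(rmat)), match(tab$word, words))
  target <- rmat[idx]
  accuracy <- target - (rowSums(rmat) - target) / 5
  out <- data.frame(observer_id = tab$observer_id,
                    animation_id = tab$animation_id,
                    generator_id = tab$generator_id,
                    word = tab$word,
                    condition = canon_condition(tab$condition),
                    accuracy = accuracy,
                    stringsAsFactors = FALSE)
  out <- merge(out, stats::setNames(participants,
                                    c("observer_id", "observer_culture",
                                      "observer_group")),
               by = "observer_id")
  out <- merge(out, stats::setNames(participants,
                                    c("generator_id", "generator_culture",
                                      "generator_group")),
               by = "generator_id")
  out[sort.list(paste(out$observer_id, out$animation_id)), ]
}

#' Assemble the modelling table
#'
#' Joins accuracy records with jerk-difference records into one row per
#' rated trial, carrying every factor and covariate the model catalogue
#' needs. The join must be lossless: unmatched keys on either side raise an
#' error naming the orphans.
#'
#' @param accuracy_records Output of [score_trials()].
#' @param jerk_difference_records Output of [jerk_difference_table()].
#' @param participants Participant roster (validates observer ids).
#' @return `model_table` data frame, one row per rating trial.
#' @export
build_model_table <- function(accuracy_records, jerk_difference_records,
                              participants) {
  key_a <- paste(accuracy_records$observer_id, accuracy_records$animation_id)
  key_j <- paste(jerk_difference_records$observer_id,
                 jerk_difference_records$animation_id)
  orphans <- c(setdiff(key_a, key_j), setdiff(key_j, key_a))
  if (length(orphans))
    stop_config("unmatched trial keys between accuracy and jerk tables: %s",
                paste(utils::head(orphans, 3), collapse = "; "))
  bad_obs <- setdiff(accuracy_records$observer_id,
                     participants$participant_id)
  if (length(bad_obs))
    stop_config("observers missing from roster: %s",
                paste(utils::head(bad_obs, 3), collapse = ", "))
  tab <- merge(accuracy_records,
               jerk_difference_records[, c("observer_id", "animation_id",
                                           "jerk_difference",
                                           "z_jerk_difference")],
               by = c("observer_id", "animation_id"))
  stopifnot(nrow(tab) == nrow(accuracy_records))
  tab$observer_culture <- canon_culture(tab$observer_culture)
  tab$observer_group <- canon_group(tab$observer_group)
  tab$generator_culture <- canon_culture(tab$generator_culture)
  tab$generator_group <- canon_group(tab$generator_group)
  tab$word <- canon_word(tab$word)
  class(tab) <- c("model_table", "data.frame")
  tab
}

#' Canonicalise a model table read back from CSV
#'
#' Restores the factor types and canonical level order of a trial-level
#' model table written by an earlier pipeline stage.
#'
#' @param df Data frame with the model-table columns.
#' @return A `model_table`.
#' @export
as_model_table <- function(df) {
  need <- c("observer_id", "animation_id", "word", "condition", "accuracy",
            "observer_culture", "observer_group", "generator_culture",
            "generator_group", "jerk_difference", "z_jerk_difference")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_config("model table is missing columns: %s",
                paste(missing_cols, collapse = ", "))
  df$condition <- canon_condition(df$condition)
  df$observer_culture <- canon_culture(df$observer_culture)
  df$observer_group <- canon_group(df$observer_group)
  df$generator_culture <- canon_culture(df$generator_culture)
  df$generator_group <- canon_group(df$generator_group)
  df$word <- canon_word(df$word)
  class(df) <- c("model_table", "data.frame")
  df
}

#' Per-animation jerk modelling table (for mean-jerk response models)
#'
#' @param animation_jerk Data frame `animation_id, mean_jerk`.
#' @param animations An `animation_set`.
#' @param participants Participant roster.
#' @return Data frame with one row per animation: generator factors, word,
#'   condition and mean jerk (plus its z-scored version as response scale).
#' @export
jerk_model_table <- function(animation_jerk, animations, participants) {
  tab <- merge(animations$animations, animation_jerk, by = "animation_id")
  tab <- merge(tab, stats::setNames(participants,
                                    c("generator_id", "culture", "group")),
               by = "generator_id")
  tab$culture <- canon_culture(tab$culture)
  tab$group <- canon_group(tab$group)
  tab$condition <- canon_condition(tab$condition)
  tab$word <- canon_word(tab$word)
  tab$z_mean_jerk <- as.vector(scale(tab$mean_jerk))
  tab[sort.list(tab$animation_id), ]
}
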