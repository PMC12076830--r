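#' Study design configuration
#'
#' Describes the crossed 2 (culture: UK, JP) x 2 (group: autistic,
#' non-autistic) generator/observer design: participants per cell, the six
#' animated words (three mental-state, three non-mental-state), how many
#' animations an observer rates per word x generator-group x
#' generator-culture cell, and the trajectory sampling rate.
#'
#' With the defaults every observer rates 6 words x 2 generator groups x
#' 2 generator cultures x 6 animations = 144 animations.
#'
#' @param n_per_cell Participants per culture x group cell.
#' @param words Data frame with columns `word`, `condition`; exactly six
#'   rows, three per condition.
#' @param animations_per_cell Animations rated per word x generator-cell.
#' @param sampling_rate Trajectory sampling rate in Hz.
#' @param seed Integer study seed; all phase RNG streams derive from it.
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_per_cell = 15,
                          words = default_words(),
                          animations_per_cell = 6,
                          sampling_rate = 60,
                          seed = 1L) {
  if (!is.numeric(n_per_cell) || n_per_cell < 1 || n_per_cell %% 1 != 0)
    stop_config("n_per_cell must be a positive integer, got %s", n_per_cell)
  words <- as.data.frame(words)
  if (!all(c("word", "condition") %in% names(words)))
    stop_config("words must have columns 'word' and 'condition'")
  if (nrow(words) != 6 || anyDuplicated(words$word))
    stop_config("word list must contain exactly 6 distinct words")
  words$condition <- canon_condition(words$condition)
  if (any(is.na(words$condition)))
    stop_config("word conditions must be 'mental' or 'non_mental'")
  if (!all(table(words$condition) == 3))
    stop_config("word list must be balanced: 3 mental, 3 non-mental words")
  if (!is.numeric(animations_per_cell) || animations_per_cell < 1)
    stop_config("animations_per_cell must be a positive integer")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop_config("sampling_rate must be positive")
  structure(
    list(n_per_cell = as.integer(n_per_cell),
         words = words,
         animations_per_cell = as.integer(animations_per_cell),
         sampling_rate = sampling_rate,
         seed = as.integer(seed)),
    class = "design_config"
  )
}

#' Build the participant roster and word table for a study
#'
#' @param config A [design_config()].
#' @return An object of class `study_design`: list with `participants`
#'   (participant_id, culture, group), `words`, and the config.
#' @export
make_design <- function(config = design_config()) {
  stopifnot(inherits(config, "design_config"))
  cells <- expand.grid(culture = CULTURE_LEVELS, group = GROUP_LEVELS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  participants <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(
      participant_id = sprintf("%s_%s_%02d", cells$culture[i], cells$group[i],
                               seq_len(config$n_per_cell)),
      culture = cells$culture[i],
      group = cells$group[i],
      stringsAsFactors = FALSE
    )
  }))
  participants$culture <- canon_culture(participants$culture)
  participants$group <- canon_group(participants$group)
  rownames(participants) <- NULL
  structure(list(participants = participants,
                 words = config$words,
                 config = config),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Animations-task study design\n")
  cat(sprintf("  %d participants (%d per culture x group cell)\n",
              nrow(x$participants), x$config$n_per_cell))
  cat(sprintf("  words: %s\n", paste(x$words$word, collapse = ", ")))
  cat(sprintf("  %d rated animations per word x generator cell, %g Hz\n",
              x$config$animations_per_cell, x$config$sampling_rate))
  invisible(x)
}
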