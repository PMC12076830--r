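#' @keywords internal
"_PACKAGE"

# Canonical factor levels used by every module. Reference levels come first
# so downstream dummy coding is stable: non_aut, UK and mental are the
# reference levels throughout.
CULTURE_LEVELS <- c("UK", "JP")
GROUP_LEVELS <- c("non_aut", "aut")
CONDITION_LEVELS <- c("mental", "non_mental")

#' Default word list of the animations task
#'
#' Three mental-state words (an agent intends to act on the other's mental
#' state) and three non-mental-state (goal-directed) words.
#'
#' @return Data frame with columns `word` and `condition`, six rows.
#' @export
default_words <- function() {
  data.frame(
    word = c("arguing", "surprising", "teasing",
             "following", "searching", "dancing"),
    condition = factor(rep(CONDITION_LEVELS, each = 3),
                       levels = CONDITION_LEVELS),
    stringsAsFactors = FALSE
  )
}

# Deterministic per-phase seed derived from the study seed, so each pipeline
# stage owns an independent reproducible RNG stream.
derive_seed <- function(seed, phase) {
  offsets <- c(design = 11L, trajectories = 23L, sessions = 37L,
               ratings = 51L, fit = 67L, replicate = 83L)
  off <- offsets[[phase]]
  as.integer((as.numeric(seed) * 97 + off) %% 2147483587)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

canon_culture <- function(x) factor(as.character(x), levels = CULTURE_LEVELS)
canon_group <- function(x) factor(as.character(x), levels = GROUP_LEVELS)
canon_condition <- function(x) factor(as.character(x), levels = CONDITION_LEVELS)

cell_key <- function(culture, group) paste(culture, group, sep = ".")

# Word factor in canonical order (mental triad first, as in the default
# word list); unknown words are appended alphabetically.
canon_word <- function(x) {
  x <- as.character(x)
  lev <- c(intersect(default_words()$word, unique(x)),
           sort(setdiff(unique(x), default_words()$word)))
  factor(x, levels = lev)
}
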