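#' Assemble pseudo-random rating sessions
#'
#' For every observer, selects `animations_per_cell` animations per word x
#' generator-group x generator-culture cell (with the defaults: 6 x 6 words
#' x 4 generator cells = 144 animations). An observer never rates their own
#' animations.
#'
#' @param design A [make_design()] result.
#' @param animations An `animation_set` from [simulate_generation_phase()].
#' @param seed RNG seed; defaults to the study's session stream.
#' @return Data frame with one row per rating trial: `observer_id,
#'   animation_id, generator_id, word`.
#' @export
assemble_rating_sessions <- function(design, animations, seed = NULL) {
  stopifnot(inherits(design, "study_design"),
            inherits(animations, "animation_set"))
  if (is.null(seed)) seed <- derive_seed(design$config$seed, "sessions")
  k <- design$config$animations_per_cell
  parts <- design$participants
  anims <- merge(animations$animations,
                 stats::setNames(parts, c("generator_id", "generator_culture",
                                          "generator_group")),
                 by = "generator_id")
  with_seed(seed, {
    out <- vector("list", nrow(parts))
    for (i in seq_len(nrow(parts))) {
      obs <- parts$participant_id[i]
      chosen <- lapply(design$words$word, function(w) {
        pool_w <- anims[anims$word == w & anims$generator_id != obs, ]
        cells <- split(pool_w, cell_key(pool_w$generator_culture,
                                        pool_w$generator_group))
        do.call(rbind, lapply(names(cells), function(cl) {
          pool <- cells[[cl]]
          if (nrow(pool) < k)
            stop_config(paste0(
              "animation pool exhausted for observer %s, word '%s', ",
              "generator cell %s: %d available, %d needed"),
              obs, w, cl, nrow(pool), k)
          pool[sample.int(nrow(pool), k), c("animation_id", "generator_id",
                                            "word")]
        }))
      })
      sess <- do.call(rbind, chosen)
      sess <- cbind(observer_id = obs, sess)
      out[[i]] <- sess
    }
    sessions <- do.call(rbind, out)
    rownames(sessions) <- NULL
    sessions
  })
}
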