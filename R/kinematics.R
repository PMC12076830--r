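#' Differentiate a trajectory by repeated central differences
#'
#' Applies central finite differences `order` times to each axis of each
#' triangle. Position can optionally be low-pass filtered first (2nd-order
#' Butterworth, zero-phase via forward-backward filtering) because third
#' derivatives amplify high-frequency noise; smoothing is off by default.
#' Each application of the central difference drops one sample at each end,
#' so the output has `2 * order` fewer samples per triangle.
#'
#' @param trajectory Long-format trajectory data frame
#'   (`t, triangle_id, x, y`), uniformly sampled.
#' @param order Derivative order, 1 (velocity) to 3 (jerk).
#' @param sampling_rate Hz; taken from the trajectory attribute if absent.
#' @param smooth_cutoff Optional low-pass cutoff in Hz applied to position
#'   before differentiating; `NULL` (default) disables smoothing.
#' @return Data frame `t, triangle_id, dx, dy` of per-sample derivative
#'   vectors (interior samples only).
#' @export
differentiate <- function(trajectory, order = 3, sampling_rate = NULL,
                          smooth_cutoff = NULL) {
  if (!all(c("t", "triangle_id", "x", "y") %in% names(trajectory)))
    stop_config("trajectory must have columns t, triangle_id, x, y")
  if (!order %in% 1:3) stop_config("order must be 1, 2 or 3")
  if (is.null(sampling_rate)) sampling_rate <- attr(trajectory, "sampling_rate")
  if (is.null(sampling_rate)) {
    dt <- diff(sort(unique(trajectory$t)))
    sampling_rate <- 1 / stats::median(dt)
  }
  pieces <- lapply(split(trajectory, trajectory$triangle_id), function(tri) {
    tri <- tri[sort.list(tri$t), ]  # `order` name is taken by the argument
    n <- nrow(tri)
    if (n < order + 2)
      stop_config("too few samples (%d) for order-%d differentiation", n, order)
    dt <- diff(tri$t)
    if (any(abs(dt - 1 / sampling_rate) > 1e-6 * max(1, 1 / sampling_rate)))
      stop_config("non-uniform sampling in triangle %s", tri$triangle_id[1])
    x <- tri$x; y <- tri$y
    if (!is.null(smooth_cutoff)) {
      bf <- signal::butter(2, smooth_cutoff / (sampling_rate / 2))
      x <- signal::filtfilt(bf, x)
      y <- signal::filtfilt(bf, y)
    }
    t <- tri$t
    for (k in seq_len(order)) {
      m <- length(x)
      x <- (x[3:m] - x[1:(m - 2)]) * (sampling_rate / 2)
      y <- (y[3:m] - y[1:(m - 2)]) * (sampling_rate / 2)
      t <- t[2:(m - 1)]
    }
    data.frame(t = t, triangle_id = tri$triangle_id[1], dx = x, dy = y)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Per-animation mean jerk
#'
#' Jerk is the third time-derivative of position. The per-sample jerk
#' magnitude is the Euclidean norm of the (x, y) jerk vector; it is averaged
#' over interior samples within each triangle and then across the two
#' triangles, yielding one non-negative intensity per animation. Using
#' magnitudes (no sign cancellation across samples) is what makes the mean
#' a meaningful movement-smoothness index.
#'
#' @inheritParams differentiate
#' @return Single non-negative number, screen units / s^3.
#' @export
mean_jerk <- function(trajectory, sampling_rate = NULL, smooth_cutoff = NULL) {
  j <- differentiate(trajectory, order = 3, sampling_rate = sampling_rate,
                     smooth_cutoff = smooth_cutoff)
  per_tri <- vapply(split(j, j$triangle_id),
                    function(d) mean(sqrt(d$dx^2 + d$dy^2)), numeric(1))
  mean(per_tri)
}

#' Mean-jerk summaries for every animation in a set
#'
#' @param animations An `animation_set`.
#' @param smooth_cutoff Optional low-pass cutoff in Hz (see
#'   [differentiate()]).
#' @return Data frame `animation_id, mean_jerk`.
#' @export
kinematic_summaries <- function(animations, smooth_cutoff = NULL) {
  stopifnot(inherits(animations, "animation_set"))
  rate <- animations$sampling_rate
  trajs <- split(animations$trajectories,
                 animations$trajectories$animation_id)
  out <- data.frame(
    animation_id = names(trajs),
    mean_jerk = vapply(trajs, mean_jerk, numeric(1),
                       sampling_rate = rate, smooth_cutoff = smooth_cutoff),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Observers' own per-word jerk
#'
#' An observer's own jerk for a word is the mean jerk of the animation they
#' themselves generated for that word.
#'
#' @inheritParams kinematic_summaries
#' @return Data frame `participant_id, word, mean_jerk`.
#' @export
observer_word_jerk <- function(animations, smooth_cutoff = NULL) {
  summaries <- kinematic_summaries(animations, smooth_cutoff)
  out <- merge(animations$animations[, c("animation_id", "generator_id",
                                         "word")],
               summaries, by = "animation_id")
  out <- out[, c("generator_id", "word", "mean_jerk")]
  names(out)[1] <- "participant_id"
  out[order(out$participant_id, out$word), ]
}

#' Observer-animation jerk differences for rated trials
#'
#' For every rating trial, the jerk difference is the absolute difference
#' between the observer's own mean jerk for the target word and the rated
#' animation's mean jerk; it is an inverse index of observer-agent movement
#' similarity. The z-standardised column is computed over the rows of the
#' returned table (the modelled dataset).
#'
#' @param observer_jerk Data frame `participant_id, word, mean_jerk`.
#' @param animation_jerk Data frame `animation_id, mean_jerk`.
#' @param sessions Data frame with `observer_id, animation_id, word`.
#' @return Data frame `observer_id, animation_id, word, jerk_difference,
#'   z_jerk_difference`, one row per rating trial.
#' @export
jerk_difference_table <- function(observer_jerk, animation_jerk, sessions) {
  own <- stats::setNames(observer_jerk,
                         c("observer_id", "word", "own_jerk"))
  tab <- merge(sessions[, c("observer_id", "animation_id", "word")], own,
               by = c("observer_id", "word"), all.x = TRUE)
  if (anyNA(tab$own_jerk)) {
    bad <- unique(tab[is.na(tab$own_jerk), c("observer_id", "word")])
    stop_config("missing own-animation jerk for: %s",
                paste(sprintf("%s/%s", bad$observer_id, bad$word)[1:min(3, nrow(bad))],
                      collapse = ", "))
  }
  tab <- merge(tab, stats::setNames(animation_jerk,
                                    c("animation_id", "animation_jerk")),
               by = "animation_id", all.x = TRUE)
  if (anyNA(tab$animation_jerk))
    stop_config("missing animation jerk for %s",
                tab$animation_id[is.na(tab$animation_jerk)][1])
  tab$jerk_difference <- abs(tab$own_jerk - tab$animation_jerk)
  tab$z_jerk_difference <- as.vector(scale(tab$jerk_difference))
  tab[, c("observer_id", "animation_id", "word", "jerk_difference",
          "z_jerk_difference")]
}

#' Between-generator jerk variability (CV) per culture x group x word
#'
#' The coefficient of variation (sample SD / mean) of generators'
#' mean-jerk values, computed within each culture x group cell for each
#' word: with six words this yields six jerk-variability values per cell.
#'
#' @param animation_jerk Data frame `animation_id, mean_jerk`.
#' @param animations An `animation_set` (links animations to generators).
#' @param participants Participant roster (`participant_id, culture, group`).
#' @return Data frame `culture, group, word, cv`, one row per combination.
#' @export
jerk_cv <- function(animation_jerk, animations, participants) {
  tab <- merge(animations$animations, animation_jerk, by = "animation_id")
  tab <- merge(tab, stats::setNames(participants,
                                    c("generator_id", "culture", "group")),
               by = "generator_id")
  grp <- split(tab, list(tab$culture, tab$group, tab$word), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(d) {
    if (nrow(d) < 2)
      stop_config("fewer than 2 jerk values in cell %s.%s word '%s'",
                  d$culture[1], d$group[1], d$word[1])
    m <- mean(d$mean_jerk)
    if (m <= 0)
      stop_config("non-positive mean jerk in cell %s.%s word '%s'",
                  d$culture[1], d$group[1], d$word[1])
    data.frame(culture = d$culture[1], group = d$group[1], word = d$word[1],
               cv = stats::sd(d$mean_jerk) / m, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$culture <- canon_culture(out$culture)
  out$group <- canon_group(out$group)
  out$word <- canon_word(out$word)
  out[order(out$culture, out$group, out$word), ]
}
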