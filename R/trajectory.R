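#' Parameters of the trajectory generator
#'
#' Synthetic finger-movement trajectories are built as a chain of smooth
#' minimum-jerk submovements: within each submovement the position follows
#' the classic quintic profile 10*tau^3 - 15*tau^4 + 6*tau^5, which has zero
#' velocity and acceleration at both ends. Jerk intensity is controlled by
#' the number of submovements packed into a fixed duration (shorter
#' submovements of similar amplitude have much higher peak jerk, which
#' scales as amplitude / T^3) and by additive positional noise.
#'
#' @param duration Movement duration in seconds.
#' @param n_submovements Number of submovements chained per triangle.
#' @param submovement_amplitude_sd SD of per-axis submovement amplitudes,
#'   in screen units (screen is the unit square).
#' @param noise_sd SD of additive white positional noise, screen units.
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(duration = 8,
                              n_submovements = 12,
                              submovement_amplitude_sd = 0.15,
                              noise_sd = 0) {
  if (!is.numeric(duration) || duration <= 0)
    stop_config("duration must be positive")
  if (!is.numeric(n_submovements) || n_submovements < 1)
    stop_config("n_submovements must be >= 1")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_config("noise_sd must be >= 0")
  structure(list(duration = duration,
                 n_submovements = as.integer(round(n_submovements)),
                 submovement_amplitude_sd = submovement_amplitude_sd,
                 noise_sd = noise_sd),
            class = "trajectory_params")
}

# Minimum-jerk position ramp on tau in [0, 1].
min_jerk_profile <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# One axis of one triangle: start position plus a chain of minimum-jerk
# displacement ramps with random amplitudes, then noise and clipping.
simulate_axis <- function(t, duration, n_sub, amp_sd, noise_sd, start) {
  amps <- stats::rnorm(n_sub, 0, amp_sd)
  breaks <- seq(0, duration, length.out = n_sub + 1)
  seg <- pmin(findInterval(t, breaks, rightmost.closed = TRUE), n_sub)
  tau <- (t - breaks[seg]) / (breaks[seg + 1] - breaks[seg])
  offset <- c(0, cumsum(amps))[seg]
  x <- start + offset + amps[seg] * min_jerk_profile(tau)
  if (noise_sd > 0) x <- x + stats::rnorm(length(t), 0, noise_sd)
  pmin(pmax(x, 0), 1)
}

#' Simulate one two-triangle trajectory
#'
#' @param params A [trajectory_params()].
#' @param sampling_rate Samples per second (Hz).
#' @param animation_id Identifier stamped on the output rows.
#' @return Long-format data frame `animation_id, t, triangle_id, x, y` with
#'   `duration * sampling_rate` samples per triangle, uniformly spaced at
#'   `1/sampling_rate`; positions lie in the unit square.
#' @export
simulate_trajectory <- function(params, sampling_rate = 60,
                                animation_id = "anim") {
  stopifnot(inherits(params, "trajectory_params"))
  n <- round(params$duration * sampling_rate)
  if (n < 8)
    stop_config(
      "trajectory too short: %d samples; need >= 8 to differentiate thrice", n)
  t <- (seq_len(n) - 1) / sampling_rate
  out <- do.call(rbind, lapply(1:2, function(tri) {
    start <- stats::runif(2, 0.25, 0.75)
    data.frame(
      animation_id = animation_id,
      t = t,
      triangle_id = tri,
      x = simulate_axis(t, params$duration, params$n_submovements,
                        params$submovement_amplitude_sd, params$noise_sd,
                        start[1]),
      y = simulate_axis(t, params$duration, params$n_submovements,
                        params$submovement_amplitude_sd, params$noise_sd,
                        start[2]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  attr(out, "sampling_rate") <- sampling_rate
  out
}
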