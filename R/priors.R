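#' Prior set for a Bayesian mixed-effects model
#'
#' Generic weakly informative priors: zero-centred normals for the intercept
#' and all regression coefficients, half-Cauchy for every random-effect and
#' residual SD. Individual coefficients can be given informative normal
#' overrides; the catalogue uses one for the jerk-difference slope, whose
#' prior is centred on the negative effect reported by earlier work with
#' this task (the centre and scale are configuration parameters and are
#' recorded on every fit).
#'
#' @param coef_scale SD of the normal prior on non-intercept coefficients.
#' @param intercept_scale SD of the normal prior on the intercept (wider by
#'   default because the response is not centred).
#' @param sd_scale Scale of the half-Cauchy prior on SDs.
#' @param informative Named list: term -> c(mean, sd) normal override.
#' @return Object of class `prior_set`.
#' @export
prior_set <- function(coef_scale = 10, intercept_scale = 50, sd_scale = 5,
                      informative = list()) {
  if (coef_scale <= 0 || intercept_scale <= 0 || sd_scale <= 0)
    stop_config("prior scales must be positive")
  for (term in names(informative)) {
    v <- informative[[term]]
    if (length(v) != 2 || v[2] <= 0)
      stop_config("informative prior for '%s' must be c(mean, sd>0)", term)
  }
  structure(list(coef_scale = coef_scale, intercept_scale = intercept_scale,
                 sd_scale = sd_scale, informative = informative),
            class = "prior_set")
}

# Per-coefficient normal prior means/sds for a fixed-effect design matrix.
coefficient_priors <- function(priors, term_names) {
  mean <- rep(0, length(term_names))
  sd <- rep(priors$coef_scale, length(term_names))
  sd[term_names == "(Intercept)"] <- priors$intercept_scale
  for (term in names(priors$informative)) {
    hit <- term_names == term
    if (any(hit)) {
      mean[hit] <- priors$informative[[term]][1]
      sd[hit] <- priors$informative[[term]][2]
    }
  }
  list(mean = mean, sd = sd)
}

#' Prior density of a coefficient at a point
#'
#' Used by the Savage-Dickey density ratio: the density of the (normal)
#' prior for `term` evaluated at `at`.
#'
#' @param priors A [prior_set()].
#' @param term Coefficient name.
#' @param at Evaluation point (default 0, the point null).
#' @param intercept Is the term the model intercept?
#' @return Prior density value.
#' @export
prior_density <- function(priors, term, at = 0, intercept = FALSE) {
  if (term %in% names(priors$informative)) {
    v <- priors$informative[[term]]
    stats::dnorm(at, v[1], v[2])
  } else {
    stats::dnorm(at, 0, if (intercept) priors$intercept_scale
                        else priors$coef_scale)
  }
}
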