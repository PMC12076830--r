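get_draws <- function(x, term = NULL) {
  if (inherits(x, "bayes_fit")) {
    if (is.null(term)) stop_config("term required")
    if (!term %in% colnames(x$draws))
      stop_config("unknown term '%s'; available: %s", term,
                  paste(colnames(x$draws), collapse = ", "))
    x$draws[, term]
  } else as.numeric(x)
}

#' Posterior summary of one effect
#'
#' Expected value under the posterior, equal-tailed 95% credible interval
#' (2.5% and 97.5% quantiles of the pooled post-warmup draws) and the
#' directional posterior probabilities P(Emu < 0) and P(Emu > 0).
#'
#' @param x A `bayes_fit` or a numeric vector of posterior draws.
#' @param term Coefficient name (when `x` is a fit).
#' @return One-row data frame: `term, e_mu, cri_low, cri_high, p_negative,
#'   p_positive`.
#' @export
summarise_effect <- function(x, term = NULL) {
  d <- get_draws(x, term)
  q <- unname(stats::quantile(d, c(0.025, 0.975), type = 7))
  data.frame(term = if (is.null(term)) "draws" else term,
             e_mu = mean(d), cri_low = q[1], cri_high = q[2],
             p_negative = mean(d < 0), p_positive = mean(d > 0),
             stringsAsFactors = FALSE)
}

#' Posterior summaries for every monitored parameter of a fit
#'
#' @param fit A `bayes_fit`.
#' @param terms Parameters to summarise; defaults to all fixed effects and
#'   SDs.
#' @return Data frame, one row per parameter.
#' @export
posterior_table <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "bayes_fit"))
  if (is.null(terms))
    terms <- colnames(fit$draws)[!grepl("^u[0-9]+\\[", colnames(fit$draws))]
  out <- do.call(rbind, lapply(terms, function(tm) summarise_effect(fit, tm)))
  out$rhat <- unname(fit$diagnostics$rhat[out$term])
  rownames(out) <- NULL
  out
}

# Equally weighted average fixed-effect row for a set of factor levels.
# Unmentioned factors are averaged over their levels with equal cell
# weights; continuous covariates are held at `covariates` (default 0, the
# z-scale centre).
cell_mean_vector <- function(fit, at, covariates = list()) {
  spec <- fit$spec
  fml <- stats::as.formula(paste("~", spec$fixed))
  vars <- all.vars(fml)
  data <- fit$design$data
  fvars <- vars[vapply(vars, function(v) is.factor(data[[v]]), logical(1))]
  nvars <- setdiff(vars, fvars)

  bad <- setdiff(names(at), fvars)
  if (length(bad))
    stop_config("contrast names unknown factors: %s", paste(bad, collapse = ", "))
  for (v in names(at))
    if (!all(at[[v]] %in% levels(data[[v]])))
      stop_config("level '%s' absent from factor '%s' in this fit",
                  setdiff(at[[v]], levels(data[[v]]))[1], v)

  grid_levels <- lapply(fvars, function(v) {
    if (v %in% names(at)) at[[v]] else levels(data[[v]])
  })
  names(grid_levels) <- fvars
  grid <- expand.grid(grid_levels, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  if (!nrow(grid)) grid <- data.frame(row.names = 1)
  for (v in fvars) grid[[v]] <- factor(grid[[v]], levels = levels(data[[v]]))
  for (v in nvars)
    grid[[v]] <- if (v %in% names(covariates)) covariates[[v]] else 0
  Xg <- stats::model.matrix(fml, grid, contrasts.arg = fit$design$contrasts)
  colMeans(Xg)
}

#' Posterior contrast of cell means
#'
#' emmeans-style post-hoc contrast: the difference between two cells (or
#' marginal averages of cells) of the fixed-effect structure, evaluated
#' draw by draw. Each cell is a named list of factor levels; factors left
#' unmentioned are averaged with equal weights, continuous covariates are
#' held at 0 on the z-scale unless given in `covariates`.
#'
#' @param fit A `bayes_fit`.
#' @param a,b Named lists of factor levels defining the two cells
#'   (`a - b`). With `b = NULL` the summary of cell `a` itself is returned.
#' @param covariates Named list of covariate values.
#' @return One-row posterior summary data frame (see [summarise_effect()]).
#' @export
posterior_contrast <- function(fit, a, b = NULL, covariates = list()) {
  stopifnot(inherits(fit, "bayes_fit"))
  ca <- cell_mean_vector(fit, a, covariates)
  w <- if (is.null(b)) ca else ca - cell_mean_vector(fit, b, covariates)
  bdraws <- fit$draws[, fit$term_names, drop = FALSE]
  est <- as.vector(bdraws %*% w)
  out <- summarise_effect(est)
  lab <- function(x) paste(names(x), vapply(x, paste, "", collapse = "+"),
                           sep = "=", collapse = ",")
  out$term <- if (is.null(b)) lab(a) else paste(lab(a), "-", lab(b))
  out
}

#' Savage-Dickey density ratio
#'
#' Approximates the Bayes factor for a point null at `at` (default 0) as
#' the ratio of the marginal posterior density to the prior density at that
#' point: `bf01 > 1` favours the model without the effect. The posterior
#' density is a Gaussian kernel estimate (Silverman bandwidth) over the
#' pooled draws. When the draws give essentially zero density at the null
#' the ratio is reported at a floor value and flagged.
#'
#' @param x A `bayes_fit` or numeric draws.
#' @param term Coefficient name (when `x` is a fit).
#' @param prior For raw draws: `c(mean, sd)` of the normal prior. Taken
#'   from the fit's prior set otherwise.
#' @param at Location of the point null.
#' @param floor Lower bound used when the posterior density at `at` is not
#'   estimable.
#' @return List of class `savage_dickey`: `term, bf01, posterior_density,
#'   prior_density, flagged`.
#' @export
savage_dickey <- function(x, term = NULL, prior = NULL, at = 0,
                          floor = 1e-4) {
  d <- get_draws(x, term)
  if (inherits(x, "bayes_fit") && is.null(prior)) {
    pd <- prior_density(x$spec$priors, term, at = at,
                        intercept = identical(term, "(Intercept)"))
  } else {
    if (is.null(prior) || length(prior) != 2)
      stop_config("prior = c(mean, sd) required for raw draws")
    pd <- stats::dnorm(at, prior[1], prior[2])
  }
  dens <- stats::density(d, bw = "nrd0")
  post0 <- if (at < min(dens$x) || at > max(dens$x)) 0
           else stats::approx(dens$x, dens$y, xout = at)$y
  flagged <- !is.finite(post0) || post0 <= 0
  bf01 <- if (flagged) floor else post0 / pd
  structure(list(term = if (is.null(term)) "draws" else term,
                 bf01 = max(bf01, if (flagged) floor else 0),
                 posterior_density = post0, prior_density = pd,
                 flagged = flagged),
            class = "savage_dickey")
}

#' @export
print.savage_dickey <- function(x, ...) {
  cat(sprintf("Savage-Dickey bf01 for %s: %.4g%s\n", x$term, x$bf01,
              if (x$flagged) " (floored: no posterior mass at the null)"
              else ""))
  invisible(x)
}
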