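# Generalised Pareto fit to sample exceedances (Zhang & Stephens 2009
# profile-posterior method). Returns shape k and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) return(list(k = Inf, sigma = NA_real_))
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar * sqrt(n))
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w_j <- 1 / vapply(l_j, function(l) sum(exp(l_j - l)), numeric(1))
  theta_hat <- sum(theta * w_j)
  k <- -mean(log1p(-theta_hat * x))
  list(k = k, sigma = k / theta_hat)
}

log_sum_exp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# Pareto-smoothed importance-sampling weights for one observation.
# lr: log importance ratios (log 1/p). Returns stabilised log weights and
# the Pareto k diagnostic.
psis_weights <- function(lr) {
  S <- length(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  lw <- lr - max(lr)
  if (M >= 5) {
    ord <- sort.list(lw)
    tail_ids <- ord[(S - M + 1):S]
    cutoff <- lw[ord[S - M]]
    fit <- gpd_fit(exp(lw[tail_ids]) - exp(cutoff))
    k <- fit$k
    if (is.finite(k) && !is.na(fit$sigma)) {
      p <- (seq_len(M) - 0.5) / M
      qgpd <- if (abs(k) < 1e-12) -fit$sigma * log1p(-p)
              else fit$sigma * (exp(-k * log1p(-p)) - 1) / k
      smoothed <- log(exp(cutoff) + qgpd)
      lw[tail_ids[sort.list(lw[tail_ids])]] <- pmin(smoothed, 0)
    }
  } else k <- NA_real_
  list(lw = lw, k = k)
}

# Per-draw pointwise log-likelihood matrix (S draws x N observations).
# Requires the fit to have been run with monitor_ranef = TRUE when the
# model has random effects.
log_lik_matrix <- function(fit) {
  stopifnot(inherits(fit, "bayes_fit"))
  dm <- fit$design
  draws <- fit$draws
  S <- nrow(draws)
  bdraws <- draws[, fit$term_names, drop = FALSE]
  mu <- bdraws %*% t(dm$X)
  for (f in seq_along(dm$random)) {
    r <- dm$random[[f]]
    q <- ncol(r$Z); L <- length(r$levels)
    for (k in seq_len(q)) {
      cols <- if (q == 1) paste0("u", f, "[", seq_len(L), "]")
              else paste0("u", f, "[", seq_len(L), ",", k, "]")
      if (!all(cols %in% colnames(draws)))
        stop_config("random-effect draws missing; refit with monitor_ranef = TRUE")
      U <- draws[, cols, drop = FALSE]
      mu <- mu + U[, r$index, drop = FALSE] *
        matrix(r$Z[, k], nrow = S, ncol = length(r$index), byrow = TRUE)
    }
  }
  sigma <- draws[, "sigma"]
  y <- matrix(dm$y, nrow = S, ncol = length(dm$y), byrow = TRUE)
  -0.5 * log(2 * pi) - log(sigma) - 0.5 * ((y - mu) / sigma)^2
}

#' Approximate leave-one-out cross-validation for a fit
#'
#' Pointwise expected log predictive density via Pareto-smoothed
#' importance-sampling LOO: for each observation the importance ratios
#' 1/p(y_i | theta) are tail-smoothed with a generalised Pareto fit before
#' combining. The fit must carry random-effect draws
#' (`fit_model(..., monitor_ranef = TRUE)`).
#'
#' @param fit A `bayes_fit`.
#' @return Object of class `loo_result`: total `elpd_loo` with `se`,
#'   `pointwise` elpds, and the Pareto `khat` diagnostics.
#' @export
loo_elpd <- function(fit) {
  ll <- log_lik_matrix(fit)
  N <- ncol(ll)
  pointwise <- numeric(N); khat <- numeric(N)
  for (i in seq_len(N)) {
    ps <- psis_weights(-ll[, i])
    pointwise[i] <- log_sum_exp(ps$lw + ll[, i]) - log_sum_exp(ps$lw)
    khat[i] <- ps$k
  }
  structure(list(elpd_loo = sum(pointwise),
                 se = stats::sd(pointwise) * sqrt(N),
                 pointwise = pointwise, khat = khat,
                 model = fit$spec$name, y = fit$design$y),
            class = "loo_result")
}

#' Compare models by LOO expected log predictive density
#'
#' @param ... `bayes_fit` or `loo_result` objects (named arguments name the
#'   models). All fits must share the same response rows.
#' @return Data frame ordered by elpd: `model, elpd_loo, se, elpd_diff,
#'   se_diff` where differences are against the best model (pointwise,
#'   so the self-difference is exactly 0).
#' @export
loo_compare <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], c("bayes_fit", "loo_result")))
    fits <- fits[[1]]
  loos <- lapply(fits, function(f) {
    if (inherits(f, "loo_result")) f else loo_elpd(f)
  })
  nms <- names(loos)
  if (is.null(nms) || any(nms == ""))
    nms <- vapply(loos, function(l) l$model, "")
  y0 <- loos[[1]]$y
  for (l in loos)
    if (length(l$y) != length(y0) || any(abs(l$y - y0) > 1e-12))
      stop_config("models were fit to different response rows")
  elpd <- vapply(loos, function(l) l$elpd_loo, numeric(1))
  best <- which.max(elpd)
  diffs <- vapply(loos, function(l) {
    d <- l$pointwise - loos[[best]]$pointwise
    c(sum(d), stats::sd(d) * sqrt(length(d)))
  }, numeric(2))
  out <- data.frame(model = nms,
                    elpd_loo = elpd,
                    se = vapply(loos, function(l) l$se, numeric(1)),
                    elpd_diff = diffs[1, ],
                    se_diff = diffs[2, ],
                    stringsAsFactors = FALSE)
  out <- out[sort.list(-out$elpd_loo), ]
  rownames(out) <- NULL
  out
}
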