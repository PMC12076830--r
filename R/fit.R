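#' MCMC sampler settings
#'
#' Defaults follow the analysis protocol: four chains of 4000 iterations
#' each, the first 1000 discarded as warm-up.
#'
#' @param chains Number of chains (>= 2).
#' @param iterations Total iterations per chain, including warmup.
#' @param warmup Warm-up (burn-in) iterations per chain.
#' @param adapt Adaptation steps before warmup.
#' @param seed Integer seed; chain seeds derive from it.
#' @return Object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 4, iterations = 4000, warmup = 1000,
                          adapt = 500, seed = 1L) {
  if (chains < 2) stop_config("chains must be >= 2")
  if (iterations <= warmup) stop_config("iterations must exceed warmup")
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 adapt = as.integer(adapt),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

# JAGS model code for a Gaussian linear model with up to two (crossed)
# independent random-effect blocks. Coefficients get normal priors with
# per-coefficient mean/sd; every SD gets a half-Cauchy prior, expressed as
# a half-t with 1 degree of freedom.
jags_code <- function(n_random_q) {
  re_mu <- ""
  re_blocks <- ""
  for (f in seq_along(n_random_q)) {
    q <- n_random_q[f]
    if (q == 1) {
      re_mu <- paste0(re_mu, sprintf(" + Z%d[i,1] * u%d[g%d[i]]", f, f, f))
      re_blocks <- paste0(re_blocks, sprintf("
  sd_u%d[1] ~ dt(0, pow(sd_scale, -2), 1) T(0,)
  for (l in 1:L%d) { u%d[l] ~ dnorm(0, pow(sd_u%d[1], -2)) }
", f, f, f, f))
    } else {
      re_mu <- paste0(re_mu, sprintf(" + inprod(Z%d[i,], u%d[g%d[i],])",
                                     f, f, f))
      re_blocks <- paste0(re_blocks, sprintf("
  for (k in 1:%d) {
    sd_u%d[k] ~ dt(0, pow(sd_scale, -2), 1) T(0,)
    for (l in 1:L%d) { u%d[l,k] ~ dnorm(0, pow(sd_u%d[k], -2)) }
  }
", q, f, f, f, f))
    }
  }
  sprintf("
model {
  for (i in 1:N) {
    mu[i] <- inprod(X[i,], b)%s
    y[i] ~ dnorm(mu[i], tau_res)
  }
  for (p in 1:P) { b[p] ~ dnorm(b_prior_mean[p], pow(b_prior_sd[p], -2)) }
%s
  sigma ~ dt(0, pow(sd_scale, -2), 1) T(0,)
  tau_res <- pow(sigma, -2)
}", re_mu, re_blocks)
}

#' Fit a declared model with MCMC
#'
#' Gaussian linear model with crossed Gaussian random intercepts/slopes,
#' normal coefficient priors and half-Cauchy SD priors, sampled with JAGS.
#' Seeded chain initialisation makes refits with identical settings
#' bit-identical. Convergence diagnostics (split-free Gelman-Rubin Rhat per
#' monitored parameter) are attached; Rhat above the threshold raises a
#' warning, never a silent discard. The Gibbs-type sampler used here has no
#' divergent-transition diagnostic, so that count is reported as `NA`.
#'
#' @param spec A [model_spec()].
#' @param table The canonical table for the spec's `data` slot.
#' @param settings An [mcmc_settings()].
#' @param monitor_ranef Also store random-effect draws (needed for
#'   pointwise log-likelihoods / LOO).
#' @param rhat_threshold Flag parameters with Rhat above this value.
#' @return Object of class `bayes_fit`: spec, named pooled draws, coda
#'   chains, design matrices, diagnostics and settings.
#' @export
fit_model <- function(spec, table, settings = mcmc_settings(),
                      monitor_ranef = FALSE, rhat_threshold = 1.01) {
  stopifnot(inherits(spec, "model_spec"), inherits(settings, "mcmc_settings"))
  dm <- build_design_matrices(spec, table)
  N <- length(dm$y); P <- ncol(dm$X)
  if (!N) stop_config("no data to fit")

  data <- list(y = as.numeric(dm$y), X = unname(dm$X), N = N, P = P,
               b_prior_mean = numeric(P), b_prior_sd = numeric(P),
               sd_scale = spec$priors$sd_scale)
  cp <- coefficient_priors(spec$priors, colnames(dm$X))
  data$b_prior_mean <- cp$mean
  data$b_prior_sd <- cp$sd

  qs <- integer(0)
  for (f in seq_along(dm$random)) {
    r <- dm$random[[f]]
    qs[f] <- ncol(r$Z)
    data[[paste0("Z", f)]] <- unname(r$Z)
    data[[paste0("g", f)]] <- r$index
    data[[paste0("L", f)]] <- length(r$levels)
  }

  monitors <- c("b", "sigma",
                if (length(qs)) paste0("sd_u", seq_along(qs)),
                if (monitor_ranef && length(qs)) paste0("u", seq_along(qs)))
  inits <- lapply(seq_len(settings$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = settings$seed * 1009L + ch)
  })

  jm <- rjags::jags.model(textConnection(jags_code(qs)), data = data,
                          inits = inits, n.chains = settings$chains,
                          n.adapt = settings$adapt, quiet = TRUE)
  stats::update(jm, settings$warmup, progress.bar = "none")
  chains <- rjags::coda.samples(jm, monitors,
                                n.iter = settings$iterations - settings$warmup,
                                progress.bar = "none")

  # map JAGS parameter names to term names
  name_map <- stats::setNames(colnames(dm$X), paste0("b[", seq_len(P), "]"))
  if (P == 1) name_map <- stats::setNames(colnames(dm$X), "b")
  for (f in seq_along(dm$random)) {
    r <- dm$random[[f]]
    sd_names <- paste0("sd_", r$group, ":", colnames(r$Z))
    jags_sd <- paste0("sd_u", f, "[", seq_len(qs[f]), "]")
    name_map <- c(name_map, stats::setNames(sd_names, jags_sd))
    if (qs[f] == 1)  # coda drops the [1] on length-1 vectors
      name_map <- c(name_map, stats::setNames(sd_names, paste0("sd_u", f)))
  }
  name_map <- c(name_map, sigma = "sigma")

  pooled <- do.call(rbind, lapply(chains, as.matrix))
  hit <- colnames(pooled) %in% names(name_map)
  colnames(pooled)[hit] <- name_map[colnames(pooled)[hit]]

  rhat <- tryCatch({
    ps <- coda::gelman.diag(chains, multivariate = FALSE,
                            autoburnin = FALSE)$psrf[, 1]
    nm <- names(ps); hit <- nm %in% names(name_map)
    nm[hit] <- name_map[nm[hit]]
    stats::setNames(ps, nm)
  }, error = function(e) stats::setNames(rep(NA_real_, ncol(pooled)),
                                         colnames(pooled)))
  flagged <- names(rhat)[!is.na(rhat) & rhat > rhat_threshold]
  diagnostics <- list(rhat = rhat, divergent_transition_count = NA_integer_,
                      rhat_threshold = rhat_threshold, flagged = flagged)
  if (length(flagged))
    warning(sprintf("model %s: Rhat > %.3f for %s", spec$name, rhat_threshold,
                    paste(utils::head(flagged, 5), collapse = ", ")),
            call. = FALSE)

  structure(list(spec = spec, draws = pooled, chains = chains,
                 design = dm, diagnostics = diagnostics,
                 settings = settings, term_names = colnames(dm$X)),
            class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat(sprintf("Bayesian mixed-effects fit: model %s (%d rows, %d draws)\n",
              x$spec$name, length(x$design$y), nrow(x$draws)))
  print(posterior_table(x))
  invisible(x)
}
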