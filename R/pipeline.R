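# Small stable checksum for provenance blocks (no external digest
# dependency): FNV-1a over the serialised JSON of the config.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = 10)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Assemble a run configuration
#'
#' @param config A [design_config()] for the synthetic study.
#' @param effects An [effect_spec()].
#' @param profiles A [kinematic_profiles()] object.
#' @param models Character: model names from [model_catalogue()].
#' @param settings An [mcmc_settings()].
#' @param outdir Output directory, or `NULL` to keep everything in memory.
#' @param catalogue The model catalogue to draw specs from.
#' @return Object of class `run_config`.
#' @export
run_config <- function(config = design_config(),
                       effects = effect_spec(),
                       profiles = kinematic_profiles(),
                       models = c("UK.1", "UK.2"),
                       settings = mcmc_settings(),
                       outdir = NULL,
                       catalogue = model_catalogue()) {
  unknown <- setdiff(models, names(catalogue))
  if (length(unknown))
    stop_config("unknown model(s): %s", paste(unknown, collapse = ", "))
  structure(list(config = config, effects = effects, profiles = profiles,
                 models = models, settings = settings, outdir = outdir,
                 catalogue = catalogue),
            class = "run_config")
}

#' Load a run configuration from a declarative YAML file
#'
#' The YAML mirrors the constructors: top-level blocks `design`, `effects`,
#' `profiles` (a `dispersion` map plus shared settings), `models`, `mcmc`
#' and `outdir`; omitted blocks fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(design_config, c(y$design))
  eff <- do.call(effect_spec, c(y$effects))
  prof <- if (is.null(y$profiles)) kinematic_profiles() else {
    args <- y$profiles
    if (!is.null(args$dispersion)) args$dispersion <- unlist(args$dispersion)
    do.call(kinematic_profiles, args)
  }
  settings <- do.call(mcmc_settings, c(y$mcmc))
  run_config(config = cfg, effects = eff, profiles = prof,
             models = if (is.null(y$models)) c("UK.1", "UK.2") else y$models,
             settings = settings, outdir = y$outdir)
}

canonical_tables <- function(study) {
  acc <- score_trials(study$ratings, study$animations,
                      study$design$participants)
  jd <- jerk_difference_table(study$kinematics$observer_jerk,
                              study$kinematics$animation_jerk, acc)
  list(
    trials = build_model_table(acc, jd, study$design$participants),
    animations = jerk_model_table(study$kinematics$animation_jerk,
                                  study$animations,
                                  study$design$participants),
    cv = jerk_cv(study$kinematics$animation_jerk, study$animations,
                 study$design$participants)
  )
}

#' Run the full pipeline: simulate, extract, score, fit, report
#'
#' Executes every stage in order — synthetic study generation, kinematic
#' feature extraction, accuracy scoring, model fitting for each selected
#' catalogue model, posterior summaries, Savage-Dickey ratios for the
#' fixed effects, and convergence diagnostics — and assembles a report
#' bundle with a provenance block (seed, config hash, package and R
#' versions). Fully deterministic given the configuration.
#'
#' @param rc A [run_config()].
#' @return Object of class `report_bundle`.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  study <- simulate_study(rc$config, rc$effects, rc$profiles)
  tables <- canonical_tables(study)

  fits <- list(); posterior <- list(); bf <- list(); diagnostics <- list()
  for (nm in rc$models) {
    spec <- rc$catalogue[[nm]]
    fit <- fit_model(spec, tables[[spec$data]], rc$settings)
    fits[[nm]] <- fit
    posterior[[nm]] <- posterior_table(fit)
    fixed <- setdiff(fit$term_names, "(Intercept)")
    bf[[nm]] <- do.call(rbind, lapply(fixed, function(tm) {
      s <- savage_dickey(fit, tm)
      data.frame(model = nm, term = tm, bf01 = s$bf01,
                 flagged = s$flagged, stringsAsFactors = FALSE)
    }))
    diagnostics[[nm]] <- list(
      max_rhat = max(fit$diagnostics$rhat, na.rm = TRUE),
      flagged = fit$diagnostics$flagged,
      divergent_transition_count =
        fit$diagnostics$divergent_transition_count)
  }

  provenance <- list(
    seed = rc$config$seed,
    config_hash = config_hash(list(
      design = unclass(rc$config)[setdiff(names(rc$config), "words")],
      words = rc$config$words$word,
      effects = unclass(rc$effects),
      profiles = unclass(rc$profiles),
      models = rc$models,
      mcmc = unclass(rc$settings))),
    package_version = as.character(utils::packageVersion("animent")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  bundle <- structure(list(study = study, tables = tables, fits = fits,
                           posterior = posterior, savage_dickey = bf,
                           diagnostics = diagnostics,
                           provenance = provenance),
                      class = "report_bundle")
  if (!is.null(rc$outdir)) write_report(bundle, rc$outdir)
  bundle
}

#' Write a report bundle's artefacts
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_study(bundle$study, file.path(dir, "study"))
  utils::write.csv(bundle$tables$trials, file.path(dir, "model_table.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$tables$cv, file.path(dir, "jerk_cv.csv"),
                   row.names = FALSE)
  for (nm in names(bundle$posterior))
    utils::write.csv(bundle$posterior[[nm]],
                     file.path(dir, sprintf("posterior_%s.csv", nm)),
                     row.names = FALSE)
  report <- list(provenance = bundle$provenance,
                 diagnostics = bundle$diagnostics,
                 posterior = bundle$posterior,
                 savage_dickey = bundle$savage_dickey)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE)
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("report_bundle: %d model(s), seed %d, config %s\n",
              length(x$fits), x$provenance$seed, x$provenance$config_hash))
  for (nm in names(x$posterior)) {
    cat(sprintf("\n== Model %s ==\n", nm))
    print(x$posterior[[nm]])
  }
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a study, fits the recovery model, and records
#' whether the 95% credible intervals cover the injected effects and how
#' biased the posterior means are. Per-replicate failures are recorded,
#' not fatal.
#'
#' @param config A [design_config()] (its seed is replaced per replicate).
#' @param effects The injected [effect_spec()].
#' @param n_replicates Number of replicates (>= 2).
#' @param seeds Integer vector of study seeds, one per replicate.
#' @param settings MCMC settings for each fit.
#' @param spec Model to fit; defaults to [recovery_model_spec()].
#' @param terms Named numeric: coefficient name -> injected true value.
#' @return Data frame: replicate, seed, term, true value, posterior mean,
#'   CrI, coverage indicator and bias (plus an `error` column for failed
#'   replicates).
#' @export
recovery_experiment <- function(config = design_config(n_per_cell = 8),
                                effects = effect_spec(),
                                n_replicates = 20,
                                seeds = seq_len(n_replicates),
                                settings = mcmc_settings(chains = 2,
                                                         iterations = 2000,
                                                         warmup = 500),
                                spec = recovery_model_spec(),
                                terms = NULL) {
  if (n_replicates < 2) stop_config("n_replicates must be >= 2")
  stopifnot(length(seeds) == n_replicates)
  if (is.null(terms))
    terms <- c(generator_groupaut = effects$beta_generator_group,
               observer_groupaut = effects$beta_observer_group)
  rows <- lapply(seq_len(n_replicates), function(i) {
    cfg <- config; cfg$seed <- as.integer(seeds[i])
    tryCatch({
      study <- simulate_study(cfg, effects)
      tables <- canonical_tables(study)
      st <- settings; st$seed <- as.integer(seeds[i])
      fit <- suppressWarnings(fit_model(spec, tables[[spec$data]], st))
      do.call(rbind, lapply(names(terms), function(tm) {
        s <- summarise_effect(fit, tm)
        data.frame(replicate = i, seed = seeds[i], term = tm,
                   true = terms[[tm]], e_mu = s$e_mu,
                   cri_low = s$cri_low, cri_high = s$cri_high,
                   covered = s$cri_low <= terms[[tm]] &
                             terms[[tm]] <= s$cri_high,
                   bias = s$e_mu - terms[[tm]],
                   error = NA_character_, stringsAsFactors = FALSE)
      }))
    }, error = function(e) {
      data.frame(replicate = i, seed = seeds[i], term = NA_character_,
                 true = NA_real_, e_mu = NA_real_, cri_low = NA_real_,
                 cri_high = NA_real_, covered = NA, bias = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
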