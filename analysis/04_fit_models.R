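#!/usr/bin/env Rscript
# Stage 4: Bayesian mixed-effects models. Fits a selection of catalogue
# models to the stage-3 modelling table, reports posterior summaries
# (Emu, 95% CrI, directional posterior probabilities), Savage-Dickey
# density ratios, the classic own-group post-hoc contrasts, and a LOO
# comparison of the two mean-jerk models (which share response rows).
#
# Sampler settings here are reduced relative to the reporting protocol
# (2 chains x 2500 iterations instead of 4 x 4000) to keep a desk-scale
# run short; pass --full for the protocol settings.

suppressMessages(library(animent))

args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(arg("--seed", "1"))
outdir <- arg("--outdir", "results")
models <- strsplit(arg("--models", "UK.1,UK.2,JP.1,JPUK.7"), ",")[[1]]
settings <- if ("--full" %in% args) mcmc_settings(seed = seed) else
  mcmc_settings(chains = 2, iterations = 2500, warmup = 500, adapt = 300,
                seed = seed)

study_dir <- file.path(outdir, "study")
trials <- as_model_table(read.csv(file.path(outdir, "model_table.csv")))
animations <- animation_set(read.csv(file.path(study_dir, "animations.csv")))
participants <- read.csv(file.path(study_dir, "participants.csv"))
kin <- read.csv(file.path(outdir, "kinematics", "kinematics.csv"))
tables <- list(trials = trials,
               animations = jerk_model_table(kin, animations, participants),
               cv = jerk_cv(kin, animations, participants))

catalogue <- model_catalogue()
fit_dir <- file.path(outdir, "fits")
dir.create(fit_dir, recursive = TRUE, showWarnings = FALSE)

for (nm in models) {
  spec <- catalogue[[nm]]
  if (is.null(spec)) stop("unknown model: ", nm)
  cat(sprintf("\n== Model %s: %s ~ %s ==\n", nm, spec$response, spec$fixed))
  fit <- fit_model(spec, tables[[spec$data]], settings)
  pt <- posterior_table(fit)
  print(pt, digits = 3)
  write.csv(pt, file.path(fit_dir, sprintf("posterior_%s.csv", nm)),
            row.names = FALSE)

  fixed <- setdiff(fit$term_names, "(Intercept)")
  bf <- do.call(rbind, lapply(fixed, function(tm) {
    s <- savage_dickey(fit, tm)
    data.frame(term = tm, bf01 = s$bf01, flagged = s$flagged)
  }))
  write.csv(bf, file.path(fit_dir, sprintf("savage_dickey_%s.csv", nm)),
            row.names = FALSE)

  if (nm %in% c("UK.1", "JP.1")) {
    # own- vs other-group generator contrast within each observer group
    for (og in c("non_aut", "aut")) {
      ct <- posterior_contrast(fit,
                               list(generator_group = "aut",
                                    observer_group = og),
                               list(generator_group = "non_aut",
                                    observer_group = og))
      cat(sprintf(
        "  contrast gen aut-non_aut | obs %s: Emu %.2f, CrI [%.2f, %.2f]\n",
        og, ct$e_mu, ct$cri_low, ct$cri_high))
    }
  }
}

cat("\n== LOO comparison: mean-jerk models JPUK.4 vs JPUK.5 ==\n")
f4 <- fit_model(catalogue$JPUK.4, tables$animations, settings,
                monitor_ranef = TRUE)
f5 <- fit_model(catalogue$JPUK.5, tables$animations, settings,
                monitor_ranef = TRUE)
cmp <- loo_compare(JPUK.4 = f4, JPUK.5 = f5)
print(cmp, digits = 4)
write.csv(cmp, file.path(fit_dir, "loo_jerk_models.csv"), row.names = FALSE)
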