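#!/usr/bin/env Rscript
# Stage 3: trial scoring. Computes accuracy (target rating minus mean
# non-target rating) for every rated trial and joins factors and the
# jerk-difference covariate into the modelling table.

suppressMessages(library(animent))

args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
outdir <- arg("--outdir", "results")
study_dir <- file.path(outdir, "study")

animations <- animation_set(read.csv(file.path(study_dir, "animations.csv")))
participants <- read.csv(file.path(study_dir, "participants.csv"))
ratings <- read.csv(file.path(study_dir, "ratings.csv"),
                    check.names = FALSE)
jd <- read.csv(file.path(outdir, "kinematics", "jerk_differences.csv"))

acc <- score_trials(ratings, animations, participants)
tab <- build_model_table(acc, jd, participants)
write.csv(tab, file.path(outdir, "model_table.csv"), row.names = FALSE)

cat(sprintf("Scored %d trials.\n", nrow(tab)))
cell_means <- aggregate(accuracy ~ observer_culture + observer_group +
                          generator_group + condition, tab, mean)
cat("Cell-mean accuracy:\n")
print(cell_means, row.names = FALSE, digits = 3)
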