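#!/usr/bin/env Rscript
# Stage 2: kinematic feature extraction. Reads the stage-1 trajectory and
# session artefacts, computes per-animation mean jerk (third derivative of
# position, magnitude-averaged), observer-animation jerk differences
# matched by word, and the per-cell jerk coefficient of variation.

suppressMessages(library(animent))

args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
outdir <- arg("--outdir", "results")
study_dir <- file.path(outdir, "study")

animations <- animation_set(
  read.csv(file.path(study_dir, "animations.csv")),
  read.csv(file.path(study_dir, "trajectories.csv")),
  sampling_rate = 60)
participants <- read.csv(file.path(study_dir, "participants.csv"))
sessions <- read.csv(file.path(study_dir, "sessions.csv"))

kin <- kinematic_summaries(animations)
own <- observer_word_jerk(animations)
jd <- jerk_difference_table(own, kin, sessions)
cv <- jerk_cv(kin, animations, participants)

dir.create(file.path(outdir, "kinematics"), recursive = TRUE,
           showWarnings = FALSE)
write.csv(kin, file.path(outdir, "kinematics", "kinematics.csv"),
          row.names = FALSE)
write.csv(own, file.path(outdir, "kinematics", "observer_jerk.csv"),
          row.names = FALSE)
write.csv(jd, file.path(outdir, "kinematics", "jerk_differences.csv"),
          row.names = FALSE)
write.csv(cv, file.path(outdir, "kinematics", "jerk_cv.csv"),
          row.names = FALSE)

cat(sprintf("Mean jerk over %d animations: median %.3f [IQR %.3f-%.3f]\n",
            nrow(kin), median(kin$mean_jerk),
            quantile(kin$mean_jerk, 0.25), quantile(kin$mean_jerk, 0.75)))
agg <- aggregate(cv ~ culture + group, cv, mean)
cat("Mean jerk CV per cell (averaged over words):\n")
print(agg, row.names = FALSE)
cat(sprintf("Jerk differences computed for %d trials\n", nrow(jd)))
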