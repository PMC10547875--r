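#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Draws a 30-subject cohort of Bayesian observers (per-context parameters
# uniform on the published group mean +/- sd ranges, coupled across contexts)
# and writes the trial tables plus the generating parameters.

suppressPackageStartupMessages(library(bayestiming))

seed <- 1L
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- cohort_spec(seed = seed)
cat(sprintf("simulating %d subjects (seed %d)...\n", spec$n_subjects, seed))
cohort <- simulate_cohort(spec)

write.csv(cohort$reproduction, file.path(out, "reproduction_trials.csv"),
          row.names = FALSE)
write.csv(cohort$discrimination, file.path(out, "discrimination_trials.csv"),
          row.names = FALSE)
write.csv(cohort$truth, file.path(out, "generating_parameters.csv"),
          row.names = FALSE)

cat(sprintf("wrote %d reproduction and %d discrimination trials for %d subjects\n",
            nrow(cohort$reproduction), nrow(cohort$discrimination),
            length(unique(cohort$truth$subject_id))))
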