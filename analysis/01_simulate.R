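#!/usr/bin/env Rscript
# Stage 1: generate the synthetic colony.
#
# Produces a multi-generational pedigree (~1000 animals across 4
# generations), gene-dropped biallelic variants, two-day behavioral item
# records driven by the bivariate Activity/Emotionality genetic model
# (h2 = 0.19 each, rho_g = 0.65), and two longitudinal treat-refusal
# assessments.  Everything downstream (stages 02-04) reads only the files
# written here.

suppressMessages(library(macaqueIT))

out_dir <- "results/synthetic"
seed <- 20260928L

cfg <- sim_config(n_founders = 150, n_generations = 4, mean_offspring = 2.2,
                  n_snvs = 2000, seed = seed)
ds <- simulate_dataset(cfg, dir = out_dir, n_assessments = 2)

cat("wrote", length(ds$files), "files to", out_dir, "\n")
cat("  animals:            ", nrow(ds$pedigree), "\n")
cat("  variants:           ", ncol(ds$geno$dosage), "\n")
cat("  inhibited fraction: ", round(mean(ds$labels$inhibited), 3), "\n")
cat("  realized h2:        ",
    paste(names(ds$phenotypes$truth$realized_h2),
          round(ds$phenotypes$truth$realized_h2, 3), collapse = ", "), "\n")
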