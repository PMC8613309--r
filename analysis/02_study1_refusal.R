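#!/usr/bin/env Rscript
# Stage 2 (Study-1 style): does infant inhibited temperament predict
# adult treat refusal, and is refusal stable across repeated assessments?
#
# Reads the refusal records written by stage 01, fits the logistic model
# refusal ~ IT (and + age), and cross-tabulates the two assessments.

suppressMessages(library(macaqueIT))

ref <- read.csv("results/synthetic/refusal.csv")
first <- ref[ref$assessment == 1, ]

fit_it <- fit_logistic(first$first_trial_refused,
                       data.frame(it = first$inhibited))
fit_age <- fit_logistic(first$first_trial_refused,
                        data.frame(it = first$inhibited, age = first$age))
print(fit_it)
print(fit_age)

m <- merge(ref[ref$assessment == 1, c("id", "refused")],
           ref[ref$assessment == 2, c("id", "refused")], by = "id")
chi <- stability_chi2(m$refused.x, m$refused.y)
print(chi)

summ <- refusal_summary(ref)
cat(sprintf("first-trial refusers retrieving later: %d/%d (%.1f%%)\n",
            summ$later_retrievers, summ$first_refusers,
            summ$later_retrieval_pct))
cat(sprintf("consistent refusal across assessments: %.1f%%\n",
            summ$consistency_pct))

dir.create("results", showWarnings = FALSE)
out <- list(
  logistic_it = fit_it[c("coefficients", "se", "z", "p_value", "n")],
  logistic_it_age = fit_age[c("coefficients", "se", "z", "p_value", "n")],
  stability = chi[c("statistic", "df", "p_value", "n")],
  summary = summ[c("first_refusers", "later_retrievers",
                   "later_retrieval_pct", "consistency_pct")])
jsonlite::write_json(out, "results/study1_refusal.json", auto_unbox = TRUE,
                     digits = NA)
cat("wrote results/study1_refusal.json\n")
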