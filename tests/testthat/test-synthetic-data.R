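test_that("pedigree simulation respects structure, determinism and errors", {
  # nuclear family forced by construction
  cfg <- sim_config(n_founders = 2, n_generations = 1, mean_offspring = 2,
                    n_snvs = 0, seed = 7)
  ped <- simulate_pedigree(cfg)
  off <- ped[ped$generation == 1, ]
  expect_true(all(off$sire == ped$id[ped$sex == "M" & ped$generation == 0]))
  expect_true(all(off$dam == ped$id[ped$sex == "F" & ped$generation == 0]))

  # zero generations: founders only
  ped0 <- simulate_pedigree(sim_config(n_founders = 8, n_generations = 0,
                                       n_snvs = 0, seed = 1))
  expect_equal(nrow(ped0), 8)
  expect_true(all(ped0$sire == 0 & ped0$dam == 0))

  # determinism
  cfg7 <- sim_config(n_founders = 30, n_generations = 3, n_snvs = 0, seed = 7)
  expect_identical(simulate_pedigree(cfg7), simulate_pedigree(cfg7))

  # every non-founder has correctly sexed parents born earlier
  big <- simulate_pedigree(sim_config(n_founders = 40, n_generations = 3,
                                      n_snvs = 0, seed = 3))
  nf <- big[big$sire != 0, ]
  expect_true(all(big$sex[match(nf$sire, big$id)] == "M"))
  expect_true(all(big$sex[match(nf$dam, big$id)] == "F"))
  expect_true(all(big$generation[match(nf$sire, big$id)] < nf$generation))

  # degenerate founder sets cannot mate
  expect_error(
    simulate_pedigree(sim_config(n_founders = 1, n_generations = 1,
                                 n_snvs = 0, seed = 1)),
    "founder")
})

test_that("gene dropping is Mendelian and conserves allele frequency", {
  ped <- nuclear_pedigree()
  cfg <- toy_config()

  # fixed founder frequencies: monomorphic sites stay monomorphic
  g0 <- gene_drop_genotypes(ped, cfg, freqs = rep(1e-12, 20))
  expect_true(all(g0$dosage == 0))
  g2 <- gene_drop_genotypes(ped, cfg, freqs = rep(1 - 1e-12, 20))
  expect_true(all(g2$dosage == 2))

  # homozygous-opposite parents always give heterozygous offspring
  # (ids: 1 = sire, 2 = dam, 3 = their offspring)
  g <- gene_drop_genotypes(ped, cfg, freqs = rep(0.5, 4000))
  sire2_dam0 <- g$dosage["1", ] == 2 & g$dosage["2", ] == 0
  expect_gt(sum(sire2_dam0), 50)
  expect_true(all(g$dosage["3", sire2_dam0] == 1))
  hom_hom <- g$dosage["1", ] == 0 & g$dosage["2", ] == 0
  expect_true(all(g$dosage["3", hom_hom] == 0))

  # parent-offspring dosage correlation -> 0.5 (replicates = unlinked loci)
  r <- cor(g$dosage["1", ], g$dosage["3", ])
  expect_lt(abs(r - 0.5), 0.05)

  # no selection: descendant allele frequency matches founders
  ped_big <- simulate_pedigree(sim_config(n_founders = 60, n_generations = 2,
                                          n_snvs = 0, seed = 8))
  gb <- gene_drop_genotypes(ped_big, toy_config(), freqs = rep(0.3, 3000))
  founder_rows <- ped_big$generation == 0
  expect_lt(abs(mean(gb$dosage[founder_rows, ]) / 2 - 0.3), 0.02)
  expect_lt(abs(mean(gb$dosage[!founder_rows, ]) / 2 - 0.3), 0.03)

  # determinism
  expect_identical(gene_drop_genotypes(ped, cfg),
                   gene_drop_genotypes(ped, cfg))
})

test_that("breeding values have covariance proportional to A", {
  ped <- small_deep_pedigree()
  A <- numerator_relationship_matrix(ped)
  cfg <- sim_config(n_founders = 4, n_generations = 0, n_snvs = 0,
                    h2_activity = 0.5, h2_emotionality = 0.5,
                    rho_g_true = 0, sex_effect = 0, seed = 1)
  B <- 400
  bvs <- matrix(NA_real_, B, nrow(ped))
  for (r in seq_len(B)) {
    cfg$seed <- r
    bvs[r, ] <- simulate_phenotypes(ped, cfg)$truth$breeding_values[, 1]
  }
  emp <- cov(bvs)                      # should be ~ 0.5 * A entrywise
  expect_lt(max(abs(emp - 0.5 * A)), 0.12)
  expect_lt(mean(abs(emp - 0.5 * A)), 0.03)
})

test_that("degenerate phenotype configurations behave as the model dictates", {
  ped <- simulate_pedigree(sim_config(n_founders = 30, n_generations = 2,
                                      n_snvs = 0, seed = 5))
  # rho_g = 1 with equal h2: breeding values identical up to sign/scale
  cfg1 <- sim_config(n_founders = 30, n_generations = 2, n_snvs = 0,
                     h2_activity = 0.4, h2_emotionality = 0.4,
                     rho_g_true = 1, seed = 5)
  bv <- simulate_phenotypes(ped, cfg1)$truth$breeding_values
  expect_equal(cor(bv[, 1], bv[, 2]), 1, tolerance = 1e-10)

  # h2 = 0: full-sib families share no phenotypic signal
  cfg0 <- sim_config(n_founders = 60, n_generations = 1, mean_offspring = 4,
                     n_snvs = 0, h2_activity = 0, h2_emotionality = 0,
                     rho_g_true = 0, sex_effect = 0, seed = 6)
  ped0 <- simulate_pedigree(cfg0)
  ph <- simulate_phenotypes(ped0, cfg0)
  expect_true(all(abs(ph$truth$breeding_values) < 1e-4))
  fam <- paste(ped0$sire, ped0$dam)[ped0$generation == 1]
  lat <- ph$truth$latent[ped0$generation == 1, 1, 1]
  expect_gt(anova(lm(lat ~ fam))$`Pr(>F)`[1], 0.01)

  # realized h2 definition holds
  cfgh <- sim_config(n_founders = 40, n_generations = 2, n_snvs = 0,
                     h2_activity = 0.3, sex_effect = 0, seed = 9)
  pedh <- simulate_pedigree(cfgh)
  phh <- simulate_phenotypes(pedh, cfgh)
  rh <- var(phh$truth$breeding_values[, 1]) /
    mean(apply(phh$truth$latent[, 1, ], 2, var))
  expect_equal(unname(phh$truth$realized_h2["activity"]), rh,
               tolerance = 1e-12)
})

test_that("refusal simulation follows its logistic model", {
  labels <- data.frame(id = 1:4000, inhibited = rep(c(TRUE, FALSE), 2000))
  cfg <- sim_config(n_snvs = 0, refusal_intercept = -0.4, beta_it = 0,
                    beta_age = 0, seed = 11)
  ref <- simulate_refusal(labels, ages = rep(5, 4000), cfg)
  expect_lt(abs(mean(ref$first_trial_refused) - plogis(-0.4)), 0.03)

  # overwhelming IT effect: every inhibited animal refuses trial 1
  cfg2 <- sim_config(n_snvs = 0, refusal_intercept = -30, beta_it = 60,
                     beta_age = 0, seed = 12)
  ref2 <- simulate_refusal(labels, ages = rep(5, 4000), cfg2)
  expect_true(all(ref2$first_trial_refused[labels$inhibited] == 1))
  expect_true(all(ref2$first_trial_refused[!labels$inhibited] == 0))
})

test_that("simulate_dataset writes a consistent, reproducible file set", {
  cfg <- sim_config(n_founders = 12, n_generations = 1, n_snvs = 20, seed = 2)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  # tiny cohort: some rare items are constant, so scoring warns by design
  suppressWarnings(out <- simulate_dataset(cfg, dir = d1))
  expect_true(all(file.exists(out$files)))
  man <- jsonlite::read_json(out$files[["manifest"]])
  expect_equal(man$seed, 2)
  # round trips
  ped2 <- read_pedigree(out$files[["pedigree"]])
  expect_equal(ped2$id, out$pedigree$id)
  rec2 <- read_phenotypes(out$files[["phenotypes"]])
  expect_equal(nrow(rec2), nrow(out$phenotypes$records))
  g2 <- read_vcf(out$files[["genotypes"]])
  expect_equal(unname(g2$dosage[as.character(out$pedigree$id), ]),
               unname(out$geno$dosage))
  # same seed, byte-identical outputs
  suppressWarnings(simulate_dataset(cfg, dir = d2))
  for (f in setdiff(names(out$files), "manifest"))
    expect_identical(readLines(out$files[[f]]),
                     readLines(file.path(d2, basename(out$files[[f]]))))
})
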