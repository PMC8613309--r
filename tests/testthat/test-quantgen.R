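test_that("univariate REML matches a dense brute-force evaluation", {
  ped <- validate_pedigree(data.frame(
    id = 1:12,
    sire = c(0, 0, 0, 0, 1, 1, 3, 3, 1, 5, 5, 7),
    dam  = c(0, 0, 0, 0, 2, 2, 4, 4, 4, 8, 8, 2),
    sex  = c("M", "F", "M", "F", "M", "F", "M", "F", "F", "M", "M", "F")))
  A <- numerator_relationship_matrix(ped)
  set.seed(10)
  L <- t(chol(A + diag(1e-10, 12)))
  y <- as.numeric(L %*% rnorm(12)) * sqrt(0.5) + rnorm(12, sd = sqrt(0.5))
  X <- cbind(1, as.numeric(ped$sex == "M"))
  fit <- reml_univariate(y, X, A)

  # same likelihood value through explicit determinants / inverses
  ll_dense <- dense_reml_ll(fit$sigma2_a, fit$sigma2_e, y, X, A)
  expect_equal(fit$loglik, ll_dense, tolerance = 1e-6)

  # dense 2-parameter maximization lands on the same optimum
  o <- optim(c(log(0.5), log(0.5)),
             function(th) -dense_reml_ll(exp(th[1]), exp(th[2]), y, X, A),
             method = "Nelder-Mead", control = list(reltol = 1e-14))
  expect_equal(fit$loglik, -o$value, tolerance = 1e-6)
  expect_equal(fit$h2, exp(o$par[1]) / sum(exp(o$par)), tolerance = 1e-3)

  # profile optimum dominates the boundaries
  expect_gte(fit$loglik + 1e-8, fit$loglik_null)
})

test_that("REML boundary and degenerate cases are handled explicitly", {
  ped <- simulate_pedigree(sim_config(n_founders = 40, n_generations = 2,
                                      n_snvs = 0, seed = 2))
  A <- numerator_relationship_matrix(ped)
  n <- nrow(A)
  # no genetic variance: estimate at/near zero, mixture p large
  set.seed(3)
  y <- rnorm(n)
  f0 <- reml_univariate(y, NULL, A)
  expect_lt(f0$h2, 0.12)
  expect_gt(f0$p_value, 0.05)

  # identity A: a and e indistinguishable, flagged
  fI <- reml_univariate(y, NULL, diag(n))
  expect_equal(fI$status, "unidentifiable")

  expect_error(reml_univariate(y, matrix(1, n, 2), A), "rank-deficient")
  expect_error(reml_univariate(y, NULL, -A), "not PSD")
})

test_that("REML agrees with the paternal half-sib ANOVA estimator", {
  # balanced design: 100 sires x 20 offspring, unknown dams
  ns <- 100; k <- 20
  ped <- validate_pedigree(data.frame(
    id = 1:(ns + ns * k),
    sire = c(rep(0, ns), rep(1:ns, each = k)),
    dam = 0,
    sex = c(rep("M", ns), rep("F", ns * k))))
  h2_true <- 0.3
  cfg <- sim_config(n_founders = 10, n_generations = 0, n_snvs = 0,
                    h2_activity = h2_true, sex_effect = 0, seed = 17)
  ph <- simulate_phenotypes(ped, cfg)
  off <- ped$sire != 0
  y <- ph$truth$latent[off, 1, 1]
  sire <- ped$sire[off]

  ms <- anova(lm(y ~ factor(sire)))
  msb <- ms$`Mean Sq`[1]; msw <- ms$`Mean Sq`[2]
  s2s <- (msb - msw) / k
  h2_anova <- 4 * s2s / (s2s + msw)

  A_off <- numerator_relationship_matrix(ped)[off, off]
  fit <- reml_univariate(y, NULL, A_off)
  expect_lt(abs(fit$h2 - h2_anova), 0.03)
  expect_lt(abs(fit$h2 - h2_true), 0.08)
})

test_that("bivariate REML handles degenerate and null inputs", {
  ped <- simulate_pedigree(sim_config(n_founders = 30, n_generations = 2,
                                      n_snvs = 0, seed = 4))
  A <- numerator_relationship_matrix(ped)
  cfg <- sim_config(n_founders = 30, n_generations = 2, n_snvs = 0,
                    h2_activity = 0.4, h2_emotionality = 0.4,
                    rho_g_true = 0.5, seed = 4)
  lat <- simulate_phenotypes(ped, cfg)$truth$latent
  y1 <- lat[, 1, 1]

  # identical traits: correlations pinned to 1
  f_same <- reml_bivariate(y1, y1, NULL, A, test = FALSE, se = FALSE)
  expect_gt(f_same$rho_g, 0.99)
  expect_gt(f_same$rho_e, 0.99)

  expect_error(reml_bivariate(y1, rep(2, length(y1)), NULL, A),
               "degenerate")

  # constrained +/-1 correlation never beats the unconstrained optimum
  f <- reml_bivariate(y1, lat[, 2, 1], NULL, A, test = TRUE, se = FALSE)
  th_hat <- c(log(f$sigma2_a[1]), log(f$sigma2_a[2]), atanh(f$rho_g * 0.999999),
              log(f$sigma2_e[1]), log(f$sigma2_e[2]), atanh(f$rho_e * 0.999999))
  Ae <- eigen(A, symmetric = TRUE)
  U <- Ae$vectors; d <- pmax(Ae$values, 0)
  Xs <- crossprod(U, matrix(1, nrow(A), 1))
  for (r in c(-0.9999, 0.9999)) {
    th_c <- th_hat; th_c[3] <- atanh(r)
    ll_c <- macaqueIT:::biv_ll(th_c, crossprod(U, y1),
                               crossprod(U, lat[, 2, 1]), Xs, d,
                               nrow(A), 1)
    expect_lte(ll_c, f$loglik + 1e-6)
  }
  # the rho_g = 0 constrained fit is also dominated
  expect_gte(f$loglik + 1e-6, f$loglik_null)
  expect_true(is.finite(f$p_value) && f$p_value <= 1)
})

test_that("heritability report assembles fits and flags failures", {
  ped <- simulate_pedigree(sim_config(n_founders = 50, n_generations = 2,
                                      n_snvs = 0, seed = 19))
  A <- numerator_relationship_matrix(ped)
  Ae <- eigen(A, symmetric = TRUE)
  cfg <- sim_config(n_founders = 50, n_generations = 2, n_snvs = 0,
                    h2_activity = 0.4, h2_emotionality = 0.4,
                    rho_g_true = 0.7, seed = 20)
  ph <- simulate_phenotypes(ped, cfg)
  sc <- score_factors(ph$records)
  lab <- classify_it(sc)
  X <- model.matrix(~ sex, ped)

  traits <- list(IT = inverse_normal_transform(lab$it_continuous),
                 activity_d1 = inverse_normal_transform(sc$activity_d1),
                 emotionality_d1 = inverse_normal_transform(sc$emotionality_d1))
  uni <- lapply(traits, function(y) reml_univariate(y, X, A, Aeig = Ae))
  biv <- list(
    "IT|activity_d1" = reml_bivariate(traits$IT, traits$activity_d1, X, A,
                                      Aeig = Ae, test = FALSE, se = FALSE),
    "activity_d1|emotionality_d1" = reml_bivariate(
      traits$activity_d1, traits$emotionality_d1, X, A, Aeig = Ae,
      test = FALSE, se = FALSE))
  rep <- heritability_report(uni, biv)
  expect_equal(nrow(rep$h2_table), 3)
  expect_equal(diag(rep$rho_g_matrix), c(IT = 1, activity_d1 = 1,
                                         emotionality_d1 = 1))
  expect_equal(rep$rho_g_matrix["IT", "activity_d1"],
               rep$rho_g_matrix["activity_d1", "IT"])
  # IT is the negative composite: genetically anti-correlated with factors
  expect_lt(rep$rho_g_matrix["IT", "activity_d1"], 0)
  expect_gt(rep$rho_g_matrix["activity_d1", "emotionality_d1"], 0)

  # a non-converged cell is NA, not a silent number
  fake <- uni
  fake$IT$status <- "not_converged"
  rep2 <- heritability_report(fake, biv)
  expect_true(is.na(rep2$h2_table$h2[rep2$h2_table$trait == "IT"]))
})
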