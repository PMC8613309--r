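#' Simulate BioBehavioral-Assessment phenotypes over a pedigree
#'
#' Generates the two latent temperament factors, Activity and
#' Emotionality, for each animal on each of two test days, then renders
#' them as observable behavioral items.
#'
#' The genetic model: per-factor breeding values are drawn jointly
#' multivariate normal with covariance \eqn{G \otimes A}, where A is the
#' pedigree numerator relationship matrix and G the 2x2 genetic covariance
#' with variances `h2_activity`, `h2_emotionality` and correlation
#' `rho_g_true` (so each latent factor has unit phenotypic variance).
#' The latent factor on day d is breeding value + optional
#' permanent-environment deviation + an independent day-specific residual;
#' cross-day phenotypic correlation therefore comes from the genetic term
#' (plus `rho_day`, default 0).  Males receive an additive `sex_effect`.
#'
#' Observable items are the latent factor plus N(0, `item_noise_sd`)
#' measurement noise, mapped to natural units (seconds, events/hour);
#' rare items are dichotomized at `rare_item_threshold` on the z scale.
#'
#' @param ped A `pedigree`.
#' @param config A [sim_config()].
#' @param A_chol Optional precomputed lower-triangular Cholesky factor of
#'   the relationship matrix (reused across replicate simulations on the
#'   same pedigree).
#' @return List with `records` (one row per animal x day: id, day, sex,
#'   item columns) and `truth` (breeding values, latent factors, realized
#'   heritabilities).
#' @export
simulate_phenotypes <- function(ped, config, A_chol = NULL) {
  ped <- validate_pedigree(ped)
  validate_sim_config(config)
  if (anyDuplicated(ped$id)) stop("duplicate individuals in pedigree")
  set.seed(derive_seed(config$seed, "phenotypes"))
  n <- nrow(ped)
  L <- if (is.null(A_chol)) {
    A <- numerator_relationship_matrix(ped)
    t(chol(A + diag(1e-10, n)))
  } else A_chol

  h2 <- c(activity = config$h2_activity, emotionality = config$h2_emotionality)
  Gmat <- diag(sqrt(h2)) %*%
    matrix(c(1, config$rho_g_true, config$rho_g_true, 1), 2) %*% diag(sqrt(h2))
  # jitter keeps the factorization defined at |rho_g| = 1 (singular G)
  bv <- L %*% matrix(stats::rnorm(2 * n), n, 2) %*% chol(Gmat + diag(1e-12, 2))
  colnames(bv) <- names(h2)

  male <- as.numeric(ped$sex == "M")
  latent <- array(NA_real_, c(n, 2, 2),
                  dimnames = list(ped$id, names(h2), c("d1", "d2")))
  for (f in 1:2) {
    s2e <- 1 - h2[f]
    pe <- stats::rnorm(n, 0, sqrt(config$rho_day * s2e))
    for (d in 1:2) {
      eps <- stats::rnorm(n, 0, sqrt((1 - config$rho_day) * s2e))
      latent[, f, d] <- bv[, f] + pe + eps + config$sex_effect * male
    }
  }

  item_map <- bba_item_map()
  rec <- do.call(rbind, lapply(1:2, function(d) {
    df <- data.frame(id = ped$id, day = d, sex = ped$sex,
                     stringsAsFactors = FALSE)
    for (k in seq_len(nrow(item_map))) {
      it <- item_map[k, ]
      z <- it$sign * latent[, it$factor, d] +
        stats::rnorm(n, 0, config$item_noise_sd)
      df[[it$item]] <- if (it$type == "continuous")
        pmax(0, it$mu + it$sd * z)
      else as.integer(z > config$rare_item_threshold)
    }
    df
  }))
  rec <- rec[order(rec$id, rec$day), ]
  rownames(rec) <- NULL

  realized_h2 <- vapply(1:2, function(f)
    stats::var(bv[, f]) / mean(apply(latent[, f, ], 2, stats::var)),
    numeric(1))
  names(realized_h2) <- names(h2)

  list(records = rec,
       truth = list(breeding_values = bv, latent = latent,
                    realized_h2 = realized_h2, h2_true = h2,
                    rho_g_true = config$rho_g_true))
}

# Item catalogue: factor membership follows the published item lists;
# signs are the identity convention ("time NOT hanging" is already
# reflected), with natural-unit anchors for the continuous items.
bba_item_map <- function() {
  data.frame(
    item = c("locomotion_s", "not_hanging_s", "exploration_rate",
             "ate_food", "drank_water", "crouching",
             "cooing_rate", "barking_rate",
             "scratched", "threats", "lipsmacked"),
    factor = c(rep("activity", 6), rep("emotionality", 5)),
    type = c("continuous", "continuous", "continuous",
             "dichotomous", "dichotomous", "dichotomous",
             "continuous", "continuous",
             "dichotomous", "dichotomous", "dichotomous"),
    sign = 1,
    mu = c(300, 1200, 20, 0, 0, 0, 30, 5, 0, 0, 0),
    sd = c(100, 300, 6, 1, 1, 1, 10, 1.5, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Simulate adult treat-refusal outcomes
#'
#' Each animal's probability of refusing the first offered treat is
#' logit-linear in its infant inhibited-temperament classification and its
#' adult age: `plogis(intercept + beta_it * inhibited + beta_age * age)`.
#' Retrieval is modeled as all-or-nothing: a first-trial refuser retrieves
#' a later treat with probability `retrieve_after_refusal`; a first-trial
#' retriever keeps retrieving.  Across repeated assessments a persistent
#' per-animal deviate (`stability_sd`) makes refusal stable within animal.
#'
#' @param labels Data frame with columns `id` and `inhibited` (logical or
#'   0/1), e.g. from [classify_it()].
#' @param ages Numeric vector of ages (years), one per animal, or NULL to
#'   draw uniformly from `config$age_range`.
#' @param config A [sim_config()].
#' @param n_assessments Number of repeated assessments per animal.
#' @param retrieve_after_refusal P(retrieve any later treat | refused
#'   trial 1); default 0.17.
#' @param stability_sd SD of the persistent per-animal logit deviate.
#' @return Data frame: id, assessment, age, sex-free refusal outcomes
#'   `first_trial_refused` and `refused` (refused all three trials), plus
#'   `inhibited`.
#' @export
simulate_refusal <- function(labels, ages = NULL, config,
                             n_assessments = 1L,
                             retrieve_after_refusal = 0.17,
                             stability_sd = 1.5) {
  stopifnot(all(c("id", "inhibited") %in% names(labels)))
  set.seed(derive_seed(config$seed, "refusal"))
  n <- nrow(labels)
  if (is.null(ages))
    ages <- stats::runif(n, config$age_range[1], config$age_range[2])
  if (length(ages) != n) stop("one age per animal required")
  u <- stats::rnorm(n, 0, stability_sd)
  it <- as.numeric(labels$inhibited)
  out <- do.call(rbind, lapply(seq_len(n_assessments), function(a) {
    age_a <- ages + (a - 1) * 1.8   # assessments ~1.8 years apart
    eta <- config$refusal_intercept + config$beta_it * it +
      config$beta_age * age_a + if (n_assessments > 1) u else 0
    first <- stats::rbinom(n, 1L, stats::plogis(eta))
    later <- stats::rbinom(n, 1L, retrieve_after_refusal)
    data.frame(id = labels$id, assessment = a, age = age_a,
               inhibited = it,
               first_trial_refused = first,
               refused = as.integer(first == 1L & later == 0L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a quantitative trait with chosen causal variants
#'
#' Utility for association power studies: builds a unit-variance trait as
#' the sum of per-allele effects at the chosen variants (each explaining a
#' stated fraction of phenotypic variance), an optional polygenic
#' (pedigree) background, and residual noise.
#'
#' @param geno A `genotype_matrix`.
#' @param causal_ids Variant ids to make causal.
#' @param var_explained Fraction of phenotypic variance per causal variant.
#' @param h2_background Polygenic background heritability (requires `ped`).
#' @param ped Pedigree (only when `h2_background > 0`).
#' @param seed Integer seed.
#' @return List: `y` (named vector), `beta` (per-allele effects).
#' @export
simulate_causal_trait <- function(geno, causal_ids, var_explained = 0.05,
                                  h2_background = 0, ped = NULL, seed = 1L) {
  set.seed(derive_seed(seed, "causal"))
  G <- geno$dosage
  stopifnot(all(causal_ids %in% colnames(G)))
  var_explained <- rep_len(var_explained, length(causal_ids))
  y <- numeric(nrow(G))
  beta <- numeric(length(causal_ids))
  for (k in seq_along(causal_ids)) {
    g <- G[, causal_ids[k]]
    vg <- stats::var(g)
    if (vg == 0) stop("causal variant ", causal_ids[k], " is monomorphic")
    beta[k] <- sqrt(var_explained[k] / vg)
    y <- y + beta[k] * g
  }
  tot_causal <- sum(var_explained)
  if (h2_background > 0) {
    if (is.null(ped)) stop("h2_background > 0 requires `ped`")
    A <- numerator_relationship_matrix(ped)
    A <- A[rownames(G), rownames(G)]
    Lc <- t(chol(A + diag(1e-10, nrow(A))))
    y <- y + sqrt(h2_background) * as.numeric(Lc %*% stats::rnorm(nrow(G)))
  }
  resid <- 1 - tot_causal - h2_background
  if (resid < 0) stop("variance fractions exceed 1")
  y <- y + stats::rnorm(nrow(G), 0, sqrt(resid))
  names(y) <- rownames(G)
  names(beta) <- causal_ids
  list(y = y, beta = beta)
}
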