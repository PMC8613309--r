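---
title: "Models and methods: pedigree genetics of infant inhibited temperament"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pedigree genetics of infant inhibited temperament}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`macaqueIT` implements the full analysis chain for studies of infant
inhibited temperament (IT) in breeding-colony rhesus macaques: behavioral
factor scoring and the dichotomous IT call, longitudinal logistic and
chi-squared analyses of adult treat refusal, pedigree-based variance
components (heritability and genetic correlation) by animal-model REML,
kinship-corrected single-variant association, and a permutation test for
enrichment of association signal in candidate gene sets.  Because colony
phenotype and pedigree data are access-restricted, the package ships a
synthetic-data generator with known ground truth; every stage is validated
against that truth or against independent brute-force oracles in the test
suite.

## Phenotype model

Behavioral observation over two test days yields, per animal and day,
continuous items (time locomoting and time not hanging, in seconds; rates
of environmental exploration, cooing and barking, in events/hour) and
rare items dichotomized to 0/1 (ate food, drank water, crouching,
scratched, threats, lipsmacked).  `score_factors()` z-scores each item
within the cohort (per day; dichotomous items enter as 0/1), combines
them with per-item loadings, and standardizes the resulting Activity and
Emotionality scores to mean 0, SD 1.

The original factor-analytic loadings are not published, so the default
(`default_loadings()`) is unit weight on every listed item, with the item
naming carrying the sign convention ("time NOT hanging" is already
reflected).  Loadings are an explicit input (`read_loadings()`) so users
with the original weights can substitute them.

`classify_it()` marks an animal inhibited when both factors fall strictly
below their cohort means across the two days.  "Across two days" is
ambiguous between two readings; the default compares the day-averaged
factor with its cohort mean, and `rule = "all_four"` requires all four
day-by-factor scores below their means.  Exact ties with the mean count
as not inhibited — scores are continuous, so ties have measure zero, and
a deterministic rule matters more than which side they land on.  The
continuous composite `it_continuous` is minus the mean of the four
standardized scores (higher = more inhibited), which supports analyses of
IT as a continuous variable.

Before any variance-component fit, traits pass through the rank-based
inverse normal transformation with the Blom offset,
$\Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$, ties receiving averaged
ranks.  The transform family is standard for these analyses; the Blom
constant is the common convention among the offsets in use, and nothing
downstream is sensitive to that choice.  The dichotomous IT label itself
can also be analyzed directly by passing the 0/1 vector to
`reml_univariate()` (a linear liability-scale treatment); the default
analyses use the continuous composite.

## Variance components: the animal model

`reml_univariate()` fits
$y = X\beta + a + e,\quad a \sim N(0, \sigma^2_a A),\quad e \sim N(0, \sigma^2_e I)$
by REML, where $A$ is the additive numerator relationship matrix from the
pedigree (`numerator_relationship_matrix()`, tabular method;
$A_{ii} = 1 + F_i$, founders unrelated and non-inbred, unknown single
parents treated as phantom founders).  The tabular construction is used
rather than the inverse-$A$ shortcut because the REML machinery needs an
eigendecomposition of $A$ itself, not its inverse; the matrix is stored
dense (a 4400-animal colony is ~150 MB, unproblematic at workstation
scale).

Writing $A = UDU'$ and rotating $y$ and $X$ by $U'$, the covariance for
any heritability $h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$ is diagonal,
the total variance profiles out analytically, and REML reduces to a 1-D
maximization of the profile likelihood over $h^2 \in [0, 1]$
(`stats::optimize`, relative tolerance $10^{-10}$, search interval
$[10^{-6}, 1-10^{-6}]$ with explicit boundary evaluation).  Fixed effects
are intercept and sex; age is deliberately not a covariate because all
animals are phenotyped in the same narrow infant window.  The standard
error of $h^2$ comes from the numerical curvature of the profile
log-likelihood at the optimum; the test of $\sigma^2_a = 0$ uses the
likelihood-ratio statistic against the 50:50
$\chi^2_0\!:\!\chi^2_1$ boundary mixture (the convention of the
variance-component software used in this literature), so an estimate on
the zero boundary reports $p = 0.5$.  A flat likelihood (e.g. $A = I$,
where $a$ and $e$ are indistinguishable) is flagged `unidentifiable`
rather than reported as a number.

`reml_bivariate()` extends this to two traits sharing the pedigree:
genetic covariance $\rho_g \sigma_{a1}\sigma_{a2}$, residual covariance
$\rho_e \sigma_{e1}\sigma_{e2}$.  After the same rotation the
$2n$-dimensional covariance splits into $n$ independent $2\times2$
blocks, so each REML evaluation is $O(n)$.  The six parameters are
maximized on an unconstrained scale (log variances, atanh correlations —
this keeps every iterate inside the valid parameter space without
explicit constraints) by Nelder-Mead with one restart from the first
optimum.  The $\rho_g = 0$ p-value is a 1-df likelihood-ratio test
against the constrained refit (an interior null, so no boundary mixture),
and `se_rho_g` comes from the inverse numerical Hessian with a
delta-method back-transform.  Correlation estimates within $10^{-4}$ of
$\pm1$ are flagged as boundary fits.

## Association scan

`lmm_scan()` implements the standard two-step mixed-model scan: variance
components are estimated once under the null model (no variant) on the
kinship matrix $K$, then every variant is tested by a generalized
least-squares Wald test with the variance ratio held fixed — the default
behavior of the tool named in this literature, and the reason a scan of
millions of variants is affordable.  The test statistic is a *t* (not a
normal) so that the $K = I$ limit reproduces simple linear regression
exactly; `per_variant_reml = TRUE` re-estimates components per variant
when exactness matters more than speed.  Missing genotypes are
mean-imputed per variant; variants monomorphic after imputation are
dropped; there is no MAF or missingness filter by default (none is
described for the motivating analysis), though both are configurable.

$K$ defaults to the allele-frequency-standardized genomic relationship
matrix $ZZ'/m$ (`genomic_relationship_matrix()`), with the
pedigree-$A$ restricted to genotyped animals as the alternative
(`kinship_for_assoc()`); leave-one-chromosome-out is not implemented.
Calibration is summarized by the genomic inflation factor
$\lambda$ (`genomic_inflation()`), and `manhattan_table()` flags hits at
the conventional $p < 5\times10^{-8}$ threshold with variant ids in
`chrom:pos:ref:alt` form.  Coordinates are 1-based throughout, as in VCF.

## Gene-set enrichment

`assign_variants_to_genes()` assigns each variant to every gene whose
interval, extended by a `flank` (default 10 kb, configurable to hundreds
of kb — published variant-to-gene attributions in this area imply a much
larger implicit window than any stated one), contains it, and takes the
per-gene minimum association p.  The permutation universe is the set of
genes with at least one assigned variant: genes without variants have no
defined minimum and are excluded from both target and null sets.

`permutation_enrichment()` computes the observed statistic $T$ = mean of
the target genes' minimum p-values and compares it with $B$ (default
10,000) same-size gene sets drawn without replacement from the universe.
The p-value is the exact proportion of permutation means *strictly*
below $T$ (ties count against enrichment), so $pB$ is always an integer
and the degenerate whole-universe target yields $p = 0$; the add-one
estimate $(k+1)/(B+1)$ is reported alongside as the usual
never-exactly-zero alternative.  The raw-mean statistic follows the
published procedure; because raw means are dominated by large p-values a
`log10_stat` variant is available.  Permuted sets are matched on gene
*count* only (the plain reading of "similarly sized"), not on gene length
or variant density — a competitive correction of that kind is explicitly
out of scope.  `run_enrichment_suite()` derives one deterministic seed
per list from the master seed by string hashing, so per-list results are
reproducible and independent, and a failing list does not abort the
others.

## Longitudinal statistics

`fit_logistic()` is a from-first-principles IRLS maximum-likelihood
logistic regression (convergence on relative log-likelihood change
$< 10^{-10}$) reporting Wald $z$ per coefficient; complete separation is
detected (runaway coefficients) and raised as an error naming the
predictor.  The primary predictor is the 0/1 IT label, with the
continuous composite as the supplementary option; age enters linearly in
years and interactions are omitted.  `stability_chi2()` is the Pearson
2×2 chi-squared with 1 df and no continuity correction by default (Yates
available); `refusal_summary()` reports refusal by group, the
all-or-nothing pattern among first-trial refusers, and cross-assessment
consistency.  In the test suite both are checked against brute-force
likelihood maximization and hand-computed tables, and both hold nominal
5% size under simulated nulls.

## The synthetic generator

`simulate_dataset()` (and its parts `simulate_pedigree()`,
`gene_drop_genotypes()`, `simulate_phenotypes()`, `simulate_refusal()`)
emulates the study conditions:

* **Pedigree.** Discrete generations; founders split between sexes; each
  dam mates with a random sire of the previous generation, avoiding her
  own sire and full brothers (colony practice; `allow_inbreeding = TRUE`
  lifts this for kinship tests); litter sizes Poisson.  Defaults (500
  founders, 5 generations, mean 2.2 offspring) give roughly the 4000+
  animals of the colony analyses.
* **Genotypes.** Unlinked biallelic variants gene-dropped through the
  pedigree: founders Hardy–Weinberg at frequencies uniform on
  `maf_range`, fair Mendelian transmission elsewhere; an unknown parent
  contributes a population allele.
* **Phenotypes.** Per-factor breeding values exact multivariate normal
  via the Cholesky factor of $A$ with 2×2 genetic covariance
  (heritabilities default 0.19 — the headline composite estimate —
  and genetic correlation 0.65, the middle of the reported 0.45–0.90
  range).  The latent factor on each day is breeding value + independent
  day residual (plus an optional permanent-environment share `rho_day`,
  default 0: the simplest structure consistent with four separately
  heritable day-by-factor variables, making cross-day correlation purely
  genetic by default).  Items are the latent factor plus N(0, 0.25)
  noise mapped to natural units; rare items are thresholded at $z > 1.5$
  (no dichotomization rule is published; 1.5 gives the single-digit
  prevalence that motivates dichotomizing at all).  Breeding values are
  generated from the pedigree, not from the simulated variants, so
  phenotype realism is independent of `n_snvs`;
  `simulate_causal_trait()` provides the variant-effect mode for
  association power studies.
* **Treat refusal.** First-trial refusal is Bernoulli with logit
  $\beta_0 + \beta_{IT}\,\mathrm{IT} + \beta_{age}\,\mathrm{age}$
  (defaults 0.6, 0.6, −0.15/yr over ages 2–10: inhibited animals refuse
  more, older animals less, overall refusal near the observed ~40%).
  Retrieval is all-or-nothing: a first-trial refuser retrieves a later
  treat with probability 0.17, matching the observed ~17% (49/292); a
  persistent per-animal deviate makes refusal stable across repeated
  assessments spaced 1.8 years.

All randomness flows from the single integer `seed` through per-stage
derived streams, so identical configurations are byte-identical on disk.
`TrueValues` (breeding values, latent factors, realized $h^2$ =
var(breeding values)/var(latent phenotype)) are returned for validation.

What the generator does **not** emulate: linkage and LD (variants are
independent, so there is no local Manhattan "skyline"), dominance or
epistatic variance, selection, X-linkage, maternal/household effects,
assortative mating, and the skew *direction* of the real factor scores.
The last point is visible in the inhibited fraction: with unit-positive
loadings the rare items skew the composite right, and ~45% of synthetic
animals fall below both means versus ~18% in the real colony, whose
unpublished loadings evidently produce the opposite skew.  The
classification rule is unaffected (it is mean-relative by construction),
but absolute prevalence comparisons with the real cohort should not be
read into the synthetic data.  Consequently, passing tests demonstrate
correctness of the estimators under the stated generative model, not
robustness to LD, ascertainment, or measurement pathologies of real
colony data.

## Numerical choices and degenerate inputs

* $A$ receives a $10^{-10}$ diagonal jitter before Cholesky; the 2×2
  genetic covariance a $10^{-12}$ jitter so $|\rho_g| = 1$ stays
  factorizable.
* Eigendecompositions of $A$/$K$ are computed once and reusable
  (`Aeig`/`A_chol` arguments) across replicate fits on a fixed pedigree.
* Negative eigenvalues beyond $-10^{-6}\cdot\|A\|$ raise a non-PSD
  error; smaller ones are clamped to zero.
* Zero-variance items are excluded from scoring with a warning;
  zero-variance traits, single-class outcomes, degenerate 2×2 margins,
  empty target/universe intersections, and impossible mating structures
  are explicit errors, never silent results.
* Non-convergence of any REML fit is carried in a `status` field and
  propagated as NA by `heritability_report()`.

## Validation design and problem sizes

The test suite validates each estimator along two independent routes:
closed-form or brute-force oracles on tiny instances (dense-determinant
REML on 12 animals at $10^{-6}$; explicit-inverse GLS on 10 animals at
$10^{-8}$; direct likelihood maximization for the logistic model at
$10^{-6}$; gene-dropping estimates of $A$ entrywise at 0.02), and
replicate-simulation studies at reduced scale chosen to keep the default
suite inside a coffee break on one core: heritability recovery with 100
replicates on a ~1800-member pedigree, genetic-correlation recovery at
$\rho_g \in \{0, 0.45, 0.89\}$ with 50 replicates near $n = 1000$,
scan calibration on a ~400-member four-generation pedigree with 4000
variants, enrichment null uniformity over 200 random target lists, and
500-replicate size checks for the boundary LRT and both Study-1 tests.
`scripts/acceptance.R` re-runs the pipeline end-to-end at colony scale
(~4000 animals) from a command-line seed and writes every headline
quantity it computes as JSON.
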