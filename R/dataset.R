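#' Generate and write a complete synthetic dataset
#'
#' End-to-end wrapper around the generator: simulates the pedigree,
#' gene-drops genotypes, simulates behavioral phenotypes and adult
#' treat-refusal outcomes, and writes everything to `dir` as plain-text
#' files with a JSON manifest:
#'
#' * `pedigree.tsv` — id, sire, dam, sex (0 = unknown parent)
#' * `phenotypes.csv` — long format, one row per animal x day x item
#' * `genotypes.vcf` — VCF v4.2, diploid GT, one contig
#' * `refusal.csv` — adult treat-refusal records
#' * `truth.json` — ground-truth values (realized h2, simulation
#'   parameters); breeding values and latent factors are returned in R
#'   but not serialized
#' * `manifest.json` — file list, seed, config
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed); NULL to skip writing.
#' @param n_assessments Repeated refusal assessments to simulate.
#' @return Invisible list with all in-memory objects: `pedigree`, `geno`,
#'   `phenotypes` (records + truth), `refusal`, `files`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL,
                             n_assessments = 1L) {
  ped <- simulate_pedigree(config)
  geno <- if (config$n_snvs > 0) gene_drop_genotypes(ped, config) else NULL
  phen <- simulate_phenotypes(ped, config)
  scores <- score_factors(phen$records)
  labels <- classify_it(scores)
  refusal <- simulate_refusal(labels, ages = NULL, config,
                              n_assessments = n_assessments)
  files <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
    files <- c(pedigree = file.path(dir, "pedigree.tsv"),
               phenotypes = file.path(dir, "phenotypes.csv"),
               refusal = file.path(dir, "refusal.csv"),
               truth = file.path(dir, "truth.json"),
               manifest = file.path(dir, "manifest.json"))
    write_pedigree(ped, files["pedigree"])
    write_phenotypes(phen$records, files["phenotypes"])
    utils::write.csv(refusal, files["refusal"], row.names = FALSE,
                     quote = FALSE)
    if (!is.null(geno)) {
      files <- c(files, genotypes = file.path(dir, "genotypes.vcf"))
      write_vcf(geno, files["genotypes"])
    }
    truth <- list(realized_h2 = as.list(phen$truth$realized_h2),
                  h2_true = as.list(phen$truth$h2_true),
                  rho_g_true = phen$truth$rho_g_true,
                  n_animals = nrow(ped),
                  inhibited_fraction = mean(labels$inhibited),
                  seed = config$seed)
    jsonlite::write_json(truth, files["truth"], auto_unbox = TRUE,
                         digits = NA)
    manifest <- list(files = as.list(files[names(files) != "manifest"]),
                     seed = config$seed,
                     config = unclass(config))
    jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(list(pedigree = ped, geno = geno, phenotypes = phen,
                 scores = scores, labels = labels, refusal = refusal,
                 files = files))
}
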