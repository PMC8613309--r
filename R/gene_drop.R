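#' Gene-drop genotypes through a pedigree
#'
#' Simulates unlinked biallelic variants: founder allele frequencies are
#' drawn uniformly from `config$maf_range`, founder genotypes from
#' Hardy-Weinberg proportions, and every non-founder receives one allele
#' from each parent by fair Mendelian transmission (an unknown parent
#' contributes a population allele at the founder frequency).  Dosages are
#' coded 0/1/2 copies of the alternate allele.
#'
#' Because sites are unlinked, transmission at each site is an independent
#' Bernoulli draw with probability `dosage/2` of passing the alternate
#' allele, which reproduces Mendelian segregation exactly for biallelic
#' loci.
#'
#' @param ped A `pedigree`.
#' @param config A [sim_config()]; uses `n_snvs`, `maf_range`, `seed`.
#' @param freqs Optional vector of founder alternate-allele frequencies
#'   (overrides `n_snvs`/`maf_range`), used by tests that need fixed
#'   frequencies.
#' @return A `genotype_matrix`: list with `dosage` (animals x variants
#'   integer matrix, dimnames = ids x variant ids), `variants` (data.frame
#'   chrom, pos, ref, alt, id), and `founder_freq`.
#' @export
gene_drop_genotypes <- function(ped, config, freqs = NULL) {
  ped <- validate_pedigree(ped)
  set.seed(derive_seed(config$seed, "genedrop"))
  m <- if (is.null(freqs)) config$n_snvs else length(freqs)
  if (is.null(freqs))
    freqs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  G <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    a1 <- if (is.na(si[i])) stats::rbinom(m, 1L, freqs)
          else stats::rbinom(m, 1L, G[si[i], ] / 2)
    a2 <- if (is.na(di[i])) stats::rbinom(m, 1L, freqs)
          else stats::rbinom(m, 1L, G[di[i], ] / 2)
    G[i, ] <- a1 + a2
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  pos <- sort(sample.int(2e8, m))
  variants <- data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
                         id = paste("1", pos, ref, alt, sep = ":"),
                         stringsAsFactors = FALSE)
  dimnames(G) <- list(ped$id, variants$id)
  structure(list(dosage = G, variants = variants, founder_freq = freqs),
            class = "genotype_matrix")
}

#' Write a genotype matrix as VCF v4.2
#'
#' Minimal sites-plus-GT VCF: one contig, diploid unphased genotypes
#' reconstructed from dosages (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.).
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path (plain text).
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  G <- geno$dosage
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")), con)
  for (j in seq_len(nrow(v))) {
    g <- G[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
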