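# Shared fixture builders.  Everything is generated in code; nothing is
# stored on disk except transient files under tempdir().

# id layout: 1 sire, 2 dam, 3..4 full sibs, 5 half sib (other dam 6)
nuclear_pedigree <- function() {
  validate_pedigree(data.frame(
    id = 1:6,
    sire = c(0, 0, 1, 1, 1, 0),
    dam = c(0, 0, 2, 2, 6, 0),
    sex = c("M", "F", "M", "F", "M", "F"),
    stringsAsFactors = FALSE))
}

# three-generation 15-member pedigree with a full-sib mating, used for
# kinship oracles
small_deep_pedigree <- function() {
  validate_pedigree(data.frame(
    id = 1:15,
    sire = c(0, 0, 0, 0, 1, 1, 3, 3, 0, 5, 5, 7, 7, 10, 12),
    dam  = c(0, 0, 0, 0, 2, 2, 4, 4, 0, 6, 9, 8, 8, 13, 13),
    sex  = c("M", "F", "M", "F", "M", "F", "M", "F", "F", "M",
             "M", "M", "F", "M", "F"),
    stringsAsFactors = FALSE))
}

founders_of <- function(ped) ped$id[ped$sire == 0 & ped$dam == 0]

toy_config <- function(...) {
  args <- utils::modifyList(
    list(n_founders = 20, n_generations = 2, mean_offspring = 2,
         n_snvs = 50, seed = 42),
    list(...))
  do.call(sim_config, args)
}

# minimal diploid VCF written as text; returns the path
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "v2", "C", "T", ".", "PASS", ".", "GT",
          "./.", "0/0", "0/1", sep = "\t"),
    paste("1", "300", "v3", "G", "A,C", ".", "PASS", ".", "GT",
          "0/1", "0/2", "1/2", sep = "\t"))
  writeLines(lines, path)
  path
}

# dense brute-force REML log-likelihood: explicit determinants and
# inverses, no eigendecomposition shortcut (independent oracle)
dense_reml_ll <- function(sigma2_a, sigma2_e, y, X, A) {
  n <- length(y); p <- ncol(X)
  V <- sigma2_a * A + sigma2_e * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       t(r) %*% Vi %*% r + (n - p) * log(2 * pi)))
}
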