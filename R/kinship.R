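#' Additive numerator relationship matrix (tabular method)
#'
#' Computes the matrix A of twice the kinship coefficients among pedigree
#' members by the recursive tabular method over the topologically sorted
#' pedigree: for individual i with parents s, d,
#' \deqn{A_{ii} = 1 + \tfrac12 A_{sd}, \qquad
#'       A_{ij} = \tfrac12 (A_{js} + A_{jd})}
#' with unknown parents contributing zero (phantom-founder convention:
#' founders and animals with unknown parents are taken unrelated and
#' non-inbred).  The diagonal is 1 + F_i where F_i is the inbreeding
#' coefficient; the matrix is symmetric positive semi-definite.
#'
#' Dense storage: a colony-scale pedigree (~4400 animals) is ~150 MB,
#' acceptable on a workstation and required anyway by the downstream
#' eigendecomposition.
#'
#' @param ped A `pedigree` (validated/sorted with [validate_pedigree()] if
#'   not produced by [simulate_pedigree()] / [read_pedigree()]).
#' @return A dense numeric matrix with dimnames = animal ids, ordered as
#'   the sorted pedigree.
#' @examples
#' ped <- data.frame(id = 1:4, sire = c(0, 0, 1, 1), dam = c(0, 0, 2, 2),
#'                   sex = c("M", "F", "M", "F"))
#' A <- numerator_relationship_matrix(validate_pedigree(ped))
#' A[3, 4]  # full sibs: 0.5
#' @export
numerator_relationship_matrix <- function(ped) {
  ped <- validate_pedigree(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(s)) 0 else A[j, s]
      ad_ <- if (is.na(d)) 0 else A[j, d]
      v <- 0.5 * (as_ + ad_)
      A[j, i] <- v
      A[i, j] <- v
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  A
}

#' Genomic relationship matrix from genotype dosages
#'
#' Standard allele-frequency-standardized GRM: with dosages g_ij in
#' \{0,1,2\} and observed allele frequency p_j, Z_ij = (g_ij - 2 p_j) /
#' sqrt(2 p_j (1 - p_j)) and K = Z Z' / m over the m polymorphic variants.
#' Missing dosages are mean-imputed per variant before standardization.
#'
#' @param geno A `genotype_matrix` (see [read_vcf()] /
#'   [gene_drop_genotypes()]) or a plain animals-by-variants dosage matrix.
#' @param min_variants Minimum number of polymorphic variants required for
#'   a stable estimate.
#' @return Symmetric PSD kinship matrix with animal-id dimnames.
#' @export
genomic_relationship_matrix <- function(geno, min_variants = 50L) {
  G <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < min_variants)
    stop("only ", sum(poly), " polymorphic variants; need >= ", min_variants,
         " for a stable GRM")
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  # mean-impute missing dosages per variant
  if (anyNA(G)) {
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- 2 * p[idx[, 2]]
  }
  Z <- sweep(G, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(G), rownames(G))
  K
}

#' Kinship matrix for association analysis
#'
#' Dispatches between the two relatedness sources the association scan can
#' use: a genotype-based GRM (default, [genomic_relationship_matrix()]) or
#' the pedigree numerator relationship matrix restricted to the genotyped
#' animals.
#'
#' @param source `"grm"` or `"pedigree"`.
#' @param geno Genotype matrix (required for both sources: it defines the
#'   animal set).
#' @param ped Pedigree (required when `source = "pedigree"`).
#' @param min_variants Passed to [genomic_relationship_matrix()].
#' @return Kinship matrix over the genotyped animals.
#' @export
kinship_for_assoc <- function(source = c("grm", "pedigree"), geno,
                              ped = NULL, min_variants = 50L) {
  source <- match.arg(source)
  ids <- if (inherits(geno, "genotype_matrix")) rownames(geno$dosage)
         else rownames(geno)
  if (source == "grm")
    return(genomic_relationship_matrix(geno, min_variants))
  if (is.null(ped)) stop("pedigree source requires `ped`")
  A <- numerator_relationship_matrix(ped)
  miss <- setdiff(ids, rownames(A))
  if (length(miss))
    stop("genotyped animals absent from pedigree: ",
         paste(utils::head(miss, 5), collapse = ", "))
  A[ids, ids]
}
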