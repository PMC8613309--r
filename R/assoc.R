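#' Read genotypes from a VCF file
#'
#' Parses a diploid VCF (v4.x, GT field) into an animals-by-variants
#' dosage matrix, preserving missing calls (`./.`) as NA.  Multi-allelic
#' sites are skipped by default (with a message) or split into one
#' pseudo-biallelic record per alternate allele.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param multiallelic `"skip"` (default) or `"split"`.
#' @return A `genotype_matrix` (see [gene_drop_genotypes()]).
#' @export
read_vcf <- function(path, multiallelic = c("skip", "split")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  multi <- grepl(",", fix$ALT)
  rows <- list(); dmat <- list()
  count_alt <- function(g, allele) {
    g[g %in% c(".", "./.", ".|.")] <- NA
    parts <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(parts, function(p) {
      if (length(p) == 0 || anyNA(p) || any(p == "."))
        return(NA_integer_)
      sum(p == as.character(allele))
    }, integer(1))
  }
  for (i in seq_len(nrow(fix))) {
    if (multi[i] && multiallelic == "skip") next
    alts <- strsplit(fix$ALT[i], ",")[[1]]
    for (k in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k],
        id = paste(fix$CHROM[i], fix$POS[i], fix$REF[i], alts[k], sep = ":"),
        stringsAsFactors = FALSE)
      dmat[[length(dmat) + 1L]] <- count_alt(gt[i, ], k)
    }
  }
  if (sum(multi) > 0 && multiallelic == "skip")
    message("skipped ", sum(multi), " multi-allelic site(s)")
  if (!length(rows)) stop("no usable biallelic records in ", path)
  variants <- do.call(rbind, rows)
  G <- do.call(cbind, dmat)
  dimnames(G) <- list(colnames(gt), variants$id)
  structure(list(dosage = G, variants = variants, founder_freq = NULL),
            class = "genotype_matrix")
}

#' Align genotypes with a phenotyped sample set
#'
#' Restricts a genotype matrix to the animals present in `ids` (in that
#' order).  VCF samples without a phenotype are excluded with a warning
#' naming them; phenotyped animals without genotypes raise an error.
#'
#' @param geno A `genotype_matrix`.
#' @param ids Character vector of phenotyped animal ids to keep.
#' @return The subsetted `genotype_matrix`.
#' @export
subset_genotypes <- function(geno, ids) {
  ids <- as.character(ids)
  have <- rownames(geno$dosage)
  extra <- setdiff(have, ids)
  if (length(extra))
    warning("excluding ", length(extra),
            " genotyped sample(s) without phenotype: ",
            paste(utils::head(extra, 5), collapse = ", "))
  miss <- setdiff(ids, have)
  if (length(miss))
    stop("phenotyped animal(s) missing from VCF: ",
         paste(utils::head(miss, 5), collapse = ", "))
  geno$dosage <- geno$dosage[ids, , drop = FALSE]
  geno
}

#' Mixed-model association scan
#'
#' Single-variant association under the linear mixed model
#' \eqn{y = X\beta + g b + u + e}, \eqn{u \sim N(0, \sigma^2_g K)}, with
#' the variance components estimated once under the null (no variant) by
#' [reml_univariate()] and then held fixed across variants — the standard
#' two-step approximation of FaST-LMM/EMMAX.  Each variant is tested by a
#' generalized-least-squares Wald test of its per-allele effect on the
#' rotated (whitened) data.  Missing genotypes are mean-imputed per
#' variant; variants monomorphic after imputation are dropped.
#'
#' @param y Phenotype vector aligned with the genotype rows.
#' @param X Fixed-effect design including intercept (e.g.
#'   `model.matrix(~ sex, ...)`); default intercept only.
#' @param K Kinship matrix (GRM or pedigree A restricted to the samples).
#' @param geno A `genotype_matrix` (or plain dosage matrix).
#' @param per_variant_reml Re-estimate variance components for every
#'   variant (exact but slow); default FALSE.
#' @param max_missing Drop variants with missingness above this fraction
#'   (default 1 = no filter).
#' @return An `assoc_result`: data.frame (chrom, pos, ref, alt, id, beta,
#'   se, stat, p) with attributes `null_fit` (the null `vc_fit`) and
#'   `n`.
#' @export
lmm_scan <- function(y, X = NULL, K, geno, per_variant_reml = FALSE,
                     max_missing = 1) {
  G <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  variants <- if (inherits(geno, "genotype_matrix")) geno$variants else
    data.frame(chrom = NA, pos = NA, ref = NA, alt = NA, id = colnames(G),
               stringsAsFactors = FALSE)
  n <- length(y)
  if (nrow(G) != n || nrow(K) != n) stop("y, K, genotypes not aligned")
  if (any(!is.finite(y))) stop("y must be finite")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)

  Keig <- eigen(K, symmetric = TRUE)
  null_fit <- reml_univariate(y, X, K, Aeig = Keig, se = FALSE)
  h2 <- null_fit$h2
  w <- 1 / (h2 * pmax(Keig$values, 0) + (1 - h2))
  sw <- sqrt(w)
  U <- Keig$vectors
  yt <- as.numeric(crossprod(U, y)) * sw
  Xt <- crossprod(U, X) * sw

  res <- vector("list", ncol(G))
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    miss <- is.na(g)
    if (mean(miss) > max_missing) next
    if (all(miss)) next
    if (any(miss)) g[miss] <- mean(g, na.rm = TRUE)
    if (stats::var(g) == 0) next
    if (per_variant_reml) {
      fit_j <- reml_univariate(y, cbind(X, g = g), K, Aeig = Keig, se = FALSE)
      h2j <- fit_j$h2
      wj <- 1 / (h2j * pmax(Keig$values, 0) + (1 - h2j))
      swj <- sqrt(wj)
      ytj <- as.numeric(crossprod(U, y)) * swj
      Xf <- crossprod(U, cbind(X, g)) * swj
      est <- gls_wald(ytj, Xf)
    } else {
      gt <- as.numeric(crossprod(U, g)) * sw
      est <- gls_wald(yt, cbind(Xt, gt))
    }
    if (is.null(est)) next
    res[[j]] <- c(beta = est$beta, se = est$se, stat = est$stat, p = est$p)
  }
  keep <- !vapply(res, is.null, logical(1))
  out <- cbind(variants[keep, , drop = FALSE],
               as.data.frame(do.call(rbind, res[keep])))
  rownames(out) <- NULL
  structure(out, class = c("assoc_result", "data.frame"),
            null_fit = null_fit, n = n)
}

# OLS on whitened data; Wald t-test of the LAST column's coefficient
# (t rather than z so that the K = I limit reproduces simple linear
# regression exactly).
gls_wald <- function(yt, Xt) {
  q <- ncol(Xt)
  XtX <- crossprod(Xt)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  bet <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, yt)))
  rss <- sum((yt - Xt %*% bet)^2)
  dfres <- length(yt) - q
  if (dfres <= 0) return(NULL)
  sigma2 <- rss / dfres
  XtXinv_qq <- sum(forwardsolve(t(ch), diag(q)[, q])^2)
  se <- sqrt(sigma2 * XtXinv_qq)
  tval <- bet[q] / se
  list(beta = bet[q], se = se, stat = tval,
       p = 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE))
}

#' Genomic inflation factor
#'
#' Lambda = median observed chi-squared statistic divided by the median of
#' the 1-df chi-squared distribution (0.4549); ~1 indicates a calibrated
#' scan.
#'
#' @param p Vector of p-values (or an `assoc_result`).
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(p) {
  if (inherits(p, "assoc_result")) p <- p$p
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Ordinary least-squares association scan (no kinship correction)
#'
#' Reference scan used to demonstrate inflation under family structure:
#' identical to [lmm_scan()] with K forced to the identity.
#'
#' @inheritParams lmm_scan
#' @return An `assoc_result`.
#' @export
ols_scan <- function(y, X = NULL, geno, max_missing = 1) {
  G <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  lmm_scan(y, X, K = diag(nrow(G)), geno = geno, max_missing = max_missing)
}

#' Manhattan-plot table and significant hits
#'
#' Adds -log10(p) and a cumulative genome coordinate to an association
#' result and flags hits below the genome-wide threshold (default
#' 5e-8, the standard GWAS significance level).
#'
#' @param results An `assoc_result`.
#' @param threshold Genome-wide significance threshold on p.
#' @return List with `table` (chrom, pos, cum_pos, id, p, neg_log10_p,
#'   significant) and `hits` (the flagged subset, ordered by p).
#' @export
manhattan_table <- function(results, threshold = 5e-8) {
  if (nrow(results) == 0) stop("empty association results")
  df <- as.data.frame(results)
  df <- df[order(df$chrom, df$pos), ]
  offs <- 0
  df$cum_pos <- NA_real_
  for (ch in unique(df$chrom)) {
    sel <- df$chrom == ch
    df$cum_pos[sel] <- df$pos[sel] + offs
    offs <- offs + max(df$pos[sel])
  }
  df$neg_log10_p <- -log10(df$p)
  df$significant <- df$p < threshold
  hits <- df[df$significant, , drop = FALSE]
  hits <- hits[order(hits$p), , drop = FALSE]
  list(table = df[c("chrom", "pos", "cum_pos", "id", "beta", "se", "p",
                    "neg_log10_p", "significant")],
       hits = hits, threshold = threshold)
}

#' Write association results as TSV
#' @param results An `assoc_result`.
#' @param path Output path.
#' @export
write_assoc <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
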