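#' Read gene models from BED6 or GFF3
#'
#' Both dialects are converted to a single 1-based closed-coordinate
#' convention (BED is 0-based half-open on disk; rtracklayer performs the
#' conversion).  For GFF3, records of type `gene` are used and the gene
#' symbol is taken from the `Name` attribute (falling back to `ID` /
#' `gene_id`).
#'
#' @param path Path to a `.bed` or `.gff`/`.gff3` file.
#' @param format Override the extension-based format guess.
#' @return A `gene_models` data.frame: gene, chrom, start, end, strand.
#' @export
read_gene_models <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed" else "gff3"
  gr <- if (format == "bed") rtracklayer::import(path, format = "BED")
        else rtracklayer::import(path, format = "GFF3")
  if (format == "gff3") {
    if ("type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[as.character(gr$type) == "gene"]
    nm <- S4Vectors::mcols(gr)
    gene <- if (!is.null(nm$Name)) as.character(nm$Name)
            else if (!is.null(nm$ID)) as.character(nm$ID)
            else as.character(nm$gene_id)
  } else gene <- as.character(gr$name)
  if (any(is.na(gene) | gene == "")) stop("gene model without a name in ", path)
  out <- data.frame(gene = gene,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("gene with start > end in ", path)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Assign variants to genes and take per-gene minimum p
#'
#' A variant is assigned to every gene whose interval, extended by
#' `flank` bp on both sides, contains its position (a variant inside two
#' overlapping genes counts for both).  Genes with no assigned variant are
#' excluded: their minimum p is undefined, and they are likewise excluded
#' from the permutation universe.
#'
#' @param results An `assoc_result` (needs chrom, pos, p).
#' @param genes A `gene_models` data.frame.
#' @param flank Flanking window in bp (default 10000; the implicit window
#'   of published variant-to-gene attributions can be much larger, so this
#'   is configurable up to ~500 kb).
#' @return A `gene_minp` data.frame: gene, min_p, n_variants.
#' @export
assign_variants_to_genes <- function(results, genes, flank = 10000) {
  stopifnot(flank >= 0)
  res <- as.data.frame(results)
  if (!all(c("chrom", "pos", "p") %in% names(res)))
    stop("association results need chrom, pos, p")
  gr_var <- GenomicRanges::GRanges(res$chrom,
                                   IRanges::IRanges(res$pos, res$pos))
  gr_gene <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$start - flank), genes$end + flank))
  ov <- GenomicRanges::findOverlaps(gr_gene, gr_var, ignore.strand = TRUE)
  if (length(ov) == 0)
    stop("no variant overlaps any gene interval; ",
         "check chromosome naming / assembly")
  gi <- S4Vectors::queryHits(ov)
  pv <- res$p[S4Vectors::subjectHits(ov)]
  min_p <- tapply(pv, gi, min)
  n_var <- tapply(pv, gi, length)
  idx <- as.integer(names(min_p))
  out <- data.frame(gene = genes$gene[idx],
                    min_p = as.numeric(min_p),
                    n_variants = as.integer(n_var),
                    stringsAsFactors = FALSE)
  # a symbol may label several gene models; keep the smallest p over them
  if (anyDuplicated(out$gene)) {
    agg_p <- tapply(out$min_p, out$gene, min)
    agg_n <- tapply(out$n_variants, out$gene, sum)
    out <- data.frame(gene = names(agg_p), min_p = as.numeric(agg_p),
                      n_variants = as.integer(agg_n),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("gene_minp", "data.frame")
  out
}

#' Permutation gene-set enrichment on per-gene minimum p-values
#'
#' The observed statistic is T = the mean of the per-gene minimum
#' association p-values over the target genes found in the universe.
#' Each of B permutations draws, without replacement, a random gene set
#' of the same size from the universe of all genes with at least one
#' assigned variant, and records its mean minimum p.  The enrichment
#' p-value is the proportion of permutations whose mean is strictly lower
#' than T (ties count as not lower); the add-one corrected estimate
#' (k+1)/(B+1) is reported alongside.
#'
#' @param gene_minp A `gene_minp` data.frame (the universe).
#' @param target_list Character vector of target gene symbols.
#' @param B Number of permutations (published default 10000).
#' @param seed Integer seed for the permutation stream.
#' @param log10_stat If TRUE use mean log10(min p) instead of the raw
#'   mean (raw means are dominated by large p-values; off by default to
#'   match the published statistic).
#' @return An `enrichment_result` list: n_target, n_universe, T_obs, B,
#'   k, p (= k/B), p_add_one, seed, statistic.
#' @export
permutation_enrichment <- function(gene_minp, target_list, B = 10000,
                                   seed = 1L, log10_stat = FALSE) {
  if (B < 1) stop("B must be >= 1")
  stat <- if (log10_stat) function(x) mean(log10(x)) else mean
  universe <- gene_minp$gene
  vals <- gene_minp$min_p
  present <- intersect(unique(target_list), universe)
  if (!length(present))
    stop("no target gene present in the min-p universe")
  m <- length(present)
  T_obs <- stat(vals[match(present, universe)])
  set.seed(seed)
  perm <- vapply(seq_len(B),
                 function(i) stat(vals[sample.int(length(vals), m)]),
                 numeric(1))
  k <- sum(perm < T_obs)
  structure(list(n_target = m, n_universe = length(universe),
                 T_obs = T_obs, B = as.integer(B), k = as.integer(k),
                 p = k / B, p_add_one = (k + 1) / (B + 1),
                 seed = as.integer(seed),
                 statistic = if (log10_stat) "mean_log10_min_p"
                             else "mean_min_p"),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "permutation enrichment: %d target genes in a universe of %d\n",
    x$n_target, x$n_universe))
  cat(sprintf("  T = %.4g  B = %d  k = %d  p = %.4g  [(k+1)/(B+1) = %.4g]\n",
              x$T_obs, x$B, x$k, x$p, x$p_add_one))
  invisible(x)
}

#' Run enrichment over several target gene lists
#'
#' One [permutation_enrichment()] per named list, each with its own seed
#' derived deterministically from the master seed and the list name, so
#' results are reproducible and per-list independent.  A failing list
#' (e.g. empty intersection with the universe) is reported as an error
#' entry without aborting the other lists.
#'
#' @param gene_minp A `gene_minp` universe.
#' @param lists Named list of character vectors of gene symbols.
#' @param B Permutations per list.
#' @param seed Master seed.
#' @param log10_stat Passed through.
#' @return Named list of `enrichment_result` (or `enrichment_error`)
#'   objects.
#' @export
run_enrichment_suite <- function(gene_minp, lists, B = 10000, seed = 1L,
                                 log10_stat = FALSE) {
  if (!length(lists) || is.null(names(lists)))
    stop("`lists` must be a non-empty named list")
  out <- lapply(names(lists), function(nm) {
    tryCatch(
      permutation_enrichment(gene_minp, lists[[nm]], B = B,
                             seed = derive_seed(seed, nm),
                             log10_stat = log10_stat),
      error = function(e) structure(list(list = nm, error = conditionMessage(e)),
                                    class = "enrichment_error"))
  })
  stats::setNames(out, names(lists))
}

#' Read a target gene list (one symbol per line)
#' @param path Text file path; blank lines and `#` comments ignored.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[x != "" & !startsWith(x, "#")]
  if (!length(x)) stop("empty gene list: ", path)
  x
}
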