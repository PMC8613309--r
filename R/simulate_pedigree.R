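#' Simulate a multi-generational breeding-colony pedigree
#'
#' Founders are split between the sexes; each subsequent generation is
#' produced by random mating among the previous generation's animals (dams
#' mate with a randomly chosen sire, avoiding their own sire and full
#' brothers unless `allow_inbreeding`), with litter sizes Poisson
#' distributed.  The result is the discrete-generation analogue of a
#' primate-center colony pedigree.
#'
#' @param config A [sim_config()].
#' @return A `pedigree` data.frame with columns `id`, `sire`, `dam`
#'   (0 = unknown), `sex` ("M"/"F") and `generation`, topologically sorted
#'   (parents precede offspring).
#' @examples
#' ped <- simulate_pedigree(sim_config(n_founders = 10, n_generations = 2, seed = 3))
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "pedigree"))
  nf <- config$n_founders
  if (nf < 2) stop("need at least 2 founders")
  sex <- rep(c("M", "F"), length.out = nf)
  id <- seq_len(nf)
  sire <- dam <- rep(0L, nf)
  gen <- rep(0L, nf)

  for (g in seq_len(config$n_generations)) {
    prev <- which(gen == g - 1L)
    dams <- prev[sex[prev] == "F"]
    sires <- prev[sex[prev] == "M"]
    if (length(dams) == 0 || length(sires) == 0)
      stop("generation ", g - 1L,
           " lacks one sex entirely; cannot mate (single-sex founders?)")
    n_off <- stats::rpois(length(dams), config$mean_offspring)
    for (j in seq_along(dams)) {
      d <- dams[j]
      if (n_off[j] == 0) next
      ok <- sires
      if (!config$allow_inbreeding) {
        # exclude the dam's own sire and her full brothers
        bad <- ok == sire[d] & sire[d] != 0L
        fullsib <- sire[ok] == sire[d] & dam[ok] == dam[d] &
          (sire[d] != 0L | dam[d] != 0L)
        ok <- ok[!(bad | fullsib)]
      }
      if (length(ok) == 0) ok <- sires   # fall back rather than fail
      s <- if (length(ok) == 1) ok else sample(ok, 1L)
      for (k in seq_len(n_off[j])) {
        id <- c(id, length(id) + 1L)
        sire <- c(sire, s)
        dam <- c(dam, d)
        sex <- c(sex, if (stats::runif(1) < 0.5) "M" else "F")
        gen <- c(gen, g)
      }
    }
  }
  ped <- data.frame(id = as.integer(id), sire = as.integer(sire),
                    dam = as.integer(dam), sex = sex,
                    generation = as.integer(gen),
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
}

#' Validate and topologically sort a pedigree
#'
#' Checks referential integrity (every named parent exists), sex
#' consistency (no id used both as sire and dam), and acyclicity, then
#' returns the pedigree ordered so that parents precede offspring.
#'
#' @param ped Data frame with columns `id`, `sire`, `dam`, `sex`
#'   (0 or NA parent = unknown).
#' @return The validated, topologically sorted `pedigree`.
#' @export
validate_pedigree <- function(ped) {
  need <- c("id", "sire", "dam", "sex")
  if (!all(need %in% names(ped)))
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  ped$sire[is.na(ped$sire)] <- 0L
  ped$dam[is.na(ped$dam)] <- 0L
  if (anyDuplicated(ped$id))
    stop("duplicate individual id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  known <- ped$id
  for (col in c("sire", "dam")) {
    ref <- ped[[col]]
    bad <- ref != 0L & !(ref %in% known)
    if (any(bad))
      stop("unknown ", col, " id referenced in row(s) ",
           paste(which(bad), collapse = ", "), ": ",
           paste(unique(ref[bad]), collapse = ", "))
  }
  both <- intersect(ped$sire[ped$sire != 0L], ped$dam[ped$dam != 0L])
  if (length(both))
    stop("id used as both sire and dam: ", paste(both, collapse = ", "))
  sx <- ped$sex[match(ped$sire[ped$sire != 0L], ped$id)]
  if (any(sx != "M"))
    stop("sire with non-male sex: ",
         paste(unique(ped$sire[ped$sire != 0L][sx != "M"]), collapse = ", "))
  sx <- ped$sex[match(ped$dam[ped$dam != 0L], ped$id)]
  if (any(sx != "F"))
    stop("dam with non-female sex: ",
         paste(unique(ped$dam[ped$dam != 0L][sx != "F"]), collapse = ", "))

  # Kahn-style topological sort; leftover rows imply a parentage cycle.
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)   # NA when parent unknown (0 never matches)
  di <- match(ped$dam, ped$id)
  placed <- logical(n)
  order_idx <- integer(0)
  repeat {
    idx <- which(!placed)
    if (!length(idx)) break
    ok_s <- is.na(si[idx]) | placed[ifelse(is.na(si[idx]), 1L, si[idx])]
    ok_d <- is.na(di[idx]) | placed[ifelse(is.na(di[idx]), 1L, di[idx])]
    ready <- idx[ok_s & ok_d]
    if (!length(ready))
      stop("pedigree contains a parentage cycle involving id(s): ",
           paste(ped$id[idx], collapse = ", "))
    placed[ready] <- TRUE
    order_idx <- c(order_idx, ready)
  }
  out <- ped[order_idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

founders <- function(ped) ped$id[ped$sire == 0L & ped$dam == 0L]

#' Read a pedigree from a TSV file
#'
#' Expects tab-separated columns `id`, `sire`, `dam`, `sex`; 0 or blank
#' marks an unknown parent.  Rows may appear in any order; the returned
#' pedigree is validated and topologically sorted.
#'
#' @param path Path to the TSV file.
#' @return A `pedigree` data.frame.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (col in c("id", "sire", "dam")) {
    v <- tab[[col]]
    if (is.character(v)) v[v == ""] <- "0"
    tab[[col]] <- suppressWarnings(as.integer(v))
    if (anyNA(tab[[col]]))
      stop("non-integer ", col, " in ", path)
  }
  validate_pedigree(tab)
}

#' Write a pedigree to TSV
#' @param ped A `pedigree`.
#' @param path Output path.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped[c("id", "sire", "dam", "sex")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
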