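#' Default factor loadings for the BBA items
#'
#' The Activity factor comprises time locomoting, time NOT hanging from
#' the cage top/side, rate of environmental exploration, and the
#' dichotomized items ate-food, drank-water and crouching; the
#' Emotionality factor comprises the rates of cooing and barking and the
#' dichotomized items scratched, threats and lipsmacked.  The original
#' factor-analytic loadings are not published, so the default is unit
#' weight on each z-scored item (item naming already encodes the sign
#' convention, e.g. "time NOT hanging").  Loadings are a configurable
#' input: supply your own named weights to override.
#'
#' @return A `factor_loadings` list with numeric named vectors `activity`
#'   and `emotionality`.
#' @export
default_loadings <- function() {
  map <- bba_item_map()
  structure(
    list(activity = stats::setNames(map$sign[map$factor == "activity"],
                                    map$item[map$factor == "activity"]),
         emotionality = stats::setNames(map$sign[map$factor == "emotionality"],
                                        map$item[map$factor == "emotionality"])),
    class = "factor_loadings")
}

#' Read factor loadings from a JSON or YAML config file
#' @param path Path to a JSON (or YAML, by extension) file with named
#'   `activity` and `emotionality` item-weight maps.
#' @return A `factor_loadings` object.
#' @export
read_loadings <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml not available")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("activity", "emotionality") %in% names(raw)))
    stop("loadings file must define 'activity' and 'emotionality'")
  structure(list(activity = unlist(raw$activity),
                 emotionality = unlist(raw$emotionality)),
            class = "factor_loadings")
}

#' Score Activity and Emotionality factors from behavioral items
#'
#' Each item is z-scored within the cohort (separately per test day;
#' dichotomous items enter as 0/1 before z-scoring), weighted by its
#' loading, summed within factor, and the resulting day-specific factor
#' scores are standardized to cohort mean 0 and SD 1.  Items with zero
#' variance in the cohort carry no information and are dropped with a
#' warning.
#'
#' @param records Data frame, one row per animal x day, with columns `id`,
#'   `day` (1/2) and the item columns named in `loadings`.
#' @param loadings A `factor_loadings` (default [default_loadings()]).
#' @return A `factor_scores` data.frame: id, activity_d1, activity_d2,
#'   emotionality_d1, emotionality_d2.
#' @export
score_factors <- function(records, loadings = default_loadings()) {
  stopifnot(all(c("id", "day") %in% names(records)))
  if (!all(records$day %in% c(1L, 2L))) stop("day must be 1 or 2")
  ids <- unique(records$id)
  cnt <- table(records$id, records$day)
  bad <- rownames(cnt)[rowSums(cnt == 1) != 2]
  if (length(bad))
    stop("animals without exactly one record per day: ",
         paste(utils::head(bad, 5), collapse = ", "))
  items <- unlist(lapply(loadings, names))
  miss <- setdiff(items, names(records))
  if (length(miss))
    stop("missing item column(s): ", paste(miss, collapse = ", "))
  if (anyNA(records[items])) stop("missing item values present")

  out <- data.frame(id = ids)
  for (fac in c("activity", "emotionality")) {
    w <- loadings[[fac]]
    for (d in 1:2) {
      sub <- records[records$day == d, , drop = FALSE]
      sub <- sub[match(ids, sub$id), , drop = FALSE]
      score <- numeric(length(ids))
      for (it in names(w)) {
        v <- as.numeric(sub[[it]])
        s <- stats::sd(v)
        if (s == 0) {
          warning("item '", it, "' (day ", d,
                  ") has zero variance; excluded from scoring")
          next
        }
        score <- score + w[[it]] * (v - mean(v)) / s
      }
      ssd <- stats::sd(score)
      out[[paste0(fac, "_d", d)]] <-
        if (ssd == 0) score - mean(score) else (score - mean(score)) / ssd
    }
  }
  class(out) <- c("factor_scores", "data.frame")
  out
}

#' Classify inhibited temperament from factor scores
#'
#' An animal is classified inhibited when its Activity and Emotionality
#' scores both fall strictly below the cohort means across the two test
#' days.  The default rule averages each factor over days and compares the
#' day-averaged scores with their cohort means; `rule = "all_four"`
#' requires all four day x factor scores to be below their respective
#' means.  Ties with the mean count as not inhibited.  Also returns the
#' continuous IT composite: minus the mean of the four standardized
#' scores, so higher = more inhibited.
#'
#' @param scores A `factor_scores` data.frame.
#' @param rule `"day_average"` (default) or `"all_four"`.
#' @return A `temperament_labels` data.frame: id, inhibited (logical),
#'   it_continuous.
#' @export
classify_it <- function(scores, rule = c("day_average", "all_four")) {
  rule <- match.arg(rule)
  cols <- c("activity_d1", "activity_d2", "emotionality_d1", "emotionality_d2")
  if (!all(cols %in% names(scores))) stop("missing factor-score columns")
  if (nrow(scores) < 2) stop("need >= 2 animals to define cohort means")
  if (anyNA(scores[cols])) stop("missing factor scores")
  S <- as.matrix(scores[cols])
  if (rule == "day_average") {
    act <- rowMeans(S[, 1:2, drop = FALSE])
    emo <- rowMeans(S[, 3:4, drop = FALSE])
    inhibited <- act < mean(act) & emo < mean(emo)
  } else {
    inhibited <- rowSums(sweep(S, 2, colMeans(S), "<")) == 4L
  }
  data.frame(id = scores$id, inhibited = inhibited,
             it_continuous = -rowMeans(S),
             stringsAsFactors = FALSE)
}

#' Rank-based inverse normal transformation
#'
#' Blom-offset transform applied before variance-component analysis:
#' \deqn{\Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)} where r_i is the rank
#' of the i-th value (ties receive the average of their ranks).  Strictly
#' monotone in the input up to ties.
#'
#' @param values Numeric vector (>= 2 finite values, not all equal).
#' @return Transformed vector, same order and names as the input.
#' @export
inverse_normal_transform <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (anyNA(values) || any(!is.finite(values))) stop("non-finite values")
  if (diff(range(values)) == 0)
    stop("all values equal; inverse normal transform undefined")
  r <- rank(values, ties.method = "average")
  out <- stats::qnorm((r - 3 / 8) / (length(values) + 1 / 4))
  names(out) <- names(values)
  out
}

#' Write / read phenotype records as long CSV
#'
#' One row per animal x day x item (`id, day, sex, item, value`), the
#' interchange format between the simulation and scoring stages.
#'
#' @param records Wide data frame (one row per animal x day).
#' @param path CSV path.
#' @export
write_phenotypes <- function(records, path) {
  meta <- c("id", "day", "sex")
  items <- setdiff(names(records), meta)
  long <- do.call(rbind, lapply(items, function(it)
    data.frame(records[meta], item = it, value = records[[it]],
               stringsAsFactors = FALSE)))
  long <- long[order(long$id, long$day, long$item), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @return `read_phenotypes`: the wide per-animal x day data frame.
#' @export
read_phenotypes <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "day", "item", "value") %in% names(long)))
  wide <- stats::reshape(long, idvar = c("id", "day", "sex"),
                         timevar = "item", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$id, wide$day), ]
}
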