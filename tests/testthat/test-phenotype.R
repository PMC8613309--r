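make_records <- function(tab) {
  # tab: data.frame with id, day and any subset of item columns; missing
  # items are filled with deterministic filler so scoring has variance
  items <- bba_items <- c("locomotion_s", "not_hanging_s", "exploration_rate",
                          "ate_food", "drank_water", "crouching",
                          "cooing_rate", "barking_rate",
                          "scratched", "threats", "lipsmacked")
  for (it in setdiff(items, names(tab)))
    tab[[it]] <- seq_len(nrow(tab)) %% 3
  tab$sex <- "F"
  tab
}

test_that("factor scoring matches a hand computation and its invariants", {
  # unit loading on one continuous item: score is that item's z-score
  rec <- make_records(data.frame(id = rep(1:5, each = 2), day = rep(1:2, 5),
                                 locomotion_s = c(10, 12, 20, 18, 30, 31,
                                                  40, 42, 50, 49)))
  one_item <- structure(list(activity = c(locomotion_s = 1),
                             emotionality = c(cooing_rate = 1)),
                        class = "factor_loadings")
  sc <- score_factors(rec, one_item)
  d1 <- rec$locomotion_s[rec$day == 1]
  expect_equal(sc$activity_d1, as.numeric(scale(d1)), tolerance = 1e-12)

  # 5-animal toy cohort, two items, spreadsheet-style arithmetic
  rec2 <- make_records(data.frame(
    id = rep(1:5, each = 2), day = rep(1:2, 5),
    locomotion_s = c(100, 90, 200, 210, 300, 290, 400, 410, 500, 505),
    exploration_rate = c(1, 2, 4, 3, 9, 8, 16, 17, 25, 24)))
  two_item <- structure(list(activity = c(locomotion_s = 1,
                                          exploration_rate = 1),
                             emotionality = c(cooing_rate = 1)),
                        class = "factor_loadings")
  sc2 <- score_factors(rec2, two_item)
  loco <- c(100, 200, 300, 400, 500)
  expl <- c(1, 4, 9, 16, 25)
  raw <- (loco - mean(loco)) / sd(loco) + (expl - mean(expl)) / sd(expl)
  expect_equal(sc2$activity_d1, as.numeric(scale(raw)), tolerance = 1e-12)

  # all animals identical: zero-variance items are dropped, scores all 0
  rec3 <- make_records(data.frame(id = rep(1:4, each = 2), day = rep(1:2, 4),
                                  locomotion_s = 7))
  rec3[setdiff(names(rec3), c("id", "day", "sex"))] <- 1
  suppressWarnings(sc3 <- score_factors(rec3))
  expect_true(all(as.matrix(sc3[-1]) == 0))
  w <- capture_warnings(score_factors(rec3))
  expect_true(all(grepl("zero variance", w)))

  # missing day / missing item are explicit errors
  expect_error(score_factors(rec[rec$day == 1, ], one_item), "per day")
  expect_error(score_factors(rec[setdiff(names(rec), "cooing_rate")],
                             one_item), "cooing_rate")
})

test_that("loadings load from a JSON config and match the defaults", {
  path <- system.file("extdata", "default_loadings.json",
                      package = "macaqueIT")
  ld <- read_loadings(path)
  def <- default_loadings()
  expect_equal(ld$activity, def$activity)
  expect_equal(ld$emotionality, def$emotionality)

  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(activity = list(x = 1)), bad, auto_unbox = TRUE)
  expect_error(read_loadings(bad), "emotionality")
})

test_that("IT classification implements the below-both-means rule", {
  sc <- data.frame(id = 1:4,
                   activity_d1 = c(-1, -1, 1, 1),
                   activity_d2 = c(-1, -1, 1, 1),
                   emotionality_d1 = c(-1, 1, -1, 1),
                   emotionality_d2 = c(-1, 1, -1, 1))
  lab <- classify_it(sc)
  expect_equal(lab$inhibited, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(lab$it_continuous, -rowMeans(sc[-1]))

  # exhaustive per-animal recheck on a simulated cohort, both rules
  cfg <- toy_config(n_snvs = 0)
  ped <- simulate_pedigree(cfg)
  scs <- score_factors(simulate_phenotypes(ped, cfg)$records)
  for (rule in c("day_average", "all_four")) {
    lab2 <- classify_it(scs, rule = rule)
    S <- as.matrix(scs[-1])
    manual <- vapply(seq_len(nrow(S)), function(i) {
      if (rule == "day_average") {
        act <- rowMeans(S[, 1:2]); emo <- rowMeans(S[, 3:4])
        act[i] < mean(act) && emo[i] < mean(emo)
      } else all(S[i, ] < colMeans(S))
    }, logical(1))
    expect_equal(lab2$inhibited, manual)
  }

  # affine rescaling of a factor leaves the classification unchanged
  sc_resc <- scs
  sc_resc$activity_d1 <- 3 * scs$activity_d1 + 10
  sc_resc$activity_d2 <- 3 * scs$activity_d2 + 10
  expect_equal(classify_it(sc_resc)$inhibited, classify_it(scs)$inhibited)

  # counts partition the cohort
  expect_equal(sum(classify_it(scs)$inhibited) +
                 sum(!classify_it(scs)$inhibited), nrow(scs))

  expect_error(classify_it(sc[1, , drop = FALSE]), ">= 2")
})

test_that("inverse normal transform follows the Blom formula", {
  # n = 3 distinct values: direct evaluation of the rank formula
  expect_equal(inverse_normal_transform(c(5, -2, 11)),
               qnorm((c(2, 1, 3) - 3 / 8) / (3 + 1 / 4)),
               tolerance = 1e-12)

  x <- c(3.2, -1, 0.5, 7, 2, 2.5, -4)
  z <- inverse_normal_transform(x)
  expect_equal(order(z), order(x))          # monotone
  expect_equal(z[order(x)][4], 0)           # odd n: middle maps to 0
  expect_lt(abs(mean(z)), 1e-8)             # symmetric rank layout
  expect_equal(inverse_normal_transform(-x), -z, tolerance = 1e-12)

  # ties share the averaged rank
  zt <- inverse_normal_transform(c(1, 1, 2))
  expect_equal(zt[1], zt[2])

  expect_error(inverse_normal_transform(rep(4, 5)), "all values equal")
  expect_error(inverse_normal_transform(3), "at least 2")
})
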