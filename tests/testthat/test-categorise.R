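test_that("quartile summaries match hand enumeration and the hinge oracle", {
  q <- quartile_summary(c(1, 2, 3, 4, 5, 6))
  expect_equal(unlist(q[c("min", "q1", "q2", "q3", "max")]),
               c(min = 1, q1 = 2, q2 = 3.5, q3 = 5, max = 6))
  flat <- quartile_summary(rep(5, 6))
  expect_true(all(unlist(flat[c("min", "q1", "q2", "q3", "max")]) == 5))

  # property: Tukey hinges equal the oracle; summary order invariant under
  # permutation; min <= Q1 <= Q2 <= Q3 <= max always
  withr::with_seed(99, {
    for (rep in 1:40) {
      n <- sample(2:12, 1)
      v <- round(runif(n, 0, 100), 1)
      q <- quartile_summary(v)
      o <- hinge_oracle(v)
      expect_equal(q[c("min", "q1", "q2", "q3", "max")], o)
      qp <- quartile_summary(sample(v))
      expect_equal(qp[c("min", "q1", "q2", "q3", "max")], o)
      expect_true(q$min <= q$q1 && q$q1 <= q$q2 &&
                    q$q2 <= q$q3 && q$q3 <= q$max)
    }
  })
  expect_error(quartile_summary(5), "at least 2")
  expect_error(quartile_summary(c(1, NA, 3)), "finite")
})

test_that("category scores follow the quartile rule table", {
  # whole replicate set above threshold (the 5 uM reference-compound
  # phospholipid case, 98.3-100%) -> 4
  expect_equal(categorise(quartile_summary(c(98.3, 99.1, 99.6, 99.8, 100,
                                             100)))$score, 4L)
  # all below threshold -> 1
  expect_equal(categorise(quartile_summary(rep(0, 6)))$score, 1L)
  # Q1 above, min below -> 3 (oracle-checked hinge)
  v3 <- c(8, 14, 15, 18, 20, 22)
  o <- hinge_oracle(v3)
  expect_gt(o$q1, 10)
  expect_lt(o$min, 10)
  expect_equal(categorise(quartile_summary(v3))$score, 3L)
  # median above, Q1 below -> 2 (the 9.9% borderline shape)
  v2 <- c(4, 6, 9.9, 12, 14, 16)
  o2 <- hinge_oracle(v2)
  expect_gt(o2$q2, 10)
  expect_lt(o2$q1, 10)
  expect_equal(categorise(quartile_summary(v2))$score, 2L)
  expect_equal(categorise(quartile_summary(v2))$label,
               "Possibly treatment-related")
})

test_that("values exactly at the threshold fall to the lower category", {
  # Q2 exactly 10 -> score 1 (strict >)
  expect_equal(categorise(quartile_summary(c(2, 4, 10, 10, 12, 14)))$score, 1L)
  # min exactly 10, Q1 above -> 3, not 4
  expect_equal(categorise(quartile_summary(c(10, 14, 15, 18, 20, 22)))$score,
               3L)
  # custom threshold honoured
  expect_equal(categorise(quartile_summary(c(30, 35, 40, 45, 50, 55)),
                          threshold = 60)$score, 1L)
})

test_that("scores are monotone and the rule chain is internally consistent", {
  withr::with_seed(7, {
    for (rep in 1:40) {
      v <- runif(sample(3:8, 1), 0, 40)
      s0 <- categorise(quartile_summary(v))$score
      s1 <- categorise(quartile_summary(v + runif(1, 0, 30)))$score
      expect_gte(s1, s0)
      q <- quartile_summary(v)
      if (q$min > 10) expect_gt(q$q1, 10)  # category 4 implies category 3
    }
  })
})

test_that("quartile convention is outcome-relevant on borderline sets and is pinned", {
  # lower hinge 9.9 under Tukey, 10.4 under linear interpolation: the
  # category flips 2 -> 3 with the convention, so the default is explicit
  v <- c(8, 9.9, 12, 14, 15, 16)
  expect_equal(quartile_summary(v, "tukey")$q1, 9.9)
  expect_equal(quartile_summary(v, "linear")$q1, 10.425)
  expect_equal(categorise(quartile_summary(v, "tukey"))$score, 2L)
  expect_equal(categorise(quartile_summary(v, "linear"))$score, 3L)
})

test_that("the detachment exclusion rule is strict, per dose, and recorded", {
  prof <- function(compound, dose, nonadh, replicate) {
    tibble::tibble(compound = compound, dose_uM = dose, is_control = FALSE,
                   replicate = replicate, pct_nonadherent = nonadh)
  }
  profiles <- dplyr::bind_rows(
    prof("a", 10, c(55, 65), 1:2),   # mean 60 -> excluded
    prof("a", 5, c(20, 30), 1:2),    # mean 25 -> retained
    prof("b", 10, c(45, 55), 1:2))   # mean exactly 50 -> retained (strict)
  ex <- apply_exclusions(profiles)
  expect_true(ex$excluded[ex$compound == "a" & ex$dose_uM == 10])
  expect_false(ex$excluded[ex$compound == "a" & ex$dose_uM == 5])
  expect_false(ex$excluded[ex$compound == "b"])
  expect_match(ex$reason[ex$compound == "a" & ex$dose_uM == 10], "> 50")
})

test_that("score matrices are deterministic, order-free, and honour exclusions", {
  b <- test_baseline(600)
  eff <- list(effect_template("cadX", "cad"),
              effect_template("steroidX", "corticosteroid"),
              effect_template("inertX", "inert"))
  tr <- expand.grid(compound = c("cadX", "steroidX", "inertX"),
                    dose_uM = c(0.1, 5), stringsAsFactors = FALSE)
  ser <- simulate_replicate_series(plate_spec("M", treatments = tr), b, eff,
                                   n = 6, base_seed = 51)
  profiles <- series_profiles(ser)
  sets <- replicate_sets(profiles)
  ex <- apply_exclusions(profiles)
  sm <- build_score_matrix(sets, ex)

  cad5 <- sm[sm$compound == "cadX" & sm$dose_uM == 5, ]
  expect_equal(cad5$elev_phospholipid, 4L)
  steroid <- sm[sm$compound == "steroidX", ]
  expect_true(all(steroid$elev_phospholipid <= 2))
  inert <- sm[sm$compound == "inertX", ]
  expect_true(all(unlist(inert[cell_attributes()]) <= 2))

  # invariance under replicate reordering
  sets_shuffled <- withr::with_seed(1, sets[sample(nrow(sets)), ])
  sm2 <- build_score_matrix(sets_shuffled, ex)
  expect_equal(as.data.frame(sm), as.data.frame(sm2))
})

test_that("an all-null panel scores 1 everywhere and heavy detachment drops a compound", {
  b <- test_baseline(500)
  eff <- list(effect_template("inertA", "inert"),
              effect_template("inertB", "inert"),
              effect_template("apoX", "apoptosis"))
  tr <- expand.grid(compound = c("inertA", "inertB", "apoX"),
                    dose_uM = 5, stringsAsFactors = FALSE)
  ser <- simulate_replicate_series(plate_spec("N", treatments = tr), b, eff,
                                   n = 5, base_seed = 61)
  profiles <- series_profiles(ser)
  ex <- apply_exclusions(profiles)
  sm <- build_score_matrix(replicate_sets(profiles), ex)

  # apoptosis template detaches ~90% of cells at 5 uM -> excluded
  expect_true(sm$excluded[sm$compound == "apoX"])
  expect_true(all(is.na(sm[sm$compound == "apoX", cell_attributes()])))
  null_scores <- unlist(sm[sm$compound %in% c("inertA", "inertB"),
                           cell_attributes()])
  expect_true(all(null_scores == 1L))
})
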