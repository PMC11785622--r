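test_that("simulation is deterministic in (spec, seed) and seeds substreams per well", {
  tr <- data.frame(compound = "cadX", dose_uM = c(1, 5))
  eff <- list(effect_template("cadX", "cad"))
  spec <- plate_spec("P1", treatments = tr)
  b <- test_baseline()

  p1 <- simulate_plate(spec, b, eff, seed = 7)
  p2 <- simulate_plate(spec, b, eff, seed = 7)
  expect_identical(p1$cells, p2$cells)
  expect_identical(p1$wells, p2$wells)
  expect_identical(p1$ground_truth, p2$ground_truth)

  p3 <- simulate_plate(spec, b, eff, seed = 8)
  expect_false(identical(p1$cells, p3$cells))
  expect_identical(p1$wells$seed, rep(7L, nrow(p1$wells)))
})

test_that("a control-only plate has all-zero ground truth and conserves counts", {
  p <- simulate_plate(plate_spec("P0"), test_baseline(500, 100), seed = 3)
  expect_true(all(p$ground_truth$planted_fraction == 0))
  expect_true(all(p$wells$planted_detachment == 0))
  expect_identical(p$wells$pre_count,
                   p$wells$adherent_count + p$wells$detached_count)
  expect_true(all(p$cells$is_control))
})

test_that("treated wells conserve counts under detachment thinning", {
  tr <- data.frame(compound = "apo", dose_uM = c(0.1, 5, 10))
  p <- simulate_plate(plate_spec("P1", treatments = tr), test_baseline(800),
                      list(effect_template("apo", "apoptosis")), seed = 11)
  expect_identical(p$wells$pre_count,
                   p$wells$adherent_count + p$wells$detached_count)
  tw <- p$wells[!p$wells$is_control, ]
  expect_true(all(tw$planted_detachment > 0))
  # detachment scales monotonically with dose
  expect_true(all(diff(tw$planted_detachment[order(tw$dose_uM)]) >= 0))
  # every adherent cell has a row; detached cells contribute none
  counts <- table(factor(p$cells$well_id, levels = p$wells$well_id))
  expect_equal(as.integer(counts), p$wells$adherent_count)
})

test_that("a planted fraction of 1 at the reference dose shifts every cell beyond mean + 2 SD", {
  tr <- data.frame(compound = "cadX", dose_uM = 5)
  b <- test_baseline()
  p <- simulate_plate(plate_spec("P1", treatments = tr), b,
                      list(effect_template("cadX", "cad")), seed = 5)
  gt <- p$ground_truth
  expect_equal(gt$planted_fraction[gt$well_id == "T01" &
                                     gt$attribute == "elev_phospholipid"], 1)
  m <- b$measures$phospho_fi$mean
  s <- b$measures$phospho_fi$sd
  treated <- p$cells[p$cells$well_id == "T01", ]
  expect_true(all(treated$phospho_fi > m + 2 * s))
  expect_true(all(treated$phospho_fi <= m + 4 * s))
})

test_that("planted abnormal fractions are recovered within 3 binomial standard errors", {
  b <- test_baseline(1000)
  m <- b$measures$phospho_fi$mean
  s <- b$measures$phospho_fi$sd
  tail_rate <- tail_prob_oracle(m, s, "lognormal", "upper")
  for (f in c(0, 0.25, 0.5, 1)) {
    eff <- compound_effect("drugX", effects = c(elev_phospholipid = f))
    tr <- data.frame(compound = "drugX", dose_uM = 5)
    p <- simulate_plate(plate_spec("P1", treatments = tr), b, list(eff),
                        seed = 100 + round(100 * f))
    prof <- well_profiles(p)
    measured <- prof$pct_elev_phospholipid[prof$well_id == "T01"]
    expected <- 100 * (f + (1 - f) * tail_rate)
    n <- p$wells$adherent_count[p$wells$well_id == "T01"]
    se <- 100 * sqrt(max(expected / 100 * (1 - expected / 100), 1e-9) / n)
    expect_lt(abs(measured - expected), max(3 * se, 0.75))
  }
})

test_that("expected percentages are monotone in the planted fraction", {
  b <- test_baseline(2000)
  measure_pct <- function(f) {
    eff <- compound_effect("d", effects = c(elev_neutral_lipid = f))
    p <- simulate_plate(plate_spec("P1",
                                   treatments = data.frame(compound = "d",
                                                           dose_uM = 5)),
                        b, list(eff), seed = 21)
    prof <- well_profiles(p)
    prof$pct_elev_neutral_lipid[prof$well_id == "T01"]
  }
  pcts <- vapply(c(0, 0.2, 0.5, 0.9), measure_pct, numeric(1))
  expect_true(all(diff(pcts) > 0))
})

test_that("simulate_plate validates its inputs", {
  tr <- data.frame(compound = "ghost", dose_uM = 5)
  expect_error(simulate_plate(plate_spec("P", treatments = tr),
                              test_baseline(), list(), seed = 1),
               "ghost")
  expect_error(plate_spec("P", n_control = 0), "control")
  expect_error(plate_spec("P", treatments = data.frame(compound = "x",
                                                       dose_uM = -1)),
               "> 0")
  expect_error(baseline_params(list(), 100, 10), "measures")
  expect_error(compound_effect("x", effects = c(not_an_attribute = 0.5)),
               "unknown effect attribute")
  expect_error(compound_effect("x", effects = c(elev_mito = 1.2)), "0, 1")
})

test_that("replicate series anchors replicate 1 and shares ground truth at zero jitter", {
  tr <- data.frame(compound = "cadX", dose_uM = 5)
  eff <- list(effect_template("cadX", "cad"))
  b <- test_baseline(400)
  spec <- plate_spec("S", treatments = tr)

  ser1 <- simulate_replicate_series(spec, b, eff, n = 1, base_seed = 9)
  direct <- simulate_plate(plate_spec("S_R1", treatments = tr), b, eff,
                           seed = 9)
  expect_identical(ser1[[1]]$cells, direct$cells)
  expect_identical(ser1[[1]]$wells, direct$wells)

  ser <- simulate_replicate_series(spec, b, eff, n = 4, base_seed = 9,
                                   jitter = 0)
  gts <- lapply(ser, function(p) p$ground_truth$planted_fraction)
  for (r in 2:4) expect_identical(gts[[r]], gts[[1]])

  serj <- simulate_replicate_series(spec, b, eff, n = 3, base_seed = 9,
                                    jitter = 0.05)
  m1 <- mean(serj[[1]]$cells$phospho_fi[serj[[1]]$cells$is_control])
  m2 <- mean(serj[[2]]$cells$phospho_fi[serj[[2]]$cells$is_control])
  expect_false(isTRUE(all.equal(m1, m2, tolerance = 1e-6)))
  expect_error(simulate_replicate_series(spec, b, eff, n = 0), ">= 1")
})
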