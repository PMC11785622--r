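test_that("baseline pools untreated cells with sample SD and hand-checkable moments", {
  cells <- tiny_cells(c(0, 2) + 100)  # phospho values 100, 102
  cells$phospho_fi <- c(0, 2)
  b <- compute_baseline(cells, tiny_wells(count = 2))
  st <- b$stats[b$stats$measure == "phospho_fi", ]
  expect_equal(st$mean, 1)
  expect_equal(st$sd, sqrt(2))  # sample SD of {0, 2}
  expect_equal(st$lower, 1 - 2 * sqrt(2))
  expect_equal(st$upper, 1 + 2 * sqrt(2))

  same <- tiny_cells(rep(7, 5))
  b2 <- compute_baseline(same, tiny_wells(count = 5))
  st2 <- b2$stats[b2$stats$measure == "phospho_fi", ]
  expect_equal(st2$mean, 7)
  expect_equal(st2$sd, 0)
})

test_that("baseline matches a brute-force pooled-moments recomputation", {
  p <- simulate_plate(plate_spec("P"), test_baseline(1000, 50), seed = 17)
  b <- compute_baseline(p$cells, p$wells)
  uc <- p$cells[p$cells$is_control, ]
  for (mcol in measure_columns()) {
    v <- uc[[mcol]]
    n <- length(v)
    mu <- sum(v) / n
    s2 <- sum((v - mu)^2) / (n - 1)
    st <- b$stats[b$stats$measure == mcol, ]
    expect_equal(st$mean, mu)
    expect_equal(st$sd, sqrt(s2))
    expect_equal(st$n, n)
  }
  expect_equal(b$mean_cell_count,
               mean(p$wells$adherent_count[p$wells$is_control]))
})

test_that("compute_baseline rejects degenerate input", {
  cells <- tiny_cells(1:5)
  wells <- tiny_wells(count = 5)
  wells$is_control <- FALSE
  expect_error(compute_baseline(cells, wells), "no untreated")
  expect_error(compute_baseline(tiny_cells(1), tiny_wells(count = 1)),
               "at least 2")
})

test_that("abnormality flags use strict two-SD inequalities with the documented tails", {
  cells <- tiny_cells(c(0, 2))
  cells$phospho_fi <- c(0, 2)
  cells$nuclear_area_um2 <- c(0, 2)
  cells$mito_fi <- c(0, 2)
  b <- compute_baseline(cells, tiny_wells(count = 2))
  up <- 1 + 2 * sqrt(2)
  lo <- 1 - 2 * sqrt(2)

  expect_false(flag_abnormal(up, "elev_phospholipid", b))  # boundary: not abnormal
  expect_true(flag_abnormal(up + 1e-9, "elev_phospholipid", b))
  expect_false(flag_abnormal(lo, "red_mito", b))
  expect_true(flag_abnormal(lo - 1e-9, "red_mito", b))
  # nuclear area flags either tail (2.5 SD below the mean is abnormal)
  expect_true(flag_abnormal(1 - 2.5 * sqrt(2), "abn_nuclear_area", b))
  expect_true(flag_abnormal(1 + 2.5 * sqrt(2), "abn_nuclear_area", b))
  expect_false(flag_abnormal(1, "abn_nuclear_area", b))
  expect_error(flag_abnormal(1, "not_an_attribute", b), "unknown")
})

test_that("flags equal a brute-force rescan of the cell table", {
  p <- simulate_plate(plate_spec("P", treatments = data.frame(
    compound = "d", dose_uM = 5)), test_baseline(500),
    list(effect_template("d", "cad")), seed = 23)
  b <- compute_baseline(p$cells, p$wells)
  reg <- hcia_attributes()
  for (a in cell_attributes()) {
    row <- reg[reg$attribute == a, ]
    st <- b$stats[b$stats$measure == row$measure, ]
    v <- p$cells[[row$measure]]
    manual <- switch(row$tail,
                     upper = v > st$mean + 2 * st$sd,
                     lower = v < st$mean - 2 * st$sd,
                     both = v > st$mean + 2 * st$sd | v < st$mean - 2 * st$sd)
    expect_identical(flag_abnormal(v, a, b), manual)
  }
})

test_that("Gaussian untreated populations show the normal-tail abnormality rates", {
  n <- 1e5
  vals <- with_seed_test(42, rnorm(n, 100, 10))
  cells <- tiny_cells(rep(1, n))
  cells$phospho_fi <- vals
  cells$nuclear_area_um2 <- with_seed_test(43, rnorm(n, 100, 10))
  b <- compute_baseline(cells, tiny_wells(count = n))
  elev <- 100 * mean(flag_abnormal(cells$phospho_fi, "elev_phospholipid", b))
  both <- 100 * mean(flag_abnormal(cells$nuclear_area_um2,
                                   "abn_nuclear_area", b))
  expect_lt(abs(elev - 100 * pnorm(-2)), 0.3)       # 2.28% one-sided
  expect_lt(abs(both - 200 * pnorm(-2)), 0.4)       # 4.55% two-sided
})

test_that("well percentages implement the printed count formulas", {
  cells <- tiny_cells(rep(100, 10))
  b <- compute_baseline(cells, tiny_wells(count = 1000))
  b$mean_cell_count <- 1000
  prof <- well_percentages(tiny_cells(rep(100, 5), control = FALSE), 400, b)
  expect_equal(prof$pct_nonadherent, 60)  # (1000 - 400) / 1000 * 100
  # treated count above the untreated mean: negative, retained unclipped
  prof2 <- well_percentages(tiny_cells(rep(100, 5), control = FALSE), 1200, b)
  expect_equal(prof2$pct_nonadherent, -20)
  # 0 flagged of 5 cells -> 0%
  expect_equal(prof$pct_elev_phospholipid, 0)
})

test_that("polynucleated change follows the printed (decrease-positive) formula", {
  cells <- tiny_cells(rep(1, 10))
  cells$nucleus_count <- c(2L, 2L, rep(1L, 8))  # 2 polynucleated in 1 well
  b <- compute_baseline(cells, tiny_wells(count = 10))
  expect_equal(b$mean_polynucleated, 2)
  treated <- tiny_cells(rep(1, 10), control = FALSE)
  treated$nucleus_count <- c(2L, rep(1L, 9))    # 1 polynucleated
  prof <- well_percentages(treated, 10, b)
  expect_equal(prof$pct_polynucleated_change, 50)  # (2 - 1) / 2 * 100
  # more polynucleated than untreated -> negative (an increase)
  treated$nucleus_count <- c(2L, 2L, 2L, 2L, rep(1L, 6))
  expect_equal(well_percentages(treated, 10, b)$pct_polynucleated_change,
               -100)
})

test_that("a fully detached well reports missing cell-level percentages", {
  cells <- tiny_cells(rep(100, 10))
  b <- compute_baseline(cells, tiny_wells(count = 10))
  prof <- well_percentages(cells[0, ], 0, b)
  expect_true(prof$detached)
  expect_true(is.na(prof$pct_elev_phospholipid))
  expect_true(is.na(prof$pct_abn_nuclear_area))
  expect_equal(prof$pct_nonadherent, 100)
})

test_that("untreated wells stay below the 10% abnormality ceiling (median)", {
  ser <- simulate_replicate_series(plate_spec("U"), baseline_j774(),
                                   n = 4, base_seed = 31)
  profiles <- series_profiles(ser)
  ctrl <- profiles[profiles$is_control, ]
  for (a in cell_attributes()) {
    expect_lt(median(ctrl[[paste0("pct_", a)]]), 10)
  }
})

test_that("rsd_percent reproduces printed untreated-population summaries", {
  expect_identical(rsd_percent(1002, 752), 38L)  # cell number per well
  expect_identical(rsd_percent(338, 106), 16L)   # hAM cell area
  expect_identical(rsd_percent(101, 38), 19L)    # nuclear area
  expect_identical(rsd_percent(500, 0), 0L)
  expect_error(rsd_percent(0, 10), "> 0")
  expect_error(rsd_percent(-5, 10), "> 0")
  expect_error(rsd_percent(10, -1), ">= 0")
})
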