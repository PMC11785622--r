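#' Untreated-population baseline statistics
#'
#' Computes the per-plate baseline used for all +/- 2 SD abnormality
#' thresholds: the mean and sample SD of each measurement over all cells
#' pooled across the plate's untreated control wells (the untreated
#' population is treated as a single pool, not a mean of per-well means),
#' plus the untreated mean adherent-cell count and mean polynucleated-cell
#' count per well.
#'
#' @param cells Cell table (tibble with [measure_columns()], `nucleus_count`,
#'   `well_id`, `is_control`). Rows with `is_control == FALSE` are ignored,
#'   so a whole-plate table can be passed directly.
#' @param wells Well table with `well_id`, `is_control`, `adherent_count`.
#' @return Object of class `baseline_stats`: list with `stats` (tibble:
#'   `measure`, `mean`, `sd`, `n`, `lower`, `upper` where the thresholds are
#'   mean -/+ 2 SD), `mean_cell_count`, `mean_polynucleated`, `n_wells`,
#'   `plate_id`.
#' @export
compute_baseline <- function(cells, wells) {
  uw <- wells[wells$is_control, , drop = FALSE]
  if (nrow(uw) == 0) stop("no untreated control wells", call. = FALSE)
  uc <- cells[cells$is_control & cells$well_id %in% uw$well_id, , drop = FALSE]
  if (nrow(uc) < 2) stop("need at least 2 untreated cells", call. = FALSE)

  stats <- lapply(measure_columns(), function(mcol) {
    v <- uc[[mcol]]
    m <- mean(v)
    s <- sd(v)  # sample SD (n - 1)
    tibble::tibble(measure = mcol, mean = m, sd = s, n = length(v),
                   lower = m - 2 * s, upper = m + 2 * s)
  })
  poly_per_well <- tapply(uc$nucleus_count >= 2, uc$well_id, sum)
  # wells with zero adherent cells contribute zero polynucleated cells
  poly_mean <- sum(poly_per_well) / nrow(uw)

  structure(
    list(stats = dplyr::bind_rows(stats),
         mean_cell_count = mean(uw$adherent_count),
         mean_polynucleated = poly_mean,
         n_wells = nrow(uw),
         plate_id = if (!is.null(uw$plate_id)) uw$plate_id[1] else NA_character_),
    class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("<baseline_stats> plate %s (%d untreated wells, %d cells)\n",
              x$plate_id, x$n_wells, x$stats$n[1]))
  print(as.data.frame(x$stats), digits = 4)
  cat(sprintf("mean cell count/well %.1f; mean polynucleated/well %.2f\n",
              x$mean_cell_count, x$mean_polynucleated))
  invisible(x)
}

#' Serialise baseline statistics to JSON
#'
#' @param baseline A `baseline_stats` object.
#' @param path Output file path.
#' @export
write_baseline_json <- function(baseline, path) {
  jsonlite::write_json(
    list(plate_id = baseline$plate_id,
         n_wells = baseline$n_wells,
         mean_cell_count = baseline$mean_cell_count,
         mean_polynucleated = baseline$mean_polynucleated,
         stats = baseline$stats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Flag abnormal single-cell measurements
#'
#' A cell is abnormal for an attribute when its measurement lies strictly
#' beyond the untreated-population mean by more than 2 SD: above for
#' "elevated" attributes, below for reduced mitochondrial activity, and on
#' either side for nuclear area. A value exactly at mean +/- 2 SD is not
#' abnormal (strict inequality).
#'
#' @param value Numeric vector of measurements.
#' @param attribute One of the single-cell attributes in [cell_attributes()]
#'   (e.g. `"elev_phospholipid"`, `"red_mito"`, `"abn_nuclear_area"`).
#' @param baseline A `baseline_stats` object from [compute_baseline()].
#' @return Logical vector, `TRUE` where abnormal.
#' @export
flag_abnormal <- function(value, attribute, baseline) {
  reg <- .attr_registry[.attr_registry$attribute == attribute, ]
  if (nrow(reg) != 1 || reg$level != "cell") {
    stop("unknown single-cell attribute: ", attribute, call. = FALSE)
  }
  st <- baseline$stats[baseline$stats$measure == reg$measure, ]
  if (nrow(st) != 1) stop("no baseline entry for measure ", reg$measure,
                          call. = FALSE)
  switch(reg$tail,
         upper = value > st$upper,
         lower = value < st$lower,
         both  = value > st$upper | value < st$lower)
}

#' Per-well response profile (ten percentages)
#'
#' Computes one well's response profile: the eight single-cell percentages
#' (100 x flagged cells / cells in the well, pooling the well's images), the
#' non-adherent percentage
#' `100 * (untreated mean count - treated count) / untreated mean count`,
#' and the polynucleated-cell change
#' `100 * (untreated mean polynucleated - polynucleated in well) / untreated
#' mean polynucleated` (positive = fewer polynucleated cells than untreated;
#' the printed formula measures a decrease and is implemented verbatim).
#' A well with zero adherent cells gets `NA` for all cell-level percentages
#' and is marked detached; a negative non-adherent percentage (treated count
#' above the untreated mean) is retained, not clipped.
#'
#' @param cells Cell-table rows belonging to one well (may have zero rows).
#' @param adherent_count Adherent cell count for the well.
#' @param baseline A `baseline_stats` from the same plate.
#' @param meta Optional named list with `plate_id`, `well_id`, `compound`,
#'   `dose_uM`, `is_control`, `replicate` carried into the output.
#' @return One-row tibble with columns `pct_<attribute>` for all ten
#'   response attributes plus metadata and `adherent_count`.
#' @export
well_percentages <- function(cells, adherent_count, baseline, meta = list()) {
  n <- nrow(cells)
  pct <- setNames(rep(NA_real_, length(response_attributes())),
                  paste0("pct_", response_attributes()))

  pct[["pct_nonadherent"]] <-
    100 * (baseline$mean_cell_count - adherent_count) /
      baseline$mean_cell_count

  if (baseline$mean_polynucleated > 0) {
    poly <- if (n > 0) sum(cells$nucleus_count >= 2) else 0
    pct[["pct_polynucleated_change"]] <-
      100 * (baseline$mean_polynucleated - poly) / baseline$mean_polynucleated
  }

  if (n > 0) {
    for (a in cell_attributes()) {
      reg <- .attr_registry[.attr_registry$attribute == a, ]
      flags <- flag_abnormal(cells[[reg$measure]], a, baseline)
      pct[[paste0("pct_", a)]] <- 100 * sum(flags) / n
    }
  }

  tibble::tibble(
    plate_id = meta$plate_id %||% NA_character_,
    well_id = meta$well_id %||% NA_character_,
    compound = meta$compound %||% NA_character_,
    dose_uM = meta$dose_uM %||% NA_real_,
    is_control = meta$is_control %||% NA,
    replicate = meta$replicate %||% NA_integer_,
    adherent_count = adherent_count,
    detached = n == 0,
    !!!as.list(pct))
}

#' Response profiles for every well of a plate
#'
#' Applies [well_percentages()] to each well of a simulated (or read-in)
#' plate, using a baseline computed from the plate's own untreated wells
#' unless one is supplied.
#'
#' @param plate An `hcia_plate`, or a list with `cells` and `wells` tibbles.
#' @param baseline Optional `baseline_stats`; computed from the plate's
#'   untreated wells when `NULL`.
#' @param replicate Optional replicate index stored in the output.
#' @return Tibble of well profiles, one row per well.
#' @export
well_profiles <- function(plate, baseline = NULL, replicate = NA_integer_) {
  cells <- plate$cells
  wells <- plate$wells
  if (is.null(baseline)) baseline <- compute_baseline(cells, wells)
  rows <- lapply(seq_len(nrow(wells)), function(i) {
    w <- wells[i, ]
    wc <- cells[cells$well_id == w$well_id, , drop = FALSE]
    well_percentages(wc, w$adherent_count, baseline,
                     meta = list(plate_id = w$plate_id, well_id = w$well_id,
                                 compound = w$compound, dose_uM = w$dose_uM,
                                 is_control = w$is_control,
                                 replicate = replicate))
  })
  dplyr::bind_rows(rows)
}

#' Response profiles for a replicate series
#'
#' @param series An `hcia_series` (list of plates) from
#'   [simulate_replicate_series()].
#' @return Tibble of well profiles with a `replicate` column.
#' @export
series_profiles <- function(series) {
  dplyr::bind_rows(lapply(seq_along(series), function(r) {
    well_profiles(series[[r]], replicate = r)
  }))
}

#' Relative standard deviation from a printed mean and 2 SD
#'
#' Recovers the RSD% column of an untreated-population summary table from its
#' printed mean and 2 SD columns: `100 * (two_sd / 2) / mean`, rounded to the
#' nearest integer.
#'
#' @param mean Printed mean (> 0).
#' @param two_sd Printed 2 SD (>= 0).
#' @return Integer percentage.
#' @export
rsd_percent <- function(mean, two_sd) {
  if (any(mean <= 0)) stop("mean must be > 0", call. = FALSE)
  if (any(two_sd < 0)) stop("two_sd must be >= 0", call. = FALSE)
  as.integer(round(100 * (two_sd / 2) / mean))
}
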