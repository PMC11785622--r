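#' Baseline (untreated-population) generating parameters
#'
#' Describes the untreated single-cell attribute distributions used by the
#' plate simulator: a location (mean) and scale (SD) per measurement, a
#' distribution family tag per measurement (`"lognormal"` for right-skewed
#' fluorescence intensities and vacuole area, `"normal"` truncated at zero for
#' the morphometric areas), the adherent-cell count model per well
#' (negative binomial via mean and SD), and the per-cell polynucleation
#' probability.
#'
#' Presets for the two screened cell types are provided by
#' [baseline_j774()] (murine J774A.1 macrophage-like line) and
#' [baseline_ham()] (primary human alveolar macrophages). Their means and SDs
#' reproduce the untreated-population summary scale of the two cell types
#' (e.g. J774A.1 cell area 249 +/- 58 um^2, ~1002 adherent cells/well;
#' hAM cell area 338 +/- 53 um^2, ~260 cells/well).
#'
#' @param measures Named list over [measure_columns()]; each element a list
#'   with numeric `mean`, `sd` and a `family` tag (`"lognormal"` or
#'   `"normal"`).
#' @param cells_per_well_mean,cells_per_well_sd Mean and SD of the adherent
#'   cell count per untreated well (negative binomial; Poisson if the SD
#'   implies underdispersion).
#' @param polynucleation_rate Probability that a cell carries two nuclei.
#'
#' @return An object of class `baseline_params`.
#' @export
baseline_params <- function(measures, cells_per_well_mean, cells_per_well_sd,
                            polynucleation_rate = 0.025) {
  cols <- measure_columns()
  if (!all(cols %in% names(measures))) {
    stop("measures must contain entries for: ",
         paste(setdiff(cols, names(measures)), collapse = ", "), call. = FALSE)
  }
  for (m in cols) {
    e <- measures[[m]]
    if (!is.numeric(e$mean) || !is.numeric(e$sd) || e$sd < 0) {
      stop("invalid mean/sd for measure ", m, call. = FALSE)
    }
    if (e$mean <= 0) stop("location for ", m, " must be > 0", call. = FALSE)
    if (!e$family %in% c("lognormal", "normal")) {
      stop("unknown distribution family for ", m, ": ", e$family,
           call. = FALSE)
    }
  }
  if (cells_per_well_mean <= 0) stop("cells_per_well mean must be > 0",
                                     call. = FALSE)
  if (cells_per_well_sd < 0) stop("cells_per_well sd must be >= 0",
                                  call. = FALSE)
  stopifnot_scalar_prob(polynucleation_rate, "polynucleation_rate")
  structure(
    list(measures = measures[cols],
         cells_per_well = list(mean = cells_per_well_mean,
                               sd = cells_per_well_sd),
         polynucleation_rate = polynucleation_rate),
    class = "baseline_params")
}

#' @export
print.baseline_params <- function(x, ...) {
  cat("<baseline_params>\n")
  for (m in names(x$measures)) {
    e <- x$measures[[m]]
    cat(sprintf("  %-18s mean %10.4g  sd %9.4g  (%s)\n",
                m, e$mean, e$sd, e$family))
  }
  cat(sprintf("  cells/well %.0f +/- %.0f, polynucleation rate %.3f\n",
              x$cells_per_well$mean, x$cells_per_well$sd,
              x$polynucleation_rate))
  invisible(x)
}

.measure_entry <- function(mean, sd, family) {
  list(mean = mean, sd = sd, family = family)
}

#' @rdname baseline_params
#' @export
baseline_j774 <- function() {
  baseline_params(
    measures = list(
      mito_fi          = .measure_entry(7126, 2436, "lognormal"),
      dead_fi          = .measure_entry(5760, 2126, "lognormal"),
      neutral_fi       = .measure_entry(6453, 3443, "lognormal"),
      phospho_fi       = .measure_entry(2789, 2574, "lognormal"),
      nuclear_area_um2 = .measure_entry(101,  19,   "normal"),
      cell_area_um2    = .measure_entry(249,  58,   "normal"),
      vacuole_area_um2 = .measure_entry(4,    9,    "lognormal")),
    cells_per_well_mean = 1002,
    cells_per_well_sd   = 376,
    polynucleation_rate = 25 / 1002)
}

#' @rdname baseline_params
#' @export
baseline_ham <- function() {
  baseline_params(
    measures = list(
      mito_fi          = .measure_entry(14436, 6960, "lognormal"),
      dead_fi          = .measure_entry(6599,  3212, "lognormal"),
      neutral_fi       = .measure_entry(11492, 2750, "lognormal"),
      phospho_fi       = .measure_entry(4343,  3469, "lognormal"),
      nuclear_area_um2 = .measure_entry(94,    8,    "normal"),
      cell_area_um2    = .measure_entry(338,   53,   "normal"),
      vacuole_area_um2 = .measure_entry(16,    34,   "lognormal")),
    cells_per_well_mean = 260,
    cells_per_well_sd   = 112,
    polynucleation_rate = 9 / 260)
}

# draw n values from one baseline measure distribution
draw_measure <- function(entry, n) {
  if (n == 0) return(numeric(0))
  m <- entry$mean
  s <- entry$sd
  if (entry$family == "lognormal") {
    if (s == 0) return(rep(m, n))
    sdlog <- sqrt(log1p((s / m)^2))
    meanlog <- log(m) - sdlog^2 / 2
    rlnorm(n, meanlog, sdlog)
  } else {
    # symmetric, truncated at zero by rejection (negligible mass for presets)
    x <- rnorm(n, m, s)
    bad <- which(x < 0)
    while (length(bad) > 0) {
      x[bad] <- rnorm(length(bad), m, s)
      bad <- bad[x[bad] < 0]
    }
    x
  }
}

# theoretical tail probability of one baseline measure beyond mean +/- 2 SD,
# used by tests as the expected untreated "abnormal" rate
measure_tail_prob <- function(entry, tail = c("upper", "lower", "both")) {
  tail <- match.arg(tail)
  m <- entry$mean
  s <- entry$sd
  if (s == 0) return(0)
  if (entry$family == "lognormal") {
    sdlog <- sqrt(log1p((s / m)^2))
    meanlog <- log(m) - sdlog^2 / 2
    up <- stats::plnorm(m + 2 * s, meanlog, sdlog, lower.tail = FALSE)
    lo <- stats::plnorm(max(m - 2 * s, 0), meanlog, sdlog)
  } else {
    up <- stats::pnorm(m + 2 * s, m, s, lower.tail = FALSE)
    lo <- stats::pnorm(m - 2 * s, m, s)
  }
  switch(tail, upper = up, lower = lo, both = up + lo)
}
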