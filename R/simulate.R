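#' Plate layout specification
#'
#' Defines the layout of one simulated screening plate: the number of
#' untreated control wells (six per plate in the emulated design), the treated
#' layout as a compound x dose table, and metadata (images per well, dose
#' ladder). One treated well is generated per row of `treatments`.
#'
#' @param plate_id Plate identifier string.
#' @param n_control Number of untreated control wells (default 6).
#' @param treatments Data frame with columns `compound` and `dose_uM`
#'   (one treated well per row), or `NULL` for a control-only plate.
#' @param images_per_well Images acquired per well (metadata only; per-well
#'   statistics pool all images, default 6).
#' @param dose_ladder Default dose ladder in uM.
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(plate_id = "plate1", n_control = 6, treatments = NULL,
                       images_per_well = 6,
                       dose_ladder = c(0.01, 0.025, 0.05, 0.1, 1, 5, 10)) {
  if (n_control < 1) stop("at least one untreated control well is required",
                          call. = FALSE)
  if (!is.null(treatments)) {
    treatments <- as.data.frame(treatments)
    if (!all(c("compound", "dose_uM") %in% names(treatments))) {
      stop("treatments must have columns compound and dose_uM", call. = FALSE)
    }
    if (any(treatments$dose_uM <= 0)) {
      stop("treatment doses must be > 0", call. = FALSE)
    }
  }
  if (any(dose_ladder <= 0)) stop("doses must be > 0", call. = FALSE)
  structure(list(plate_id = plate_id, n_control = n_control,
                 treatments = treatments, images_per_well = images_per_well,
                 dose_ladder = dose_ladder),
            class = "plate_spec")
}

# resolve a list of compound_effect objects into a named list
.effect_index <- function(effects) {
  if (inherits(effects, "compound_effect")) effects <- list(effects)
  stopifnot(all(vapply(effects, inherits, logical(1), "compound_effect")))
  setNames(effects, vapply(effects, `[[`, character(1), "name"))
}

# draw one well's cells; planted abnormal cells are uniform over the band
# (mean + 2 SD, mean + 4 SD] (mirrored for reduced, random side for
# two-sided), so they are unambiguously abnormal but not degenerate
.draw_well_cells <- function(n, baseline, planted) {
  out <- list()
  reg <- .attr_registry[.attr_registry$level == "cell", ]
  for (mcol in measure_columns()) {
    entry <- baseline$measures[[mcol]]
    vals <- draw_measure(entry, n)
    rows <- reg[!is.na(reg$measure) & reg$measure == mcol, ]
    if (nrow(rows) > 0 && n > 0) {
      f <- setNames(planted[rows$attribute], rows$attribute)
      f[is.na(f)] <- 0
      if (sum(f) > 0) {
        # disjoint assignment when two attributes share a measure (mito)
        u <- runif(n)
        lo <- 0
        m <- entry$mean
        s <- entry$sd
        for (k in seq_len(nrow(rows))) {
          a <- rows$attribute[k]
          sel <- which(u >= lo & u < lo + f[[a]])
          lo <- lo + f[[a]]
          if (!length(sel)) next
          tail <- rows$tail[k]
          side <- switch(tail,
                         upper = rep("upper", length(sel)),
                         lower = rep("lower", length(sel)),
                         both  = sample(c("upper", "lower"), length(sel),
                                        replace = TRUE))
          up <- side == "upper"
          if (any(up)) vals[sel[up]] <- runif(sum(up), m + 2 * s, m + 4 * s)
          if (any(!up)) vals[sel[!up]] <- runif(sum(!up), max(m - 4 * s, 0),
                                                max(m - 2 * s, 0))
        }
      }
    }
    out[[mcol]] <- vals
  }
  # polynucleation: planted "polynucleated_change" fraction f lowers the
  # polynucleation rate to (1 - f) * baseline rate, so the well shows the
  # corresponding relative decrease in polynucleated cells
  f_poly <- planted[["polynucleated_change"]] %||% 0
  if (is.na(f_poly)) f_poly <- 0
  rate <- baseline$polynucleation_rate * (1 - f_poly)
  out$nucleus_count <- 1L + rbinom(n, 1L, rate)
  out
}

.draw_well_count <- function(cpw) {
  m <- cpw$mean
  v <- cpw$sd^2
  if (v > m) {
    size <- m^2 / (v - m)
    rnbinom(1, size = size, mu = m)
  } else {
    rpois(1, m)
  }
}

#' Simulate one screening plate with known ground truth
#'
#' Generates a per-cell feature table and per-well adherent-cell counts for a
#' plate of untreated control wells plus treated wells. Untreated cells are
#' drawn from the baseline distributions; each treated well is a two-component
#' mixture: a planted, dose-scaled fraction of cells shifted beyond the
#' baseline mean +/- 2 SD on the affected attribute's abnormal side, the rest
#' drawn from baseline. The pre-treatment cell count is thinned binomially by
#' the dose-scaled detachment probability before any cells are drawn
#' (detached cells contribute no rows). The same `(spec, seed)` pair yields
#' bit-identical output; per-well RNG substreams are derived by stable hashing
#' of (plate, well, seed).
#'
#' @param spec A [plate_spec()].
#' @param baseline A [baseline_params()].
#' @param effects List of [compound_effect()] covering every treated compound.
#' @param seed Integer master seed (recorded in the output).
#' @return An object of class `hcia_plate`: list with `cells` (tibble, one row
#'   per adherent cell), `wells` (tibble with `pre_count`, `adherent_count`,
#'   `detached_count`), `ground_truth` (tibble of planted per-well x attribute
#'   fractions plus planted detachment), and `seed`.
#' @export
simulate_plate <- function(spec, baseline, effects = list(), seed = 1) {
  stopifnot(inherits(spec, "plate_spec"), inherits(baseline, "baseline_params"))
  effects <- .effect_index(effects)
  tr <- spec$treatments
  if (!is.null(tr) && nrow(tr) > 0) {
    unknown <- setdiff(unique(tr$compound), names(effects))
    if (length(unknown)) {
      stop("treated compounds missing from effects: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  wells <- data.frame(
    well_id = sprintf("C%02d", seq_len(spec$n_control)),
    compound = "untreated", dose_uM = 0, is_control = TRUE,
    stringsAsFactors = FALSE)
  if (!is.null(tr) && nrow(tr) > 0) {
    wells <- rbind(wells, data.frame(
      well_id = sprintf("T%02d", seq_len(nrow(tr))),
      compound = tr$compound, dose_uM = tr$dose_uM, is_control = FALSE,
      stringsAsFactors = FALSE))
  }

  scored <- scored_attributes()
  cell_chunks <- vector("list", nrow(wells))
  gt_chunks <- vector("list", nrow(wells))
  pre <- adh <- integer(nrow(wells))
  detach <- numeric(nrow(wells))

  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    planted <- setNames(rep(0, length(scored)), scored)
    d <- 0
    if (!w$is_control) {
      ef <- effects[[w$compound]]
      if (length(ef$effects)) {
        planted[names(ef$effects)] <-
          dose_fraction(ef$effects, w$dose_uM, ef$ref_dose, ef$hill)
      }
      d <- dose_fraction(ef$detachment, w$dose_uM, ef$ref_dose, ef$hill)
    }
    wseed <- stable_hash(spec$plate_id, w$well_id, seed)
    chunk <- with_seed(wseed, {
      n_pre <- .draw_well_count(baseline$cells_per_well)
      n_adh <- if (d > 0) rbinom(1, n_pre, 1 - d) else n_pre
      vals <- .draw_well_cells(n_adh, baseline, planted)
      list(n_pre = n_pre, n_adh = n_adh, vals = vals)
    })
    pre[i] <- chunk$n_pre
    adh[i] <- chunk$n_adh
    detach[i] <- d
    if (chunk$n_adh > 0) {
      cell_chunks[[i]] <- tibble::tibble(
        plate_id = spec$plate_id, well_id = w$well_id,
        compound = w$compound, dose_uM = w$dose_uM,
        is_control = w$is_control,
        cell_id = sprintf("%s_%04d", w$well_id, seq_len(chunk$n_adh)),
        !!!chunk$vals)
    }
    gt_chunks[[i]] <- tibble::tibble(
      plate_id = spec$plate_id, well_id = w$well_id,
      attribute = scored, planted_fraction = unname(planted))
  }

  wells_out <- tibble::tibble(
    plate_id = spec$plate_id, well_id = wells$well_id,
    compound = wells$compound, dose_uM = wells$dose_uM,
    is_control = wells$is_control,
    pre_count = pre, adherent_count = adh,
    detached_count = pre - adh,
    planted_detachment = detach,
    images_per_well = spec$images_per_well,
    seed = as.integer(seed))

  structure(
    list(cells = dplyr::bind_rows(cell_chunks),
         wells = wells_out,
         ground_truth = dplyr::bind_rows(gt_chunks),
         spec = spec, baseline = baseline, seed = seed),
    class = "hcia_plate")
}

#' @export
print.hcia_plate <- function(x, ...) {
  cat(sprintf("<hcia_plate> %s: %d wells (%d control), %d cells, seed %d\n",
              x$spec$plate_id, nrow(x$wells), sum(x$wells$is_control),
              nrow(x$cells), x$seed))
  invisible(x)
}

#' Simulate a replicate series of plates
#'
#' Generates `n` independent plates emulating replicate experiments
#' (cell passages or donors). Replicate `r` uses master seed
#' `base_seed + r - 1` and plate id `<plate_id>_R<r>`. Between-replicate
#' variability is injected by jittering each baseline location parameter by a
#' multiplicative factor `1 + jitter * z`, `z ~ N(0, 1)`; replicate 1 is the
#' unjittered anchor so a single-replicate series reproduces
#' [simulate_plate()] exactly.
#'
#' @inheritParams simulate_plate
#' @param n Number of replicate plates (>= 1).
#' @param base_seed Integer master seed for replicate 1.
#' @param jitter Relative SD of the between-replicate location jitter
#'   (default 0.05).
#' @return A list of `hcia_plate` objects (class `hcia_series`).
#' @export
simulate_replicate_series <- function(spec, baseline, effects = list(),
                                      n = 6, base_seed = 1, jitter = 0.05) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  plates <- vector("list", n)
  for (r in seq_len(n)) {
    spec_r <- spec
    spec_r$plate_id <- sprintf("%s_R%d", spec$plate_id, r)
    base_r <- baseline
    if (r > 1 && jitter > 0) {
      fac <- with_seed(stable_hash("replicate-jitter", spec_r$plate_id,
                                   base_seed),
                       1 + jitter * rnorm(length(measure_columns()) + 1))
      fac <- pmax(fac, 0.05)
      for (k in seq_along(measure_columns())) {
        mcol <- measure_columns()[k]
        base_r$measures[[mcol]]$mean <- base_r$measures[[mcol]]$mean * fac[k]
      }
      base_r$cells_per_well$mean <-
        base_r$cells_per_well$mean * fac[length(fac)]
    }
    plates[[r]] <- simulate_plate(spec_r, base_r, effects,
                                  seed = base_seed + r - 1)
  }
  structure(plates, class = "hcia_series")
}
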