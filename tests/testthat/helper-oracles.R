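# Independent oracles and small fixture builders shared across the suite.

# Tukey hinges by direct enumeration of the definition: hinges are medians of
# the lower/upper half, each half including the sample median when n is odd.
hinge_oracle <- function(values) {
  x <- sort(values)
  n <- length(x)
  mid <- function(v) {
    m <- length(v)
    if (m %% 2 == 1) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
  }
  half <- ceiling(n / 2)
  list(min = x[1],
       q1 = mid(x[1:half]),
       q2 = mid(x),
       q3 = mid(x[(n - half + 1):n]),
       max = x[n])
}

# Greedy minimum-variance (Ward) merge search: at every step merge the pair
# of clusters whose union minimally increases the within-cluster sum of
# squares; heights reported on the Euclidean-compatible sqrt(2 * deltaESS)
# scale.
ward_oracle_heights <- function(m) {
  ess <- function(rows) {
    if (nrow(rows) < 2) return(0)
    sum(sweep(rows, 2, colMeans(rows))^2)
  }
  cl <- lapply(seq_len(nrow(m)), function(i) m[i, , drop = FALSE])
  heights <- numeric(0)
  while (length(cl) > 1) {
    best <- c(NA, NA)
    bd <- Inf
    for (i in seq_len(length(cl) - 1)) {
      for (j in (i + 1):length(cl)) {
        d <- ess(rbind(cl[[i]], cl[[j]])) - ess(cl[[i]]) - ess(cl[[j]])
        if (d < bd) { bd <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, sqrt(2 * bd))
    cl[[best[1]]] <- rbind(cl[[best[1]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
  }
  heights
}

# theoretical probability that a baseline draw falls beyond mean +/- 2 SD,
# recomputed here from first principles (independent of package internals)
tail_prob_oracle <- function(mean, sd, family, tail) {
  if (family == "lognormal") {
    sdlog <- sqrt(log(1 + (sd / mean)^2))
    meanlog <- log(mean) - sdlog^2 / 2
    up <- plnorm(mean + 2 * sd, meanlog, sdlog, lower.tail = FALSE)
    lo <- plnorm(max(mean - 2 * sd, 0), meanlog, sdlog)
  } else {
    up <- pnorm(2, lower.tail = FALSE)
    lo <- pnorm(-2)
  }
  switch(tail, upper = up, lower = lo, both = up + lo)
}

# compact baseline for simulation tests: realistic J774A.1-scale locations
# with a tightly controlled cell count so binomial error budgets are exact
test_baseline <- function(cells_per_well = 1000, count_sd = 0,
                          polynucleation_rate = 0.025) {
  b <- baseline_j774()
  b$cells_per_well$mean <- cells_per_well
  b$cells_per_well$sd <- count_sd
  b$polynucleation_rate <- polynucleation_rate
  b
}

# minimal hand-built cell table (one well) for arithmetic checks
tiny_cells <- function(values, measure = "phospho_fi", well = "C01",
                       control = TRUE) {
  n <- length(values)
  base <- tibble::tibble(
    plate_id = "P", well_id = well, compound = if (control) "untreated" else "drug",
    dose_uM = if (control) 0 else 5, is_control = control,
    cell_id = sprintf("%s_%d", well, seq_len(n)),
    mito_fi = 100, dead_fi = 100, neutral_fi = 100, phospho_fi = 100,
    nuclear_area_um2 = 100, cell_area_um2 = 250, vacuole_area_um2 = 5,
    nucleus_count = 1L)
  base[[measure]] <- values
  base
}

tiny_wells <- function(well = "C01", control = TRUE, count = NULL, n = 1) {
  tibble::tibble(plate_id = "P",
                 well_id = if (n == 1) well else sprintf("%s%02d", well, 1:n),
                 compound = if (control) "untreated" else "drug",
                 dose_uM = if (control) 0 else 5, is_control = control,
                 adherent_count = count %||% 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_test <- function(seed, expr) withr::with_seed(seed, expr)
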