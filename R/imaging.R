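# Optional imaging front-end: renders synthetic multi-channel wells from a
# cell table, segments them, and re-extracts features, validating that the
# measurement path preserves the statistics the pipeline consumes. Requires
# the EBImage package (Suggests).

.check_ebimage <- function() {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("the imaging module requires the EBImage package", call. = FALSE)
  }
}

.stack_channels <- function() {
  c("nuclear", "cytoplasm", "mito", "dead", "neutral", "phospho")
}

#' Imaging specification
#'
#' Raster geometry and noise model for synthetic well rendering. Defaults
#' emulate a 20x objective: 0.5 um/pixel on a 1024 x 1024 raster. Intensities
#' are linear (marker value times a per-channel scale, uniform over the cell
#' disc), with additive Gaussian background noise and no point-spread
#' blurring or bleed-through.
#'
#' @param width,height Raster size in pixels.
#' @param pixel_size_um Pixel edge length in um (default 0.5).
#' @param background Constant background level (default 0.002).
#' @param noise_sd Additive Gaussian noise SD (default 0.002).
#' @param intensity_scale Scale from stored fluorescence values (a.u.) to
#'   pixel values; default 1/30000 keeps preset intensities within [0, 1].
#' @return A list of class `image_spec`.
#' @export
image_spec <- function(width = 1024, height = 1024, pixel_size_um = 0.5,
                       background = 0.002, noise_sd = 0.002,
                       intensity_scale = 1 / 30000) {
  if (pixel_size_um <= 0) stop("pixel size must be > 0", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size_um = pixel_size_um, background = background,
                 noise_sd = noise_sd, intensity_scale = intensity_scale),
            class = "image_spec")
}

# non-overlapping disc placement by rejection sampling
.place_cells <- function(radii, width, height, margin = 2) {
  n <- length(radii)
  xs <- ys <- numeric(n)
  for (i in seq_len(n)) {
    r <- radii[i]
    ok <- FALSE
    for (try in seq_len(4000)) {
      x <- runif(1, r + 1, width - r - 1)
      y <- runif(1, r + 1, height - r - 1)
      if (i == 1) { ok <- TRUE } else {
        j <- seq_len(i - 1)
        ok <- all((xs[j] - x)^2 + (ys[j] - y)^2 >
                    (radii[j] + r + margin)^2)
      }
      if (ok) { xs[i] <- x; ys[i] <- y; break }
    }
    if (!ok) stop("cell density too high: could not place all cells ",
                  "without overlap", call. = FALSE)
  }
  cbind(x = xs, y = ys)
}

.disc_idx <- function(cx, cy, r, width, height) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(width, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(height, ceiling(cy + r))
  gx <- x0:x1; gy <- y0:y1
  dd <- outer((gx - cx)^2, (gy - cy)^2, "+")
  sel <- which(dd <= r^2, arr.ind = TRUE)
  cbind(gx[sel[, 1]], gy[sel[, 2]])
}

# anti-aliased disc: pixel weights approximate edge coverage so integrated
# intensity recovers the analytic disc area to subpixel accuracy
.disc_cover <- function(cx, cy, r, width, height) {
  x0 <- max(1L, floor(cx - r - 1)); x1 <- min(width, ceiling(cx + r + 1))
  y0 <- max(1L, floor(cy - r - 1)); y1 <- min(height, ceiling(cy + r + 1))
  gx <- x0:x1; gy <- y0:y1
  dd <- sqrt(outer((gx - cx)^2, (gy - cy)^2, "+"))
  w <- pmin(pmax(r + 0.5 - dd, 0), 1)
  sel <- which(w > 0, arr.ind = TRUE)
  list(idx = cbind(gx[sel[, 1]], gy[sel[, 2]]), w = w[sel])
}

#' Render a synthetic multi-channel well image
#'
#' Renders each cell as a nucleus disc (two adjacent discs for polynucleated
#' cells) inside a cytoplasm disc whose radius matches the stored cell area.
#' Marker channels are uniform over the cell disc at the cell's stored
#' fluorescence value times the channel scale. The vacuole is rendered as a
#' zero-intensity disc in the cytoplasm channel (unstained cytoplasm).
#' Deterministic for a fixed seed.
#'
#' @param cells Cell-table rows to render (non-overlapping placement must be
#'   feasible at the requested density).
#' @param spec An [image_spec()].
#' @param seed Integer seed for placement and noise.
#' @return A `channel_stack`: named list of numeric matrices (channels
#'   `nuclear`, `cytoplasm`, `mito`, `dead`, `neutral`, `phospho`), with
#'   attributes `pixel_size_um` and `placement` (tibble of cell centres).
#' @export
render_well <- function(cells, spec = image_spec(), seed = 1) {
  w <- spec$width; h <- spec$height
  px <- spec$pixel_size_um
  chans <- setNames(lapply(.stack_channels(),
                           function(ch) matrix(spec$background, w, h)),
                    .stack_channels())
  placement <- tibble::tibble(cell_id = character(0),
                              x = numeric(0), y = numeric(0))
  n <- nrow(cells)
  if (n > 0) {
    r_cell <- sqrt(cells$cell_area_um2 / pi) / px
    # placement keeps nucleus groups of neighbouring cells far enough apart
    # that seed merging (segment_cells) cannot bridge two cells
    k_nuc <- pmax(1L, cells$nucleus_count)
    r_nuc_one <- sqrt(cells$nuclear_area_um2 / k_nuc / pi) / px
    r_nuc_ext <- ((k_nuc - 1) * (2 * r_nuc_one + 1.5)) / 2 + r_nuc_one
    r_place <- pmax(r_cell, r_nuc_ext)
    with_seed(seed, {
      pos <- .place_cells(r_place, w, h, margin = 8)
      marker_cols <- c(mito = "mito_fi", dead = "dead_fi",
                       neutral = "neutral_fi", phospho = "phospho_fi")
      for (i in seq_len(n)) {
        cell_px <- .disc_idx(pos[i, 1], pos[i, 2], r_cell[i], w, h)
        chans$cytoplasm[cell_px] <- 0.6
        for (ch in names(marker_cols)) {
          chans[[ch]][cell_px] <-
            cells[[marker_cols[[ch]]]][i] * spec$intensity_scale
        }
        # nuclei: one disc per nucleus, adjacent near the centre
        k <- max(1L, cells$nucleus_count[i])
        r_nuc <- sqrt(cells$nuclear_area_um2[i] / k / pi) / px
        offs <- if (k == 1) cbind(0, 0) else
          cbind((seq_len(k) - (k + 1) / 2) * (2 * r_nuc + 1.5), 0)
        for (j in seq_len(k)) {
          nuc <- .disc_cover(pos[i, 1] + offs[j, 1],
                             pos[i, 2] + offs[j, 2], r_nuc, w, h)
          chans$nuclear[nuc$idx] <- pmax(chans$nuclear[nuc$idx],
                                         spec$background + 0.8 * nuc$w)
        }
        # vacuole: unstained hole in the cytoplasm channel
        if (cells$vacuole_area_um2[i] > 0) {
          r_vac <- sqrt(cells$vacuole_area_um2[i] / pi) / px
          vx <- pos[i, 1] + 0.55 * r_cell[i]
          vac_px <- .disc_idx(vx, pos[i, 2], r_vac, w, h)
          inside <- (vac_px[, 1] - pos[i, 1])^2 +
            (vac_px[, 2] - pos[i, 2])^2 <= r_cell[i]^2
          chans$cytoplasm[vac_px[inside, , drop = FALSE]] <- 0
        }
      }
      if (spec$noise_sd > 0) {
        for (ch in names(chans)) {
          chans[[ch]] <- pmax(chans[[ch]] +
                                matrix(rnorm(w * h, 0, spec$noise_sd), w, h),
                              0)
        }
      }
      placement <- tibble::tibble(cell_id = cells$cell_id,
                                  x = pos[, 1], y = pos[, 2])
    })
  }
  structure(chans, class = "channel_stack", pixel_size_um = px,
            placement = placement)
}

#' Segment single cells in a channel stack
#'
#' Nuclei-seeded segmentation of the cytoplasm mask: Otsu threshold on the
#' cytoplasm channel (holes filled, so vacuoles stay inside their cell),
#' nucleus seeds from an Otsu threshold on the nuclear channel, seed blobs
#' closer than `nucleus_merge_um` merged (so the nuclei of one polynucleated
#' cell form a single seed), then Voronoi-style propagation of seed labels
#' through the cytoplasm mask splits touching cells.
#'
#' @param stack A `channel_stack` with `nuclear` and `cytoplasm` channels.
#' @param nucleus_merge_um Merge radius for nucleus seeds in um (default
#'   1.5): nucleus blobs closer than about twice this distance become one
#'   seed, which keeps a polynucleated cell's adjacent nuclei on one label
#'   without bridging neighbouring cells.
#' @return Integer label matrix (0 = background, 1..K = cells) with attribute
#'   `pixel_size_um`.
#' @export
segment_cells <- function(stack, nucleus_merge_um = 1.5) {
  .check_ebimage()
  if (!all(c("nuclear", "cytoplasm") %in% names(stack))) {
    stop("stack must contain nuclear and cytoplasm channels", call. = FALSE)
  }
  px <- attr(stack, "pixel_size_um")
  nuc <- stack$nuclear
  cyto <- stack$cytoplasm
  # empty-field guard: no plausible nuclear signal at all
  if (max(nuc) < 0.2) {
    lab <- matrix(0L, nrow(nuc), ncol(nuc))
    attr(lab, "pixel_size_um") <- px
    return(lab)
  }
  th_n <- EBImage::otsu(EBImage::Image(nuc), range = c(0, 1))
  th_c <- EBImage::otsu(EBImage::Image(cyto), range = c(0, 1))
  nucmask <- nuc > th_n
  mask <- EBImage::fillHull(EBImage::Image(cyto > th_c))
  brush_px <- max(3L, 2L * as.integer(ceiling(nucleus_merge_um / px)) + 1L)
  seeds <- EBImage::bwlabel(EBImage::dilate(
    EBImage::Image(nucmask), EBImage::makeBrush(brush_px, "disc")))
  seeds <- seeds * nucmask  # restrict merged labels back to nucleus pixels
  lab <- EBImage::propagate(EBImage::Image(cyto), seeds = seeds, mask = mask)
  lab <- EBImage::imageData(lab)
  # relabel 1..K in first-occurrence order
  u <- setdiff(sort(unique(as.integer(lab))), 0L)
  out <- matrix(match(as.integer(lab), u, nomatch = 0L), nrow(lab), ncol(lab))
  out[is.na(out)] <- 0L
  attr(out, "pixel_size_um") <- px
  out
}

#' Extract a cell table from a segmented channel stack
#'
#' Per label: mean intensity of each marker channel, cell area (pixel count x
#' pixel size^2), nuclear area (background-subtracted nuclear-channel
#' integral over the label divided by the plateau intensity — subpixel
#' accurate against the anti-aliased rendering), vacuole area (in-cell pixels
#' whose cytoplasm stain falls below the Otsu threshold, i.e. unstained
#' cytoplasm), and nucleus count (nucleus seed components within the label).
#'
#' @param stack A `channel_stack`.
#' @param labels Label matrix from [segment_cells()] (dimensions must match).
#' @return Tibble with one row per label and the canonical measurement
#'   columns plus `cell_id` (the label).
#' @export
extract_features <- function(stack, labels) {
  .check_ebimage()
  if (!all(dim(labels) == dim(stack$cytoplasm))) {
    stop("label map dimensions do not match the stack", call. = FALSE)
  }
  px <- attr(stack, "pixel_size_um")
  k <- max(labels)
  if (k == 0) {
    return(tibble::tibble(cell_id = integer(0), mito_fi = numeric(0),
                          dead_fi = numeric(0), neutral_fi = numeric(0),
                          phospho_fi = numeric(0),
                          nuclear_area_um2 = numeric(0),
                          cell_area_um2 = numeric(0),
                          vacuole_area_um2 = numeric(0),
                          nucleus_count = integer(0)))
  }
  th_n <- EBImage::otsu(EBImage::Image(stack$nuclear), range = c(0, 1))
  th_c <- EBImage::otsu(EBImage::Image(stack$cytoplasm), range = c(0, 1))
  nuccomp <- EBImage::imageData(EBImage::bwlabel(
    EBImage::Image(stack$nuclear > th_n)))

  idx <- which(labels > 0)
  lab_v <- labels[idx]
  area_px <- tabulate(lab_v, nbins = k)
  mean_by <- function(ch) {
    sums <- vapply(split(ch[idx], lab_v), sum, numeric(1))
    out <- rep(NA_real_, k)
    out[as.integer(names(sums))] <- sums
    out / area_px
  }
  vac_v <- stack$cytoplasm[idx] < th_c
  vac_sums <- vapply(split(vac_v, lab_v), sum, numeric(1))
  vac_px <- rep(0, k)
  vac_px[as.integer(names(vac_sums))] <- vac_sums

  # nuclear area by intensity integration: background-subtracted nuclear
  # signal within the label, divided by the rendering plateau (0.8)
  bg <- if (any(labels == 0)) median(stack$nuclear[labels == 0]) else 0
  nuc_sig <- pmax(stack$nuclear[idx] - bg, 0)
  nuc_sums <- vapply(split(nuc_sig, lab_v), sum, numeric(1))
  nuc_area_px <- rep(0, k)
  nuc_area_px[as.integer(names(nuc_sums))] <- nuc_sums / 0.8

  # assign each nucleus component to the cell label owning most of its pixels
  nuc_count <- rep(0L, k)
  nz <- which(nuccomp > 0 & labels > 0)
  if (length(nz)) {
    tab <- table(nuccomp[nz], labels[nz])
    owner <- as.integer(colnames(tab))[max.col(tab, ties.method = "first")]
    for (ci in seq_along(owner)) {
      nuc_count[owner[ci]] <- nuc_count[owner[ci]] + 1L
    }
  }

  tibble::tibble(
    cell_id = seq_len(k),
    mito_fi = mean_by(stack$mito),
    dead_fi = mean_by(stack$dead),
    neutral_fi = mean_by(stack$neutral),
    phospho_fi = mean_by(stack$phospho),
    nuclear_area_um2 = nuc_area_px * px^2,
    cell_area_um2 = area_px * px^2,
    vacuole_area_um2 = vac_px * px^2,
    nucleus_count = pmax(nuc_count, 1L))
}

#' Write / read a channel stack as multi-page TIFF
#'
#' Channels are written in the order of [image_spec()]'s registry
#' (`nuclear`, `cytoplasm`, `mito`, `dead`, `neutral`, `phospho`) as 32-bit
#' float pages.
#'
#' @param stack A `channel_stack`.
#' @param path TIFF path.
#' @export
write_channel_stack <- function(stack, path) {
  .check_ebimage()
  arr <- simplify2array(stack[.stack_channels()])
  EBImage::writeImage(EBImage::Image(arr), path, type = "tiff",
                      bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_channel_stack
#' @param pixel_size_um Pixel size to attach on read.
#' @export
read_channel_stack <- function(path, pixel_size_um = 0.5) {
  .check_ebimage()
  img <- EBImage::imageData(EBImage::readImage(path))
  chans <- setNames(lapply(seq_len(dim(img)[3]),
                           function(i) img[, , i]),
                    .stack_channels()[seq_len(dim(img)[3])])
  structure(chans, class = "channel_stack", pixel_size_um = pixel_size_um,
            placement = NULL)
}
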