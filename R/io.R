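#' Canonical cell-table CSV columns
#'
#' @return Character vector of the fixed header, in order.
#' @export
cell_table_columns <- function() {
  c("plate_id", "well_id", "compound", "dose_uM", "is_control", "cell_id",
    "mito_fi", "dead_fi", "neutral_fi", "phospho_fi",
    "nuclear_area_um2", "cell_area_um2", "vacuole_area_um2", "nucleus_count")
}

#' Write a cell table
#'
#' Writes the canonical UTF-8, comma-separated, "."-decimal cell-table
#' dialect: one row per segmented cell.
#'
#' @param cells Cell table tibble (e.g. `plate$cells`).
#' @param path Output CSV path.
#' @export
write_cell_table <- function(cells, path) {
  cols <- cell_table_columns()
  missing <- setdiff(cols, names(cells))
  if (length(missing)) stop("cell table is missing columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  readr::write_csv(cells[cols], path)
  invisible(path)
}

#' Read a cell table
#'
#' Reads the canonical cell-table CSV. In strict mode (default) any malformed
#' row aborts with its line number; in lenient mode malformed rows are
#' skipped with a warning reporting how many were dropped.
#'
#' @param path CSV path.
#' @param strict Abort on malformed rows (default TRUE).
#' @return Tibble of typed cell records.
#' @export
read_cell_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  cols <- cell_table_columns()
  missing <- setdiff(cols, names(raw))
  if (length(missing)) {
    stop("cell table header is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[cols]
  num_cols <- c("dose_uM", measure_columns(), "nucleus_count")
  suppress <- function(x) suppressWarnings(as.numeric(x))
  parsed <- lapply(raw[num_cols], suppress)
  lgl <- toupper(raw$is_control) %in% c("TRUE", "FALSE")
  bad <- rowSums(vapply(parsed, is.na, logical(nrow(raw)))) > 0 | !lgl
  bad <- bad |
    (!is.na(parsed$dose_uM) & parsed$dose_uM < 0) |
    (!is.na(parsed$nucleus_count) & parsed$nucleus_count < 1) |
    Reduce(`|`, lapply(parsed[c("nuclear_area_um2", "cell_area_um2",
                                "vacuole_area_um2")],
                       function(x) !is.na(x) & x < 0))
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    if (strict) {
      stop("malformed cell-table row(s) at line(s): ",
           paste(head(lines, 10), collapse = ", "),
           if (length(lines) > 10) " ..." else "", call. = FALSE)
    }
    warning(sprintf("skipped %d malformed row(s)", sum(bad)), call. = FALSE)
  }
  keep <- !bad
  tibble::tibble(
    plate_id = raw$plate_id[keep], well_id = raw$well_id[keep],
    compound = raw$compound[keep], dose_uM = parsed$dose_uM[keep],
    is_control = toupper(raw$is_control[keep]) == "TRUE",
    cell_id = raw$cell_id[keep],
    mito_fi = parsed$mito_fi[keep], dead_fi = parsed$dead_fi[keep],
    neutral_fi = parsed$neutral_fi[keep],
    phospho_fi = parsed$phospho_fi[keep],
    nuclear_area_um2 = parsed$nuclear_area_um2[keep],
    cell_area_um2 = parsed$cell_area_um2[keep],
    vacuole_area_um2 = parsed$vacuole_area_um2[keep],
    nucleus_count = as.integer(parsed$nucleus_count[keep]))
}

#' Write / read ground truth JSON
#'
#' Ground truth (planted abnormal fractions and detachment per well) is
#' serialised as JSON beside the cell table so parameter-recovery checks can
#' run on files alone.
#'
#' @param plate An `hcia_plate`.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(plate, path) {
  jsonlite::write_json(
    list(seed = plate$seed,
         plate_id = plate$spec$plate_id,
         detachment = plate$wells[c("well_id", "planted_detachment")],
         planted = plate$ground_truth),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bundled compound panel
#'
#' Reads a compound panel YAML (name, pharmaceutical class, lipophilicity
#' rank used only for deterministic row ordering, effect template). The
#' bundled panel (`system.file("extdata", "compound_panel.yaml", package =
#' "hciascreen")`) lists the screened inhaled-drug classes with synthetic
#' ranks; physicochemical predictions are carried as inert metadata only.
#'
#' @param path Panel YAML path; default the bundled panel.
#' @return Tibble with `compound`, `class`, `lipophilicity_rank`, `template`.
#' @export
read_compound_panel <- function(path = NULL) {
  path <- path %||% system.file("extdata", "compound_panel.yaml",
                                package = "hciascreen")
  y <- yaml::read_yaml(path)
  dplyr::bind_rows(lapply(y$compounds, function(e) {
    tibble::tibble(compound = e$name, class = e$class,
                   lipophilicity_rank = e$lipophilicity_rank,
                   template = e$template)
  }))
}

#' Effects list from a compound panel
#'
#' @param panel Tibble from [read_compound_panel()].
#' @return Named list of [compound_effect()] objects built from the panel's
#'   templates.
#' @export
panel_effects <- function(panel) {
  .effect_index(lapply(seq_len(nrow(panel)), function(i) {
    effect_template(panel$compound[i], template = panel$template[i],
                    class = panel$class[i])
  }))
}

#' Run configuration
#'
#' Assembles (or reads from YAML/JSON) the configuration of a full pipeline
#' run: cell-type preset, dose ladder, replicate count, the fixed thresholds
#' (SD multiplier 2, abnormality 10%, detachment exclusion 50%), quartile
#' convention, clustering options, and the master seed.
#'
#' @param preset `"j774"` or `"ham"`.
#' @param doses Dose ladder in uM (default: preset ladder subset used for the
#'   bundled fixture).
#' @param n_replicates Replicate experiments (default 6 for j774, 5 donors
#'   for ham).
#' @param compounds Compound names from the panel to include (default: all).
#' @param panel_path Optional path to a compound panel YAML.
#' @param seed Master seed.
#' @param threshold_pct Abnormality threshold (percent, default 10).
#' @param detachment_pct Exclusion threshold (percent, default 50).
#' @param quartile_convention `"tukey"` or `"linear"`.
#' @param cluster_k Number of discrete clusters (default 2).
#' @param cluster_dose Dose (uM) at which to cluster (default 5).
#' @param standardise Standardise features before clustering (default FALSE).
#' @param jitter Between-replicate jitter (default 0.05).
#' @param plots Render PNG heatmaps (default TRUE).
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(preset = c("j774", "ham"),
                       doses = c(0.1, 1, 5),
                       n_replicates = NULL,
                       compounds = NULL,
                       panel_path = NULL,
                       seed = 1,
                       threshold_pct = 10,
                       detachment_pct = 50,
                       quartile_convention = c("tukey", "linear"),
                       cluster_k = 2,
                       cluster_dose = 5,
                       standardise = FALSE,
                       jitter = 0.05,
                       plots = TRUE) {
  preset <- match.arg(preset)
  quartile_convention <- match.arg(quartile_convention)
  doses <- as.numeric(unlist(doses))
  if (!is.null(compounds)) compounds <- as.character(unlist(compounds))
  if (threshold_pct <= 0 || detachment_pct <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  n_replicates <- n_replicates %||% if (preset == "j774") 6L else 5L
  structure(list(preset = preset, doses = doses,
                 n_replicates = as.integer(n_replicates),
                 compounds = compounds, panel_path = panel_path,
                 seed = as.integer(seed),
                 threshold_pct = threshold_pct,
                 detachment_pct = detachment_pct,
                 quartile_convention = quartile_convention,
                 cluster_k = as.integer(cluster_k),
                 cluster_dose = cluster_dose,
                 standardise = isTRUE(standardise),
                 jitter = jitter,
                 plots = isTRUE(plots)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML or JSON config file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, lst[intersect(names(lst),
                                    names(formals(run_config)))])
}
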