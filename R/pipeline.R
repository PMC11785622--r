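#' Run the full screening pipeline
#'
#' Chains every stage on simulated data: replicate-series simulation from the
#' configured cell-type preset and compound panel, per-replicate untreated
#' baselines, well profiles, detachment exclusions, the compound x dose score
#' matrix (TSV + heatmap), Ward/Euclidean clustering at the configured dose
#' (linkage, leaf order, k-cluster assignment), and a run manifest recording
#' the configuration, seed and artefact list. Identical configurations yield
#' byte-identical numeric outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(msg) message("[hciascreen] ", msg)

  stage("simulate")
  panel <- read_compound_panel(config$panel_path)
  if (!is.null(config$compounds)) {
    missing <- setdiff(config$compounds, panel$compound)
    if (length(missing)) stop("compounds not in panel: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    panel <- panel[panel$compound %in% config$compounds, ]
  }
  effects <- panel_effects(panel)
  baseline <- if (config$preset == "j774") baseline_j774() else baseline_ham()
  treatments <- expand.grid(compound = panel$compound,
                            dose_uM = config$doses,
                            stringsAsFactors = FALSE)
  spec <- plate_spec(plate_id = paste0(config$preset, "_plate"),
                     treatments = treatments)
  series <- simulate_replicate_series(spec, baseline, effects,
                                      n = config$n_replicates,
                                      base_seed = config$seed,
                                      jitter = config$jitter)

  stage("score wells")
  baselines <- lapply(series, function(p) compute_baseline(p$cells, p$wells))
  profiles <- dplyr::bind_rows(lapply(seq_along(series), function(r) {
    well_profiles(series[[r]], baselines[[r]], replicate = r)
  }))

  stage("categorise")
  exclusions <- apply_exclusions(profiles, config$detachment_pct)
  sets <- replicate_sets(profiles)
  scores <- build_score_matrix(sets, exclusions, panel,
                               threshold = config$threshold_pct,
                               convention = config$quartile_convention)

  stage("cluster")
  m <- mean_response_matrix(profiles, config$cluster_dose, exclusions)
  tree <- ward_linkage(m, standardise = config$standardise)
  assignment <- cut_to_k(tree, k = config$cluster_k)

  stage("report")
  paths <- list(
    cells = file.path(out_dir, "cell_table.csv"),
    baseline = file.path(out_dir, "baseline_stats.json"),
    profiles = file.path(out_dir, "well_profiles.csv"),
    exclusions = file.path(out_dir, "exclusions.tsv"),
    scores = file.path(out_dir, "score_matrix.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_cell_table(dplyr::bind_rows(lapply(series, `[[`, "cells")),
                   paths$cells)
  write_baseline_json(baselines[[1]], paths$baseline)
  readr::write_csv(profiles, paths$profiles)
  readr::write_tsv(exclusions, paths$exclusions)
  write_score_matrix(scores, paths$scores)
  cm <- export_clustermap(
    m, tree, assignment,
    annotations = setNames(panel$class, panel$compound),
    path_prefix = file.path(out_dir, "cluster"),
    plot = config$plots)
  paths <- c(paths, cm)
  if (config$plots) {
    hm_path <- file.path(out_dir, "score_heatmap.png")
    png(hm_path, width = 1400, height = 200 + 30 * nrow(scores), res = 144)
    print(plot_score_heatmap(scores))
    dev.off()
    paths$score_heatmap <- hm_path
  }

  manifest <- list(
    package = "hciascreen",
    version = as.character(packageVersion("hciascreen")),
    config = unclass(config),
    seed = config$seed,
    artefacts = unname(unlist(lapply(paths, basename))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(list(series = series, baselines = baselines,
                 profiles = profiles, exclusions = exclusions,
                 scores = scores, response_matrix = m, tree = tree,
                 assignment = assignment, paths = paths,
                 manifest = manifest))
}
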