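#' Cell-table measurement columns
#'
#' Names of the per-cell measurement columns in the canonical cell table:
#' four fluorescence intensities (arbitrary units) and three areas (um^2).
#'
#' @return Character vector of seven column names.
#' @export
measure_columns <- function() {
  c("mito_fi", "dead_fi", "neutral_fi", "phospho_fi",
    "nuclear_area_um2", "cell_area_um2", "vacuole_area_um2")
}

# Registry of the nine cell-level response attributes (heatmap columns) plus
# the well-level non-adherent percentage. `tail` states which side of the
# untreated mean +/- 2 SD band flags a cell as abnormal.
.attr_registry <- data.frame(
  attribute = c("nonadherent",
                "elev_mito", "red_mito", "elev_membrane_perm",
                "abn_nuclear_area", "elev_cell_area", "polynucleated_change",
                "elev_vacuole", "elev_neutral_lipid", "elev_phospholipid"),
  measure = c(NA,
              "mito_fi", "mito_fi", "dead_fi",
              "nuclear_area_um2", "cell_area_um2", NA,
              "vacuole_area_um2", "neutral_fi", "phospho_fi"),
  tail = c(NA,
           "upper", "lower", "upper",
           "both", "upper", NA,
           "upper", "upper", "upper"),
  level = c("well",
            "cell", "cell", "cell",
            "cell", "cell", "well",
            "cell", "cell", "cell"),
  stringsAsFactors = FALSE
)

#' Response-attribute registry
#'
#' The ten response attributes reported per well: the well-level
#' non-adherent percentage, the well-level polynucleated-cell change, and
#' eight single-cell percent-abnormal attributes. For single-cell attributes
#' the registry records the measurement column and the abnormal tail
#' (`upper`, `lower`, or `both`) relative to the untreated mean +/- 2 SD band.
#'
#' @return A tibble with columns `attribute`, `measure`, `tail`, `level`.
#' @export
hcia_attributes <- function() tibble::as_tibble(.attr_registry)

#' @rdname hcia_attributes
#' @export
cell_attributes <- function() {
  .attr_registry$attribute[.attr_registry$level == "cell"]
}

#' @rdname hcia_attributes
#' @export
response_attributes <- function() .attr_registry$attribute

# the nine attributes that receive 1-4 category scores (all but nonadherent)
scored_attributes <- function() {
  setdiff(response_attributes(), "nonadherent")
}

profile_columns <- function() {
  c("plate_id", "well_id", "compound", "dose_uM", "is_control", "replicate",
    "adherent_count", paste0("pct_", response_attributes()))
}
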