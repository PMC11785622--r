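#' Phenomenological compound effect specification
#'
#' Describes what a compound does to the simulated cell population as a set of
#' planted per-attribute abnormal fractions at a reference dose, plus a
#' detachment probability. Effects are phenomenological mixtures, not a
#' mechanistic model: at dose d a fraction f(d) of cells is drawn from an
#' unambiguously abnormal component (uniform over the band from 2 SD to 4 SD
#' beyond the untreated mean, on the attribute's abnormal side) and the rest
#' from the untreated baseline.
#'
#' The dose scaling is a saturating curve with unit asymmetry parameter
#' `hill`, normalised so the planted fraction at `ref_dose` equals the
#' specified target: f(d) = min(1, f_ref * g(d) / g(ref)) with
#' g(d) = (d/ref)^h / (1 + (d/ref)^h).
#'
#' @param name Compound name.
#' @param class Pharmaceutical class label (e.g. "CAD", "antibiotic",
#'   "beta-agonist", "anticholinergic", "apoptosis inducer", "corticosteroid",
#'   "miscellaneous").
#' @param effects Named numeric vector of target abnormal fractions in
#'   `[0, 1]` at `ref_dose`; names must be scored response attributes (see
#'   [hcia_attributes()]), e.g. `c(elev_phospholipid = 1)`.
#' @param detachment Detachment probability at `ref_dose`, in `[0, 1]`.
#' @param ref_dose Reference dose in uM (default 5).
#' @param hill Steepness of the saturating dose curve (default 1).
#'
#' @return An object of class `compound_effect`.
#' @export
compound_effect <- function(name, class = "miscellaneous",
                            effects = numeric(0), detachment = 0,
                            ref_dose = 5, hill = 1) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("name must be a non-empty string", call. = FALSE)
  }
  effects <- unlist(effects)
  if (length(effects)) {
    bad <- setdiff(names(effects), scored_attributes())
    if (length(bad)) {
      stop("unknown effect attribute(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(effects < 0 | effects > 1)) {
      stop("effect fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  stopifnot_scalar_prob(detachment, "detachment")
  if (ref_dose <= 0) stop("ref_dose must be > 0", call. = FALSE)
  if (hill <= 0) stop("hill must be > 0", call. = FALSE)
  structure(list(name = name, class = class, effects = effects,
                 detachment = detachment, ref_dose = ref_dose, hill = hill),
            class = "compound_effect")
}

#' @export
print.compound_effect <- function(x, ...) {
  cat(sprintf("<compound_effect> %s [%s]  ref dose %g uM, hill %g\n",
              x$name, x$class, x$ref_dose, x$hill))
  if (length(x$effects)) {
    for (a in names(x$effects)) {
      cat(sprintf("  %-22s f_ref = %.3g\n", a, x$effects[[a]]))
    }
  }
  cat(sprintf("  detachment at ref dose: %.3g\n", x$detachment))
  invisible(x)
}

#' Planted-fraction dose scaling
#'
#' Scales a reference-dose target fraction to an arbitrary dose with the
#' normalised saturating curve described in [compound_effect()].
#'
#' @param f_ref Target fraction at `ref_dose`.
#' @param dose Dose in uM (vectorised).
#' @param ref_dose,hill See [compound_effect()].
#' @return Planted fraction(s) in `[0, 1]`.
#' @export
dose_fraction <- function(f_ref, dose, ref_dose = 5, hill = 1) {
  g <- function(d) (d / ref_dose)^hill / (1 + (d / ref_dose)^hill)
  pmin(1, f_ref * g(dose) / g(ref_dose))
}

#' Built-in compound effect templates
#'
#' Qualitative effect templates mirroring the response patterns seen in the
#' screen: cationic amphiphilic drugs (CADs) drive elevated phospholipid
#' staining (with secondary mitochondrial and neutral-lipid responses),
#' apoptosis inducers cause massive cell detachment with membrane
#' permeabilisation, corticosteroid-like compounds give a weak neutral-lipid
#' response, and inert compounds do nothing.
#'
#' @param name Compound name.
#' @param class Override the template's class label.
#' @param template One of `"cad"`, `"apoptosis"`, `"corticosteroid"`,
#'   `"inert"`.
#' @return A [compound_effect()].
#' @export
effect_template <- function(name,
                            template = c("cad", "apoptosis",
                                         "corticosteroid", "inert"),
                            class = NULL) {
  template <- match.arg(template)
  switch(template,
    cad = compound_effect(
      name, class %||% "CAD",
      effects = c(elev_phospholipid = 1.0, elev_mito = 0.30,
                  elev_neutral_lipid = 0.30, elev_vacuole = 0.20),
      detachment = 0.15),
    apoptosis = compound_effect(
      name, class %||% "apoptosis inducer",
      effects = c(elev_membrane_perm = 0.60, red_mito = 0.40,
                  abn_nuclear_area = 0.40),
      detachment = 0.90),
    corticosteroid = compound_effect(
      name, class %||% "corticosteroid",
      effects = c(elev_neutral_lipid = 0.15),
      detachment = 0.05),
    inert = compound_effect(name, class %||% "miscellaneous"))
}
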