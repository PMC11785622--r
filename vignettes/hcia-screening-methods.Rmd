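---
title: "Methods: abnormality scoring, response categorisation and profile clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: abnormality scoring, response categorisation and profile clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hciascreen)
```

## The measurement model

High-content image analysis (HCIA) cytotoxicity screening measures many
attributes of each segmented cell in a well — fluorescence intensities of a
mitochondrial-activity stain, a membrane-integrity stain, neutral-lipid and
phospholipid stains, plus nuclear area, cell area, vacuole (unstained
cytoplasm) area and nucleus count — and summarises each treated well as the
percentage of cells that are *abnormal* for each attribute. Two additional
well-level attributes are computed from counts: the percentage of
non-adherent cells relative to the untreated mean, and the relative change in
polynucleated cells.

A cell is abnormal for an attribute when its value lies strictly more than
2 standard deviations from the mean of the plate's untreated population:
above the mean for the "elevated" attributes, below it for reduced
mitochondrial activity, and on either side for nuclear area. The untreated
population is the pool of all cells across the plate's untreated control
wells (six per plate in the emulated design); we pool cells rather than
average per-well means because the 2 SD band is a property of the single-cell
population, and we use the sample SD (n − 1), matching typical instrument
software. All per-well percentages pool the well's acquired images; a
per-image aggregation path is deliberately not exposed.

Two sign conventions deserve a note. The non-adherent percentage
`100 × (untreated mean count − treated count) / untreated mean count` can be
negative when a treated well holds more cells than the untreated average;
the value is retained unclipped (it never triggers exclusion). The
polynucleated-change formula has the same shape and is implemented exactly as
printed, so a *positive* value means *fewer* polynucleated cells than the
untreated average. Because it is a relative change of a small count
(tens of cells per well), it is by far the noisiest attribute; its null
distribution easily spans ±30% at realistic polynucleation rates, which is
worth remembering when reading score heatmaps.

## The four-category response score

For each compound × dose × attribute, the replicate percent-abnormal values
(one per experiment or donor) are summarised by their five-number summary
(min, Q1, median, Q3, max) and scored against a 10% abnormality threshold —
the empirical ceiling of abnormal-cell percentages in untreated populations:

| score | rule (strict inequalities) | reading |
|---|---|---|
| 4 | min > 10% | whole replicate set above threshold |
| 3 | Q1 > 10% | more than 75% of the set above threshold |
| 2 | Q2 > 10% | median above threshold |
| 1 | otherwise | indistinguishable from untreated |

Rules are evaluated most-severe-first; a value exactly at the threshold falls
to the lower category.

**Quartile convention.** With typical replicate numbers (n = 5–6) the hinge
convention is outcome-relevant: a lower hinge of 9.9% versus an interpolated
10.4% flips a score from 2 to 3. The default is Tukey hinges
(`stats::fivenum`), the convention behind classic box-and-whisker displays;
a linear-interpolation alternative (`stats::quantile` type 7) is available
via `quartile_summary(..., convention = "linear")`, and the test suite pins
both behaviours on a borderline fixture. No claim is made about which
convention any particular instrument software uses.

**Exclusion.** A compound × dose condition is excluded when the
replicate-mean non-adherent percentage strictly exceeds 50% — too few cells
survive for a robust population statistic. Exclusion is per dose (a compound
cytotoxic only at its top dose keeps its lower doses) and propagates to all
nine scored attributes.

## Clustering of response profiles

For similarity analysis each retained compound at a fixed dose is represented
by its mean response vector: the replicate means of all ten attributes,
*including* the non-adherent percentage, which is often a strong driver of
the partition. Rows are clustered by agglomerative hierarchical clustering
with Euclidean distances under Ward's minimum-variance criterion
(`stats::hclust`, method `"ward.D2"`); merge heights are reported on the
`sqrt(2 × ΔESS)` scale, which reduces to the Euclidean distance for singleton
merges, and the test suite verifies the heights against an exhaustive greedy
minimum-variance search on small fixtures. Features are left on their raw
percentage scale by default — the heatmap values are raw mean percentages —
with per-feature standardisation available as an option
(`ward_linkage(..., standardise = TRUE)`); switching it changes the tree.
Discrete assignments use `cut_to_k` (default k = 2), with cluster labels
renumbered deterministically by first row occurrence. Ties between
equal-height merges follow `hclust`'s deterministic lowest-index order.

## The synthetic plate simulator

No public single-cell dataset accompanies the screening design this package
implements, so the simulator is a first-class module: it generates plates
with known ground truth against which every downstream stage is tested.

**Baselines.** Untreated attribute distributions are parameterised by the
location/scale summaries of the two screened cell types: murine J774A.1
macrophage-like cells (`baseline_j774()`: e.g. cell area 249 ± 58 µm²,
nuclear area 101 ± 19 µm², ≈ 1002 adherent cells/well with SD 376, ≈ 25
polynucleated cells/well) and primary human alveolar macrophages
(`baseline_ham()`: cell area 338 ± 53 µm², ≈ 260 cells/well). Fluorescence
intensities are right-skewed, so they are drawn lognormal with matched mean
and SD; nuclear and cell areas are symmetric normals truncated at zero.
Vacuole area is also drawn lognormal: its summary (mean 4 µm², SD 9 µm²,
minimum 0) cannot be approximated by any symmetric law, and the per-attribute
family tag exists precisely for such cases. Only the first two moments are
matched — no claim is made about the true distribution shape. Adherent
counts per well are negative binomial (the observed count spread is far
over-Poisson); polynucleation is Bernoulli per cell.

**Effects.** Compound effects are phenomenological mixtures, not a
pharmacokinetic or lysosomal-trapping model. At dose *d* a planted fraction
*f(d)* of cells is drawn uniformly from the band 2–4 SD beyond the untreated
mean on the attribute's abnormal side (both tails, split at random, for
nuclear area), the rest from baseline; detachment thins the pre-treatment
count binomially *before* cells are drawn, so detached cells contribute no
rows and counts are conserved (`pre = adherent + detached`). The dose curve
is a saturating form normalised so the fraction at the reference dose equals
the specified target: `f(d) = min(1, f_ref · g(d)/g(ref))` with
`g(d) = (d/ref)^h / (1 + (d/ref)^h)` and h = 1 by default; the screen shows
dose dependence but no functional form, so the simplest saturating curve is
used. Built-in templates mirror the qualitative response patterns of the
screen: CAD-like compounds (planted elevated-phospholipid fraction 1.0 at the
5 µM reference dose, matching the observed 98.3–100% response, with
secondary mitochondrial/neutral-lipid/vacuole effects), apoptosis inducers
(90% detachment — reliably excluded), weak corticosteroid-like responders,
and inert compounds.

**Replicates and seeds.** A replicate series jitters every baseline location
by a multiplicative 5% Gaussian factor per replicate — a plausible magnitude
for passage-to-passage or donor-to-donor drift, chosen once since no
magnitude is stated — with replicate 1 kept as the unjittered anchor.
Determinism is strict: one master seed, per-well substreams derived by a
stable polynomial hash of (plate, well, seed), so identical configurations
give bit-identical tables and the full pipeline writes byte-identical
artefacts.

**What passing tests do and do not show.** The simulator reproduces the
*summary scale* of real plates (means, SDs, count dispersion, control-well
tail rates ≈ 2.3% one-sided / 4.6% two-sided) and known planted effects. It
does not reproduce correlated multi-attribute responses within single cells
beyond independent mixtures, spatial within-well effects, donor-specific
response patterns, or heavy-tailed instrument artefacts — so green tests
validate the statistical machinery, not biological claims about any real
compound.

## The imaging front-end

An optional validation harness closes the loop from pixels: `render_well`
draws each cell as an anti-aliased nucleus disc (two adjacent discs for
polynucleated cells) inside a uniform cytoplasm disc, with marker channels
linear in the stored values, vacuoles as unstained holes, and additive
Gaussian noise; `segment_cells` segments by Otsu thresholding of the
cytoplasm channel (holes filled) with nucleus-seeded label propagation —
nucleus seeds closer than ~3 µm are merged so a polynucleated cell stays one
object; `extract_features` recovers the canonical cell table (nuclear area
by background-subtracted intensity integration, subpixel-accurate). The
round trip recovers cell counts exactly on non-overlapping fixtures,
rank-correlates intensities at ρ > 0.95, and reproduces well profiles within
2 percentage points — which is the point: the pipeline's canonical input is
the cell table, and the imaging path demonstrates the measurement model is
consistent with it. Real-microscope effects (illumination gradients, PSF
blur, bleed-through, autofocus failures) are out of scope.

## Numerical and interface choices

* Problem sizes in the bundled fixture (8 compounds × 3 doses × 6
  replicates at ≈ 1000 cells/well) keep a full pipeline run to a few
  seconds while exercising every stage; the simulator scales to full panels
  by configuration.
* Degenerate inputs: a fully detached well reports missing (NA) cell-level
  percentages rather than zeros and is flagged; baselines require ≥ 1
  untreated well and ≥ 2 pooled cells; score matrices refuse silently
  missing replicate sets unless the condition is excluded.
* The panel of compound names, classes and within-class ordering ranks is an
  editable YAML fixture; the ordering ranks are synthetic and only make row
  order deterministic.
* The command-line entry point (`inst/cli/hcia.R`) is a thin wrapper over
  the exported functions with distinct exit codes for configuration (2),
  I/O (3) and stage (4) errors; the R API is the primary interface.

## Known limitations

Effects are independent across attributes within a cell (no joint
covariance); the polynucleated-change attribute is intrinsically noisy at
realistic counts; the detachment exclusion interacts with the simulator's
large count dispersion, so borderline detachment probabilities (near 50%)
produce seed-dependent exclusion; and the two-category cluster cut is only
as meaningful as the separation of the underlying profiles — no stability or
model-selection machinery is provided because the analysis design fixes
k = 2.
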