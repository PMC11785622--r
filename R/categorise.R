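#' Five-number quartile summary of replicate percentages
#'
#' Summarises a replicate set (one percent-abnormal value per experiment or
#' donor) as min, Q1, median (Q2), Q3, max. The default convention is Tukey
#' hinges (hinges are medians of the lower/upper half, including the sample
#' median in each half for odd halves) — the convention behind the classic
#' box-and-whisker plot. A linear-interpolation convention
#' (`stats::quantile` type 7) is available; with small replicate numbers the
#' two can disagree on borderline sets, so the convention is explicit.
#'
#' @param values Numeric vector of at least two finite values.
#' @param convention `"tukey"` (default) or `"linear"`.
#' @return Object of class `quartile_summary`: named list with `min`, `q1`,
#'   `q2`, `q3`, `max`, `n`, `convention`.
#' @export
quartile_summary <- function(values, convention = c("tukey", "linear")) {
  convention <- match.arg(convention)
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (convention == "tukey") {
    f <- fivenum(values)
  } else {
    f <- unname(quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  }
  structure(list(min = f[1], q1 = f[2], q2 = f[3], q3 = f[4], max = f[5],
                 n = length(values), convention = convention),
            class = "quartile_summary")
}

#' @export
print.quartile_summary <- function(x, ...) {
  cat(sprintf("<quartile_summary> n=%d (%s): min %.4g | Q1 %.4g | Q2 %.4g | Q3 %.4g | max %.4g\n",
              x$n, x$convention, x$min, x$q1, x$q2, x$q3, x$max))
  invisible(x)
}

.category_labels <- c(`1` = "Normal",
                      `2` = "Possibly treatment-related",
                      `3` = "Likely treatment-related",
                      `4` = "Treatment-related")

#' Four-category treatment-response score
#'
#' Assigns the ordinal 1-4 response category to a replicate set's quartile
#' summary relative to the abnormality threshold (default 10%, the empirical
#' ceiling of percent-abnormal in untreated populations). Rules are evaluated
#' most-severe-first with strict inequalities, so a value exactly at the
#' threshold falls to the lower category:
#'
#' * score 4 ("Treatment-related"): minimum > threshold — the whole replicate
#'   set exceeds the threshold;
#' * score 3 ("Likely treatment-related"): Q1 > threshold;
#' * score 2 ("Possibly treatment-related"): median (Q2) > threshold;
#' * score 1 ("Normal"): otherwise (median below or at the threshold).
#'
#' @param summary A [quartile_summary()] (or numeric vector of replicate
#'   values, summarised with the default convention).
#' @param threshold Abnormality threshold in percent (default 10).
#' @return Object of class `category_score`: list with integer `score`,
#'   `label`, `threshold`.
#' @export
categorise <- function(summary, threshold = 10) {
  if (is.numeric(summary)) summary <- quartile_summary(summary)
  stopifnot(inherits(summary, "quartile_summary"))
  score <- if (summary$min > threshold) 4L
           else if (summary$q1 > threshold) 3L
           else if (summary$q2 > threshold) 2L
           else 1L
  structure(list(score = score,
                 label = unname(.category_labels[as.character(score)]),
                 threshold = threshold),
            class = "category_score")
}

#' @export
print.category_score <- function(x, ...) {
  cat(sprintf("<category_score> %d (%s), threshold %g%%\n",
              x$score, x$label, x$threshold))
  invisible(x)
}

#' Long-format replicate sets from well profiles
#'
#' Reshapes well profiles into one row per
#' compound x dose x attribute x replicate for the nine scored attributes.
#'
#' @param profiles Tibble of well profiles (see [well_profiles()]) for
#'   treated wells across replicates; control wells are dropped.
#' @return Long tibble with columns `compound`, `dose_uM`, `attribute`,
#'   `replicate`, `value`.
#' @export
replicate_sets <- function(profiles) {
  tr <- profiles[!profiles$is_control, , drop = FALSE]
  keep <- c("compound", "dose_uM", "replicate",
            paste0("pct_", scored_attributes()))
  long <- tidyr::pivot_longer(tr[keep],
                              cols = dplyr::starts_with("pct_"),
                              names_to = "attribute", values_to = "value",
                              names_prefix = "pct_")
  long[c("compound", "dose_uM", "attribute", "replicate", "value")]
}

#' Detachment exclusion rule
#'
#' A compound x dose condition is excluded from scoring when the
#' replicate-mean non-adherent percentage exceeds 50% (strictly), i.e. when
#' on average more than half of the adherent cells were lost relative to the
#' untreated wells. Exclusion is per dose, not per compound, and propagates
#' to all nine cell-level attributes of that condition.
#'
#' @param profiles Tibble of well profiles across replicates.
#' @param threshold Exclusion threshold in percent (default 50).
#' @return Tibble with `compound`, `dose_uM`, `mean_nonadherent`, `excluded`,
#'   `reason`.
#' @export
apply_exclusions <- function(profiles, threshold = 50) {
  tr <- profiles[!profiles$is_control, , drop = FALSE]
  if (nrow(tr) == 0) {
    return(tibble::tibble(compound = character(0), dose_uM = numeric(0),
                          mean_nonadherent = numeric(0),
                          excluded = logical(0), reason = character(0)))
  }
  agg <- dplyr::summarise(
    dplyr::group_by(tr, .data$compound, .data$dose_uM),
    mean_nonadherent = mean(.data$pct_nonadherent), .groups = "drop")
  agg$excluded <- agg$mean_nonadherent > threshold
  agg$reason <- ifelse(
    agg$excluded,
    sprintf("mean loss of adherent cells %.1f%% > %g%%",
            agg$mean_nonadherent, threshold),
    NA_character_)
  agg
}

#' Compound x dose score matrix
#'
#' Applies [categorise()] cell-wise to every compound x dose x attribute
#' replicate set, honouring exclusions. Rows are ordered by pharmaceutical
#' class, then lipophilicity rank, then ascending dose when a compound panel
#' is supplied, otherwise alphabetically; ordering is deterministic.
#'
#' @param sets Long replicate sets from [replicate_sets()].
#' @param exclusions Exclusion table from [apply_exclusions()] (optional).
#' @param panel Optional compound panel tibble with `compound`, `class`,
#'   `lipophilicity_rank` (see [read_compound_panel()]).
#' @param threshold Abnormality threshold in percent (default 10).
#' @param convention Quartile convention, see [quartile_summary()].
#' @return Object of class `score_matrix`: tibble with `compound`, `class`,
#'   `dose_uM`, `excluded`, and one integer score column per scored attribute
#'   (`NA` where excluded).
#' @export
build_score_matrix <- function(sets, exclusions = NULL, panel = NULL,
                               threshold = 10,
                               convention = c("tukey", "linear")) {
  convention <- match.arg(convention)
  combos <- unique(sets[c("compound", "dose_uM")])
  if (is.null(exclusions)) {
    excl <- rep(FALSE, nrow(combos))
  } else {
    key <- paste(combos$compound, combos$dose_uM)
    ekey <- paste(exclusions$compound, exclusions$dose_uM)
    excl <- exclusions$excluded[match(key, ekey)]
    excl[is.na(excl)] <- FALSE
  }
  attrs <- scored_attributes()
  score_cols <- matrix(NA_integer_, nrow(combos), length(attrs),
                       dimnames = list(NULL, attrs))
  for (i in seq_len(nrow(combos))) {
    if (excl[i]) next
    sub <- sets[sets$compound == combos$compound[i] &
                sets$dose_uM == combos$dose_uM[i], ]
    for (a in attrs) {
      v <- sub$value[sub$attribute == a]
      v <- v[is.finite(v)]
      if (length(v) < 2) {
        stop(sprintf("missing replicate set for %s @ %g uM, attribute %s",
                     combos$compound[i], combos$dose_uM[i], a), call. = FALSE)
      }
      score_cols[i, a] <-
        categorise(quartile_summary(v, convention), threshold)$score
    }
  }
  out <- tibble::tibble(compound = combos$compound,
                        dose_uM = combos$dose_uM,
                        excluded = excl,
                        tibble::as_tibble(score_cols))
  if (!is.null(panel)) {
    m <- match(out$compound, panel$compound)
    out$class <- panel$class[m]
    ord <- order(out$class, panel$lipophilicity_rank[m], out$compound,
                 out$dose_uM)
  } else {
    out$class <- NA_character_
    ord <- order(out$compound, out$dose_uM)
  }
  out <- out[ord, c("compound", "class", "dose_uM", "excluded", attrs)]
  structure(out, class = c("score_matrix", class(tibble::tibble())),
            threshold = threshold, convention = convention)
}

#' Export a score matrix as TSV
#'
#' Scores are written as integers, excluded conditions as `"X"`.
#'
#' @param x A `score_matrix`.
#' @param path Output TSV path.
#' @export
write_score_matrix <- function(x, path) {
  out <- as.data.frame(x)
  for (a in scored_attributes()) {
    out[[a]] <- ifelse(out$excluded, "X", as.character(out[[a]]))
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Score heatmap
#'
#' Tile heatmap of category scores (compound x dose rows, attribute columns)
#' with excluded conditions marked "X".
#'
#' @param x A `score_matrix`.
#' @return A ggplot object.
#' @export
plot_score_heatmap <- function(x) {
  attrs <- scored_attributes()
  df <- as.data.frame(x)
  df$row <- factor(paste0(df$compound, " @ ", df$dose_uM, " uM"),
                   levels = rev(unique(paste0(df$compound, " @ ",
                                              df$dose_uM, " uM"))))
  long <- tidyr::pivot_longer(df, cols = dplyr::all_of(attrs),
                              names_to = "attribute", values_to = "score")
  long$attribute <- factor(long$attribute, levels = attrs)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$attribute, y = .data$row,
                                     fill = factor(.data$score))) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::geom_text(data = long[is.na(long$score), ],
                       ggplot2::aes(label = "X"), inherit.aes = TRUE) +
    ggplot2::scale_fill_manual(
      values = c(`1` = "#ffffcc", `2` = "#a1dab4",
                 `3` = "#41b6c4", `4` = "#225ea8"),
      na.value = "grey85", name = "category") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
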