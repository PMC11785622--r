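#' Compound x feature mean-response matrix
#'
#' Builds the clustering input at one fixed dose: one row per retained
#' compound, one column per response feature (the nine cell-level attributes
#' plus the non-adherent percentage — detachment is deliberately kept as a
#' clustering feature), values the replicate means of the percent-abnormal
#' values. Compound x dose conditions excluded by the detachment rule are
#' omitted with a logged reason.
#'
#' @param profiles Tibble of well profiles across replicates.
#' @param dose Dose in uM at which to build the matrix.
#' @param exclusions Optional exclusion table from [apply_exclusions()].
#' @return Numeric matrix (compounds x 10 features) with a `dropped`
#'   attribute listing omitted compounds and reasons.
#' @export
mean_response_matrix <- function(profiles, dose, exclusions = NULL) {
  tr <- profiles[!profiles$is_control & profiles$dose_uM == dose, ,
                 drop = FALSE]
  if (nrow(tr) == 0) stop("no treated wells at dose ", dose, call. = FALSE)
  dropped <- character(0)
  if (!is.null(exclusions)) {
    ex <- exclusions[exclusions$excluded & exclusions$dose_uM == dose, ,
                     drop = FALSE]
    dropped <- setNames(ex$reason, ex$compound)
    tr <- tr[!tr$compound %in% ex$compound, , drop = FALSE]
  }
  if (nrow(tr) == 0) stop("empty response matrix after exclusions",
                          call. = FALSE)
  feats <- paste0("pct_", response_attributes())
  agg <- dplyr::summarise(dplyr::group_by(tr, .data$compound),
                          dplyr::across(dplyr::all_of(feats),
                                        ~ mean(.x, na.rm = TRUE)),
                          .groups = "drop")
  agg <- agg[order(agg$compound), ]
  m <- as.matrix(agg[feats])
  rownames(m) <- agg$compound
  colnames(m) <- response_attributes()
  if (anyNA(m)) stop("missing feature values among retained compounds",
                     call. = FALSE)
  attr(m, "dose_uM") <- dose
  attr(m, "dropped") <- dropped
  m
}

#' Ward-linkage hierarchical clustering of compound profiles
#'
#' Agglomerative clustering of the rows of a response matrix under Ward's
#' minimum-variance criterion with Euclidean distances (`stats::hclust`,
#' method `"ward.D2"`). Features are left on their raw percentage scale by
#' default — the clustering operates on mean percent-abnormal values, so
#' standardisation (offered via `standardise = TRUE`) changes the tree and is
#' off unless requested. Merge heights equal `sqrt(2 * delta ESS)`, the
#' Euclidean-scaled increase in within-cluster sum of squares, and are
#' non-decreasing.
#'
#' @param m Numeric matrix, rows = compounds (>= 2), all values finite.
#' @param standardise Scale columns to unit variance first (default FALSE).
#' @return An `hclust` tree.
#' @export
ward_linkage <- function(m, standardise = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 rows to cluster", call. = FALSE)
  if (any(!is.finite(m))) stop("response matrix must be finite",
                               call. = FALSE)
  if (standardise) {
    s <- apply(m, 2, sd)
    s[s == 0] <- 1
    m <- sweep(m, 2, s, "/")
  }
  hclust(dist(m, method = "euclidean"), method = "ward.D2")
}

#' Cut a linkage tree into k clusters
#'
#' Removes the `k - 1` highest merges and returns one label per compound.
#' Labels are deterministic: cluster 1 is the cluster containing the first
#' row, cluster 2 the next new cluster in row order, and so on. The screen's
#' discrete assignment uses `k = 2`.
#'
#' @param tree An `hclust` from [ward_linkage()].
#' @param k Number of clusters (default 2; must not exceed the leaf count).
#' @return Named integer vector (compound -> cluster label).
#' @export
cut_to_k <- function(tree, k = 2) {
  n_leaves <- length(tree$order)
  if (k > n_leaves) stop("k exceeds the number of leaves", call. = FALSE)
  raw <- cutree(tree, k = k)
  relab <- match(raw, unique(raw))
  setNames(as.integer(relab), names(raw))
}

#' Export the cluster map and its tabular sidecars
#'
#' Writes (1) a cluster-map heatmap (PNG) with dendrogram-ordered rows and a
#' pharmaceutical-class colour strip, (2) a TSV of the leaf display order
#' with cluster labels, and (3) a TSV of the linkage merge list (pair,
#' height, size).
#'
#' @param m Response matrix from [mean_response_matrix()].
#' @param tree `hclust` from [ward_linkage()].
#' @param assignment Cluster labels from [cut_to_k()].
#' @param annotations Named character vector or tibble mapping every row of
#'   `m` to a pharmaceutical class.
#' @param path_prefix Output path prefix; writes `<prefix>_clustermap.png`,
#'   `<prefix>_leaves.tsv`, `<prefix>_linkage.tsv`.
#' @param plot Render the PNG (default TRUE).
#' @return Invisibly, the named list of written paths.
#' @export
export_clustermap <- function(m, tree, assignment, annotations,
                              path_prefix, plot = TRUE) {
  if (is.data.frame(annotations)) {
    annotations <- setNames(annotations$class, annotations$compound)
  }
  missing_ann <- setdiff(rownames(m), names(annotations))
  if (length(missing_ann)) {
    stop("missing class annotation for: ",
         paste(missing_ann, collapse = ", "), call. = FALSE)
  }
  leaves <- tibble::tibble(
    position = seq_along(tree$order),
    compound = tree$labels[tree$order],
    cluster = unname(assignment[tree$labels[tree$order]]),
    class = unname(annotations[tree$labels[tree$order]]))
  linkage <- tibble::tibble(
    merge_a = tree$merge[, 1], merge_b = tree$merge[, 2],
    height = tree$height,
    size = vapply(seq_len(nrow(tree$merge)), function(i) {
      count_leaves <- function(x) {
        if (x < 0) 1L else
          count_leaves(tree$merge[x, 1]) + count_leaves(tree$merge[x, 2])
      }
      count_leaves(i)
    }, integer(1)))

  paths <- list(leaves = paste0(path_prefix, "_leaves.tsv"),
                linkage = paste0(path_prefix, "_linkage.tsv"),
                png = paste0(path_prefix, "_clustermap.png"))
  readr::write_tsv(leaves, paths$leaves)
  readr::write_tsv(linkage, paths$linkage)
  if (plot) {
    ann_row <- data.frame(class = unname(annotations[rownames(m)]),
                          cluster = factor(unname(assignment[rownames(m)])),
                          row.names = rownames(m))
    png(paths$png, width = 1400, height = 200 + 40 * nrow(m), res = 144)
    pheatmap::pheatmap(m, cluster_rows = tree, cluster_cols = FALSE,
                       annotation_row = ann_row)
    dev.off()
  } else {
    paths$png <- NULL
  }
  invisible(paths)
}
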