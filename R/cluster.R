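signature_matrix <- function(signatures, mode = c("relative", "absolute", "row_scaled")) {
  mode <- match.arg(mode)
  value_col <- if (mode == "relative") "relative_pct" else "fitted_um"
  wide <- signatures$curves |>
    dplyr::select("metabolite", "position", dplyr::all_of(value_col)) |>
    tidyr::pivot_wider(names_from = "position", values_from = dplyr::all_of(value_col))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$metabolite
  if (anyNA(m)) stop("signatures are not on a common grid", call. = FALSE)
  if (mode == "row_scaled") m <- scale_rows(m)
  m
}

scale_rows <- function(m) {
  t(apply(m, 1, function(r) {
    s <- sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
}

#' Pairwise distances between kinetic signatures
#'
#' Euclidean distance between fitted curve vectors. The default mode uses
#' the relative (%) curves: on absolute concentrations, high-abundance
#' analytes (glucose, in mM) would dominate every distance regardless of
#' shape. Absolute and row-scaled modes are provided for sensitivity
#' analysis.
#'
#' @param signatures A `kinetic_signatures` object.
#' @param mode `"relative"` (default), `"absolute"` or `"row_scaled"`.
#' @return A `dist` object labeled by metabolite.
#' @export
signature_distance_matrix <- function(signatures,
                                      mode = c("relative", "absolute", "row_scaled")) {
  stats::dist(signature_matrix(signatures, mode), method = "euclidean")
}

#' Agglomerative clustering of signatures
#'
#' Standard hierarchical clustering of the signature distance matrix;
#' complete linkage by default.
#'
#' @param distances A `dist` object from [signature_distance_matrix()].
#' @param linkage `"complete"` (default), `"average"` or `"ward"`
#'   (Ward.D2).
#' @return An `hclust` tree.
#' @export
hierarchical_cluster <- function(distances, linkage = c("complete", "average", "ward")) {
  linkage <- match.arg(linkage)
  method <- if (linkage == "ward") "ward.D2" else linkage
  hclust(distances, method = method)
}

#' Cut the cluster tree at a height threshold
#'
#' Clusters are the connected components after removing merges above
#' `height`; ids are renumbered 1..k by order of first appearance along the
#' dendrogram leaf order, so cluster 1 always contains the leftmost leaf.
#'
#' @param tree An `hclust` tree.
#' @param height Cut height (default 35, the reference threshold on
#'   relative-percent curves).
#' @return Tibble `metabolite`, `cluster`.
#' @export
cut_tree <- function(tree, height = 35) {
  stopifnot(height >= 0)
  cl <- cutree(tree, h = height)
  leaf_order <- tree$labels[tree$order]
  first_seen <- unique(cl[leaf_order])
  remap <- stats::setNames(seq_along(first_seen), first_seen)
  tibble::tibble(
    metabolite = names(cl),
    cluster = unname(remap[as.character(cl)])
  )
}

#' Cluster median shape templates
#'
#' Pointwise median of member relative curves per cluster, labeled with the
#' segment-slope pattern classifier. Singleton clusters reproduce their
#' member's curve exactly.
#'
#' @param assignment Tibble from [cut_tree()].
#' @param signatures A `kinetic_signatures` object.
#' @inheritParams classify_kinetic_pattern
#' @return A `shape_templates` object: list with `curves` (tibble
#'   `cluster`, `position`, `median_pct`) and `info` (tibble `cluster`,
#'   `n_members`, `members`, `pattern_class`).
#' @export
derive_templates <- function(assignment, signatures,
                             boundaries = c(25, 75, 100), sustained_band = 20,
                             late_ratio = 0.5) {
  joined <- dplyr::inner_join(signatures$curves, assignment, by = "metabolite")
  if (!setequal(assignment$metabolite, unique(signatures$curves$metabolite))) {
    stop("assignment does not cover the signature panel", call. = FALSE)
  }
  curves <- joined |>
    dplyr::group_by(.data$cluster, .data$position) |>
    dplyr::summarise(median_pct = median(.data$relative_pct), .groups = "drop")
  info <- curves |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      pattern_class = classify_kinetic_pattern(.data$median_pct, .data$position,
                                               boundaries, sustained_band, late_ratio),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      assignment |>
        dplyr::group_by(.data$cluster) |>
        dplyr::summarise(n_members = dplyr::n(),
                         members = paste(.data$metabolite, collapse = ", "),
                         .groups = "drop"),
      by = "cluster"
    )
  structure(list(curves = curves, info = info), class = "shape_templates")
}

#' @export
print.shape_templates <- function(x, ...) {
  cat("<shape_templates>", nrow(x$info), "cluster template(s)\n")
  print(x$info, ...)
  invisible(x)
}

#' Row-scaled heatmap matrix in dendrogram order
#'
#' Display-only export: each metabolite row of the fitted concentration
#' matrix is centered and scaled to unit variance (zero-variance rows set
#' to 0) and rows are ordered by the dendrogram leaf order. Never feeds
#' back into clustering.
#'
#' @param signatures A `kinetic_signatures` object.
#' @param tree The `hclust` tree used for ordering.
#' @return A numeric matrix (metabolites x grid positions).
#' @export
heatmap_export <- function(signatures, tree) {
  m <- scale_rows(signature_matrix(signatures, "absolute"))
  m[tree$labels[tree$order], , drop = FALSE]
}

#' Cluster kinetic signatures into shape templates
#'
#' Convenience wrapper: distance matrix, hierarchical tree, height cut and
#' cluster median templates in one step.
#'
#' @inheritParams signature_distance_matrix
#' @inheritParams hierarchical_cluster
#' @inheritParams cut_tree
#' @inheritParams derive_templates
#' @return A `signature_clusters` object: list with `tree` (`hclust`),
#'   `assignment`, `templates`, `mode`, `linkage`, `cut_height`.
#' @export
cluster_signatures <- function(signatures, mode = "relative",
                               linkage = "complete", cut_height = 35,
                               boundaries = c(25, 75, 100),
                               sustained_band = 20, late_ratio = 0.5) {
  d <- signature_distance_matrix(signatures, mode)
  tree <- hierarchical_cluster(d, linkage)
  assignment <- cut_tree(tree, cut_height)
  templates <- derive_templates(assignment, signatures,
                                boundaries, sustained_band, late_ratio)
  structure(
    list(tree = tree, assignment = assignment, templates = templates,
         mode = mode, linkage = linkage, cut_height = cut_height),
    class = "signature_clusters"
  )
}

#' @export
print.signature_clusters <- function(x, ...) {
  cat("<signature_clusters>", max(x$assignment$cluster), "clusters at height",
      x$cut_height, "(", x$linkage, "linkage,", x$mode, "curves )\n")
  print(x$templates$info, ...)
  invisible(x)
}

#' @describeIn cluster_signatures Tidy the cluster assignment (one row per
#'   metabolite).
#' @param x A `signature_clusters` object.
#' @param ... Unused.
#' @method tidy signature_clusters
#' @export
tidy.signature_clusters <- function(x, ...) {
  dplyr::left_join(x$assignment, x$templates$info, by = "cluster")
}

#' @describeIn cluster_signatures One-row summary (cluster count, cut
#'   height, linkage, mode).
#' @method glance signature_clusters
#' @export
glance.signature_clusters <- function(x, ...) {
  tibble::tibble(
    n_clusters = max(x$assignment$cluster),
    cut_height = x$cut_height, linkage = x$linkage, mode = x$mode,
    n_metabolites = nrow(x$assignment)
  )
}
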