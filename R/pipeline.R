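#' Merge predictor strength and kinetic pattern into marker headlines
#'
#' The final two-step classification: a metabolite's predictor class (from
#' fold change + significance) is combined with its kinetic pattern class
#' (from the fitted signature) into a headline such as
#' `"strong predictor, late marker"`. Metabolites that fail the predictor
#' thresholds are `"not selected"` regardless of pattern. A pure join:
#' input order never changes any headline.
#'
#' @param records A [biomarker_table()] result.
#' @param patterns Tibble `metabolite`, `pattern_class`
#'   ([signature_patterns()]).
#' @param assignment Optional cluster assignment ([cut_tree()]) to carry
#'   cluster ids along.
#' @return Tibble `metabolite`, `predictor_class`, `pattern_class`,
#'   (`cluster`), `headline`.
#' @export
classify_markers <- function(records, patterns, assignment = NULL) {
  a <- sort(unique(records$metabolite))
  b <- sort(unique(patterns$metabolite))
  if (!identical(a, b)) {
    stop("metabolite panels differ between records and patterns: ",
         paste(c(setdiff(a, b), setdiff(b, a)), collapse = ", "),
         call. = FALSE)
  }
  out <- records |>
    dplyr::select("metabolite", "predictor_class", "mfc", "p_adj") |>
    dplyr::inner_join(patterns, by = "metabolite") |>
    dplyr::mutate(
      headline = ifelse(
        .data$predictor_class == "none", "not selected",
        paste0(.data$predictor_class, " predictor, ", .data$pattern_class, " marker")
      )
    )
  if (!is.null(assignment)) {
    out <- dplyr::left_join(out, assignment, by = "metabolite") |>
      dplyr::relocate("cluster", .after = "pattern_class")
  }
  out
}

#' Run the full kinetic-biomarker pipeline
#'
#' Executes the complete workflow on a tidy cohort: manual exclusions,
#' rescaling to the relative-workload axis, linear interpolation onto the
#' common grid, cohort median extraction, MFC + signed-rank biomarker
#' ranking with FDR control, polynomial kinetic-signature fitting,
#' hierarchical clustering into shape templates, pattern classification,
#' and the final marker headlines. Deterministic: identical input and
#' configuration give identical output.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param exclusions Optional exclusion list ([apply_exclusions()]).
#' @param grid_step,recovery_position Grid controls ([position_grid()]).
#' @param degree Polynomial degree ([fit_kinetic_signatures()]).
#' @param alpha,moderate_cut,strong_cut,min_pairs Ranking controls
#'   ([biomarker_table()]).
#' @param cluster_mode,linkage,cut_height Clustering controls
#'   ([cluster_signatures()]).
#' @param boundaries,sustained_band,late_ratio Pattern-classifier controls
#'   ([classify_kinetic_pattern()]).
#' @return A `metakin_result` list: `biomarkers`, `signatures`, `clusters`,
#'   `patterns`, `classification`, `medians`, `curves`, `volcano`,
#'   `heatmap`, `config`.
#' @export
run_pipeline <- function(cohort, exclusions = NULL,
                         grid_step = 1, recovery_position = 117, degree = 9,
                         alpha = 0.001, moderate_cut = 1.20, strong_cut = 1.40,
                         min_pairs = 6, cluster_mode = "relative",
                         linkage = "complete", cut_height = 35,
                         boundaries = c(25, 75, 100), sustained_band = 20,
                         late_ratio = 0.5) {
  config <- list(
    grid_step = grid_step, recovery_position = recovery_position,
    degree = degree, alpha = alpha, moderate_cut = moderate_cut,
    strong_cut = strong_cut, min_pairs = min_pairs,
    cluster_mode = cluster_mode, linkage = linkage, cut_height = cut_height,
    boundaries = boundaries, sustained_band = sustained_band,
    late_ratio = late_ratio
  )
  cohort <- validate_cohort(cohort)
  if (!is.null(exclusions)) cohort <- apply_exclusions(cohort, exclusions)
  rescaled <- rescale_cohort(cohort, recovery_position)
  grid <- position_grid(grid_step, recovery_position)
  curves <- interpolate_cohort(rescaled, grid)
  medians <- extract_median_curves(curves)
  biomarkers <- biomarker_table(curves, medians, alpha = alpha,
                                moderate_cut = moderate_cut,
                                strong_cut = strong_cut, min_pairs = min_pairs)
  signatures <- fit_kinetic_signatures(medians, degree)
  clusters <- cluster_signatures(signatures, cluster_mode, linkage, cut_height,
                                 boundaries, sustained_band, late_ratio)
  patterns <- signature_patterns(signatures, boundaries, sustained_band, late_ratio)
  classification <- classify_markers(biomarkers, patterns, clusters$assignment)
  structure(
    list(
      biomarkers = biomarkers, signatures = signatures, clusters = clusters,
      patterns = patterns, classification = classification,
      medians = medians, curves = curves,
      volcano = volcano_table(biomarkers),
      heatmap = heatmap_export(signatures, clusters$tree),
      config = config
    ),
    class = "metakin_result"
  )
}

#' @export
print.metakin_result <- function(x, ...) {
  cat("<metakin_result>\n")
  cat("  metabolites:", nrow(x$biomarkers), "\n")
  cat("  clusters:   ", max(x$clusters$assignment$cluster),
      "at cut height", x$config$cut_height, "\n")
  sel <- x$classification[x$classification$headline != "not selected", ]
  cat("  candidates: ", nrow(sel), "\n")
  if (nrow(sel) > 0) {
    print(dplyr::arrange(sel[, c("metabolite", "mfc", "p_adj", "headline")],
                         dplyr::desc(.data$mfc)), n = 15)
  }
  invisible(x)
}

#' @describeIn run_pipeline Tidy the final marker classification.
#' @param x A `metakin_result`.
#' @param ... Unused.
#' @method tidy metakin_result
#' @export
tidy.metakin_result <- function(x, ...) x$classification

#' @describeIn run_pipeline One-row run summary.
#' @method glance metakin_result
#' @export
glance.metakin_result <- function(x, ...) {
  tibble::tibble(
    n_metabolites = nrow(x$biomarkers),
    n_strong = sum(x$biomarkers$predictor_class == "strong"),
    n_moderate = sum(x$biomarkers$predictor_class == "moderate"),
    n_clusters = max(x$clusters$assignment$cluster),
    degree = x$config$degree,
    cut_height = x$config$cut_height
  )
}

#' Volcano plot of biomarker candidates
#'
#' log2 MFC against -log10 adjusted P with guide lines at the moderate and
#' strong fold-change cuts and the significance level.
#'
#' @param records A [biomarker_table()] result.
#' @param alpha,moderate_cut,strong_cut Guide-line positions.
#' @return A ggplot object.
#' @export
plot_volcano <- function(records, alpha = 0.001, moderate_cut = 1.20,
                         strong_cut = 1.40) {
  ggplot2::ggplot(records,
                  ggplot2::aes(.data$log2_mfc, .data$neglog10_p,
                               colour = .data$predictor_class)) +
    ggplot2::geom_hline(yintercept = -log10(alpha), colour = "blue",
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = log2(moderate_cut), colour = "blue",
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = log2(strong_cut), colour = "darkgreen",
                        linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(log[2] ~ "(MFC)"),
                  y = expression(-log[10] ~ "(adjusted P)"),
                  colour = "predictor") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_kinetic_signatures Relative kinetic signatures, one line
#'   per metabolite, on the default -20% to 40% display band.
#' @param object A `kinetic_signatures` object.
#' @method autoplot kinetic_signatures
#' @export
autoplot.kinetic_signatures <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(.data$position, .data$relative_pct,
                               colour = .data$metabolite)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::coord_cartesian(ylim = c(-20, 40)) +
    ggplot2::labs(x = "relative workload position (%)",
                  y = "relative concentration change (%)") +
    ggplot2::theme_minimal()
}

#' @describeIn derive_templates Cluster shape templates, one panel per
#'   cluster with its pattern label.
#' @param object A `shape_templates` object.
#' @param ... Unused.
#' @method autoplot shape_templates
#' @export
autoplot.shape_templates <- function(object, ...) {
  dat <- dplyr::left_join(object$curves, object$info, by = "cluster") |>
    dplyr::mutate(panel = paste0("cluster ", .data$cluster, " (",
                                 .data$pattern_class, ")"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$position, .data$median_pct)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "relative workload position (%)",
                  y = "median relative change (%)") +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Heatmap of row-scaled fitted curves in dendrogram order
#'
#' @param result A `metakin_result`.
#' @return A ggplot object.
#' @export
plot_signature_heatmap <- function(result) {
  m <- result$heatmap
  dat <- tibble::as_tibble(m, rownames = "metabolite") |>
    tidyr::pivot_longer(-"metabolite", names_to = "position",
                        values_to = "z") |>
    dplyr::mutate(position = as.numeric(.data$position),
                  metabolite = factor(.data$metabolite, levels = rev(rownames(m))))
  ggplot2::ggplot(dat, ggplot2::aes(.data$position, .data$metabolite,
                                    fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "darkred", mid = "white",
                                  high = "navy") +
    ggplot2::labs(x = "relative workload position (%)", y = NULL,
                  fill = "row z") +
    ggplot2::theme_minimal()
}
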