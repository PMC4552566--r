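#' Locate the extrema of a median curve
#'
#' Global minimum and maximum with earliest-index tie breaking. A constant
#' curve degenerates to `idx_min == idx_max` (and an MFC of 1 downstream).
#'
#' @param values Numeric curve values (fully defined).
#' @return List with `idx_min`, `idx_max` (1-based indices), `conc_min`,
#'   `conc_max`.
#' @export
locate_extrema <- function(values) {
  stopifnot(length(values) > 0, !anyNA(values))
  list(
    idx_min = which.min(values), idx_max = which.max(values),
    conc_min = min(values), conc_max = max(values)
  )
}

#' Directional maximum fold change
#'
#' The MFC is oriented by order of occurrence of the extrema on the median
#' curve: conc_max / conc_min when the minimum occurs first (MFC >= 1),
#' conc_min / conc_max otherwise (MFC <= 1); a flat curve gives 1.
#'
#' @param extrema Output of [locate_extrema()].
#' @return The MFC (positive scalar).
#' @export
compute_mfc <- function(extrema) {
  if (extrema$conc_min <= 0) {
    stop("MFC undefined: minimum concentration is not positive", call. = FALSE)
  }
  if (extrema$idx_min == extrema$idx_max) return(1)
  if (extrema$idx_min < extrema$idx_max) {
    extrema$conc_max / extrema$conc_min
  } else {
    extrema$conc_min / extrema$conc_max
  }
}

#' Per-subject concentration pairs at the median-curve extrema
#'
#' For one metabolite, extracts each subject's interpolated values at the
#' positions of the median curve's minimum and maximum. Subjects whose
#' observed support does not cover both positions are dropped (and
#' counted); because rest and recovery samples anchor every series and
#' interior gaps are bridged, drops occur only when boundary samples were
#' excluded.
#'
#' @param curves Interpolated curves ([interpolate_cohort()]) for one or
#'   more metabolites.
#' @param metabolite Metabolite name.
#' @param pos_min,pos_max Grid positions of the median extrema.
#' @return A tibble `subject_id`, `x` (value at `pos_min`), `y` (value at
#'   `pos_max`), with attribute `"n_dropped"`.
#' @export
paired_samples_at_extrema <- function(curves, metabolite, pos_min, pos_max) {
  cm <- curves[curves$metabolite == metabolite, ]
  wide <- cm |>
    dplyr::filter(.data$position %in% c(pos_min, pos_max)) |>
    dplyr::mutate(which = ifelse(.data$position == pos_min, "x", "y")) |>
    dplyr::select("subject_id", "which", "value_um") |>
    tidyr::pivot_wider(names_from = "which", values_from = "value_um")
  if (pos_min == pos_max) wide$y <- wide$x
  if (!"x" %in% names(wide)) wide$x <- NA_real_
  if (!"y" %in% names(wide)) wide$y <- NA_real_
  ok <- !is.na(wide$x) & !is.na(wide$y)
  out <- wide[ok, c("subject_id", "x", "y")]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Shapiro-Wilk normality screen
#'
#' Report-only check of the concentration samples entering the paired test;
#' the pipeline always proceeds nonparametrically regardless of the
#' outcome, so that all metabolites are tested on the same (rank) scale.
#'
#' @param values Numeric sample.
#' @param alpha Significance level (default 0.01).
#' @return List with `flag` (`"pass"`, `"fail"`, `"not_assessed"`),
#'   `statistic`, `p`.
#' @export
normality_screen <- function(values, alpha = 0.01) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(unique(values)) == 1) {
    return(list(flag = "not_assessed", statistic = NA_real_, p = NA_real_))
  }
  sw <- shapiro.test(values)
  list(flag = if (sw$p.value < alpha) "fail" else "pass",
       statistic = unname(sw$statistic), p = sw$p.value)
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (the classic signed-rank treatment). With
#' no ties among the absolute differences the exact signed-rank null
#' distribution is used at any n; with ties, mid-ranks with the normal
#' approximation and continuity correction. All differences zero gives
#' P = 1.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `p` (two-sided), `statistic` (V), `n_used` (pairs
#'   after zero removal), `branch` (`"exact"`, `"approx"`, `"degenerate"`).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- y - x
  d <- d[!is.na(d)]
  d <- d[d != 0]
  if (length(d) == 0) {
    return(list(p = 1, statistic = NA_real_, n_used = 0L, branch = "degenerate"))
  }
  ties <- anyDuplicated(abs(d)) > 0
  wt <- suppressWarnings(
    wilcox.test(d, mu = 0, alternative = "two.sided",
                exact = !ties, correct = TRUE)
  )
  list(p = min(wt$p.value, 1), statistic = unname(wt$statistic),
       n_used = length(d), branch = if (ties) "approx" else "exact")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: sort ascending, adj_(i) = min over j >= i of
#' p_(j) * m / j, capped at 1, mapped back to input order.
#'
#' @param p Vector of raw p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
fdr_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Predictor-strength classification
#'
#' Thresholds act on the effective fold-change magnitude
#' M = max(MFC, 1/MFC), so decreasing metabolites are judged symmetrically:
#' strong if M > `strong_cut` and adjusted P < `alpha`; moderate if
#' M > `moderate_cut` and adjusted P < `alpha`; otherwise none.
#'
#' @param mfc Directional MFC values.
#' @param p_adj FDR-adjusted p-values.
#' @param alpha Significance level (default 0.001).
#' @param moderate_cut,strong_cut MFC magnitude thresholds (defaults 1.20,
#'   1.40).
#' @return Character vector: `"none"`, `"moderate"` or `"strong"`.
#' @export
classify_predictor <- function(mfc, p_adj, alpha = 0.001,
                               moderate_cut = 1.20, strong_cut = 1.40) {
  m <- pmax(mfc, 1 / mfc)
  dplyr::case_when(
    m > strong_cut & p_adj < alpha ~ "strong",
    m > moderate_cut & p_adj < alpha ~ "moderate",
    TRUE ~ "none"
  )
}

#' Rank dynamic biomarker candidates
#'
#' The volcano-stage analysis: per metabolite, locate the extrema of the
#' cohort median curve, compute the directional MFC, extract each subject's
#' interpolated concentrations at the two extremum positions, run the
#' paired Wilcoxon signed-rank test, adjust across metabolites by
#' Benjamini-Hochberg, and classify predictor strength.
#'
#' @param curves Interpolated per-subject curves ([interpolate_cohort()]).
#' @param medians Median curves ([extract_median_curves()]); computed from
#'   `curves` when omitted.
#' @param alpha,moderate_cut,strong_cut Passed to [classify_predictor()].
#' @param min_pairs Minimum usable pairs for testing (default 6); below it
#'   the metabolite's P is set to `NA` and flagged.
#' @param shapiro_alpha Level of the report-only normality screen.
#' @return A tibble with one row per metabolite: `mfc`, `log2_mfc`,
#'   `p_raw`, `p_adj`, `neglog10_p`, `predictor_class`, extremum positions
#'   and concentrations, pair counts, test branch and normality flags.
#' @export
biomarker_table <- function(curves, medians = NULL, alpha = 0.001,
                            moderate_cut = 1.20, strong_cut = 1.40,
                            min_pairs = 6, shapiro_alpha = 0.01) {
  if (is.null(medians)) medians <- extract_median_curves(curves)
  rows <- medians |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$position)
      ex <- locate_extrema(df$median_um)
      pos_min <- df$position[ex$idx_min]
      pos_max <- df$position[ex$idx_max]
      pairs <- paired_samples_at_extrema(curves, key$metabolite, pos_min, pos_max)
      sw_min <- normality_screen(pairs$x, shapiro_alpha)
      sw_max <- normality_screen(pairs$y, shapiro_alpha)
      if (ex$idx_min == ex$idx_max) {
        test <- list(p = 1, statistic = NA_real_, n_used = 0L, branch = "degenerate")
      } else if (nrow(pairs) < min_pairs) {
        test <- list(p = NA_real_, statistic = NA_real_,
                     n_used = nrow(pairs), branch = "skipped")
      } else {
        test <- wilcoxon_signed_rank(pairs$x, pairs$y)
      }
      tibble::tibble(
        mfc = compute_mfc(ex),
        pos_min = pos_min, pos_max = pos_max,
        conc_min = ex$conc_min, conc_max = ex$conc_max,
        p_raw = test$p, test_branch = test$branch,
        n_pairs = nrow(pairs), n_dropped = attr(pairs, "n_dropped"),
        normal_at_min = sw_min$flag, normal_at_max = sw_max$flag
      )
    }) |>
    dplyr::ungroup()
  rows |>
    dplyr::mutate(
      log2_mfc = log2(.data$mfc),
      p_adj = fdr_adjust(.data$p_raw),
      neglog10_p = -log10(.data$p_adj),
      predictor_class = classify_predictor(.data$mfc, .data$p_adj, alpha,
                                           moderate_cut, strong_cut)
    ) |>
    dplyr::relocate("metabolite", "mfc", "log2_mfc", "p_raw", "p_adj",
                    "neglog10_p", "predictor_class")
}

#' Volcano-plot data
#'
#' The exact data behind the volcano plot: effect size and significance per
#' metabolite.
#'
#' @param records A [biomarker_table()] result.
#' @return Tibble `metabolite`, `log2_mfc`, `neglog10_p`,
#'   `predictor_class`.
#' @export
volcano_table <- function(records) {
  dplyr::select(records, "metabolite", "log2_mfc", "neglog10_p", "predictor_class")
}
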