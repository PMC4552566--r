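#' Rescale subject trajectories onto the relative-workload axis
#'
#' Maps every sample of every subject-metabolite series onto the common
#' axis: rest = 0, each workload level at 100 * W / W_max (W_max is the
#' subject's maximum reached workload), recovery at `recovery_position`
#' (default 117, the reference cohort's median relative recovery time).
#' Missing concentrations are dropped together with their positions; series
#' left with fewer than 3 usable samples are skipped with a warning.
#'
#' @param cohort A validated cohort tibble.
#' @param recovery_position Relative position assigned to the recovery
#'   sample (percent, default 117).
#' @return A tibble with columns `subject_id`, `metabolite`, `position`,
#'   `value_um`, positions strictly increasing within each series.
#' @export
rescale_cohort <- function(cohort, recovery_position = 117) {
  res <- cohort |>
    dplyr::group_by(.data$subject_id, .data$metabolite) |>
    dplyr::group_modify(function(df, key) {
      w_max <- max(df$workload_w, na.rm = TRUE)
      pos <- dplyr::case_when(
        df$stage == "rest" ~ 0,
        df$stage == "recovery" ~ recovery_position,
        TRUE ~ 100 * df$workload_w / w_max
      )
      keep <- !is.na(df$concentration_um)
      tibble::tibble(position = pos[keep], value_um = df$concentration_um[keep])
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subject_id, .data$metabolite, .data$position)

  counts <- dplyr::count(res, .data$subject_id, .data$metabolite)
  thin <- counts[counts$n < 3, ]
  if (nrow(thin) > 0) {
    warning("skipping ", nrow(thin),
            " series with fewer than 3 usable samples (e.g. subject ",
            thin$subject_id[1], ", ", thin$metabolite[1], ")", call. = FALSE)
    res <- dplyr::anti_join(res, thin, by = c("subject_id", "metabolite"))
  }
  res
}

#' Median relative recovery position of a cohort
#'
#' When sampling time stamps are available, the recovery sample is placed
#' at the cohort median of 100 * t_recovery / t_max (t_max the time of the
#' maximum-workload sample). Without time stamps the configured default is
#' used.
#'
#' @param cohort A cohort tibble.
#' @param default Fallback position (default 117).
#' @return The median relative recovery position (percent).
#' @export
median_recovery_position <- function(cohort, default = 117) {
  per_subj <- cohort |>
    dplyr::distinct(.data$subject_id, .data$stage, .data$time_min, .data$workload_w) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      t_max = {
        lev <- grepl("^level_", .data$stage)
        if (any(lev)) .data$time_min[lev][which.max(.data$workload_w[lev])] else NA_real_
      },
      t_rec = if (any(.data$stage == "recovery"))
        .data$time_min[.data$stage == "recovery"][1] else NA_real_,
      .groups = "drop"
    )
  ratio <- 100 * per_subj$t_rec / per_subj$t_max
  ratio <- ratio[is.finite(ratio)]
  if (length(ratio) == 0) {
    message("no usable time stamps; using default recovery position ", default)
    return(default)
  }
  median(ratio)
}

#' Common interpolation grid
#'
#' Evenly spaced relative-workload positions from 0 to the recovery
#' position; 0, 100 and the recovery position are always included exactly.
#'
#' @param step Grid step (default 1, i.e. 118 points for recovery at 117).
#' @param recovery_position End of the grid (default 117).
#' @return Numeric vector of grid positions.
#' @export
position_grid <- function(step = 1, recovery_position = 117) {
  sort(unique(c(seq(0, recovery_position, by = step), 100, recovery_position)))
}

#' Linearly interpolate rescaled series onto the common grid
#'
#' Piecewise-linear interpolation between consecutive observed samples; no
#' extrapolation outside a series' observed support (grid points before the
#' first or after the last observed sample are simply absent for that
#' subject). Interior gaps — e.g. a missing maximum-load sample — are
#' bridged by the single connecting segment.
#'
#' @param rescaled Output of [rescale_cohort()].
#' @param grid Grid positions from [position_grid()].
#' @return A tibble `subject_id`, `metabolite`, `position`, `value_um`
#'   restricted to each series' observed support, with the grid attached as
#'   attribute `"grid"`.
#' @export
interpolate_cohort <- function(rescaled, grid = position_grid()) {
  out <- rescaled |>
    dplyr::group_by(.data$subject_id, .data$metabolite) |>
    dplyr::group_modify(function(df, key) {
      support <- grid[grid >= min(df$position) & grid <= max(df$position)]
      tibble::tibble(
        position = support,
        value_um = approx(df$position, df$value_um, xout = support,
                          method = "linear", ties = "ordered")$y
      )
    }) |>
    dplyr::ungroup()
  attr(out, "grid") <- grid
  out
}

#' Pointwise median curves across subjects
#'
#' The cohort median at every grid position, per metabolite, ignoring
#' subjects whose support does not reach the position. Medians over even
#' counts are the mean of the two central order statistics. Taking the
#' median here is the pipeline's outlier defence: single aberrant subjects
#' cannot move the curve.
#'
#' @param curves Output of [interpolate_cohort()].
#' @return A tibble `metabolite`, `position`, `median_um` covering the full
#'   grid; a grid position with no contributing subject raises an error
#'   naming the position.
#' @export
extract_median_curves <- function(curves) {
  grid <- attr(curves, "grid")
  med <- curves |>
    dplyr::group_by(.data$metabolite, .data$position) |>
    dplyr::summarise(median_um = median(.data$value_um), .groups = "drop")
  if (!is.null(grid)) {
    cover <- med |>
      dplyr::group_by(.data$metabolite) |>
      dplyr::summarise(missing = list(setdiff(grid, .data$position)), .groups = "drop")
    bad <- cover[lengths(cover$missing) > 0, ]
    if (nrow(bad) > 0) {
      stop("no subject covers grid position(s) ",
           paste(head(bad$missing[[1]], 3), collapse = ", "),
           " for metabolite ", bad$metabolite[1], call. = FALSE)
    }
    attr(med, "grid") <- grid
  }
  med
}
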