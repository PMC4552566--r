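fit_poly_one <- function(position, values, degree) {
  n <- length(position)
  if (n <= degree) {
    warning("curve has ", n, " points; reducing polynomial degree to ", n - 1,
            call. = FALSE)
    degree <- n - 1
  }
  xn <- position / max(position)  # [0,1] abscissa for conditioning
  V <- outer(xn, 0:degree, `^`)
  fit <- lm.fit(V, values)
  fitted <- drop(V %*% fit$coefficients)
  list(coefficients = unname(fit$coefficients), fitted = fitted,
       rss = sum((values - fitted)^2), degree = degree)
}

#' Fit polynomial kinetic signatures to median curves
#'
#' Ordinary least squares of a degree-`degree` polynomial (default nine,
#' the degree giving a smooth but faithful representation of incremental
#' exercise trajectories) to each metabolite's median concentration curve.
#' The abscissa is linearly mapped to [0, 1] before fitting because a raw
#' high-degree Vandermonde on 0-117 is catastrophically ill-conditioned;
#' reported coefficients a_0 ... a_n live on that normalized axis. Fitted
#' values are re-expressed as the relative curve
#' 100 * (f(s) - f(0)) / f(0), i.e. percent change versus the modeled
#' concentration at rest, which removes concentration scale and makes
#' metabolites comparable.
#'
#' @param medians Median curves from [extract_median_curves()].
#' @param degree Polynomial degree (default 9; reduced with a warning when
#'   a curve has too few points).
#' @return A `kinetic_signatures` object: list with `curves` (tibble
#'   `metabolite`, `position`, `median_um`, `fitted_um`, `relative_pct`),
#'   `coefficients` (tibble `metabolite`, `term`, `estimate`), `stats`
#'   (per-metabolite residual sum of squares and degree) and `degree`.
#' @export
fit_kinetic_signatures <- function(medians, degree = 9) {
  fits <- medians |>
    dplyr::arrange(.data$metabolite, .data$position) |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_split() |>
    purrr::map(function(df) {
      f <- fit_poly_one(df$position, df$median_um, degree)
      f0 <- f$fitted[which.min(df$position)]
      if (f0 <= 0) {
        stop("nonphysical fit: modeled rest concentration <= 0 for ",
             df$metabolite[1], call. = FALSE)
      }
      list(
        curves = tibble::tibble(
          metabolite = df$metabolite[1], position = df$position,
          median_um = df$median_um, fitted_um = f$fitted,
          relative_pct = 100 * (f$fitted - f0) / f0
        ),
        coefficients = tibble::tibble(
          metabolite = df$metabolite[1],
          term = 0:f$degree, estimate = f$coefficients
        ),
        stats = tibble::tibble(metabolite = df$metabolite[1],
                               rss = f$rss, degree = f$degree,
                               n_points = nrow(df))
      )
    })
  structure(
    list(
      curves = purrr::list_rbind(purrr::map(fits, "curves")),
      coefficients = purrr::list_rbind(purrr::map(fits, "coefficients")),
      stats = purrr::list_rbind(purrr::map(fits, "stats")),
      degree = degree
    ),
    class = "kinetic_signatures"
  )
}

#' @export
print.kinetic_signatures <- function(x, ...) {
  cat("<kinetic_signatures> degree", x$degree, "fits for",
      nrow(x$stats), "metabolite(s)\n")
  print(x$stats, ...)
  invisible(x)
}

#' Convert an absolute fitted curve to relative concentration changes
#'
#' rel(s) = 100 * (f(s) - f(0)) / f(0); exactly 0 at rest and invariant
#' under rescaling of the absolute curve.
#'
#' @param fitted Fitted concentration values (first element at position 0).
#' @return Relative curve in percent.
#' @export
to_relative <- function(fitted) {
  f0 <- fitted[1]
  if (is.na(f0) || f0 <= 0) stop("fitted value at rest must be > 0", call. = FALSE)
  100 * (fitted - f0) / f0
}

#' Classify a kinetic response pattern
#'
#' Operationalizes the five-way response taxonomy. A curve whose total
#' relative range stays below `sustained_band` percentage points (twice the
#' +/-10% band accepted as biological and analytical variability) is
#' sustained. Otherwise the axis is partitioned into early [0, 25), halving
#' [25, 75), late [75, 100] and delayed (100, recovery] segments; each
#' segment is scored by its concentration excursion per unit position
#' (range of the curve within the segment divided by segment length — a
#' mean-absolute-slope measure that is insensitive to smoothing ripple yet
#' still sees transient dips). The decision then follows the taxonomy's
#' semantics rather than a bare argmax, which would be fragile for the
#' uniform ramp whose early/halving/late scores tie exactly:
#' \enumerate{
#'   \item delayed, if the recovery segment scores at least as high as
#'     every exercise segment (change concentrated after exercise);
#'   \item late, if the final exercise quarter still accumulates change at
#'     no less than `late_ratio` of the strongest exercise segment's rate
#'     (a late response keeps changing up to the end of exercise, whereas
#'     early and halving responses have plateaued);
#'   \item otherwise early or halving, whichever of the two segments
#'     scores higher (exact ties resolve to the later one).
#' }
#'
#' @param relative_pct Relative curve (percent) on the full grid.
#' @param positions Grid positions (same length).
#' @param boundaries Segment boundaries, default `c(25, 75, 100)`.
#' @param sustained_band Total-range threshold in percentage points
#'   (default 20).
#' @param late_ratio Minimum ratio of the late-segment score to the best
#'   exercise-segment score for a "late" call (default 0.5).
#' @return One of `"sustained"`, `"early"`, `"halving"`, `"late"`,
#'   `"delayed"`.
#' @export
classify_kinetic_pattern <- function(relative_pct, positions,
                                     boundaries = c(25, 75, 100),
                                     sustained_band = 20, late_ratio = 0.5) {
  stopifnot(length(relative_pct) == length(positions), length(boundaries) == 3)
  ord <- order(positions)
  positions <- positions[ord]
  relative_pct <- relative_pct[ord]
  if (diff(range(relative_pct)) < sustained_band) return("sustained")
  lo <- c(min(positions), boundaries)
  hi <- c(boundaries, max(positions))
  score <- vapply(seq_along(lo), function(i) {
    inside <- positions >= lo[i] & positions <= hi[i]
    if (sum(inside) < 2) return(0)
    diff(range(relative_pct[inside])) / (hi[i] - lo[i])
  }, numeric(1))
  names(score) <- c("early", "halving", "late", "delayed")
  if (score["delayed"] >= max(score[1:3])) return("delayed")
  if (score["late"] >= late_ratio * max(score[1:2])) return("late")
  if (score["early"] > score["halving"]) "early" else "halving"
}

#' Match a relative curve against the basis-shape library
#'
#' The basis-function route: each template kind (with default shape
#' constants, unit amplitude) is fitted to the curve by least-squares
#' amplitude scaling, and the kind with the smallest residual norm wins.
#' The flat (sustained) shape cannot be amplitude-fitted; it is selected
#' whenever no other shape achieves a fitted amplitude of at least
#' `amplitude_min` percent, mirroring the variability band below which a
#' response is not considered a real change. For the hockey stick the
#' breakpoint is free and chosen over a coarse grid.
#'
#' @param relative_pct Relative curve (percent).
#' @param positions Grid positions.
#' @param amplitude_min Minimum fitted amplitude (percent) for a non-flat
#'   shape to be accepted (default 10).
#' @return A tibble with one row per candidate shape (`kind`, `amplitude`,
#'   `rss`, `selected`), best match first.
#' @export
match_template <- function(relative_pct, positions, amplitude_min = 10) {
  kinds <- setdiff(template_kinds, "sustained_const")
  shapes <- list()
  for (k in kinds) {
    if (k == "delayed_hockey") {
      for (bp in seq(75, 110, by = 5)) {
        shapes[[paste0(k, "@", bp)]] <-
          list(kind = k,
               b = 100 * template_value(template_spec(k, 1, 1, breakpoint = bp),
                                        positions))
      }
    } else {
      shapes[[k]] <- list(kind = k,
                          b = 100 * template_value(template_spec(k, 1, 1), positions))
    }
  }
  rows <- purrr::map(shapes, function(sh) {
    b <- sh$b
    amp <- sum(b * relative_pct) / sum(b * b)
    # amp scales a unit-amplitude basis whose own excursion is 100%, so the
    # fitted response amplitude in percent is 100 * amp
    tibble::tibble(kind = sh$kind, amplitude = 100 * amp,
                   rss = sum((relative_pct - amp * b)^2))
  }) |> purrr::list_rbind()
  rows <- rows |>
    dplyr::group_by(.data$kind) |>
    dplyr::slice_min(.data$rss, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  rows <- dplyr::bind_rows(
    rows,
    tibble::tibble(kind = "sustained_const", amplitude = 0,
                   rss = sum(relative_pct^2))
  )
  eligible <- rows$kind == "sustained_const" | abs(rows$amplitude) >= amplitude_min
  best <- rows$kind[eligible][which.min(rows$rss[eligible])]
  rows |>
    dplyr::mutate(selected = .data$kind == best) |>
    dplyr::arrange(dplyr::desc(.data$selected), .data$rss)
}

#' Pattern classes of fitted signatures
#'
#' @param signatures A `kinetic_signatures` object.
#' @inheritParams classify_kinetic_pattern
#' @return Tibble `metabolite`, `pattern_class`.
#' @export
signature_patterns <- function(signatures, boundaries = c(25, 75, 100),
                               sustained_band = 20, late_ratio = 0.5) {
  signatures$curves |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(
      pattern_class = classify_kinetic_pattern(.data$relative_pct, .data$position,
                                               boundaries, sustained_band, late_ratio),
      .groups = "drop"
    )
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @describeIn fit_kinetic_signatures Tidy the fitted coefficients (one row
#'   per metabolite and polynomial term, on the normalized abscissa).
#' @param x A `kinetic_signatures` object.
#' @param ... Unused.
#' @method tidy kinetic_signatures
#' @export
tidy.kinetic_signatures <- function(x, ...) x$coefficients

#' @describeIn fit_kinetic_signatures Per-metabolite fit summaries (degree,
#'   residual sum of squares, points).
#' @method glance kinetic_signatures
#' @export
glance.kinetic_signatures <- function(x, ...) x$stats
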