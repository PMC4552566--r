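#' @importFrom rlang .data
#' @importFrom stats median approx sd setNames p.adjust shapiro.test wilcox.test
#'   hclust cutree as.dist rnorm runif rlnorm quantile
#' @importFrom utils head tail
NULL

cohort_columns <- c(
  "subject_id", "group", "metabolite", "stage",
  "workload_w", "time_min", "concentration_um"
)

cohort_groups <- c("male_average", "male_athletic", "female_average", "female_athletic")

#' Stage label for the k-th workload level
#'
#' Levels follow the incremental protocol: level k corresponds to a workload
#' of 50 + 25 * (k - 1) W (the 25 W step is skipped, exercise starts at 50 W).
#'
#' @param k Level index (1-based).
#' @return Character vector of stage labels, e.g. `"level_3"`.
#' @keywords internal
level_stage <- function(k) paste0("level_", k)

level_workload <- function(k) 50 + 25 * (k - 1)

stage_order_key <- function(stage) {
  key <- rep(NA_real_, length(stage))
  key[stage == "rest"] <- 0
  key[stage == "recovery"] <- Inf
  lev <- grepl("^level_\\d+$", stage)
  key[lev] <- as.numeric(sub("^level_", "", stage[lev]))
  key
}

#' Validate a tidy longitudinal cohort table
#'
#' Checks the seven-column schema, stage labels, the 50 + 25 * (k - 1) W
#' workload ladder, per-subject workload monotonicity, uniqueness of stages
#' within a subject-metabolite series, and the presence of rest and recovery
#' rows for every subject and metabolite. Concentrations may be missing
#' (explicit `NA`), stages may not.
#'
#' @param cohort A data frame in the cohort schema.
#' @return The cohort, invisibly, ordered by subject, metabolite and stage.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_stage <- setdiff(unique(cohort$stage), c("rest", "recovery"))
  bad_stage <- bad_stage[!grepl("^level_\\d+$", bad_stage)]
  if (length(bad_stage) > 0) {
    stop("unrecognized stage label(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }
  conc <- cohort$concentration_um
  if (any(!is.na(conc) & conc <= 0)) {
    stop("non-missing concentrations must be > 0", call. = FALSE)
  }
  lev <- grepl("^level_", cohort$stage)
  k <- as.numeric(sub("^level_", "", cohort$stage[lev]))
  expected_w <- level_workload(k)
  if (any(abs(cohort$workload_w[lev] - expected_w) > 1e-9)) {
    bad <- unique(cohort$subject_id[lev][abs(cohort$workload_w[lev] - expected_w) > 1e-9])
    stop("workload does not follow the 50 + 25*(k-1) W ladder for subject(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }

  out <- cohort |>
    dplyr::mutate(.key = stage_order_key(.data$stage)) |>
    dplyr::arrange(.data$subject_id, .data$metabolite, .data$.key)

  checks <- out |>
    dplyr::group_by(.data$subject_id, .data$metabolite) |>
    dplyr::summarise(
      has_rest = any(.data$stage == "rest"),
      has_recovery = any(.data$stage == "recovery"),
      dup_stage = anyDuplicated(.data$stage) > 0,
      n_levels = sum(is.finite(.data$.key) & .data$.key > 0),
      level_gap = {
        ks <- sort(.data$.key[is.finite(.data$.key) & .data$.key > 0])
        length(ks) > 0 && !identical(as.numeric(ks), as.numeric(seq_along(ks)))
      },
      .groups = "drop"
    )
  fail <- function(cond, what) {
    if (any(cond)) {
      bad <- unique(checks$subject_id[cond])
      stop("cohort validation: ", what, " for subject(s): ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  fail(!checks$has_rest, "missing rest stage")
  fail(!checks$has_recovery, "missing recovery stage")
  fail(checks$dup_stage, "duplicated stage labels")
  fail(checks$level_gap, "non-contiguous (non-monotone) workload levels")

  invisible(dplyr::select(out, -".key"))
}

#' Read a tidy longitudinal cohort table
#'
#' Reads a long CSV with one row per subject x metabolite x sampling stage
#' and columns `subject_id`, `group`, `metabolite`, `stage`, `workload_w`,
#' `time_min`, `concentration_um`. Missing concentrations must be empty
#' cells (never 0 or sentinel values). Stages are ordered
#' rest, level_1 ... level_K, recovery and validated against the incremental
#' protocol (25 W steps from 50 W).
#'
#' @param path Path to the CSV file.
#' @return A tibble in validated stage order.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  cohort <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      group = readr::col_character(),
      metabolite = readr::col_character(),
      stage = readr::col_character(),
      workload_w = readr::col_double(),
      time_min = readr::col_double(),
      concentration_um = readr::col_double()
    )
  )
  validate_cohort(cohort)
}

#' Write a tabular result to CSV
#'
#' Plain readr-based export; missing values are written as empty cells so
#' that `read_cohort()` / `readr::read_csv()` round-trip without loss.
#'
#' @param records A data frame (may have zero rows; must have columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (ncol(as.data.frame(records)) == 0) {
    stop("refusing to write a table with no columns", call. = FALSE)
  }
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Blank manually excluded measurements
#'
#' Applies a visual-inspection exclusion list to a cohort: matching
#' concentration values are set to missing, rows are never dropped. An
#' exclusion row targets one subject and stage and either a single
#' metabolite or all metabolites (`"*"`). Stage identity (not workload) is
#' the key, because the recovery sample carries no workload. Unknown
#' subjects raise a warning, not an error.
#'
#' @param cohort A cohort table.
#' @param exclusions A data frame with columns `subject_id`, `stage`,
#'   `metabolite` (use `"*"` for all metabolites). An empty data frame is a
#'   no-op.
#' @return The cohort with matching concentrations set to `NA`; the number
#'   of blanked values is reported via `message()` and attached as attribute
#'   `"n_removed"`.
#' @export
apply_exclusions <- function(cohort, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0) {
    attr(cohort, "n_removed") <- 0L
    return(cohort)
  }
  stopifnot(all(c("subject_id", "stage", "metabolite") %in% names(exclusions)))
  unknown <- setdiff(unique(as.character(exclusions$subject_id)),
                     unique(as.character(cohort$subject_id)))
  if (length(unknown) > 0) {
    warning("exclusion list references unknown subject(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  hit <- rep(FALSE, nrow(cohort))
  for (i in seq_len(nrow(exclusions))) {
    m <- cohort$subject_id == as.character(exclusions$subject_id[i]) &
      cohort$stage == exclusions$stage[i]
    if (exclusions$metabolite[i] != "*") {
      m <- m & cohort$metabolite == exclusions$metabolite[i]
    }
    hit <- hit | m
  }
  n_removed <- sum(hit & !is.na(cohort$concentration_um))
  cohort$concentration_um[hit] <- NA_real_
  message("apply_exclusions: blanked ", n_removed, " concentration value(s)")
  attr(cohort, "n_removed") <- n_removed
  cohort
}

#' Default manual exclusion list of the reference study design
#'
#' The three documented visual-inspection removals: all recovery samples of
#' subject 14, all samples at the 175 W level (level 6) of subject 35, and
#' the resting glucose value of subject 42.
#'
#' @return A three-row exclusion tibble.
#' @export
default_exclusions <- function() {
  tibble::tibble(
    subject_id = c("14", "35", "42"),
    stage = c("recovery", level_stage(6), "rest"),
    metabolite = c("*", "*", "glucose")
  )
}
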