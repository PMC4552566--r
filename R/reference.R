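#' Published reference biomarker ranking for the 30-metabolite panel
#'
#' The published candidate-selection table for the incremental
#' cycle-ergometry cohort the synthetic generator emulates: per metabolite
#' the directional maximum fold change, its log2, the FDR-adjusted P of the
#' paired signed-rank test at the median-curve extrema, and -log10 of that
#' P, all at the printed precision (2 decimal places; P to three
#' significant digits). Used to calibrate the default simulation panel and
#' to cross-check the package's volcano transforms.
#'
#' @return A 30-row tibble: `metabolite`, `mfc`, `log2_mfc`, `p_adj`,
#'   `neglog10_p`.
#' @export
reference_biomarkers <- function() {
  path <- system.file("extdata", "reference_biomarkers.csv",
                      package = "metakin", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    metabolite = readr::col_character(), .default = readr::col_double()
  ))
}
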