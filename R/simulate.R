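template_kinds <- c(
  "sustained_const", "early_log", "halving_sigmoid",
  "late_linear", "late_quadratic", "late_exponential", "delayed_hockey"
)

#' Ground-truth kinetic shape template
#'
#' A template describes one metabolite's true relative-concentration
#' trajectory on the common relative-workload axis (rest = 0, individual
#' maximum = 100, recovery = 117). All shapes are anchored at 0 at rest and
#' reach the full `amplitude` at the end of exercise (position 100); during
#' recovery the exercise shapes hold their final value, while
#' `delayed_hockey` stays flat up to its breakpoint and rises linearly to
#' `amplitude` at position 117.
#'
#' Shape definitions (s = relative position, a = amplitude):
#' \itemize{
#'   \item `sustained_const`: 0 everywhere (noise-only trajectory).
#'   \item `early_log`: a * log(1 + beta*s) / log(1 + 100*beta), `beta`
#'     fixing where the change concentrates early (default 0.2).
#'   \item `halving_sigmoid`: logistic step centred at s = 50 with time
#'     constant `tau` (default 8), normalized to run from 0 to a.
#'   \item `late_linear` / `late_quadratic`: a * (s/100), a * (s/100)^2.
#'   \item `late_exponential`: a * (exp(g*s/100) - 1) / (exp(g) - 1),
#'     growth `g` (default 3), concentrating change near exercise end.
#'   \item `delayed_hockey`: 0 up to breakpoint `k` (default 100), then
#'     linear to a at position 117 (the recovery overshoot shape).
#' }
#' An optional early transient `dip` (relative fraction, default 0) adds
#' `dip * sin(pi*s/25)^2` on positions 0-25, mimicking metabolites with an
#' initial drop before their main response.
#'
#' @param kind One of `"sustained_const"`, `"early_log"`,
#'   `"halving_sigmoid"`, `"late_linear"`, `"late_quadratic"`,
#'   `"late_exponential"`, `"delayed_hockey"`.
#' @param baseline Resting concentration in uM (> 0).
#' @param amplitude Target relative change at end of exercise (fraction,
#'   may be negative, |amplitude| <= 5).
#' @param dip Optional early-dip amplitude (fraction), applied on [0, 25].
#' @param beta,tau,g,breakpoint Shape constants, see above.
#' @return A `template_spec` list.
#' @export
template_spec <- function(kind, baseline = 1, amplitude = 0, dip = 0,
                          beta = 0.2, tau = 8, g = 3, breakpoint = 100) {
  kind <- match.arg(kind, template_kinds)
  stopifnot(baseline > 0, abs(amplitude) <= 5)
  structure(
    list(kind = kind, baseline = baseline, amplitude = amplitude, dip = dip,
         beta = beta, tau = tau, g = g, breakpoint = breakpoint),
    class = "template_spec"
  )
}

#' Evaluate a template's true relative deviation from baseline
#'
#' @param spec A [template_spec()].
#' @param s Relative positions in [0, 117] (vectorized).
#' @return Relative deviation from baseline (fraction of baseline; 0 at
#'   rest by construction for every kind).
#' @export
template_value <- function(spec, s) {
  stopifnot(inherits(spec, "template_spec"))
  if (any(s < 0 | s > 117)) {
    stop("template position s must lie in [0, 117]", call. = FALSE)
  }
  a <- spec$amplitude
  se <- pmin(s, 100)  # exercise shapes hold their final value in recovery
  base <- switch(
    spec$kind,
    sustained_const = rep(0, length(s)),
    early_log = a * log(1 + spec$beta * se) / log(1 + 100 * spec$beta),
    halving_sigmoid = {
      sig <- function(u) 1 / (1 + exp(-(u - 50) / spec$tau))
      a * (sig(se) - sig(0)) / (sig(100) - sig(0))
    },
    late_linear = a * se / 100,
    late_quadratic = a * (se / 100)^2,
    late_exponential = a * (exp(spec$g * se / 100) - 1) / (exp(spec$g) - 1),
    delayed_hockey = {
      k <- spec$breakpoint
      ifelse(s <= k, 0, a * (s - k) / (117 - k))
    }
  )
  if (spec$dip != 0) {
    early <- s <= 25
    base[early] <- base[early] + spec$dip * sin(pi * s[early] / 25)^2
  }
  base
}

#' True directional maximum fold change of a template
#'
#' Evaluates the template on a fine grid and applies the directional MFC
#' rule: (1 + max)/(1 + min) when the minimum occurs first, the reciprocal
#' otherwise.
#'
#' @param spec A [template_spec()].
#' @return The true MFC (scalar).
#' @export
template_true_mfc <- function(spec) {
  s <- seq(0, 117, by = 0.1)
  r <- template_value(spec, s)
  i_min <- which.min(r)
  i_max <- which.max(r)
  if (i_min == i_max) return(1)
  if (i_min < i_max) (1 + r[i_max]) / (1 + r[i_min]) else (1 + r[i_min]) / (1 + r[i_max])
}

#' Expected response-pattern class of a template
#'
#' Classifies the noise-free template curve itself with the package's
#' segment-slope classifier, so simulated metabolites carry the pattern
#' label the pipeline is expected to recover.
#'
#' @param spec A [template_spec()].
#' @inheritParams classify_kinetic_pattern
#' @return One of `"sustained"`, `"early"`, `"halving"`, `"late"`,
#'   `"delayed"`.
#' @export
template_pattern <- function(spec, boundaries = c(25, 75, 100),
                             sustained_band = 20) {
  s <- seq(0, 117, by = 0.5)
  classify_kinetic_pattern(100 * template_value(spec, s), s,
                           boundaries = boundaries,
                           sustained_band = sustained_band)
}

#' Default 30-metabolite simulation panel
#'
#' A panel emulating a targeted exercise-metabolomics assay: 11
#' acylcarnitines, 18 amino acids and glucose. Shapes and amplitudes are
#' calibrated to the published kinetic behavior of the corresponding
#' analytes (e.g. acetylcarnitine rising steeply to about +67% late in
#' exercise after a small initial dip; valerylcarnitine dipping about -16%
#' early; methionine a sigmoid plateau near +13%; glucose a hockey-stick
#' recovery overshoot). The majority of the panel changes by less than the
#' +/-10% variability band and therefore carries a sustained expected
#' pattern.
#'
#' @return A named list of [template_spec()] objects.
#' @export
default_panel <- function() {
  p <- list(
    carnitine_C0          = template_spec("late_linear",      35,   -0.08),
    acetylcarnitine_C2    = template_spec("late_exponential",  8,    0.67, dip = -0.10),
    propionylcarnitine_C3 = template_spec("late_quadratic",    0.35, 0.52, dip = -0.05),
    methylmalonylcarnitine_C3DCM = template_spec("late_quadratic", 0.05, 0.26),
    butyrylcarnitine_C4   = template_spec("late_quadratic",    0.20, 0.27, dip = -0.05),
    valerylcarnitine_C5   = template_spec("late_linear",       0.12, 0.13, dip = -0.16),
    hydroxyvalerylcarnitine_C5OH = template_spec("late_linear", 0.04, 0.26),
    hexadecanoylcarnitine_C16 = template_spec("late_linear",   0.08, 0.12),
    octadecanoylcarnitine_C18 = template_spec("late_linear",   0.04, 0.17),
    octadecenoylcarnitine_C181 = template_spec("late_linear",  0.10, 0.10),
    octadecadienylcarnitine_C182 = template_spec("delayed_hockey", 0.03, 0.21),
    alanine        = template_spec("late_linear",     350, 0.42),
    arginine       = template_spec("late_linear",      95, 0.36),
    aspartic_acid  = template_spec("early_log",        15, -0.12),
    citrulline     = template_spec("late_linear",      30, 0.12),
    glutamic_acid  = template_spec("late_linear",      60, 0.12),
    glycine        = template_spec("late_linear",     230, 0.11),
    histidine      = template_spec("late_linear",      75, 0.14),
    lysine         = template_spec("late_linear",     170, 0.11),
    methionine     = template_spec("halving_sigmoid",  25, 0.13),
    ornithine      = template_spec("late_linear",      60, 0.19),
    phenylalanine  = template_spec("late_linear",      60, 0.14),
    proline        = template_spec("late_linear",     180, 0.11),
    serine         = template_spec("late_linear",     110, 0.11),
    threonine      = template_spec("late_linear",     130, 0.09),
    tryptophan     = template_spec("late_linear",      60, 0.18),
    tyrosine       = template_spec("late_linear",      60, 0.12),
    valine         = template_spec("late_linear",     220, 0.09),
    xleucine       = template_spec("late_linear",     150, 0.09),
    glucose        = template_spec("delayed_hockey", 4600, 0.25)
  )
  p
}

#' One-metabolite-per-shape test panel
#'
#' Seven metabolites, one per template kind, with well-separated amplitudes
#' large enough that none falls inside the sustained variability band.
#'
#' @return A named list of [template_spec()] objects.
#' @export
shape_panel <- function() {
  list(
    m_sustained = template_spec("sustained_const", 50, 0),
    m_early     = template_spec("early_log",       50, -0.30),
    m_halving   = template_spec("halving_sigmoid", 50, 0.50),
    m_late_lin  = template_spec("late_linear",     50, 0.32),
    m_late_quad = template_spec("late_quadratic",  50, 0.60),
    m_late_exp  = template_spec("late_exponential", 50, 0.80),
    m_delayed   = template_spec("delayed_hockey",  50, 0.40)
  )
}

subject_stage_table <- function(n_levels) {
  tibble::tibble(
    stage = c("rest", level_stage(seq_len(n_levels)), "recovery"),
    workload_w = c(0, level_workload(seq_len(n_levels)), NA_real_),
    # level j runs from 3(j-1) to 3j min; profiling samples at 2:30 into
    # each level, recovery sampled 5 min after the end of the last level
    time_min = c(0, 3 * (seq_len(n_levels) - 1) + 2.5, 3 * n_levels + 5)
  )
}

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))  # mean exactly 1
}

#' Simulate an incremental-exercise metabolomics cohort
#'
#' Generates a tidy cohort following the study protocol the package
#' targets: each subject cycles from 50 W in 25 W / 3 min increments up to
#' an individual maximum workload drawn uniformly from 150-425 W; blood is
#' sampled at rest, 2:30 min into every workload level, and 5 min after the
#' end of exercise (recovery). Per metabolite, concentration is
#' baseline * (1 + template_value(s)) * eps with s the relative-workload
#' position of the sample and eps multiplicative log-normal noise of mean 1
#' and coefficient of variation `noise_cv`. An optional log-normal
#' per-subject baseline spread (`baseline_cv`, default 0, i.e. the plain
#' multiplicative-noise model) is available for sensitivity analysis of
#' the median-based pipeline against between-subject abundance
#' variability. With probability `p_missing_max` a subject's maximum-load
#' sample is missing (all metabolites), as observed in practice when
#' sampling at exhaustion fails; rest and recovery samples are never
#' deleted.
#'
#' @param n_subjects Number of subjects (default 47).
#' @param panel Named list of [template_spec()]s (default [default_panel()]).
#' @param noise_cv CV of the multiplicative measurement noise (default 0.1).
#' @param p_missing_max Probability that a subject's maximum-load sample is
#'   missing (default 12/47).
#' @param baseline_cv CV of the optional per-subject baseline spread
#'   (default 0).
#' @param seed Optional RNG seed for full reproducibility.
#' @return A list with `cohort` (tidy cohort tibble) and `truth` (tibble
#'   with per-metabolite kind, baseline, amplitude, true MFC and expected
#'   pattern class).
#' @export
simulate_cohort <- function(n_subjects = 47, panel = default_panel(),
                            noise_cv = 0.1, p_missing_max = 12 / 47,
                            baseline_cv = 0, seed = NULL) {
  if (length(panel) == 0) stop("panel must contain at least one metabolite", call. = FALSE)
  stopifnot(noise_cv >= 0, noise_cv <= 1, p_missing_max >= 0, p_missing_max <= 1)
  if (!is.null(seed)) set.seed(seed)

  workload_steps <- seq(150, 425, by = 25)
  w_max <- sample(workload_steps, n_subjects, replace = TRUE)
  # group sizes follow the reference cohort composition (16/8/11/12)
  group_pool <- rep(cohort_groups, times = c(16, 8, 11, 12))
  groups <- if (n_subjects == 47) sample(group_pool) else
    sample(cohort_groups, n_subjects, replace = TRUE, prob = c(16, 8, 11, 12) / 47)

  subj <- purrr::map(seq_len(n_subjects), function(i) {
    n_lev <- (w_max[i] - 50) / 25 + 1
    st <- subject_stage_table(n_lev)
    st$position <- c(0, 100 * st$workload_w[-c(1, nrow(st))] / w_max[i], 117)
    drop_max <- runif(1) < p_missing_max
    st$subject_id <- as.character(i)
    st$group <- groups[i]
    st$.drop_max <- drop_max & st$stage == level_stage(n_lev)
    st
  }) |> purrr::list_rbind()

  met_names <- names(panel)
  cohort <- purrr::map(met_names, function(m) {
    sp <- panel[[m]]
    b_subj <- sp$baseline *
      (if (baseline_cv > 0) {
        s2 <- log(1 + baseline_cv^2)
        stats::setNames(rlnorm(n_subjects, -s2 / 2, sqrt(s2)), as.character(seq_len(n_subjects)))
      } else stats::setNames(rep(1, n_subjects), as.character(seq_len(n_subjects))))
    val <- b_subj[subj$subject_id] * (1 + template_value(sp, subj$position)) *
      lognormal_noise(nrow(subj), noise_cv)
    val[subj$.drop_max] <- NA_real_
    tibble::tibble(
      subject_id = subj$subject_id, group = subj$group, metabolite = m,
      stage = subj$stage, workload_w = subj$workload_w,
      time_min = subj$time_min, concentration_um = unname(val)
    )
  }) |> purrr::list_rbind()

  truth <- tibble::tibble(
    metabolite = met_names,
    kind = unname(purrr::map_chr(panel, "kind")),
    baseline_um = unname(purrr::map_dbl(panel, "baseline")),
    amplitude = unname(purrr::map_dbl(panel, "amplitude")),
    true_mfc = unname(purrr::map_dbl(panel, template_true_mfc)),
    true_pattern = unname(purrr::map_chr(panel, template_pattern))
  )
  list(cohort = validate_cohort(cohort), truth = truth)
}

#' Simulate the lactate gold-standard channel
#'
#' Lactate is the reference analyte for grading exertion: near-resting
#' levels during light work, then a steep rise to the individual maximum,
#' and a partial washout during recovery. The deterministic profile is
#' calibrated so cohort medians are 1.2 mM at rest, 8.5 mM at maximum
#' workload and 7.2 mM at recovery. Lactate is sampled 1:30 min into each
#' level (one minute before the metabolite-profiling sample).
#'
#' @inheritParams simulate_cohort
#' @return A tidy cohort-schema tibble, `metabolite = "lactate"`,
#'   concentrations in mM.
#' @export
lactate_reference <- function(n_subjects = 47, noise_cv = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lact <- function(s) {
    ifelse(s <= 100,
           1.2 + (8.5 - 1.2) * (s / 100)^3,
           8.5 - (8.5 - 7.2) * (s - 100) / 17)
  }
  workload_steps <- seq(150, 425, by = 25)
  w_max <- sample(workload_steps, n_subjects, replace = TRUE)
  purrr::map(seq_len(n_subjects), function(i) {
    n_lev <- (w_max[i] - 50) / 25 + 1
    st <- subject_stage_table(n_lev)
    st$time_min <- c(0, 3 * (seq_len(n_lev) - 1) + 1.5, 3 * n_lev + 5)
    pos <- c(0, 100 * st$workload_w[-c(1, nrow(st))] / w_max[i], 117)
    tibble::tibble(
      subject_id = as.character(i), group = NA_character_,
      metabolite = "lactate", stage = st$stage, workload_w = st$workload_w,
      time_min = st$time_min,
      concentration_um = lact(pos) * lognormal_noise(nrow(st), noise_cv)
    )
  }) |> purrr::list_rbind()
}
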