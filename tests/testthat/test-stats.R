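test_that("extrema location uses earliest-index tie breaking", {
  ex <- locate_extrema(c(2, 1, 4, 3))
  expect_equal(c(ex$idx_min, ex$idx_max), c(2, 3))
  tie <- locate_extrema(c(1, 4, 1, 4))
  expect_equal(c(tie$idx_min, tie$idx_max), c(1, 2))
  flat <- locate_extrema(c(5, 5, 5))
  expect_equal(flat$idx_min, flat$idx_max)
})

test_that("the directional MFC follows the order-of-occurrence rule", {
  expect_equal(compute_mfc(locate_extrema(c(2, 1, 4))), 4)
  expect_equal(compute_mfc(locate_extrema(c(4, 2, 1))), 0.25)
  expect_equal(compute_mfc(locate_extrema(c(3, 3, 3))), 1)
  expect_error(compute_mfc(locate_extrema(c(0, 1, 2))), "positive")

  set.seed(1)
  for (i in 1:50) {
    v <- runif(20, 1, 5)
    expect_equal(compute_mfc(locate_extrema(v)), mfc_scan_oracle(v))
    expect_equal(compute_mfc(locate_extrema(2.5 * v)),
                 compute_mfc(locate_extrema(v)))  # scale invariance
    if (which.min(v) != which.max(v) &&
        sum(v == min(v)) == 1 && sum(v == max(v)) == 1) {
      expect_equal(compute_mfc(locate_extrema(rev(v))),
                   1 / compute_mfc(locate_extrema(v)))
    }
  }
})

test_that("signed-rank test handles symmetry, zeros and reports its branch", {
  d <- c(1.2, 2.7, 0.4, 3.3, 5.1)
  sym <- wilcoxon_signed_rank(rep(0, 10), c(d, -d))
  expect_equal(sym$p, 1, tolerance = 1e-9)

  zero <- wilcoxon_signed_rank(1:4, 1:4)
  expect_equal(zero$p, 1)
  expect_equal(zero$branch, "degenerate")

  pos <- wilcoxon_signed_rank(rep(0, 5), c(0.3, 1.1, 2.2, 3.5, 4.1))
  expect_equal(pos$p, 0.0625)
  expect_equal(pos$branch, "exact")

  tied <- wilcoxon_signed_rank(rep(0, 8), c(1, 1, 1, 2, 2, 3, 3, 4))
  expect_equal(tied$branch, "approx")
  expect_true(tied$p > 0 && tied$p < 1)
})

test_that("normality screen passes normal samples and fails heavy tails", {
  set.seed(33)
  reps <- 400
  pass_normal <- mean(replicate(reps, {
    normality_screen(rnorm(50, 100, 10))$flag == "pass"
  }))
  expect_gte(pass_normal, 0.97)  # alpha = 0.01 screen
  fail_lnorm <- mean(replicate(reps, {
    normality_screen(rlnorm(50, 0, 1))$flag == "fail"
  }))
  expect_gte(fail_lnorm, 0.95)
  expect_equal(normality_screen(rep(3, 10))$flag, "not_assessed")
  expect_equal(normality_screen(c(1, 2))$flag, "not_assessed")
})

test_that("FDR adjustment matches the step-up definition", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.04, 6)), rep(0.04, 6))
  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p) && all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # order preserved
  }
})

test_that("predictor classification applies symmetric cuts and is monotone", {
  expect_equal(classify_predictor(1.97, 2.84e-13), "strong")
  expect_equal(classify_predictor(1.32, 2.38e-8), "moderate")
  expect_equal(classify_predictor(1.16, 9.81e-3), "none")
  expect_equal(classify_predictor(0.70, 1e-6), "strong")  # 1/0.70 > 1.40
  expect_equal(classify_predictor(1.25, 0.002), "none")   # significance gate

  lvl <- c(none = 0, moderate = 1, strong = 2)
  set.seed(5)
  for (i in 1:100) {
    mfc <- runif(1, 0.5, 2.5)
    p <- 10^runif(1, -10, 0)
    a <- lvl[classify_predictor(mfc, p)]
    b <- lvl[classify_predictor(max(mfc, 1 / mfc) * 1.1, p)]
    cc <- lvl[classify_predictor(mfc, p / 10)]
    expect_gte(b, a)
    expect_gte(cc, a)
  }
})

test_that("paired extraction keeps complete subjects and degenerates gracefully", {
  sim <- simulate_cohort(47, list(m = template_spec("late_linear", 10, 0.4)),
                         noise_cv = 0, p_missing_max = 0, seed = 6)
  curves <- interpolate_cohort(rescale_cohort(sim$cohort), position_grid())
  pairs <- paired_samples_at_extrema(curves, "m", 0, 100)
  expect_equal(nrow(pairs), 47)
  expect_equal(attr(pairs, "n_dropped"), 0)
  expect_equal(unique(round(pairs$y / pairs$x, 12)), 1.4)

  # bridged interior gaps still cover interior extrema positions
  sim2 <- simulate_cohort(47, list(m = template_spec("late_linear", 10, 0.4)),
                          noise_cv = 0, p_missing_max = 1, seed = 6)
  curves2 <- interpolate_cohort(rescale_cohort(sim2$cohort), position_grid())
  pairs2 <- paired_samples_at_extrema(curves2, "m", 0, 100)
  expect_equal(nrow(pairs2), 47)
})

test_that("biomarker table wires MFC, test, FDR and transforms together", {
  panel <- list(
    up = template_spec("late_linear", 10, 0.5),
    down = template_spec("early_log", 10, -0.3),
    flat = template_spec("sustained_const", 10, 0)
  )
  sim <- simulate_cohort(20, panel, noise_cv = 0.05, p_missing_max = 0, seed = 10)
  curves <- interpolate_cohort(rescale_cohort(sim$cohort), position_grid())
  tab <- biomarker_table(curves)
  expect_setequal(tab$metabolite, names(panel))
  expect_equal(tab$log2_mfc, log2(tab$mfc))
  expect_equal(tab$neglog10_p, -log10(tab$p_adj), tolerance = 1e-9)
  expect_equal(tab$p_adj, fdr_adjust(tab$p_raw))
  expect_true(all(tab$p_adj >= tab$p_raw & tab$p_adj <= 1))
  expect_true(tab$mfc[tab$metabolite == "up"] > 1)
  expect_true(tab$mfc[tab$metabolite == "down"] < 1)
  vol <- volcano_table(tab)
  expect_named(vol, c("metabolite", "log2_mfc", "neglog10_p", "predictor_class"))
})
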