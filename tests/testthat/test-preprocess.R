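test_that("rescaling maps workloads proportionally and anchors rest/recovery", {
  co <- toy_cohort(list(s1 = 5))  # levels 50..150 W
  r <- rescale_cohort(co)
  expect_equal(r$position,
               c(0, 100 * c(50, 75, 100, 125, 150) / 150, 117),
               tolerance = 1e-9)

  co3 <- toy_cohort(list(s1 = 3))  # max 100 W
  expect_equal(rescale_cohort(co3)$position, c(0, 50, 75, 100, 117))
})

test_that("missing samples drop their positions; thin series are skipped", {
  co <- toy_cohort(list(s9 = 5))
  co$concentration_um[co$stage == "level_5"] <- NA  # the 150 W sample
  r <- rescale_cohort(co)
  expect_false(100 %in% r$position)
  expect_equal(nrow(r), 6)

  thin <- toy_cohort(list(s1 = 5))
  thin$concentration_um[3:7] <- NA  # 2 usable samples left
  expect_warning(out <- rescale_cohort(thin), "fewer than 3")
  expect_equal(nrow(out), 0)
})

test_that("median recovery position is the cohort median of time ratios", {
  co <- toy_cohort(list(a = 4, b = 6, c = 8))
  co <- co |>
    dplyr::group_by(subject_id) |>
    dplyr::mutate(time_min = ifelse(stage == "recovery",
                                    1.17 * max(time_min[grepl("^level", stage)]),
                                    time_min)) |>
    dplyr::ungroup()
  expect_equal(median_recovery_position(co), 117)

  # distinct per-subject ratios 110, 117, 125 -> middle order statistic
  co2 <- toy_cohort(list(a = 4, b = 4, c = 4))
  ratio <- c(a = 1.10, b = 1.17, c = 1.25)
  co2 <- co2 |>
    dplyr::group_by(subject_id) |>
    dplyr::mutate(time_min = ifelse(stage == "recovery",
                                    ratio[subject_id[1]] * max(time_min[grepl("^level", stage)]),
                                    time_min)) |>
    dplyr::ungroup()
  expect_equal(median_recovery_position(co2), 117)

  no_time <- toy_cohort(list(a = 4))
  no_time$time_min <- NA_real_
  expect_message(val <- median_recovery_position(no_time), "default")
  expect_equal(val, 117)
})

test_that("interpolation is exact at nodes, linear between, bridging gaps", {
  r <- tibble::tibble(subject_id = "a", metabolite = "m",
                      position = c(0, 100), value_um = c(10, 20))
  ic <- interpolate_cohort(r, position_grid())
  expect_equal(ic$value_um[ic$position == 50], 15)
  expect_equal(ic$value_um[ic$position == 0], 10)
  expect_equal(ic$value_um[ic$position == 100], 20)
  expect_false(117 %in% ic$position)  # no extrapolation past the support

  # gap across a missing maximum: single bridging segment over (91.7, 117)
  r2 <- tibble::tibble(
    subject_id = "a", metabolite = "m",
    position = c(0, 50, 91.7, 117), value_um = c(10, 12, 14, 20)
  )
  ic2 <- interpolate_cohort(r2, position_grid())
  seg <- ic2[ic2$position > 91.7 & ic2$position < 117, ]
  expect_equal(seg$value_um,
               14 + (20 - 14) * (seg$position - 91.7) / (117 - 91.7),
               tolerance = 1e-9)
})

test_that("median curves are robust order statistics with the even-count rule", {
  mk <- function(sid, val) tibble::tibble(
    subject_id = sid, metabolite = "m",
    position = c(0, 60, 117), value_um = val
  )
  three <- dplyr::bind_rows(mk("a", rep(1, 3)), mk("b", rep(2, 3)),
                            mk("c", rep(9, 3)))
  med3 <- extract_median_curves(interpolate_cohort(three, position_grid()))
  expect_true(all(med3$median_um == 2))

  two <- dplyr::bind_rows(mk("a", rep(1, 3)), mk("b", rep(3, 3)))
  med2 <- extract_median_curves(interpolate_cohort(two, position_grid()))
  expect_true(all(med2$median_um == 2))
})

test_that("noiseless cohorts reproduce the generating template medians exactly", {
  sp <- template_spec("late_linear", 20, 0.32)
  sim <- simulate_cohort(15, list(m = sp), noise_cv = 0, p_missing_max = 0,
                         seed = 4)
  med <- extract_median_curves(
    interpolate_cohort(rescale_cohort(sim$cohort), position_grid())
  )
  expect_equal(med$median_um,
               20 * (1 + template_value(sp, med$position)),
               tolerance = 1e-12)
})

test_that("median extraction is homogeneous and interpolation preserves monotonicity", {
  set.seed(7)
  base <- purrr::map(1:5, function(i) tibble::tibble(
    subject_id = as.character(i), metabolite = "m",
    position = c(0, sort(runif(4, 5, 95)), 117),
    value_um = sort(runif(6, 1, 10))  # monotone series
  )) |> purrr::list_rbind()
  ic <- interpolate_cohort(base, position_grid())
  mono <- ic |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$value_um))
  expect_true(all(mono$ok))

  med1 <- extract_median_curves(ic)
  scaled <- dplyr::mutate(base, value_um = 3.7 * .data$value_um)
  med2 <- extract_median_curves(interpolate_cohort(scaled, position_grid()))
  expect_equal(med2$median_um, 3.7 * med1$median_um, tolerance = 1e-12)
})

test_that("a grid position nobody covers raises a named error", {
  r <- tibble::tibble(subject_id = "a", metabolite = "m",
                      position = c(10, 50, 117), value_um = c(1, 2, 3))
  ic <- interpolate_cohort(r, position_grid())
  expect_error(extract_median_curves(ic), "position")
})
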