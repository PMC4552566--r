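# signatures object with prescribed constant relative curves
const_signatures <- function(levels_pct, names_ = NULL) {
  g <- position_grid()
  if (is.null(names_)) names_ <- paste0("m", seq_along(levels_pct))
  curves <- purrr::map2(names_, levels_pct, function(nm, v) {
    tibble::tibble(metabolite = nm, position = g,
                   median_um = 10, fitted_um = 10,
                   relative_pct = rep(v, length(g)))
  }) |> purrr::list_rbind()
  structure(list(curves = curves,
                 coefficients = tibble::tibble(),
                 stats = tibble::tibble(metabolite = names_),
                 degree = 9),
            class = "kinetic_signatures")
}

random_signatures <- function(n, seed) {
  set.seed(seed)
  g <- position_grid()
  curves <- purrr::map(seq_len(n), function(i) {
    r <- cumsum(rnorm(length(g), 0, 2))
    r <- r - r[1]
    tibble::tibble(metabolite = sprintf("m%02d", i), position = g,
                   median_um = 10, fitted_um = 10 * (1 + r / 100),
                   relative_pct = r)
  }) |> purrr::list_rbind()
  structure(list(curves = curves, coefficients = tibble::tibble(),
                 stats = tibble::tibble(metabolite = unique(curves$metabolite)),
                 degree = 9),
            class = "kinetic_signatures")
}

test_that("signature distances are Euclidean, symmetric and zero on equals", {
  sig <- const_signatures(c(0, 0, 10))
  d <- as.matrix(signature_distance_matrix(sig))
  expect_equal(d["m1", "m2"], 0)
  expect_equal(d["m1", "m3"], 10 * sqrt(length(position_grid())))
  expect_equal(d, t(d))
  expect_equal(diag(d), c(m1 = 0, m2 = 0, m3 = 0))
})

test_that("agglomeration merges the close pair first; n leaves give n-1 merges", {
  sig <- const_signatures(c(0, 1, 10))
  tree <- hierarchical_cluster(signature_distance_matrix(sig))
  expect_equal(nrow(tree$merge), 2)
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))  # m1, m2 join first
  u <- sqrt(length(position_grid()))
  expect_equal(tree$height, c(1 * u, 10 * u))  # complete: max(d13, d23)

  big <- random_signatures(30, seed = 1)
  btree <- hierarchical_cluster(signature_distance_matrix(big))
  expect_equal(nrow(btree$merge), 29)
})

test_that("tree cutting spans the trivial extremes and is monotone in height", {
  sig <- random_signatures(20, seed = 2)
  tree <- hierarchical_cluster(signature_distance_matrix(sig))
  expect_equal(max(cut_tree(tree, 0)$cluster), 20)
  expect_equal(max(cut_tree(tree, max(tree$height))$cluster), 1)
  ks <- vapply(seq(0, max(tree$height), length.out = 25),
               function(h) max(cut_tree(tree, h)$cluster), numeric(1))
  expect_true(all(diff(ks) <= 0))
  # ids contiguous from 1, numbered by first-leaf order
  a <- cut_tree(tree, median(tree$height))
  expect_equal(sort(unique(a$cluster)), seq_len(max(a$cluster)))
})

test_that("cluster assignments ignore metabolite input order", {
  sig <- random_signatures(18, seed = 3)
  a <- cluster_signatures(sig, cut_height = 40)
  set.seed(99)
  perm <- sample(unique(sig$curves$metabolite))
  sig2 <- sig
  sig2$curves <- sig$curves |>
    dplyr::mutate(metabolite = factor(.data$metabolite, levels = perm)) |>
    dplyr::arrange(.data$metabolite, .data$position) |>
    dplyr::mutate(metabolite = as.character(.data$metabolite))
  b <- cluster_signatures(sig2, cut_height = 40)
  ja <- a$assignment[order(a$assignment$metabolite), ]
  jb <- b$assignment[order(b$assignment$metabolite), ]
  expect_true(same_partition(ja$cluster, jb$cluster))
})

test_that("templates are member medians: singletons exact, mirrors cancel", {
  g <- position_grid()
  ramp <- 30 * g / max(g)
  curves <- dplyr::bind_rows(
    tibble::tibble(metabolite = "plus", position = g, median_um = 10,
                   fitted_um = 10, relative_pct = ramp),
    tibble::tibble(metabolite = "minus", position = g, median_um = 10,
                   fitted_um = 10, relative_pct = -ramp),
    tibble::tibble(metabolite = "lone", position = g, median_um = 10,
                   fitted_um = 10, relative_pct = 100 * template_value(
                     template_spec("delayed_hockey", 1, 0.4), g))
  )
  sig <- structure(list(curves = curves, coefficients = tibble::tibble(),
                        stats = tibble::tibble(metabolite = c("plus", "minus", "lone")),
                        degree = 9), class = "kinetic_signatures")
  assignment <- tibble::tibble(metabolite = c("plus", "minus", "lone"),
                               cluster = c(1, 1, 2))
  tpl <- derive_templates(assignment, sig)
  mirror <- tpl$curves$median_pct[tpl$curves$cluster == 1]
  expect_true(all(mirror == 0))
  expect_equal(tpl$info$pattern_class[tpl$info$cluster == 1], "sustained")
  lone <- tpl$curves$median_pct[tpl$curves$cluster == 2]
  expect_equal(lone, curves$relative_pct[curves$metabolite == "lone"])
  expect_equal(tpl$info$pattern_class[tpl$info$cluster == 2], "delayed")
})

test_that("heatmap rows are centered, unit-scaled and display-only", {
  sig <- random_signatures(10, seed = 4)
  sig$curves$fitted_um[sig$curves$metabolite == "m01"] <- 4  # constant row
  cl <- cluster_signatures(sig, cut_height = 40)
  m <- heatmap_export(sig, cl$tree)
  expect_equal(rownames(m), cl$tree$labels[cl$tree$order])
  expect_true(all(m["m01", ] == 0))
  other <- m[rownames(m) != "m01", ]
  expect_true(all(abs(rowMeans(other)) < 1e-9))
  expect_true(all(abs(apply(other, 1, sd) - 1) < 1e-9))
  cl2 <- cluster_signatures(sig, cut_height = 40)  # unchanged by the export
  expect_identical(cl$assignment, cl2$assignment)
})
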