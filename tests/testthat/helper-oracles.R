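# Independent oracles and small fixture builders shared across tests.

# Full-enumeration two-sided signed-rank P over all 2^n sign assignments.
# Assumes no zero differences and no ties among |d|.
wilcoxon_enum_oracle <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Step-up FDR adjustment written directly from its definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- p[o] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Brute-force directional MFC: explicit scan with earliest-index ties.
mfc_scan_oracle <- function(v) {
  i_min <- 1L
  i_max <- 1L
  for (i in seq_along(v)) {
    if (v[i] < v[i_min]) i_min <- i
    if (v[i] > v[i_max]) i_max <- i
  }
  if (i_min == i_max) return(1)
  if (i_min < i_max) v[i_max] / v[i_min] else v[i_min] / v[i_max]
}

# Two partitions are the same up to label renaming.
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  ca <- outer(a, a, `==`)
  cb <- outer(b, b, `==`)
  identical(ca, cb)
}

# Hand-built cohort: one metabolite, explicit workload levels per subject.
toy_cohort <- function(levels_by_subject, metabolite = "met",
                       conc = function(stage_idx, n) 10 + stage_idx) {
  purrr::imap(levels_by_subject, function(n_lev, sid) {
    stages <- c("rest", paste0("level_", seq_len(n_lev)), "recovery")
    tibble::tibble(
      subject_id = sid, group = "male_average", metabolite = metabolite,
      stage = stages,
      workload_w = c(0, 50 + 25 * (seq_len(n_lev) - 1), NA),
      time_min = c(0, 3 * (seq_len(n_lev) - 1) + 2.5, 3 * n_lev + 5),
      concentration_um = conc(seq_along(stages), length(stages))
    )
  }) |> purrr::list_rbind()
}
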