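# shared fixtures, built in code

# printed MS/MS m/z values used for fidelity checks (2-decimal precision)
printed_mz <- list(
  a26_diag = 306.12, a23_diag = 408.15,
  core_y = c(y1 = 487.19, y2 = 690.27, y3_y4 = 1014.37, y4_y4 = 1176.43),
  antenna_y = c(y1 = 341.13, y2 = 544.21, y4_y5_y5 = 1233.45, y4_y5 = 1395.51)
)

# small long peak table: two samples, two compositions
tiny_peak_table <- function() {
  tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 4),
    class = rep(c("control", "melanoma"), each = 4),
    composition = rep(c("N4H5S2", "N4H5S2", "N5H6S2", "N5H6S2"), 2),
    isomer_index = rep(c(1L, 2L, 1L, 2L), 2),
    rt_min = rep(c(70.5, 72.0, 62.0, 63.0), 2),
    area = c(10, 30, 40, 20, 5, 15, 60, 20)
  )
}

# random valid peak table for property tests
random_peak_table <- function(n_samples = 6, n_iso = 8) {
  comps <- rep(c("N4H5S2", "N5H6S3"), length.out = n_iso)
  idx <- as.integer(stats::ave(seq_len(n_iso), comps, FUN = seq_along))
  tidyr::crossing(
    tibble::tibble(sample_id = sprintf("s%02d", seq_len(n_samples)),
                   class = rep(c("melanoma", "control"),
                               length.out = n_samples)),
    tibble::tibble(composition = comps, isomer_index = idx)
  ) |>
    dplyr::mutate(rt_min = 60 + isomer_index,
                  area = stats::rlnorm(dplyr::n(), log(100), 0.8))
}

# well-separated two-feature, two-class matrix
separable_matrix <- function(n_per_class = 10, gap = 8, seed = 11) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("x%02d", seq_len(2 * n_per_class)),
    class = rep(c("melanoma", "control"), each = n_per_class),
    f1 = c(stats::rnorm(n_per_class, gap), stats::rnorm(n_per_class, 0)),
    f2 = c(stats::rnorm(n_per_class, gap / 2), stats::rnorm(n_per_class, 0))
  )
}

# random small glycan topology for property tests
random_topology <- function() {
  n_ant <- sample(2:4, 1)
  n_sia <- sample(1:n_ant, 1)
  build_topology(
    n_antennae = n_ant,
    sialylation = sample(c("a23", "a26", "unknown"), n_sia, replace = TRUE),
    core_fucose = sample(c(TRUE, FALSE), 1),
    antenna_fucose = sample(0:n_ant, 1),
    lacnac = sample(0:1, 1)
  )
}
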