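#' Synthetic catalog of the 102 AGP N-glycan isomers
#'
#' A synthetic stand-in for the AGP isomer inventory: 102 complex-type,
#' sialylated N-glycan isomers across mono- to tetrasialylated
#' compositions with 0-3 fucoses and N-acetyllactosamine-elongated
#' variants, eluting in sialylation-ordered retention clusters
#' (monosialylated 43.49-47.15 min, bisialylated 61.36-75.31 min, tri-
#' and tetrasialylated 83.46-112.60 min). Isomer multiplicities honor
#' the structurally anchored ones (5 isomers of N4H5SF, 3 of N4H5S2,
#' 2 of N4H5S2F); baseline relative abundances are plausible synthetic
#' placeholders dominated by bi/triantennary species - the true
#' clinical abundances are not published. Within-class RSDs default to
#' 30 % (the tens-of-percent inter-individual scale).
#'
#' @return Tibble with one row per isomer: `composition`,
#'   `isomer_index`, `rt_min`, `baseline_mean_pct`, `rsd_pct`.
#' @examples
#' nrow(default_catalog()) # 102
#' @export
default_catalog <- function() {
  spec <- tibble::tribble(
    ~composition, ~n_isomers, ~glycan_pct,
    # monosialylated cluster
    "N4H5S",      3L,  2.0,
    "N4H5SF",     5L,  1.5,
    "N4H5SF2",    1L,  0.3,
    # bisialylated cluster
    "N4H5S2",     3L, 22.0,
    "N4H5S2F",    2L,  3.0,
    "N4H5S2F2",   2L,  0.8,
    "N5H6S2",     6L, 10.0,
    "N5H6S2F",    4L,  3.0,
    "N5H6S2F2",   2L,  0.8,
    "N6H7S2",     5L,  4.0,
    "N6H7S2F",    3L,  1.5,
    # trisialylated cluster
    "N5H6S3",     6L, 16.0,
    "N5H6S3F",    4L,  4.0,
    "N5H6S3F2",   3L,  1.5,
    "N5H6S3F3",   2L,  0.6,
    "N6H7S3",     6L,  8.0,
    "N6H7S3F",    4L,  3.0,
    "N6H7S3F2",   3L,  1.0,
    "N7H8S3",     3L,  0.8,
    # tetrasialylated cluster
    "N6H7S4",     8L,  7.0,
    "N6H7S4F",    5L,  3.0,
    "N6H7S4F2",   3L,  1.2,
    "N6H7S4F3",   2L,  0.5,
    "N7H8S4",     6L,  2.5,
    "N7H8S4F",    4L,  1.2,
    "N7H8S4F2",   2L,  0.5,
    "N8H9S4",     3L,  0.8,
    "N8H9S4F",    2L,  0.4
  )
  clusters <- list(`1` = c(43.49, 47.15), `2` = c(61.36, 75.31),
                   `3` = c(83.46, 99.50), `4` = c(99.80, 112.60))
  spec$n_neuac <- parse_composition(spec$composition)$n_neuac
  spec <- spec |>
    dplyr::group_by(.data$n_neuac) |>
    dplyr::mutate(cluster_pos = dplyr::row_number(),
                  cluster_n = dplyr::n()) |>
    dplyr::ungroup()
  out <- purrr::pmap_dfr(spec, function(composition, n_isomers, glycan_pct,
                                        n_neuac, cluster_pos, cluster_n) {
    k <- seq_len(n_isomers)
    # decreasing within-glycan split; earlier-eluting isomers larger
    wts <- rev(k) + 1
    rng <- clusters[[as.character(n_neuac)]]
    lo <- rng[1] + (rng[2] - rng[1]) * (cluster_pos - 1) / cluster_n
    hi <- rng[1] + (rng[2] - rng[1]) * cluster_pos / cluster_n
    tibble::tibble(
      composition = composition,
      isomer_index = k,
      rt_min = round(lo + (hi - lo) * (k - 0.5) / n_isomers, 2),
      baseline_mean_pct = glycan_pct * wts / sum(wts),
      rsd_pct = 30
    )
  })
  # renormalize so baselines sum to exactly 100 %
  out$baseline_mean_pct <- 100 * out$baseline_mean_pct / sum(out$baseline_mean_pct)
  out
}

#' Default class-effect map (melanoma vs control)
#'
#' Multiplicative effects on baseline isomer means in the melanoma
#' class, following the directions seen in the clinical panel:
#' downregulation of the nonfucosylated bisialylated N5H6S2 (strongest
#' in its later-eluting isomers 4 and 5) and upregulation of the
#' fucosylated N6H7S2F (strongest in isomer 3). `isomer_index = NA`
#' applies to all isomers of the composition.
#'
#' @return Tibble: `composition`, `isomer_index`, `effect`.
#' @export
default_effects <- function() {
  tibble::tribble(
    ~composition, ~isomer_index, ~effect,
    "N5H6S2",      4L,           0.50,
    "N5H6S2",      5L,           0.67,
    "N6H7S2F",     3L,           1.90,
    "N6H7S2F",     1L,           1.15,
    "N6H7S2F",     2L,           1.15
  )
}

#' Default isomer-ratio shifts (melanoma vs control)
#'
#' Fraction of the donor isomer's class-adjusted mean abundance moved to
#' the acceptor isomer in melanoma samples, emulating the shift toward
#' later-eluting (more alpha-2,6 sialylated) isomers of the same glycan.
#'
#' @return Tibble: `composition`, `donor`, `acceptor`, `fraction`.
#' @export
default_ratio_shifts <- function() {
  tibble::tribble(
    ~composition, ~donor, ~acceptor, ~fraction,
    "N5H6S3F",    1L,     2L,        0.15,
    "N6H7S2",     3L,     5L,        0.25,
    "N6H7S2",     4L,     5L,        0.25,
    "N6H7S2F",    2L,     3L,        0.25
  )
}

#' The feature descriptors planted as informative by the defaults
#'
#' The ten features (isomer percentages, glycan sums, isomer ratios)
#' made class-informative by [default_effects()] and
#' [default_ratio_shifts()], with their planted direction in melanoma.
#'
#' @return Tibble: `feature`, `direction` (`"up"`/`"down"`).
#' @export
planted_features <- function() {
  tibble::tribble(
    ~feature,          ~direction,
    "N5H6S2|iso4",     "down",
    "N5H6S2|iso5",     "down",
    "N5H6S2|sum",      "down",
    "N5H6S2|r4:5",     "down",
    "N5H6S3F|r1:2",    "down",
    "N6H7S2|r3:5",     "down",
    "N6H7S2|r4:5",     "down",
    "N6H7S2F|r2:3",    "down",
    "N6H7S2F|iso3",    "up",
    "N6H7S2F|sum",     "up"
  )
}

#' The isomer-ratio pairs tracked by the default analysis
#'
#' @return Tibble with `composition`, `i`, `j`, suitable for
#'   [isomer_ratios()].
#' @export
default_ratio_pairs <- function() {
  tibble::tribble(
    ~composition, ~i, ~j,
    "N5H6S2",     4L, 5L,
    "N5H6S3F",    1L, 2L,
    "N6H7S2",     3L, 5L,
    "N6H7S2",     4L, 5L,
    "N6H7S2F",    2L, 3L
  )
}

#' Generate a synthetic two-class cohort of isomer peak areas
#'
#' Draws per-sample, per-isomer latent abundances from a positive
#' right-skewed noise model (lognormal by default, gamma alternative)
#' around class-adjusted means: melanoma means are baseline times the
#' effect map, after moving the ratio-shift fractions from donor to
#' acceptor isomers. Each sample is then multiplied by a random global
#' scale factor (lognormal, sd `scale_sd`) emulating injection and
#' instrument-response variability, so raw areas are NOT closed to
#' 100 % - [relative_areas()] has to recover that.
#'
#' @param n_melanoma,n_control Class sizes (defaults 18 / 19, the study
#'   cohort layout).
#' @param catalog Isomer catalog (see [default_catalog()]).
#' @param effects Effect map (see [default_effects()]); use an empty or
#'   all-1 map for a null cohort.
#' @param ratio_shifts Ratio-shift map (see [default_ratio_shifts()]).
#' @param noise `"lognormal"` or `"gamma"`.
#' @param scale_sd sd of the per-sample log-scale factor (default 0.3).
#' @param glycan_cor Fraction of the within-class log-variance shared by
#'   all isomers of the same glycan (default 0.7). Isomers of one
#'   composition co-vary within a sample (they respond to the same
#'   glycan-level regulation), which is what makes isomer ratios of the
#'   same glycan usable features: the shared factor cancels in the
#'   ratio. The total per-isomer RSD stays at the catalog value.
#' @param seed Optional integer seed (fixes the cohort byte-for-byte).
#' @return List: `peak_table` (long tibble: `sample_id`, `class`,
#'   `composition`, `isomer_index`, `rt_min`, `area`) and `truth`
#'   (planted feature directions, expected fold changes per isomer, the
#'   maps and seed used).
#' @export
generate_cohort <- function(n_melanoma = 18L, n_control = 19L,
                            catalog = default_catalog(),
                            effects = default_effects(),
                            ratio_shifts = default_ratio_shifts(),
                            noise = c("lognormal", "gamma"),
                            scale_sd = 0.3, glycan_cor = 0.7, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(glycan_cor >= 0, glycan_cor < 1)
  if (n_melanoma < 2 || n_control < 2) {
    stop("n_melanoma and n_control must each be >= 2", call. = FALSE)
  }
  if (any(catalog$baseline_mean_pct <= 0)) {
    stop("catalog baseline_mean_pct must be > 0", call. = FALSE)
  }
  if (nrow(effects) > 0 && any(effects$effect <= 0)) {
    stop("effects must be > 0", call. = FALSE)
  }
  if (nrow(ratio_shifts) > 0 &&
      any(ratio_shifts$fraction < 0 | ratio_shifts$fraction >= 1)) {
    stop("ratio-shift fractions must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  key <- paste0(catalog$composition, "|iso", catalog$isomer_index)
  mu_ctrl <- catalog$baseline_mean_pct
  mu_mel <- mu_ctrl
  if (nrow(effects) > 0) {
    for (r in seq_len(nrow(effects))) {
      hit <- catalog$composition == effects$composition[r] &
        (is.na(effects$isomer_index[r]) |
           catalog$isomer_index == effects$isomer_index[r])
      if (!any(hit)) {
        stop(sprintf("effect row %d matches no catalog isomer (%s)", r,
                     effects$composition[r]), call. = FALSE)
      }
      mu_mel[hit] <- mu_mel[hit] * effects$effect[r]
    }
  }
  if (nrow(ratio_shifts) > 0) {
    for (r in seq_len(nrow(ratio_shifts))) {
      di <- which(key == paste0(ratio_shifts$composition[r], "|iso",
                                ratio_shifts$donor[r]))
      ai <- which(key == paste0(ratio_shifts$composition[r], "|iso",
                                ratio_shifts$acceptor[r]))
      if (length(di) != 1 || length(ai) != 1) {
        stop(sprintf("ratio-shift row %d references missing isomer(s) of %s",
                     r, ratio_shifts$composition[r]), call. = FALSE)
      }
      moved <- ratio_shifts$fraction[r] * mu_mel[di]
      mu_mel[di] <- mu_mel[di] - moved
      mu_mel[ai] <- mu_mel[ai] + moved
    }
  }

  cv <- catalog$rsd_pct / 100
  # split the log-variance into a per-glycan shared part and a
  # per-isomer residual so total per-isomer RSD stays at the catalog value
  sd_tot2 <- log(1 + cv^2)
  sd_gly <- sqrt(glycan_cor * sd_tot2)
  sd_res2 <- (1 - glycan_cor) * sd_tot2
  glycan_of <- match(catalog$composition, unique(catalog$composition))
  n_glycans <- max(glycan_of)
  draw <- function(mu) {
    g <- stats::rnorm(n_glycans)            # shared glycan-level factor
    shared <- exp(sd_gly * g[glycan_of] - sd_gly^2 / 2)
    resid <- if (noise == "lognormal") {
      sdl <- sqrt(sd_res2)
      stats::rlnorm(length(mu), meanlog = -sdl^2 / 2, sdlog = sdl)
    } else {
      cv_res <- sqrt(exp(sd_res2) - 1)
      shape <- 1 / cv_res^2
      stats::rgamma(length(mu), shape = shape, scale = 1 / shape)
    }
    mu * shared * resid
  }

  n <- n_melanoma + n_control
  classes <- c(rep("melanoma", n_melanoma), rep("control", n_control))
  ids <- sprintf("%s%02d", ifelse(classes == "melanoma", "MM", "CTRL"),
                 c(seq_len(n_melanoma), seq_len(n_control)))
  tables <- vector("list", n)
  for (s in seq_len(n)) {
    mu <- if (classes[s] == "melanoma") mu_mel else mu_ctrl
    scale <- stats::rlnorm(1, meanlog = 0, sdlog = scale_sd)
    tables[[s]] <- tibble::tibble(
      sample_id = ids[s], class = classes[s],
      composition = catalog$composition,
      isomer_index = catalog$isomer_index,
      rt_min = catalog$rt_min,
      area = draw(mu) * scale * 1e6
    )
  }
  truth <- list(
    planted = planted_features(),
    expected_isomer_fold_change = tibble::tibble(
      composition = catalog$composition,
      isomer_index = catalog$isomer_index,
      fold_change = mu_mel / mu_ctrl
    ),
    effects = effects, ratio_shifts = ratio_shifts,
    noise = noise, scale_sd = scale_sd, seed = seed
  )
  list(peak_table = dplyr::bind_rows(tables), truth = truth)
}

#' Generate a synthetic MS/MS spectrum from a glycan topology
#'
#' Places peaks at every fragment m/z enumerated from the topology
#' (Y/Z/B ions up to `max_cleavages` cleavages, singly charged) plus the
#' sialic-linkage diagnostic ions applicable to the topology's linkage
#' tags, with lognormal intensities around ion-type-dependent levels,
#' and adds uniformly scattered low-intensity noise peaks. The planted
#' fragment list is attached as the `truth` attribute.
#'
#' @param topology A `glycan_topology`.
#' @param n_noise_peaks Number of noise peaks (default 20).
#' @param max_cleavages Cleavage depth for planted fragments (default 2).
#' @param base_intensity Median intensity of planted Y ions.
#' @param seed Optional integer seed.
#' @return A `glyco_spectrum` with attribute `truth` (the planted
#'   fragment tibble).
#' @export
generate_spectrum <- function(topology, n_noise_peaks = 20L,
                              max_cleavages = 2L, base_intensity = 100,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  frags <- enumerate_fragments(topology, types = c("B", "Y", "Z"),
                               max_cleavages = max_cleavages, charges = 1L)
  tags <- unique(stats::na.omit(topology$sia_linkage))
  frags <- dplyr::filter(frags, is.na(.data$diagnostic) |
                           .data$diagnostic %in% tags)
  level <- c(Y = 1, Z = 0.4, B = 0.6, C = 0.5, A = 0.8)[frags$type]
  planted_int <- stats::rlnorm(nrow(frags), log(base_intensity * level), 0.4)
  comp <- topology_composition(topology)
  precursor <- mz(glycan_mass(comp, labeled = attr(topology, "labeled")), 1L)
  noise_mz <- stats::runif(n_noise_peaks, 150, precursor)
  noise_int <- stats::runif(n_noise_peaks, 0, base_intensity / 10)
  sp <- spectrum(c(frags$mz, noise_mz), c(planted_int, noise_int),
                 precursor_mz = precursor, charge = 1L,
                 title = paste0("synthetic:", comp$composition))
  attr(sp, "truth") <- frags
  sp
}
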