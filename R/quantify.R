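#' Relative peak areas (closure to 100 % per sample)
#'
#' Converts a long peak table into a wide feature matrix of relative
#' peak areas: each isomer's area as a percentage of the summed areas of
#' that sample, the normalization that removes per-sample differences in
#' injected amount and instrument response.
#'
#' @param peak_table Data frame with columns `sample_id`, `class`
#'   (`"melanoma"`, `"control"` or `"unknown"`), `composition`,
#'   `isomer_index`, and `area` (>= 0); `rt_min` is carried if present.
#'   Isomers absent from a sample count as area 0.
#' @return Wide tibble, one row per sample: `sample_id`, `class`, then
#'   one column per isomer named `"<composition>|iso<k>"`, in percent.
#'   Each row sums to 100.
#' @examples
#' pt <- tibble::tibble(sample_id = "s1", class = "control",
#'   composition = "N4H5S2", isomer_index = 1:2, area = c(1, 3))
#' relative_areas(pt)
#' @export
relative_areas <- function(peak_table) {
  check_peak_table(peak_table)
  wide <- peak_table |>
    dplyr::mutate(feature = paste0(.data$composition, "|iso", .data$isomer_index)) |>
    dplyr::select("sample_id", "class", "feature", "area") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "area",
                       values_fill = 0)
  vals <- as.matrix(wide[, feature_columns(wide), drop = FALSE])
  totals <- rowSums(vals)
  if (any(totals <= 0)) {
    bad <- wide$sample_id[totals <= 0]
    stop(sprintf("sample(s) with zero total area: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  wide[, feature_columns(wide)] <- 100 * vals / totals
  wide
}

#' Add per-glycan sum features
#'
#' One additional feature per composition: the sum of the relative
#' areas of all its isomers, named `"<composition>|sum"`. The glycan
#' sums of a sample partition its 100 %.
#'
#' @param features Wide feature matrix from [relative_areas()].
#' @return The input tibble with the sum columns appended.
#' @export
glycan_sums <- function(features) {
  iso <- grep("\\|iso[0-9]+$", feature_columns(features), value = TRUE)
  if (length(iso) == 0) stop("no isomer %% features present", call. = FALSE)
  comps <- unique(sub("\\|iso[0-9]+$", "", iso))
  for (comp in comps) {
    cols <- iso[startsWith(iso, paste0(comp, "|iso"))]
    features[[paste0(comp, "|sum")]] <-
      rowSums(features[, cols, drop = FALSE])
  }
  features
}

#' Add isomer-ratio features of the same glycan
#'
#' For each requested pair, the ratio of isomer i's relative area to
#' isomer j's within the same composition, named
#' `"<composition>|r<i>:<j>"`. Ratios of relative areas equal ratios of
#' raw areas (the per-sample total cancels). Zero denominators are
#' floored at half the smallest nonzero relative area in the matrix and
#' flagged in the `"ratio_floored"` attribute.
#'
#' @param features Wide feature matrix containing the isomer % columns.
#' @param pairs Data frame with columns `composition`, `i`, `j`.
#' @return The input tibble with ratio columns appended; attribute
#'   `ratio_floored` is a tibble of (sample_id, feature) cells where the
#'   epsilon floor was applied.
#' @export
isomer_ratios <- function(features, pairs) {
  stopifnot(all(c("composition", "i", "j") %in% names(pairs)))
  vals <- as.matrix(features[, grep("\\|iso[0-9]+$", feature_columns(features),
                                    value = TRUE), drop = FALSE])
  nz <- vals[vals > 0]
  floor_val <- if (length(nz)) min(nz) / 2 else NA_real_
  flagged <- list()
  for (r in seq_len(nrow(pairs))) {
    ci <- paste0(pairs$composition[r], "|iso", pairs$i[r])
    cj <- paste0(pairs$composition[r], "|iso", pairs$j[r])
    missing_col <- setdiff(c(ci, cj), names(features))
    if (length(missing_col) > 0) {
      stop(sprintf("ratio pair references missing isomer feature(s): %s",
                   paste(missing_col, collapse = ", ")), call. = FALSE)
    }
    name <- paste0(pairs$composition[r], "|r", pairs$i[r], ":", pairs$j[r])
    denom <- features[[cj]]
    zero <- denom <= 0
    if (any(zero)) {
      denom[zero] <- floor_val
      flagged[[name]] <- tibble::tibble(
        sample_id = features$sample_id[zero], feature = name)
    }
    features[[name]] <- features[[ci]] / denom
  }
  attr(features, "ratio_floored") <- dplyr::bind_rows(flagged)
  features
}

#' Group means, fold changes and RSDs per feature
#'
#' Class-wise means of every feature, the melanoma/control fold change,
#' and per-class relative standard deviations (100 * sd / mean, sample
#' sd with n-1), the summary behind group-level abundance-change plots.
#'
#' @param features Wide feature matrix with a `class` column containing
#'   both `"melanoma"` and `"control"` (>= 2 samples each).
#' @return Tibble: `feature`, `mean_control`, `mean_melanoma`,
#'   `fold_change`, `rsd_control`, `rsd_melanoma`.
#' @export
group_summary <- function(features) {
  for (cls in c("melanoma", "control")) {
    if (sum(features$class == cls) < 2) {
      stop(sprintf("class '%s' needs >= 2 samples", cls), call. = FALSE)
    }
  }
  features |>
    dplyr::select(-"sample_id") |>
    tidyr::pivot_longer(-"class", names_to = "feature") |>
    dplyr::group_by(.data$feature, .data$class) |>
    dplyr::summarise(mean = mean(.data$value),
                     rsd = 100 * stats::sd(.data$value) / mean(.data$value),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "class", values_from = c("mean", "rsd")) |>
    dplyr::transmute(
      feature = .data$feature,
      mean_control = .data$mean_control,
      mean_melanoma = .data$mean_melanoma,
      fold_change = .data$mean_melanoma / .data$mean_control,
      rsd_control = .data$rsd_control,
      rsd_melanoma = .data$rsd_melanoma
    )
}

#' Feature columns of a wide feature matrix
#'
#' Everything except the `sample_id` and `class` bookkeeping columns.
#'
#' @param features Wide feature matrix.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(features) {
  setdiff(names(features), c("sample_id", "class"))
}

check_peak_table <- function(peak_table) {
  need <- c("sample_id", "class", "composition", "isomer_index", "area")
  missing_cols <- setdiff(need, names(peak_table))
  if (length(missing_cols) > 0) {
    stop(sprintf("peak table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (any(peak_table$area < 0)) stop("negative peak areas", call. = FALSE)
  bad <- setdiff(unique(peak_table$class), c("melanoma", "control", "unknown"))
  if (length(bad) > 0) {
    stop(sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  dup <- peak_table |>
    dplyr::count(.data$sample_id, .data$composition, .data$isomer_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(sprintf("duplicated (sample, composition, isomer) rows, e.g. %s/%s/%d",
                 dup$sample_id[1], dup$composition[1], dup$isomer_index[1]),
         call. = FALSE)
  }
  invisible(peak_table)
}
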