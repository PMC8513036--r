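#' Read and validate a peak-area table
#'
#' CSV schema: `sample_id, class, composition, isomer_index, rt_min,
#' area` (UTF-8, comma-separated, `.` decimal, header mandatory).
#' Compositions are validated through the composition grammar and
#' normalized to canonical form; duplicate (sample, composition, isomer)
#' rows are rejected; isomers missing from a sample are filled with area
#' 0 (reported via a message).
#'
#' @param path Path to the CSV file.
#' @return A validated long peak-table tibble.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample_id", "class", "composition", "isomer_index", "area")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("peak table %s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad_class <- which(!raw$class %in% c("melanoma", "control", "unknown"))
  if (length(bad_class) > 0) {
    stop(sprintf("unknown class label '%s' at data row %d",
                 raw$class[bad_class[1]], bad_class[1]), call. = FALSE)
  }
  # canonicalize compositions through the grammar (errors name the token)
  comp_map <- parse_composition(unique(raw$composition))
  raw$composition <- comp_map$composition[match(raw$composition,
                                                unique(raw$composition))]
  check_peak_table(raw)
  # complete the sample x isomer grid with zero areas
  iso <- dplyr::distinct(raw, .data$composition, .data$isomer_index)
  full <- tidyr::crossing(dplyr::distinct(raw, .data$sample_id, .data$class), iso)
  out <- dplyr::left_join(full, raw,
                          by = c("sample_id", "class", "composition",
                                 "isomer_index"))
  n_filled <- sum(is.na(out$area))
  if (n_filled > 0) {
    message(sprintf("read_peak_table: %d missing sample x isomer cells filled with area 0",
                    n_filled))
    out$area[is.na(out$area)] <- 0
  }
  out
}

#' Write a peak table as CSV
#'
#' @param peak_table Long peak-table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peak_table, path) {
  check_peak_table(peak_table)
  readr::write_csv(peak_table, path)
  invisible(path)
}

#' Read spectra from a Mascot generic format (MGF) file
#'
#' Supports the dialect used for negative-mode glycan MS/MS exchange:
#' `BEGIN IONS` / `END IONS` blocks with `TITLE`, `PEPMASS` (precursor
#' m/z), `CHARGE` with a trailing minus (e.g. `2-`), and `m/z intensity`
#' peak lines.
#'
#' @param path Path to the MGF file.
#' @return List of `glyco_spectrum` objects sorted by title; empty list
#'   for an empty file.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  title <- ""
  pep <- NA_real_
  charge <- 1L
  pk_mz <- numeric()
  pk_int <- numeric()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (ln == "BEGIN IONS") {
      if (in_block) stop(sprintf("line %d: nested BEGIN IONS", i), call. = FALSE)
      in_block <- TRUE
      title <- ""; pep <- NA_real_; charge <- 1L
      pk_mz <- numeric(); pk_int <- numeric()
    } else if (ln == "END IONS") {
      if (!in_block) stop(sprintf("line %d: END IONS without BEGIN", i),
                          call. = FALSE)
      spectra[[length(spectra) + 1L]] <-
        spectrum(pk_mz, pk_int, precursor_mz = pep, charge = charge,
                 title = title)
      in_block <- FALSE
    } else if (!in_block) {
      next                                   # header comments between blocks
    } else if (grepl("^TITLE=", ln)) {
      title <- sub("^TITLE=", "", ln)
    } else if (grepl("^PEPMASS=", ln)) {
      pep <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
    } else if (grepl("^CHARGE=", ln)) {
      ch <- sub("^CHARGE=", "", ln)
      if (!grepl("-", ch, fixed = TRUE)) {
        stop(sprintf("line %d: expected negative-mode charge, got '%s'", i, ch),
             call. = FALSE)
      }
      charge <- as.integer(gsub("[^0-9]", "", ch))
    } else if (grepl("=", ln, fixed = TRUE)) {
      next                                   # other headers ignored
    } else {
      parts <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) < 2 || any(is.na(vals[1:2]))) {
        stop(sprintf("line %d: malformed peak line '%s'", i, ln), call. = FALSE)
      }
      pk_mz <- c(pk_mz, vals[1]); pk_int <- c(pk_int, vals[2])
    }
  }
  if (in_block) stop("unterminated BEGIN IONS block at end of file",
                     call. = FALSE)
  spectra[order(vapply(spectra, function(s) s$title, character(1)))]
}

#' Write spectra to an MGF file
#'
#' @param spectra List of `glyco_spectrum` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "glyco_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$title), con)
    if (!is.na(sp$precursor_mz)) {
      writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    }
    writeLines(sprintf("CHARGE=%d-", sp$charge), con)
    writeLines(sprintf("%.6f %.4f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Default analysis configuration
#'
#' All knobs of the pipeline with their documented defaults: panel size
#' `k = 10`, fragment-match tolerance 10 ppm, cross-validation plan
#' 25 training samples x 10 repetitions (unstratified, panel selected
#' once on the full cohort), shrinkage `lambda = 1e-3`, ratio
#' zero-policy `"epsilon-floor"`, metric rounding to 1 decimal.
#'
#' @param ... Named overrides of any default.
#' @return A named list (class `agp_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    k = 10L, tol_ppm = 10, n_train = 25L, reps = 10L, stratified = FALSE,
    nested = FALSE, lambda = 1e-3, zero_policy = "epsilon-floor",
    seed = 1L, ratio_pairs = default_ratio_pairs()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "agp_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified knobs keep their [default_config()] values; the
#' round-trip through [write_config()] is the identity.
#'
#' @param path YAML file path.
#' @return An `agp_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$ratio_pairs)) {
    raw$ratio_pairs <- dplyr::bind_rows(lapply(raw$ratio_pairs, tibble::as_tibble))
  }
  do.call(default_config, raw)
}

#' @rdname read_config
#' @param config An `agp_config`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$ratio_pairs <- purrr::transpose(as.list(out$ratio_pairs))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full biomarker pipeline on a peak table
#'
#' Executes the analysis end to end: relative-area quantification,
#' glycan sums and isomer ratios, Fisher-index panel selection, linear
#' discriminant fit with resubstitution classification, per-feature
#' ablation, and repeated leave-one-third-out cross-validation. When
#' `out_dir` is given, writes the feature matrix, the Fisher score
#' table, the classification and cross-validation reports, the ablation
#' table, the projected coordinates, and a JSON run manifest (seed,
#' package version, config hash).
#'
#' @param peak_table Long peak table (tibble or CSV path).
#' @param config An `agp_config` (see [default_config()]).
#' @param out_dir Optional output directory for the report bundle.
#' @return List (class `agp_run`): `features`, `scores`, `selected`,
#'   `model`, `classification` (tibble), `resubstitution`
#'   ([confusion_metrics()] row), `ablation`, `cv` (`agp_cv`),
#'   `group_summary`, `manifest`.
#' @export
run_pipeline <- function(peak_table, config = default_config(),
                         out_dir = NULL) {
  if (is.character(peak_table)) peak_table <- read_peak_table(peak_table)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  features <- stage("quantify", {
    relative_areas(peak_table) |> glycan_sums()
  })
  pairs <- config$ratio_pairs
  pairs <- pairs[paste0(pairs$composition, "|iso", pairs$i) %in% names(features) &
                   paste0(pairs$composition, "|iso", pairs$j) %in% names(features), ]
  features <- stage("quantify", isomer_ratios(features, pairs))
  scores <- stage("select", fisher_scores(features))
  selected <- stage("select", select_features(features, config$k)$feature)
  model <- stage("fit", fit_lda(features, selected, lambda = config$lambda))
  classification <- stage("classify", classify(model, features))
  cc <- confusion_counts(features$class, classification$predicted)
  resub <- confusion_metrics(cc["tp"], cc["fn"], cc["tn"], cc["fp"])
  abl <- stage("ablate", ablation(features, selected, lambda = config$lambda))
  cv <- stage("crossval", cross_validate(
    features, selected = if (config$nested) NULL else selected, k = config$k,
    n_train = config$n_train, reps = config$reps, seed = config$seed,
    stratified = config$stratified, nested = config$nested,
    lambda = config$lambda))
  gs <- stage("summary", group_summary(features))
  cfg_plain <- unclass(config)
  cfg_plain$ratio_pairs <- as.data.frame(cfg_plain$ratio_pairs)
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("agpglyco")),
    config_hash = rlang::hash(cfg_plain),
    n_samples = nrow(features), n_features = length(feature_columns(features)),
    positive_class = "melanoma"
  )
  bundle <- structure(
    list(features = features, scores = scores, selected = selected,
         model = model, classification = classification,
         resubstitution = resub, ablation = abl, cv = cv,
         group_summary = gs, manifest = manifest),
    class = "agp_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(features, file.path(out_dir, "feature_matrix.csv"))
    readr::write_csv(scores, file.path(out_dir, "fisher_scores.csv"))
    readr::write_csv(classification, file.path(out_dir, "classification.csv"))
    readr::write_csv(resub, file.path(out_dir, "resubstitution_report.csv"))
    readr::write_csv(abl, file.path(out_dir, "ablation.csv"))
    readr::write_csv(cv$report, file.path(out_dir, "crossval_report.csv"))
    readr::write_csv(cv$predictions, file.path(out_dir, "crossval_predictions.csv"))
    readr::write_csv(gs, file.path(out_dir, "group_summary.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

#' @export
print.agp_run <- function(x, ...) {
  cat(sprintf("<agp_run> %d samples, %d features, panel of %d\n",
              x$manifest$n_samples, x$manifest$n_features, length(x$selected)))
  cat("resubstitution:\n"); print(x$resubstitution)
  cat("cross-validation:\n"); print(x$cv$report)
  invisible(x)
}
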