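#' Fisher's index of class separability for one feature
#'
#' Ratio of between-group to within-group variance in the two-class
#' analysis-of-variance form: `[sum n_g (mu_g - mu)^2 / (G - 1)] /
#' [sum (x - mu_g)^2 / (n - G)]`. Larger F means better univariate
#' separation; F is invariant under affine rescaling of the feature.
#'
#' @param x Numeric feature values.
#' @param labels Class labels (two classes, >= 2 samples each).
#' @return F (>= 0). Zero within-group variance with distinct means
#'   returns `Inf`; zero within- and between-group variance returns 0.
#' @export
fisher_index <- function(x, labels) {
  stopifnot(length(x) == length(labels), all(is.finite(x)))
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2) stop("exactly two classes required", call. = FALSE)
  if (any(table(labels) < 2)) stop("each class needs >= 2 samples", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  between <- 0
  within <- 0
  for (g in groups) {
    xg <- x[labels == g]
    between <- between + length(xg) * (mean(xg) - mu)^2
    within <- within + sum((xg - mean(xg))^2)
  }
  between <- between / (length(groups) - 1)
  within <- within / (n - length(groups))
  if (within == 0) {
    return(if (between == 0) 0 else Inf)
  }
  between / within
}

#' Fisher scores of every feature in a matrix
#'
#' @param features Wide feature matrix with a `class` column.
#' @return Tibble `feature`, `fisher_f`, `rank`, sorted by descending F;
#'   ties broken by feature name (deterministic).
#' @export
fisher_scores <- function(features) {
  cols <- feature_columns(features)
  f <- vapply(cols, function(cn) fisher_index(features[[cn]], features$class),
              numeric(1), USE.NAMES = FALSE)
  tibble::tibble(feature = cols, fisher_f = f) |>
    dplyr::arrange(dplyr::desc(.data$fisher_f), .data$feature) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Select the k features with highest discriminatory power
#'
#' Ranks features by Fisher's index and returns the top `k`. To avoid
#' the small-sample-size problem, the number of independent variables
#' must stay below one third of the number of samples; `k` violating
#' that bound is rejected.
#'
#' @param features Wide feature matrix with a `class` column.
#' @param k Number of features to select; must satisfy `k < n/3`.
#' @return Tibble of the top-k [fisher_scores()] rows.
#' @export
select_features <- function(features, k) {
  n <- nrow(features)
  if (k >= n / 3) {
    stop(sprintf(paste0("k = %d violates the one-third rule: the number of ",
                        "independent variables must be less than n/3 = %.1f ",
                        "for n = %d samples"), k, n / 3, n), call. = FALSE)
  }
  utils::head(fisher_scores(features), k)
}

#' Fit a two-class linear discriminant
#'
#' Solves `S_w w = mu_melanoma - mu_control` with `S_w` the pooled
#' within-class covariance matrix, shrinkage-regularized as
#' `(1 - lambda) S_w + lambda diag(S_w)` to keep small-sample fits
#' well-conditioned. The decision threshold is the midpoint of the
#' projected class means (equal priors); samples projecting on the
#' melanoma side (ties included) are called melanoma.
#'
#' @param features Wide feature matrix with `sample_id` and `class`
#'   (`"melanoma"` / `"control"`, >= 2 samples each) columns.
#' @param selected Character vector of feature columns to use (default:
#'   all feature columns). Must number fewer than n/3.
#' @param lambda Shrinkage intensity in `[0, 1]` (default 1e-3).
#' @return An `agp_lda` model: selected features, named weight vector
#'   `w`, `threshold`, projected class means, `lambda`, and training
#'   metadata.
#' @export
fit_lda <- function(features, selected = NULL, lambda = 1e-3) {
  if (is.null(selected)) selected <- feature_columns(features)
  missing_cols <- setdiff(selected, names(features))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing feature column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  cls <- features$class
  n <- nrow(features)
  if (sum(cls == "melanoma") < 2 || sum(cls == "control") < 2) {
    stop("need >= 2 samples per class", call. = FALSE)
  }
  # the one-third rule is enforced where the panel is chosen
  # (select_features, against the full cohort); the fit itself only
  # needs enough residual df for the pooled covariance
  if (length(selected) > n - 3) {
    stop(sprintf("%d features cannot be fit on %d samples", length(selected), n),
         call. = FALSE)
  }
  x <- as.matrix(features[, selected, drop = FALSE])
  xm <- x[cls == "melanoma", , drop = FALSE]
  xc <- x[cls == "control", , drop = FALSE]
  mu_m <- colMeans(xm)
  mu_c <- colMeans(xc)
  sw <- ((nrow(xm) - 1) * stats::cov(xm) + (nrow(xc) - 1) * stats::cov(xc)) /
    (n - 2)
  sw <- (1 - lambda) * sw + lambda * diag(diag(sw), nrow = ncol(x))
  w <- tryCatch(solve(sw, mu_m - mu_c), error = function(e) {
    stop(paste0("pooled within-class covariance is singular even after ",
                "shrinkage; increase lambda"), call. = FALSE)
  })
  names(w) <- selected
  if (all(w == 0)) stop("degenerate discriminant: zero weight vector",
                        call. = FALSE)
  proj_m <- sum(w * mu_m)
  proj_c <- sum(w * mu_c)
  structure(
    list(features = selected, w = w, threshold = (proj_m + proj_c) / 2,
         proj_means = c(control = proj_c, melanoma = proj_m),
         lambda = lambda, n = n,
         n_class = c(control = nrow(xc), melanoma = nrow(xm))),
    class = "agp_lda"
  )
}

#' @export
print.agp_lda <- function(x, ...) {
  cat(sprintf("<agp_lda> %d features, n = %d (melanoma %d / control %d)\n",
              length(x$features), x$n, x$n_class[["melanoma"]],
              x$n_class[["control"]]))
  cat(sprintf("  threshold %.4g; projected means: control %.4g, melanoma %.4g\n",
              x$threshold, x$proj_means[["control"]], x$proj_means[["melanoma"]]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_lda
#' @param x,object An `agp_lda` model.
#' @param ... Unused.
#' @export
tidy.agp_lda <- function(x, ...) {
  tibble::tibble(feature = x$features, weight = unname(x$w))
}

#' @rdname fit_lda
#' @export
glance.agp_lda <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = length(x$features),
                 lambda = x$lambda, threshold = x$threshold,
                 proj_separation = unname(x$proj_means["melanoma"] -
                                            x$proj_means["control"]))
}

#' Classify samples with a fitted linear discriminant
#'
#' Projects each sample onto the discriminant axis and thresholds.
#' Samples exactly at the threshold are called melanoma (documented tie
#' rule).
#'
#' @param model An `agp_lda` model.
#' @param features Wide feature matrix containing the model's features.
#' @return Tibble: `sample_id`, `score` (projected coordinate),
#'   `predicted` (`"melanoma"` / `"control"`).
#' @export
classify <- function(model, features) {
  stopifnot(inherits(model, "agp_lda"))
  missing_cols <- setdiff(model$features, names(features))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing feature column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(features[, model$features, drop = FALSE])
  score <- drop(x %*% model$w)
  tibble::tibble(
    sample_id = if ("sample_id" %in% names(features)) features$sample_id else
      as.character(seq_len(nrow(features))),
    score = score,
    predicted = ifelse(score >= model$threshold, "melanoma", "control")
  )
}

#' @rdname classify
#' @param object An `agp_lda` model.
#' @param newdata Feature matrix to classify.
#' @param ... Unused.
#' @export
predict.agp_lda <- function(object, newdata, ...) classify(object, newdata)

#' Confusion counts from truth and predicted labels
#'
#' Melanoma is the positive class throughout.
#'
#' @param truth,predicted Character vectors of `"melanoma"` / `"control"`.
#' @return Named integer vector `c(tp, fn, tn, fp)`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  c(tp = sum(truth == "melanoma" & predicted == "melanoma"),
    fn = sum(truth == "melanoma" & predicted == "control"),
    tn = sum(truth == "control" & predicted == "control"),
    fp = sum(truth == "control" & predicted == "melanoma"))
}

#' Diagnostic performance metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and
#' negative predictive value `TP/(TP+FP)` / `TN/(TN+FN)`, and accuracy
#' `(TP+TN)/total`, in percent rounded half-away-from-zero to one
#' decimal. A zero-denominator metric is reported as `NA`, not 0.
#' Melanoma is the positive class.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts (total > 0).
#' @return One-row tibble with the counts and the five metrics (%).
#' @examples
#' confusion_metrics(tp = 15, fn = 3, tn = 18, fp = 1)
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn + tn + fp > 0)
  tp <- unname(tp); fn <- unname(fn); tn <- unname(tn); fp <- unname(fp)
  pct <- function(num, den) if (den == 0) NA_real_ else
    round_half_up(100 * num / den, 1)
  tibble::tibble(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    ppv = pct(tp, tp + fp),
    npv = pct(tn, tn + fn),
    accuracy = pct(tp + tn, tp + fn + tn + fp)
  )
}

#' Per-feature ablation of a discriminant panel
#'
#' Refits the discriminant once per feature with that feature omitted
#' and reports resubstitution confusion counts and metrics, quantifying
#' each variable's contribution to the panel.
#'
#' @param features Wide feature matrix with `class`.
#' @param selected Character vector (>= 2) of panel features, in report
#'   order.
#' @param lambda Shrinkage passed to [fit_lda()].
#' @return Tibble with one row per omitted feature: `omitted` plus the
#'   [confusion_metrics()] columns.
#' @export
ablation <- function(features, selected, lambda = 1e-3) {
  stopifnot(length(selected) >= 2)
  purrr::map_dfr(selected, function(f) {
    keep <- setdiff(selected, f)
    fit <- fit_lda(features, keep, lambda = lambda)
    pred <- classify(fit, features)
    cc <- confusion_counts(features$class, pred$predicted)
    dplyr::bind_cols(tibble::tibble(omitted = f),
                     confusion_metrics(cc["tp"], cc["fn"], cc["tn"], cc["fp"]))
  })
}

#' Repeated leave-one-third-out cross-validation
#'
#' Repeatedly draws a training set of `n_train` samples at random (by
#' default unstratified, uniform without replacement), fits the
#' discriminant on it, predicts the held-out samples, and pools the
#' confusion counts over all repetitions. With the defaults on a
#' 37-sample cohort this scores `10 * 12 = 120` held-out predictions.
#' Feature selection is done once on the full cohort by default
#' (matching the original workflow, which fixes the panel before
#' cross-validating the classifier); `nested = TRUE` instead re-selects
#' the top `k` features inside each training fold, the estimate free of
#' selection bias.
#'
#' @param features Wide feature matrix with `sample_id` and `class`.
#' @param selected Panel features; if `NULL` and `nested = FALSE`,
#'   selected once on the full data with [select_features()] at `k`.
#' @param k Panel size used whenever selection is performed.
#' @param n_train Training-set size per repetition (default 25).
#' @param reps Number of repetitions (default 10).
#' @param seed Integer seed for reproducible draws (optional).
#' @param stratified Draw the training set per class, preserving class
#'   proportions (default FALSE: uniform draws).
#' @param nested Re-select features inside each training fold.
#' @param lambda Shrinkage passed to [fit_lda()].
#' @param max_redraws Bound on redraws when an (unstratified) training
#'   draw misses a class.
#' @return An `agp_cv` object: `report` (pooled [confusion_metrics()]
#'   row), `predictions` (tibble rep/sample_id/truth/score/predicted),
#'   `selected_per_rep`, `n_redraws`, and the plan parameters.
#' @export
cross_validate <- function(features, selected = NULL, k = 10, n_train = 25,
                           reps = 10, seed = NULL, stratified = FALSE,
                           nested = FALSE, lambda = 1e-3, max_redraws = 100) {
  n <- nrow(features)
  stopifnot(n_train < n, reps >= 1)
  if (!all(features$class %in% c("melanoma", "control"))) {
    stop("cross-validation requires labeled samples only", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if ((nested || is.null(selected)) && k >= n / 3) {
    stop(sprintf("k = %d violates the one-third rule for the %d-sample cohort",
                 k, n), call. = FALSE)
  }
  if (!nested && is.null(selected)) {
    selected <- select_features(features, k)$feature
  }
  idx_by_class <- split(seq_len(n), features$class)
  n_redraws <- 0L
  draws <- function() {
    if (stratified) {
      prop <- n_train / n
      take <- vapply(idx_by_class,
                     function(ix) max(2L, as.integer(round(length(ix) * prop))),
                     integer(1))
      # keep the total at n_train after per-class rounding
      while (sum(take) > n_train) take[which.max(take)] <- take[which.max(take)] - 1L
      while (sum(take) < n_train) take[which.min(take)] <- take[which.min(take)] + 1L
      sort(unlist(mapply(function(ix, m) sample(ix, m), idx_by_class, take,
                         SIMPLIFY = FALSE), use.names = FALSE))
    } else {
      for (attempt in seq_len(max_redraws)) {
        tr <- sort(sample.int(n, n_train))
        if (all(c("melanoma", "control") %in% features$class[tr]) &&
            all(table(features$class[tr]) >= 2)) {
          return(tr)
        }
        n_redraws <<- n_redraws + 1L
      }
      stop("could not draw a training set containing both classes", call. = FALSE)
    }
  }
  preds <- vector("list", reps)
  sel_per_rep <- vector("list", reps)
  for (r in seq_len(reps)) {
    tr <- draws()
    te <- setdiff(seq_len(n), tr)
    # nested mode re-ranks inside the fold; the one-third rule was
    # already checked against the full cohort size above
    sel <- if (nested) utils::head(fisher_scores(features[tr, ]), k)$feature
           else selected
    sel_per_rep[[r]] <- sel
    fit <- fit_lda(features[tr, ], sel, lambda = lambda)
    p <- classify(fit, features[te, ])
    p$truth <- features$class[te]
    p$rep <- r
    preds[[r]] <- p
  }
  predictions <- dplyr::bind_rows(preds)[, c("rep", "sample_id", "truth",
                                             "score", "predicted")]
  cc <- confusion_counts(predictions$truth, predictions$predicted)
  if (n_redraws > 0) {
    message(sprintf("cross_validate: %d training draw(s) redrawn for missing a class",
                    n_redraws))
  }
  structure(
    list(report = confusion_metrics(cc["tp"], cc["fn"], cc["tn"], cc["fp"]),
         predictions = predictions, selected_per_rep = sel_per_rep,
         n_redraws = n_redraws,
         plan = list(n_train = n_train, reps = reps, stratified = stratified,
                     nested = nested, k = k, lambda = lambda, seed = seed)),
    class = "agp_cv"
  )
}

#' @export
print.agp_cv <- function(x, ...) {
  cat(sprintf(
    "<agp_cv> %d reps x %d held-out = %d pooled predictions (positive class: melanoma)\n",
    x$plan$reps, nrow(x$predictions) / x$plan$reps, nrow(x$predictions)))
  print(x$report)
  invisible(x)
}

#' @rdname cross_validate
#' @param x,object An `agp_cv` object.
#' @param ... Unused.
#' @export
tidy.agp_cv <- function(x, ...) x$predictions

#' @rdname cross_validate
#' @export
glance.agp_cv <- function(x, ...) x$report
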