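test_that("Fisher's index follows the variance-ratio formula and its edge cases", {
  # identical class means with spread -> 0
  expect_equal(fisher_index(c(1, 2, 3, 1, 2, 3),
                            rep(c("a", "b"), each = 3)), 0)
  # zero within-variance with distinct means -> infinity sentinel
  expect_equal(fisher_index(c(0, 0, 0, 1, 1, 1),
                            rep(c("a", "b"), each = 3)), Inf)
  # zero within and between -> 0
  expect_equal(fisher_index(rep(2, 6), rep(c("a", "b"), each = 3)), 0)

  # exact-moment oracle: n1 = n2 = 10, means 0 / 1, within-sd 1 ->
  # between MS = 10*(.5)^2 + 10*(.5)^2 = 5, within MS = 1 -> F = 5
  set.seed(2)
  g1 <- as.numeric(scale(rnorm(10)))
  g2 <- as.numeric(scale(rnorm(10))) + 1
  expect_equal(fisher_index(c(g1, g2), rep(c("a", "b"), each = 10)), 5,
               tolerance = 1e-10)
})

test_that("Fisher's index is invariant under positive affine transforms", {
  set.seed(17)
  labels <- rep(c("melanoma", "control"), each = 12)
  for (i in 1:20) {
    x <- rnorm(24, mean = rep(c(0, 1), each = 12))
    a <- stats::runif(1, 0.01, 100)
    b <- stats::rnorm(1, 0, 50)
    expect_equal(fisher_index(a * x + b, labels), fisher_index(x, labels),
                 tolerance = 1e-8)
  }
})

test_that("feature selection ranks planted signal above noise", {
  set.seed(23)
  n <- 40
  labels <- rep(c("melanoma", "control"), each = n / 2)
  noise <- matrix(rnorm(n * 50), n, 50,
                  dimnames = list(NULL, sprintf("noise%02d", 1:50)))
  signal <- sapply(1:3, function(i) rnorm(n) + 3 * (labels == "melanoma"))
  colnames(signal) <- sprintf("planted%d", 1:3)
  fm <- dplyr::bind_cols(tibble::tibble(sample_id = as.character(1:n),
                                        class = labels),
                         tibble::as_tibble(cbind(signal, noise)))
  top <- select_features(fm, 3)
  expect_setequal(top$feature, sprintf("planted%d", 1:3))
})

test_that("the one-third rule bounds the panel size", {
  fm <- tibble::tibble(sample_id = as.character(1:37),
                       class = rep(c("melanoma", "control"), length.out = 37),
                       f1 = rnorm(37), f2 = rnorm(37))
  expect_error(select_features(fm, 13), "one-third")
  expect_silent(select_features(fm, 12))   # 12 < 37/3 is the admissible bound
})

test_that("class-constant features rank deterministically with F = 0", {
  fm <- tibble::tibble(sample_id = as.character(1:8),
                       class = rep(c("melanoma", "control"), each = 4),
                       b = rep(1, 8), a = rep(2, 8), c = rep(3, 8))
  sc <- fisher_scores(fm)
  expect_equal(sc$fisher_f, rep(0, 3))
  expect_equal(sc$feature, c("a", "b", "c"))  # lexicographic tie-break
})

test_that("the discriminant separates well-separated clouds perfectly", {
  fm <- separable_matrix()
  fit <- fit_lda(fm)
  pred <- classify(fit, fm)
  expect_equal(pred$predicted, fm$class)
  expect_equal(glance(fit)$n, 20)
  expect_equal(tidy(fit)$feature, c("f1", "f2"))
})

test_that("the weight direction maximizes the Fisher ratio (brute-force check)", {
  set.seed(29)
  for (i in 1:5) {
    n <- 30
    labels <- rep(c("melanoma", "control"), each = n / 2)
    x1 <- rnorm(n, ifelse(labels == "melanoma", 2, 0), 1)
    x2 <- 0.6 * x1 + rnorm(n, ifelse(labels == "melanoma", 1, 0), 1.5)
    fm <- tibble::tibble(sample_id = as.character(1:n), class = labels,
                         f1 = x1, f2 = x2)
    fit <- fit_lda(fm, lambda = 1e-9)
    # independent oracle: grid search of J(w) over unit vectors
    xm <- cbind(x1, x2)[labels == "melanoma", ]
    xc <- cbind(x1, x2)[labels == "control", ]
    sw <- ((nrow(xm) - 1) * stats::cov(xm) + (nrow(xc) - 1) * stats::cov(xc)) /
      (n - 2)
    dmu <- colMeans(xm) - colMeans(xc)
    sb <- outer(dmu, dmu)
    theta <- seq(0, pi, length.out = 20000)
    j <- vapply(theta, function(t) {
      w <- c(cos(t), sin(t))
      (w %*% sb %*% w) / (w %*% sw %*% w)
    }, numeric(1))
    wbest <- c(cos(theta[which.max(j)]), sin(theta[which.max(j)]))
    cosine <- abs(sum(fit$w * wbest)) /
      (sqrt(sum(fit$w^2)) * sqrt(sum(wbest^2)))
    expect_gt(cosine, 0.999)
  }
})

test_that("the discriminant direction agrees with an independent LDA fit", {
  fm <- separable_matrix(n_per_class = 15, gap = 3, seed = 41)
  fit <- fit_lda(fm, lambda = 1e-9)
  ref <- MASS::lda(as.matrix(fm[, c("f1", "f2")]), grouping = fm$class)
  cosine <- abs(sum(fit$w * ref$scaling)) /
    (sqrt(sum(fit$w^2)) * sqrt(sum(ref$scaling^2)))
  expect_gt(cosine, 0.999)
})

test_that("predictions are equivariant to feature rescaling and column order", {
  fm <- separable_matrix(n_per_class = 8, gap = 3, seed = 43)
  base <- classify(fit_lda(fm), fm)
  fm2 <- fm
  fm2$f1 <- fm2$f1 * 37.5
  expect_equal(classify(fit_lda(fm2), fm2)$predicted, base$predicted)
  fm3 <- fm[, c("sample_id", "class", "f2", "f1")]
  expect_equal(classify(fit_lda(fm, c("f1", "f2")), fm3)$predicted,
               base$predicted)
})

test_that("univariate fit reduces to the closed form w proportional to dmu/var", {
  set.seed(47)
  fm <- tibble::tibble(
    sample_id = as.character(1:20),
    class = rep(c("melanoma", "control"), each = 10),
    f1 = rnorm(20, rep(c(3, 0), each = 10), 1.2)
  )
  fit <- fit_lda(fm, lambda = 0)
  xm <- fm$f1[fm$class == "melanoma"]
  xc <- fm$f1[fm$class == "control"]
  pooled_var <- (9 * stats::var(xm) + 9 * stats::var(xc)) / 18
  expect_equal(unname(fit$w), (mean(xm) - mean(xc)) / pooled_var,
               tolerance = 1e-10)
})

test_that("a sample exactly at the threshold is called melanoma", {
  fm <- separable_matrix(n_per_class = 6, gap = 4, seed = 53)
  fit <- fit_lda(fm)
  # construct a sample projecting exactly onto the threshold
  x0 <- fit$threshold * fit$w / sum(fit$w^2)
  at <- tibble::tibble(sample_id = "tie", f1 = x0[1], f2 = x0[2])
  expect_equal(classify(fit, at)$predicted, "melanoma")
  expect_error(classify(fit, at[, "sample_id"]), "missing feature")
})

test_that("ablation exposes the feature carrying the signal", {
  set.seed(59)
  n <- 30
  labels <- rep(c("melanoma", "control"), each = n / 2)
  fm <- tibble::tibble(
    sample_id = as.character(1:n), class = labels,
    signal = rnorm(n, ifelse(labels == "melanoma", 4, 0), 0.8),
    junk1 = rnorm(n), junk2 = rnorm(n)
  )
  abl <- ablation(fm, c("signal", "junk1", "junk2"))
  expect_equal(nrow(abl), 3)
  expect_lt(abl$accuracy[abl$omitted == "signal"], 75)
  expect_equal(abl$accuracy[abl$omitted == "junk1"], 100)
  expect_equal(abl$accuracy[abl$omitted == "junk2"], 100)

  # dropping one of two duplicated columns changes nothing
  fm$dup <- fm$signal
  abl2 <- ablation(fm, c("signal", "dup", "junk1"))
  expect_equal(abl2$accuracy[abl2$omitted == "signal"],
               abl2$accuracy[abl2$omitted == "dup"])
})

test_that("confusion metrics reproduce the published biomarker table rows", {
  # comparator serum marker: 12 of 18 melanomas missed, 18 of 19 controls ok
  s100b <- confusion_metrics(tp = 6, fn = 12, tn = 18, fp = 1)
  expect_equal(s100b$sensitivity, 33.3)
  expect_equal(s100b$specificity, 94.7)
  expect_equal(s100b$ppv, 85.7)
  expect_equal(s100b$npv, 60.0)

  # resubstitution classification: 3 + 1 misclassifications out of 37
  cls <- confusion_metrics(tp = 15, fn = 3, tn = 18, fp = 1)
  expect_equal(cls$accuracy, 89.2)
  expect_equal(cls$sensitivity, 83.3)
  expect_equal(cls$npv, 85.7)

  # pooled cross-validation: 52/55 melanomas, 64/65 controls
  cv <- confusion_metrics(tp = 52, fn = 3, tn = 64, fp = 1)
  expect_equal(cv$accuracy, 96.7)
  expect_equal(cv$specificity, 98.5)
  expect_equal(cv$ppv, 98.1)
  expect_equal(cv$npv, 95.5)
})

test_that("undefined metrics are reported as NA, not zero", {
  m <- confusion_metrics(tp = 0, fn = 0, tn = 5, fp = 0)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
  expect_equal(m$specificity, 100)
})
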