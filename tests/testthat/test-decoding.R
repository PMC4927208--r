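test_that("coefficient vectorization is a recorded, invertible flattening", {
  set.seed(20)
  h <- array(runif(6 * 2 * 9), c(6, 2, 9))
  labels <- rep(c("x", "y"), 3)
  tab <- vectorize_coefficients(list(h = h), labels)
  expect_identical(ncol(tab) - 1L, 18L)   # P * L features
  expect_identical(unvectorize_coefficients(tab), h)
  # named column (p = 1, l = 2) equals direct indexing
  expect_identical(tab$h_p1_l2, h[, 1, 2])
  fi <- attr(tab, "feature_index")
  j <- which(fi$p == 2 & fi$l == 5)
  expect_identical(tab[[fi$column[j]]], h[, 2, 5])
  expect_error(vectorize_coefficients(list(h = h), labels[1:3]),
               class = "spacebytime_validation_error")
})

test_that("the shrinkage LDA matches closed forms and brute-force scores", {
  # two 1-D classes at means 0 and 2: boundary at the midpoint 1
  tab <- two_class_table(0, 2, n = 200, sd = 0.4, seed = 21)
  fit <- fit_lda(tab, shrinkage = 0)
  bnd <- lda_boundary_2d(
    dplyr::mutate(tab, f2 = f1 + rnorm(dplyr::n(), sd = 0.4)),
    features = c("f1", "f2"))
  expect_equal(unname(fit$class_means[, 1]), c(0, 2), tolerance = 0.1)
  # brute-force per-point discriminant evaluation agrees with predict()
  xy <- spacebytime:::table_xy(tab)
  pred <- predict(fit, xy$x)
  inv <- solve(fit$pooled_covariance)
  brute <- apply(xy$x, 1, function(xi) {
    sc <- vapply(1:2, function(k) {
      m <- fit$class_means[k, ]
      drop(xi %*% inv %*% m) - 0.5 * drop(m %*% inv %*% m) +
        log(fit$priors[k])
    }, numeric(1))
    fit$classes[which.max(sc)]
  })
  expect_identical(as.character(pred), brute)
  # boundary w points toward the second class's mean
  expect_gt(sum(bnd$w * (fit$class_means[2, 1] - fit$class_means[1, 1])), 0)
})

test_that("LDA predictions agree with an independent reference fit", {
  skip_if_not_installed("MASS")
  tab <- two_class_table(c(0, 0, 1), c(1.5, 0.5, 0), n = 80, seed = 22)
  xy <- spacebytime:::table_xy(tab)
  ours <- predict(fit_lda(xy$x, xy$y, shrinkage = 0), xy$x)
  ref <- predict(MASS::lda(xy$x, grouping = xy$y))$class
  expect_gt(mean(as.character(ours) == as.character(ref)), 0.99)
})

test_that("duplicated features with shrinkage do not change predictions", {
  tab <- two_class_table(c(0, 1), c(1, 0), n = 60, seed = 23)
  xy <- spacebytime:::table_xy(tab)
  x2 <- cbind(xy$x, xy$x)   # exact duplicates: singular without shrinkage
  expect_error(fit_lda(x2, xy$y, shrinkage = 0),
               class = "spacebytime_numerical_error")
  p1 <- predict(fit_lda(xy$x, xy$y, shrinkage = 1e-3), xy$x)
  p2 <- predict(fit_lda(x2, xy$y, shrinkage = 1e-3), x2)
  expect_identical(p1, p2)
})

test_that("leave-one-out decoding separates what is separable", {
  # means +/- 3 at unit sd: Bayes accuracy pnorm(3) ~ 99.9%
  tab <- two_class_table(-3, 3, n = 100, sd = 1, seed = 24)
  res <- loo_cv_decode(tab)
  expect_gt(res$accuracy, 95)
  expect_equal(unname(rowSums(res$confusion)), c(1, 1), tolerance = 1e-12)
  expect_equal(res$accuracy,
               100 * sum(diag(res$confusion) *
                         as.numeric(table(res$truth))) / res$n_trials,
               tolerance = 1e-9)
  # fully separated classes give an identity confusion matrix
  sep <- two_class_table(-50, 50, n = 30, sd = 0.5, seed = 25)
  expect_equal(unclass(loo_cv_decode(sep)$confusion), diag(2),
               ignore_attr = TRUE)
  # feature permutation leaves the leave-one-out accuracy unchanged
  tab3 <- two_class_table(c(-1, 0.5, 1), c(1, 0, -1), n = 60, seed = 26)
  tab3p <- tab3[, c("f3", "f1", "f2", ".label")]
  expect_equal(loo_cv_decode(tab3)$accuracy, loo_cv_decode(tab3p)$accuracy)
})

test_that("label-free features decode at chance for 2 and 6 classes", {
  accs2 <- vapply(1:5, function(s) {
    loo_cv_decode(chance_table(150, d = 5, seed = s))$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs2) - 50), 6)
  set.seed(26)
  x <- matrix(abs(rnorm(180 * 4)), ncol = 4)
  colnames(x) <- paste0("f", 1:4)
  tab6 <- tibble::as_tibble(x)
  tab6$.label <- rep(letters[1:6], each = 30)
  acc6 <- loo_cv_decode(tab6)$accuracy
  expect_lt(abs(acc6 - 100 / 6), 8)
})

test_that("decoding errors on unusable inputs", {
  tab <- two_class_table(0, 1, n = 2, seed = 27)
  tab_bad <- tab[c(1, 2, 3), ]        # class b has a single trial
  expect_error(loo_cv_decode(tab_bad),
               class = "spacebytime_insufficient_data_error")
  expect_error(fit_lda(matrix(rnorm(10), 5, 2), rep("a", 5)),
               class = "spacebytime_validation_error")
})

test_that("subspace powers isolate the informative component", {
  # only AU component 2 differs between classes
  set.seed(28)
  h <- array(runif(240 * 2 * 3, 0.5, 1), c(240, 2, 3))
  labels <- rep(c("a", "b"), each = 120)
  h[labels == "b", , 2] <- h[labels == "b", , 2] + 1.5
  tab <- vectorize_coefficients(list(h = h), labels)
  pw <- subspace_power(tab, "au_component")
  expect_identical(nrow(pw), 3L)
  expect_gt(pw$accuracy[pw$l == 2] - max(pw$accuracy[pw$l != 2]), 20)
  # uninformative components sit near two-class chance
  expect_lt(abs(pw$accuracy[pw$l == 1] - 50), 10)
  # full coefficient grid is reported for all P * L combinations
  pwc <- subspace_power(tab, "coefficient")
  expect_identical(nrow(pwc), 6L)
  expect_error(subspace_power(tab, "au_component", index = 9),
               class = "spacebytime_validation_error")
})

test_that("the 2-D boundary respects symmetry and translation", {
  # classes mirrored about the line x = y
  set.seed(29)
  n <- 300
  base <- cbind(rnorm(n, 1, 0.3), rnorm(n, 0, 0.3))
  tab <- tibble::tibble(f1 = c(base[, 1], base[, 2]),
                        f2 = c(base[, 2], base[, 1]),
                        .label = rep(c("a", "b"), each = n))
  bnd <- lda_boundary_2d(tab)
  dir <- bnd$w / sqrt(sum(bnd$w^2))
  expect_equal(unname(abs(dir)), c(1, 1) / sqrt(2), tolerance = 1e-6)
  expect_equal(bnd$b / sqrt(sum(bnd$w^2)), 0, tolerance = 1e-6)
  # boundary sign agrees with full LDA predictions on every training point
  fit <- fit_lda(tab)
  xy <- spacebytime:::table_xy(tab)
  side <- drop(xy$x %*% bnd$w + bnd$b) > 0
  expect_identical(side, as.character(predict(fit, xy$x)) == bnd$classes[2])
  # translating both classes shifts b, not w
  tab2 <- dplyr::mutate(tab, f1 = f1 + 2, f2 = f2 - 1)
  bnd2 <- lda_boundary_2d(tab2)
  expect_equal(bnd2$w, bnd$w, tolerance = 1e-9)
  expect_equal(bnd2$b, bnd$b - sum(bnd$w * c(2, -1)), tolerance = 1e-9)
  # coincident class means are degenerate
  same <- tibble::tibble(f1 = rep(rnorm(20), 2), f2 = rep(rnorm(20), 2),
                         .label = rep(c("a", "b"), each = 20))
  expect_error(lda_boundary_2d(same), class = "spacebytime_degenerate_error")
})

test_that("coefficient decoding beats raw-pixel decoding on low-rank data", {
  # planted low-rank data with far fewer trials than T * S raw features
  fx <- recovery_fixture(n_per_class = 20, seed = 30, coeff_noise = 0.4)
  fit <- fit_sbt(fx$data, 2, 3, restarts = 3, max_iter = 400, seed = 31)
  coef_acc <- loo_cv_decode(vectorize_coefficients(fit, fx$data$labels))$accuracy
  flat <- matrix(fx$data$data, nrow = dim(fx$data$data)[1])
  colnames(flat) <- paste0("v", seq_len(ncol(flat)))
  raw_tab <- tibble::as_tibble(flat)
  raw_tab$.label <- fx$data$labels
  raw_acc <- loo_cv_decode(raw_tab)$accuracy
  expect_gte(coef_acc, raw_acc)
})
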