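# brute-force relative error, no matrix products (independent oracle)
naive_rel_error <- function(model, data) {
  num <- 0; den <- 0
  d <- dim(data$data)
  for (n in seq_len(d[1])) for (t in seq_len(d[2])) for (s in seq_len(d[3])) {
    rec <- 0
    for (p in seq_len(ncol(model$w_tem))) for (l in seq_len(nrow(model$w_spa))) {
      rec <- rec + model$w_tem[t, p] * model$h[n, p, l] * model$w_spa[l, s]
    }
    num <- num + (data$data[n, t, s] - rec)^2
    den <- den + data$data[n, t, s]^2
  }
  num / den
}

test_that("a rank-1 dataset is fit exactly at P = L = 1", {
  set.seed(10)
  u <- runif(8); v <- runif(5); cn <- runif(20, 0.5, 2)
  dat <- array(0, c(20, 8, 5))
  for (n in 1:20) dat[n, , ] <- cn[n] * (u %o% v)
  fit <- fit_sbt(dat, p = 1, l = 1, restarts = 3, seed = 1)
  expect_lt(fit$rel_error, 1e-8)
  # reconstruction_error agrees with its definition and the naive oracle
  tt <- as_tibble(trial_tensor(dat, seq(0, 1, length.out = 8),
                               paste0("AU", 1:5)))
  expect_equal(reconstruction_error(fit, dat), fit$rel_error, tolerance = 1e-9)
  expect_equal(reconstruction_error(fit, dat), naive_rel_error(fit, list(data = dat)),
               tolerance = 1e-9)
})

test_that("the objective trace is nonincreasing on arbitrary data", {
  set.seed(11)
  for (s in 1:3) {
    dat <- array(runif(15 * 10 * 6), c(15, 10, 6))
    fit <- fit_sbt(dat, p = 2, l = 2, restarts = 1, max_iter = 60, seed = s)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * tr[-length(tr)]))
  }
})

test_that("noiseless planted structure is recovered at the true order", {
  fx <- recovery_fixture(n_per_class = 30, seed = 12)
  fit <- fit_sbt(fx$data, p = 2, l = 3, restarts = 8, max_iter = 1500,
                 seed = 2)
  expect_lt(fit$rel_error, 1e-5)
  expect_true(all(match_components(fit$w_tem, fx$pm$w_tem)$cosine > 0.99))
  expect_true(all(match_components(t(fit$w_spa), t(fx$pm$w_spa))$cosine > 0.99))
  expect_true(all(fit$w_tem >= 0) && all(fit$w_spa >= 0) && all(fit$h >= 0))
})

test_that("normalization preserves the reconstruction and fixes scale", {
  set.seed(13)
  fx <- recovery_fixture(n_per_class = 10, seed = 13)
  fit <- fit_sbt(fx$data, p = 2, l = 3, restarts = 2, max_iter = 200, seed = 3)
  expect_equal(unname(sqrt(colSums(fit$w_tem^2))), rep(1, 2), tolerance = 1e-12)
  expect_equal(unname(sqrt(rowSums(fit$w_spa^2))), rep(1, 3), tolerance = 1e-12)
  err1 <- reconstruction_error(fit, fx$data)
  renorm <- normalize_sbt(fit)
  expect_equal(reconstruction_error(renorm, fx$data), err1, tolerance = 1e-12)
  # scale equivariance: data * 4 with the same seed gives the same unit-norm
  # factors and coefficients scaled by 4
  scaled <- fx$data
  scaled$data <- scaled$data * 4
  fit4 <- fit_sbt(scaled, p = 2, l = 3, restarts = 2, max_iter = 200, seed = 3)
  expect_equal(fit4$w_tem, fit$w_tem, tolerance = 1e-6)
  expect_equal(fit4$w_spa, fit$w_spa, tolerance = 1e-6)
  expect_equal(fit4$h, 4 * fit$h, tolerance = 1e-5)
})

test_that("permuting AU columns permutes the spatial factor equivalently", {
  fx <- recovery_fixture(n_per_class = 15, seed = 14)
  perm <- c(3, 1, 4, 2, 6, 5, 8, 7)
  permuted <- fx$data
  permuted$data <- fx$data$data[, , perm]
  permuted$au_codes <- fx$data$au_codes[perm]
  fit1 <- fit_sbt(fx$data, 2, 3, restarts = 5, max_iter = 1000, seed = 4)
  fit2 <- fit_sbt(permuted, 2, 3, restarts = 5, max_iter = 1000, seed = 4)
  m <- match_components(t(fit2$w_spa), t(fit1$w_spa[, perm]))
  expect_true(all(m$cosine > 0.99))
})

test_that("component matching recovers known permutations", {
  set.seed(15)
  w <- matrix(runif(10 * 4), 10, 4)
  self <- match_components(w, w)
  expect_identical(self$permutation, 1:4)
  expect_equal(self$cosine, rep(1, 4))
  perm <- c(3, 1, 4, 2)
  m <- match_components(w[, perm], w)
  expect_identical(m$permutation, as.integer(perm))
  # orthogonal components match with zero similarity
  ortho <- match_components(diag(4)[, 1:2], diag(4)[, 3:4])
  expect_equal(ortho$cosine, c(0, 0))
  expect_error(match_components(w, w[, 1:2]),
               class = "spacebytime_validation_error")
})

test_that("reconstruction error handles the degenerate limits", {
  pm <- planted_model(cbind(c(1, 1)), rbind(c(1, 1)),
                      list(a = matrix(1)))
  tt <- simulate_planted(pm, 3, seed = 1)
  zero_model <- list(w_tem = cbind(c(0, 0)), w_spa = rbind(c(0, 0)),
                     h = array(0, c(3, 1, 1)))
  class(zero_model) <- "sbt_model"
  expect_equal(reconstruction_error(zero_model, tt), 1)
  expect_error(normalize_sbt(zero_model),
               class = "spacebytime_degenerate_error")
  zero_data <- trial_tensor(array(0, c(3, 2, 2)), c(0, 1), c("AU1", "AU2"))
  expect_error(reconstruction_error(zero_model, zero_data),
               class = "spacebytime_degenerate_error")
  expect_error(fit_sbt(tt, p = 5, l = 1), class = "spacebytime_config_error")
})

test_that("decompositions of the same data from different seeds agree", {
  fx <- recovery_fixture(n_per_class = 20, seed = 16)
  fit1 <- fit_sbt(fx$data, 2, 3, restarts = 5, max_iter = 800, seed = 21)
  fit2 <- fit_sbt(fx$data, 2, 3, restarts = 5, max_iter = 800, seed = 22)
  cmp <- compare_decompositions(fit1, fit2)
  expect_identical(cmp$type, c("temporal", "spatial"))
  expect_true(all(cmp$mean_r > 0.99))
  # identical models: correlation exactly 1 with zero sem
  self <- compare_decompositions(fit1, fit1)
  expect_equal(self$mean_r, c(1, 1))
  expect_equal(self$sem_r, c(0, 0), tolerance = 1e-12)
})
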