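# planted coefficient table for a two-class problem:
#   component 1 "shared"  — identical class-conditional coefficients
#   component 2 diagnostic for b — elevated only under class b
#   component 3 nearly silent — excluded by the 10% activation rule
planted_pair_table <- function(n = 120, seed = 40) {
  set.seed(seed)
  h <- array(runif(2 * n * 2 * 3, 0.8, 1.2), c(2 * n, 2, 3))
  labels <- rep(c("a", "b"), each = n)
  h[labels == "b", , 2] <- h[labels == "b", , 2] + 1.5
  h[, , 3] <- h[, , 3] * 0.02
  vectorize_coefficients(list(h = h), labels)
}

test_that("the activation-exclusion rule retains the right components", {
  tab <- planted_pair_table()
  active <- active_components(tab, c("a", "b"))
  expect_identical(active, c(1L, 2L))          # component 3 is ~1% of max
  expect_identical(active_components(tab, c("a", "b"), threshold = 0),
                   1:3)
  # hand-computed toy check: per-component activation is the max over
  # temporal coefficients of the trial mean
  h <- array(0, c(4, 2, 3))
  h[, 1, 1] <- 1;  h[, 2, 1] <- 0.2
  h[, 1, 2] <- 0.04; h[, 2, 2] <- 0.09
  h[, 1, 3] <- 0.5; h[, 2, 3] <- 0.6
  toy <- vectorize_coefficients(list(h = h), rep(c("a", "b"), 2))
  expect_identical(active_components(toy, c("a", "b")), c(1L, 3L))
  expect_error(active_components(toy, c("a", "zz")),
               class = "spacebytime_validation_error")
})

test_that("shared and diagnostic roles are assigned from decoding power", {
  tab <- planted_pair_table()
  roles <- classify_roles(tab, c("a", "b"))
  expect_identical(roles$component, c(1L, 2L))
  expect_identical(roles$role[1], "shared")
  expect_identical(roles$role[2], "diagnostic_for_b")
  expect_lt(abs(roles$power[1] - 50), 5)       # within the chance band
  expect_gt(roles$power[2], 55)                # well above the band
})

test_that("pair reports assemble powers, bars and roles coherently", {
  tab <- planted_pair_table()
  h <- unvectorize_coefficients(tab)
  model <- list(h = h, w_tem = matrix(runif(12 * 2), 12, 2),
                w_spa = matrix(runif(3 * 5), 3, 5))
  labels <- tab$.label
  rep <- pair_report(model, labels, c("a", "b"))
  expect_identical(rep$active_components, c(1L, 2L))
  # report's best component power equals the max over direct subspace calls
  sub <- spacebytime:::restore_table_attrs(
    dplyr::filter(tab, .data$.label %in% c("a", "b")), tab)
  direct <- subspace_power(sub, "au_component")
  expect_equal(max(rep$component_power$accuracy), max(direct$accuracy))
  # bar data: one mean +/- sem per class x temporal x component
  expect_identical(nrow(rep$mean_coefficients), 2L * 2L * 3L)
  expect_true(all(rep$combination_power$accuracy >= 0 &
                  rep$combination_power$accuracy <= 100))
  # roles partition the active set
  expect_identical(sort(rep$roles$component), rep$active_components)
  expect_error(pair_report(model, rep("a", length(labels)), c("a", "b")),
               class = "spacebytime_validation_error")
})

test_that("removing a diagnostic component hurts; removing a shared one does not", {
  tab <- planted_pair_table()
  fi <- attr(tab, "feature_index")
  full_cols <- fi$column[fi$l %in% c(1, 2)]
  no_diag <- fi$column[fi$l == 1]
  no_shared <- fi$column[fi$l == 2]
  acc_full <- loo_cv_decode(tab, features = full_cols)$accuracy
  acc_no_diag <- loo_cv_decode(tab, features = no_diag)$accuracy
  acc_no_shared <- loo_cv_decode(tab, features = no_shared)$accuracy
  expect_gt(acc_full - acc_no_diag, 20)
  expect_lt(abs(acc_full - acc_no_shared), 5)
})
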