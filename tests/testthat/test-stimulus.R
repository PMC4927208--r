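test_that("AU subset sizes follow the truncated binomial", {
  cfg <- generator_config()
  set.seed(1)
  sizes <- replicate(1e5, length(sample_au_subset(cfg)))
  expect_true(all(sizes >= 1 & sizes <= 6))
  expect_identical(median(sizes), 3)

  # empirical distribution vs the analytic truncated pmf (renormalized after
  # dropping k = 0): total-variation distance < 0.01 at 1e5 draws
  pmf <- subset_size_pmf(cfg)
  emp <- tabulate(sizes, nbins = max(pmf$size)) / length(sizes)
  tv <- 0.5 * sum(abs(emp[pmf$size] - pmf$prob))
  expect_lt(tv, 0.01)

  # every subset is a distinct-member draw from the catalog
  s <- sample_au_subset(cfg)
  expect_true(all(s %in% cfg$catalog))
  expect_identical(anyDuplicated(s), 0L)
})

test_that("temporal parameters satisfy the ordering and uniform marginals", {
  cfg <- generator_config()
  set.seed(2)
  draws <- replicate(1e4, {
    p <- sample_temporal_params(cfg)
    c(p$onset_latency, p$peak_latency, p$offset_latency, p$peak_amplitude)
  })
  expect_true(all(draws[1, ] < draws[2, ]))          # onset < peak
  expect_true(all(draws[2, ] <= draws[3, ]))         # peak <= offset
  expect_true(all(draws[3, ] <= 1.25))               # within the animation
  expect_true(all(draws[1, ] >= 0))
  # amplitude is an unconditioned uniform: mean = midpoint of [0.2, 1]
  expect_equal(mean(draws[4, ]), 0.6, tolerance = 0.01)
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(binomial_p = 1.2),
               class = "spacebytime_config_error")
  expect_error(generator_config(min_aus = 3, max_aus = 2),
               class = "spacebytime_config_error")
  expect_error(
    generator_config(param_ranges = list(onset = c(0.9, 1.0),
                                         peak = c(0.1, 0.5))),
    class = "spacebytime_config_error")
  expect_error(temporal_params(0.5, 1, 0.5, 0.4, 1, 1),  # onset > peak
               class = "spacebytime_validation_error")
})

test_that("rendered curves rise to the peak and fall to the offset", {
  tg <- seq(0, 1.25, by = 0.05)
  p <- temporal_params(onset_latency = 0.2, acceleration = 2,
                       peak_amplitude = 0.8, peak_latency = 0.5,
                       deceleration = 0.7, offset_latency = 1.0)
  y <- render_curve(p, tg)
  expect_true(all(y >= 0))
  expect_true(all(y[tg < 0.2] == 0))
  expect_true(all(y[tg > 1.0] == 0))
  # peak latency lies on this grid: exact peak value there
  expect_identical(y[tg == 0.5], 0.8)
  # monotone rise then fall, checked by successive differences
  expect_true(all(diff(y[tg >= 0.2 & tg <= 0.5]) >= 0))
  expect_true(all(diff(y[tg >= 0.5 & tg <= 1.0]) <= 0))
  # zero amplitude gives the zero curve
  p0 <- temporal_params(0.2, 2, 0, 0.5, 0.7, 1.0)
  expect_true(all(render_curve(p0, tg) == 0))
})

test_that("trial rendering stacks per-AU curves into the catalog frame", {
  tg <- seq(0, 1.25, by = 0.05)
  catalog <- au_catalog()
  ps <- list(temporal_params(0.1, 1, 0.9, 0.4, 1, 0.8),
             temporal_params(0.3, 2, 0.5, 0.7, 2, 1.2),
             temporal_params(0.0, 1, 0.7, 0.6, 1, 0.6))
  spec <- stimulus_spec(c("AU5", "AU26", "AU9"), ps)
  m <- render_trial(spec, tg, catalog)
  expect_identical(dim(m), c(length(tg), 42L))
  nz <- colSums(m) > 0
  expect_identical(sort(colnames(m)[nz]), sort(c("AU5", "AU26", "AU9")))
  # matrix equals column-stacking of independently rendered curves
  for (i in seq_along(ps)) {
    expect_identical(m[, spec$au_ids[i]], render_curve(ps[[i]], tg))
  }
  expect_error(render_trial(stimulus_spec("AU999", ps[1]), tg, catalog),
               class = "spacebytime_validation_error")
  expect_error(stimulus_spec(character(0), list()),
               class = "spacebytime_validation_error")
})

test_that("a simulated experiment is shaped, nonnegative and reproducible", {
  cfg <- generator_config()
  tt1 <- simulate_experiment(cfg, 40, seed = 99)
  tt2 <- simulate_experiment(cfg, 40, seed = 99)
  expect_identical(dim(tt1), c(40L, 26L, 42L))
  expect_true(all(tt1$data >= 0))
  expect_identical(tt1$data, tt2$data)   # seeded determinism, bit-exact
  # full 42-AU six-parameter encoding spans 252 degrees of freedom
  expect_identical(ncol(stimulus_parameter_matrix(tt1)), 252L)
})
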