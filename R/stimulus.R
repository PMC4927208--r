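#' Stimulus generator configuration
#'
#' Parameters of the synthetic dynamic-expression generator. Defaults follow
#' the generative stimulus procedure this package emulates: on each trial a
#' subset of AUs is drawn from a Binomial(`binomial_n`, `binomial_p`)
#' truncated to `[min_aus, max_aus]` (defaults give a median subset size of
#' 3), and each selected AU receives six temporal parameters drawn uniformly
#' and rendered to an activation curve over a `duration`-second animation.
#'
#' `param_ranges` is a named list of length-2 numeric bounds:
#' \describe{
#'   \item{onset}{onset latency (s), default `c(0, 0.5)`}
#'   \item{peak}{peak latency (s), drawn uniformly on
#'     `[max(onset + min_gap, peak[1]), peak[2]]`, default `c(0.1, 1)`}
#'   \item{offset}{offset latency (s), drawn on `[max(peak, offset[1]), offset[2]]`,
#'     default `c(0, 1.25)`}
#'   \item{amplitude}{peak amplitude in `[0, 1]`, default `c(0.2, 1)`}
#'   \item{acceleration, deceleration}{shape exponents `> 0`, default `c(0.5, 3)`}
#' }
#'
#' @param binomial_n,binomial_p Binomial size and success probability for the
#'   AU-subset size.
#' @param min_aus,max_aus Truncation bounds for the subset size.
#' @param duration Animation duration in seconds.
#' @param n_time Number of time samples spanning `[0, duration]`.
#' @param param_ranges Named list of uniform bounds, see Details.
#' @param min_gap Minimum onset-to-peak separation (s).
#' @param catalog Character vector of AU codes to sample from.
#' @return A `generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config()
#' cfg$binomial_n
generator_config <- function(binomial_n = 5L, binomial_p = 0.6,
                             min_aus = 1L, max_aus = 6L,
                             duration = 1.25, n_time = 26L,
                             param_ranges = list(), min_gap = 0.1,
                             catalog = au_catalog()) {
  defaults <- list(onset = c(0, 0.5), peak = c(0.1, 1.0),
                   offset = c(0, 1.25), amplitude = c(0.2, 1),
                   acceleration = c(0.5, 3), deceleration = c(0.5, 3))
  param_ranges <- modifyList(defaults, param_ranges)
  cfg <- list(binomial_n = as.integer(binomial_n), binomial_p = binomial_p,
              min_aus = as.integer(min_aus), max_aus = as.integer(max_aus),
              duration = duration, n_time = as.integer(n_time),
              param_ranges = param_ranges, min_gap = min_gap,
              catalog = as.character(catalog))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$binomial_p <= 0 || cfg$binomial_p >= 1) {
    abort("`binomial_p` must lie in (0, 1).", class = "spacebytime_config_error")
  }
  if (cfg$min_aus < 1L || cfg$max_aus < cfg$min_aus) {
    abort("Need 1 <= min_aus <= max_aus.", class = "spacebytime_config_error")
  }
  if (length(cfg$catalog) < cfg$max_aus) {
    abort("AU catalog smaller than `max_aus`.", class = "spacebytime_config_error")
  }
  pr <- cfg$param_ranges
  if (any(vapply(pr, function(r) r[1L] > r[2L], logical(1)))) {
    abort("Every parameter range needs lower <= upper.",
          class = "spacebytime_config_error")
  }
  for (nm in c("onset", "peak", "offset")) {
    if (pr[[nm]][1L] < 0 || pr[[nm]][2L] > cfg$duration) {
      abort(sprintf("Latency range `%s` must lie within [0, duration].", nm),
            class = "spacebytime_config_error")
    }
  }
  if (pr$onset[1L] + cfg$min_gap > pr$peak[2L] || pr$peak[1L] > cfg$duration) {
    abort("Latency ranges make onset < peak unsatisfiable.",
          class = "spacebytime_config_error")
  }
  invisible(cfg)
}

#' Time grid of a generator configuration
#' @param cfg A [generator_config()].
#' @return Numeric vector of `n_time` equally spaced seconds over
#'   `[0, duration]`.
#' @export
time_grid <- function(cfg) seq(0, cfg$duration, length.out = cfg$n_time)

#' Probability mass of the truncated binomial subset size
#'
#' Analytic pmf of Binomial(`binomial_n`, `binomial_p`) truncated by
#' rejection to `[min_aus, max_aus]`, i.e. renormalized over the retained
#' support.
#'
#' @param cfg A [generator_config()].
#' @return Tibble with columns `size` and `prob` (summing to 1).
#' @export
#' @examples
#' subset_size_pmf(generator_config())
subset_size_pmf <- function(cfg) {
  ks <- cfg$min_aus:min(cfg$max_aus, cfg$binomial_n)
  p <- dbinom(ks, cfg$binomial_n, cfg$binomial_p)
  tibble::tibble(size = ks, prob = p / sum(p))
}

#' Sample an AU subset for one trial
#'
#' Draws the subset size from the truncated binomial (rejection sampling:
#' redraw while outside `[min_aus, max_aus]`), then the members uniformly
#' without replacement from the catalog.
#'
#' @param cfg A [generator_config()].
#' @return Character vector of distinct AU codes.
#' @export
sample_au_subset <- function(cfg) {
  repeat {
    k <- stats::rbinom(1L, cfg$binomial_n, cfg$binomial_p)
    if (k >= cfg$min_aus && k <= cfg$max_aus) break
  }
  sample(cfg$catalog, k)
}

#' Sample the six temporal parameters of one AU
#'
#' Onset latency is uniform on its range; peak latency uniform on
#' `[max(onset + min_gap, peak[1]), peak[2]]`; offset uniform on
#' `[max(peak, offset[1]), offset[2]]` — so `onset < peak <= offset` holds by
#' construction. Amplitude and the two shape exponents are independent
#' uniforms.
#'
#' @param cfg A [generator_config()].
#' @return A `temporal_params` list with fields `onset_latency`,
#'   `acceleration`, `peak_amplitude`, `peak_latency`, `deceleration`,
#'   `offset_latency`.
#' @export
sample_temporal_params <- function(cfg) {
  pr <- cfg$param_ranges
  onset <- runif(1L, pr$onset[1L], pr$onset[2L])
  peak_lo <- max(onset + cfg$min_gap, pr$peak[1L])
  if (peak_lo > pr$peak[2L]) {
    # configured onset range can exceed peak range; redraw onset where feasible
    onset <- runif(1L, pr$onset[1L], min(pr$onset[2L], pr$peak[2L] - cfg$min_gap))
    peak_lo <- max(onset + cfg$min_gap, pr$peak[1L])
  }
  peak <- runif(1L, peak_lo, pr$peak[2L])
  off_lo <- max(peak, pr$offset[1L])
  offset <- runif(1L, off_lo, max(off_lo, pr$offset[2L]))
  temporal_params(
    onset_latency = onset,
    acceleration = runif(1L, pr$acceleration[1L], pr$acceleration[2L]),
    peak_amplitude = runif(1L, pr$amplitude[1L], pr$amplitude[2L]),
    peak_latency = peak,
    deceleration = runif(1L, pr$deceleration[1L], pr$deceleration[2L]),
    offset_latency = offset,
    duration = cfg$duration)
}

#' Construct and validate temporal curve parameters
#'
#' @param onset_latency,peak_latency,offset_latency Latencies in seconds,
#'   `0 <= onset < peak <= offset <= duration`.
#' @param acceleration,deceleration Positive shape exponents of the rising
#'   and falling curve segments.
#' @param peak_amplitude Peak activation in `[0, 1]`.
#' @param duration Trial duration in seconds.
#' @return A `temporal_params` list.
#' @export
temporal_params <- function(onset_latency, acceleration, peak_amplitude,
                            peak_latency, deceleration, offset_latency,
                            duration = 1.25) {
  p <- list(onset_latency = onset_latency, acceleration = acceleration,
            peak_amplitude = peak_amplitude, peak_latency = peak_latency,
            deceleration = deceleration, offset_latency = offset_latency,
            duration = duration)
  ok <- onset_latency >= 0 && onset_latency < peak_latency &&
    peak_latency <= offset_latency && offset_latency <= duration &&
    peak_amplitude >= 0 && peak_amplitude <= 1 &&
    acceleration > 0 && deceleration > 0
  if (!isTRUE(ok)) {
    abort("Invalid temporal parameters: need 0 <= onset < peak <= offset <= duration, amplitude in [0,1], positive shape exponents.",
          class = "spacebytime_validation_error")
  }
  structure(p, class = "temporal_params")
}

#' Render one AU activation curve
#'
#' Piecewise power ramp: zero outside `[onset, offset]`, rising as
#' `A * ((t - t_on) / (t_pk - t_on))^acceleration` and falling as
#' `A * (1 - (t - t_pk) / (t_off - t_pk))^deceleration`, hitting
#' `peak_amplitude` exactly at `peak_latency`.
#'
#' @param params A [temporal_params()].
#' @param time_grid Numeric vector of sample times within `[0, duration]`.
#' @return Nonnegative numeric vector, one value per grid point.
#' @export
#' @examples
#' p <- temporal_params(0.1, 1, 0.8, 0.5, 2, 1.0)
#' render_curve(p, seq(0, 1.25, by = 0.05))
render_curve <- function(params, time_grid) {
  if (!inherits(params, "temporal_params")) {
    params <- do.call(temporal_params, as.list(params))
  }
  t_on <- params$onset_latency
  t_pk <- params$peak_latency
  t_off <- params$offset_latency
  a <- params$peak_amplitude
  y <- numeric(length(time_grid))
  rise <- time_grid >= t_on & time_grid <= t_pk
  y[rise] <- a * ((time_grid[rise] - t_on) / (t_pk - t_on))^params$acceleration
  if (t_off > t_pk) {
    fall <- time_grid > t_pk & time_grid <= t_off
    y[fall] <- a * (1 - (time_grid[fall] - t_pk) / (t_off - t_pk))^params$deceleration
  }
  y
}

#' Stimulus specification for one trial
#'
#' @param au_ids Character vector of 1..`max_aus` distinct AU codes.
#' @param params List of [temporal_params()], one per AU in `au_ids`.
#' @return A `stimulus_spec` list.
#' @export
stimulus_spec <- function(au_ids, params) {
  au_ids <- as.character(au_ids)
  if (length(au_ids) < 1L || anyDuplicated(au_ids)) {
    abort("`au_ids` must be a nonempty set of distinct AU codes.",
          class = "spacebytime_validation_error")
  }
  if (length(params) != length(au_ids)) {
    abort("One `temporal_params` per AU is required.",
          class = "spacebytime_validation_error")
  }
  structure(list(au_ids = au_ids, params = params), class = "stimulus_spec")
}

#' Render a full trial to a time-by-AU activation matrix
#'
#' @param spec A [stimulus_spec()].
#' @param time_grid Sample times in seconds.
#' @param catalog AU catalog defining the column order.
#' @return A `length(time_grid) x length(catalog)` nonnegative matrix;
#'   columns of unselected AUs are zero.
#' @export
render_trial <- function(spec, time_grid, catalog = au_catalog()) {
  miss <- setdiff(spec$au_ids, catalog)
  if (length(miss) > 0L) {
    abort(paste0("AU codes not in catalog: ", paste(miss, collapse = ", ")),
          class = "spacebytime_validation_error")
  }
  m <- matrix(0, nrow = length(time_grid), ncol = length(catalog),
              dimnames = list(NULL, catalog))
  for (i in seq_along(spec$au_ids)) {
    m[, spec$au_ids[i]] <- render_curve(spec$params[[i]], time_grid)
  }
  m
}

#' Simulate a full randomized-expression experiment
#'
#' Generates `n_trials` independent stimuli: an AU subset from the truncated
#' binomial, six temporal parameters per selected AU, curves rendered over
#' the configured time grid. The per-trial [stimulus_spec()]s are attached as
#' attribute `"specs"` so the raw six-parameter encoding remains available
#' via [stimulus_parameter_matrix()].
#'
#' @param cfg A [generator_config()].
#' @param n_trials Number of trials (the emulated study used 2400 per
#'   observer).
#' @param seed Optional integer seed; identical config + seed reproduce the
#'   tensor bit-exactly.
#' @return An unlabeled [trial_tensor()].
#' @export
#' @examples
#' tt <- simulate_experiment(generator_config(), n_trials = 5, seed = 1)
#' dim(tt)
simulate_experiment <- function(cfg, n_trials, seed = NULL) {
  if (n_trials < 1L) {
    abort("`n_trials` must be >= 1.", class = "spacebytime_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  tg <- time_grid(cfg)
  S <- length(cfg$catalog)
  dat <- array(0, dim = c(n_trials, cfg$n_time, S))
  specs <- vector("list", n_trials)
  for (n in seq_len(n_trials)) {
    aus <- sample_au_subset(cfg)
    pars <- purrr::map(aus, function(a) sample_temporal_params(cfg))
    specs[[n]] <- stimulus_spec(aus, pars)
    dat[n, , ] <- render_trial(specs[[n]], tg, cfg$catalog)
  }
  tt <- trial_tensor(dat, tg, cfg$catalog)
  attr(tt, "specs") <- specs
  attr(tt, "seed") <- seed
  tt
}

#' Raw six-parameter stimulus encoding
#'
#' Flattens each trial's stimulus specification to the raw parameter space:
#' one column per (AU, temporal parameter) pair, zero where the AU was not
#' selected. With the full 42-AU catalog this is the 42 x 6 = 252-dimensional
#' degrees-of-freedom space of the stimulus generator.
#'
#' @param experiment A [trial_tensor()] produced by [simulate_experiment()]
#'   (carrying per-trial specs).
#' @return A tibble with `n_trials` rows and `6 * S` numeric columns named
#'   `<au>_<parameter>`.
#' @export
stimulus_parameter_matrix <- function(experiment) {
  specs <- attr(experiment, "specs")
  if (is.null(specs)) {
    abort("`experiment` carries no stimulus specs (not from simulate_experiment()).",
          class = "spacebytime_validation_error")
  }
  catalog <- experiment$au_codes
  pnames <- c("onset_latency", "acceleration", "peak_amplitude",
              "peak_latency", "deceleration", "offset_latency")
  cols <- as.vector(outer(catalog, pnames, paste, sep = "_"))
  m <- matrix(0, nrow = length(specs), ncol = length(catalog) * 6L,
              dimnames = list(NULL, cols))
  for (n in seq_along(specs)) {
    sp <- specs[[n]]
    for (i in seq_along(sp$au_ids)) {
      v <- unlist(sp$params[[i]][pnames], use.names = FALSE)
      m[n, paste(sp$au_ids[i], pnames, sep = "_")] <- v
    }
  }
  tibble::as_tibble(m)
}
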