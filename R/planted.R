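#' Planted space-by-time ground-truth model
#'
#' Defines a known tri-factorization from which labeled trials can be
#' simulated: per trial of class `c`, coefficients
#' `H_n = class_coeff_means[[c]] + noise` (zero-mean Gaussian of sd
#' `coeff_noise_scale`, clipped at 0) and data
#' `M_n = w_tem %*% H_n %*% w_spa + noise` (sd `obs_noise_scale`, clipped at
#' 0). Optionally a Gaussian-copula correlation is imposed on one designated
#' coefficient pair before clipping.
#'
#' @param w_tem Nonnegative `T x P` matrix of temporal components (columns).
#' @param w_spa Nonnegative `L x S` matrix of AU components (rows).
#' @param class_coeff_means Named list of nonnegative `P x L` matrices, one
#'   per class.
#' @param coeff_noise_scale,obs_noise_scale Nonnegative noise standard
#'   deviations (clipping at zero makes the realized noise slightly
#'   nonzero-mean).
#' @param coeff_correlation Optional correlation in `[-1, 1]` imposed on the
#'   pair `corr_pair`.
#' @param corr_pair Optional list of two `c(p, l)` index pairs naming the
#'   correlated coefficients.
#' @param time_grid,au_codes Optional metadata carried into generated data.
#' @return A `planted_model` list.
#' @export
planted_model <- function(w_tem, w_spa, class_coeff_means,
                          coeff_noise_scale = 0, obs_noise_scale = 0,
                          coeff_correlation = NULL, corr_pair = NULL,
                          time_grid = NULL, au_codes = NULL) {
  w_tem <- as.matrix(w_tem); w_spa <- as.matrix(w_spa)
  if (any(w_tem < 0) || any(w_spa < 0)) {
    abort("Planted factors must be nonnegative.",
          class = "spacebytime_validation_error")
  }
  if (coeff_noise_scale < 0 || obs_noise_scale < 0) {
    abort("Noise scales must be >= 0.", class = "spacebytime_config_error")
  }
  if (length(class_coeff_means) < 1L) {
    abort("At least one class is required.", class = "spacebytime_config_error")
  }
  P <- ncol(w_tem); L <- nrow(w_spa)
  class_coeff_means <- lapply(class_coeff_means, function(h) {
    h <- as.matrix(h)
    if (any(h < 0) || nrow(h) != P || ncol(h) != L) {
      abort("Each class coefficient mean must be a nonnegative P x L matrix.",
            class = "spacebytime_validation_error")
    }
    h
  })
  if (is.null(names(class_coeff_means))) {
    names(class_coeff_means) <- paste0("class", seq_along(class_coeff_means))
  }
  if (!is.null(coeff_correlation)) {
    if (abs(coeff_correlation) > 1 || length(corr_pair) != 2L) {
      abort("`coeff_correlation` needs |rho| <= 1 and `corr_pair` = list(c(p,l), c(p,l)).",
            class = "spacebytime_config_error")
    }
  }
  if (is.null(time_grid)) time_grid <- seq(0, 1.25, length.out = nrow(w_tem))
  if (is.null(au_codes)) au_codes <- paste0("AU", seq_len(ncol(w_spa)))
  structure(
    list(w_tem = w_tem, w_spa = w_spa, class_coeff_means = class_coeff_means,
         coeff_noise_scale = coeff_noise_scale,
         obs_noise_scale = obs_noise_scale,
         coeff_correlation = coeff_correlation, corr_pair = corr_pair,
         time_grid = as.numeric(time_grid), au_codes = as.character(au_codes)),
    class = "planted_model")
}

#' Simulate labeled trials from a planted model
#'
#' @param pm A [planted_model()].
#' @param n_per_class Trials per class.
#' @param seed Optional integer seed.
#' @return A labeled [trial_tensor()]; the realized per-trial coefficient
#'   array (`N x P x L`) is attached as attribute `"h_true"`.
#' @export
#' @examples
#' pm <- planted_model(w_tem = cbind(c(1, 2, 1)), w_spa = rbind(c(1, 0.5)),
#'                     class_coeff_means = list(a = matrix(1), b = matrix(2)))
#' tt <- simulate_planted(pm, n_per_class = 3, seed = 1)
#' table(tt$labels)
simulate_planted <- function(pm, n_per_class, seed = NULL) {
  stopifnot(inherits(pm, "planted_model"))
  if (!is.null(seed)) set.seed(seed)
  P <- ncol(pm$w_tem); L <- nrow(pm$w_spa)
  Tn <- nrow(pm$w_tem); S <- ncol(pm$w_spa)
  classes <- names(pm$class_coeff_means)
  N <- n_per_class * length(classes)
  dat <- array(0, dim = c(N, Tn, S))
  h_true <- array(0, dim = c(N, P, L))
  labels <- character(N)
  n <- 0L
  for (cl in classes) {
    mu <- pm$class_coeff_means[[cl]]
    for (i in seq_len(n_per_class)) {
      n <- n + 1L
      h <- mu + coeff_noise(pm, P, L)
      h[h < 0] <- 0
      m <- pm$w_tem %*% h %*% pm$w_spa
      if (pm$obs_noise_scale > 0) {
        m <- m + matrix(rnorm(Tn * S, sd = pm$obs_noise_scale), Tn, S)
        m[m < 0] <- 0
      }
      dat[n, , ] <- m
      h_true[n, , ] <- h
      labels[n] <- cl
    }
  }
  tt <- trial_tensor(dat, pm$time_grid, pm$au_codes, labels = labels)
  attr(tt, "h_true") <- h_true
  attr(tt, "seed") <- seed
  tt
}

# Gaussian coefficient noise; the designated pair gets correlation rho via a
# bivariate normal (Gaussian copula collapses to this for normal marginals).
coeff_noise <- function(pm, P, L) {
  e <- matrix(rnorm(P * L, sd = pm$coeff_noise_scale), P, L)
  if (!is.null(pm$coeff_correlation) && pm$coeff_noise_scale > 0) {
    rho <- pm$coeff_correlation
    i1 <- pm$corr_pair[[1L]]; i2 <- pm$corr_pair[[2L]]
    z1 <- e[i1[1L], i1[2L]] / pm$coeff_noise_scale
    z2 <- e[i2[1L], i2[2L]] / pm$coeff_noise_scale
    e[i2[1L], i2[2L]] <- pm$coeff_noise_scale * (rho * z1 + sqrt(1 - rho^2) * z2)
  }
  e
}

#' Planted model emulating the study's component structure
#'
#' Builds a [planted_model()] whose ground-truth factors look like those the
#' decomposition recovers from facial-expression data: temporal components
#' are distinct activation bursts (staggered piecewise power curves over the
#' trial, mildly overlapping) and AU components activate largely disjoint AU
#' groups, each with one exclusive dominant AU. The disjoint support makes
#' the factorization essentially unique, so recovery can be scored against
#' the planted factors; dense unstructured nonnegative factors would not be
#' identifiable.
#'
#' @param p,l Numbers of temporal and AU components.
#' @param s Number of AUs (`>= l`).
#' @param n_time Time samples over `[0, duration]`.
#' @param duration Trial duration (s).
#' @param class_coeff_means As in [planted_model()]; default two classes
#'   with distinct coefficient patterns.
#' @param cross_loading Loading of each AU component on AUs outside its own
#'   group (0 gives perfectly disjoint supports).
#' @param ... Passed to [planted_model()] (noise scales, correlation, ...).
#' @return A `planted_model`.
#' @export
#' @examples
#' pm <- planted_study_model(p = 2, l = 3, s = 9)
#' dim(pm$w_tem); dim(pm$w_spa)
planted_study_model <- function(p = 2L, l = 3L, s = 10L, n_time = 26L,
                                duration = 1.25,
                                class_coeff_means = NULL,
                                cross_loading = 0.05, ...) {
  tg <- seq(0, duration, length.out = n_time)
  # staggered bursts: peaks spread over the trial, moderate width
  peaks <- seq(0.25, 0.8, length.out = p) * duration
  width <- 0.55 * duration / p
  w_tem <- vapply(seq_len(p), function(j) {
    render_curve(temporal_params(
      onset_latency = max(0, peaks[j] - width),
      acceleration = 1.5, peak_amplitude = 1,
      peak_latency = peaks[j], deceleration = 1.5,
      offset_latency = min(duration, peaks[j] + width),
      duration = duration), tg)
  }, numeric(n_time))
  # AU groups: component k owns a contiguous block of AUs
  groups <- split(seq_len(s), sort(rep_len(seq_len(l), s)))
  w_spa <- matrix(cross_loading, l, s)
  for (k in seq_len(l)) {
    w_spa[k, groups[[k]]] <- seq(1, 0.6, length.out = length(groups[[k]]))
  }
  if (is.null(class_coeff_means)) {
    # class "a" pairs low-index AU components with early temporal bursts
    # (and vice versa), class "b" reverses the pairing; the zeros this ramp
    # puts in the coefficients (components fully off on some trials) are
    # what makes the planted factorization identifiable.
    pos_p <- if (p > 1L) (seq_len(p) - 1) / (p - 1) else 0.5
    pos_l <- if (l > 1L) (seq_len(l) - 1) / (l - 1) else 0.5
    m1 <- 2 * outer(pos_p, pos_l, function(a, b) pmax(0, 1 - abs(a - b)))
    class_coeff_means <- list(a = m1, b = m1[rev(seq_len(p)), , drop = FALSE])
  }
  planted_model(w_tem = w_tem, w_spa = w_spa,
                class_coeff_means = class_coeff_means,
                time_grid = tg, ...)
}

#' Rank-1 sequence variants from a two-temporal-component model
#'
#' For each AU component, builds a single-trial activation matrix pairing it
#' with one temporal component only: in `"original"` mode the temporal
#' component with the higher average activation coefficient (the other set
#' to 0), in `"inverted"` mode the lower-average one. Each output is the
#' rank-1 outer product `mean_coefficient * w_tem[, p*] %o% w_spa[l, ]`.
#'
#' @param model A fitted or planted model-like object with `w_tem` (T x 2),
#'   `w_spa` (L x S) and coefficients `h` (N x 2 x L).
#' @param mode `"original"` or `"inverted"`.
#' @return A list of `L` matrices (`T x S`), one per AU component, with the
#'   retained temporal index attached as attribute `"temporal_component"`.
#' @export
sequence_variants <- function(model, mode = c("original", "inverted")) {
  mode <- match.arg(mode)
  if (ncol(model$w_tem) != 2L) {
    abort("Sequence variants are defined for exactly 2 temporal components.",
          class = "spacebytime_order_error")
  }
  h <- model$h
  mean_h <- apply(h, c(2L, 3L), mean)   # P x L average activation coefficients
  L <- nrow(model$w_spa)
  out <- vector("list", L)
  for (l in seq_len(L)) {
    p_star <- if (mode == "original") which.max(mean_h[, l]) else which.min(mean_h[, l])
    m <- mean_h[p_star, l] * (model$w_tem[, p_star] %o% model$w_spa[l, ])
    attr(m, "temporal_component") <- p_star
    out[[l]] <- m
  }
  out
}
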