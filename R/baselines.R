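#' Simulate two-AU trials from a planted two-component basis
#'
#' Each trial is a nonnegative linear combination `c_1 w_1 + c_2 w_2` of two
#' planted AU-activation basis vectors (rows of `basis`), with coefficients
#' i.i.d. uniform(0, 1); on a fraction of trials a Gaussian-copula
#' correlation `rho` is imposed between the two coefficients (emulating AU
#' synergies), and small zero-mean Gaussian noise (clipped at 0) is added.
#'
#' @param n_trials Number of trials (default 600).
#' @param basis 2 x 2 nonnegative matrix, planted components as rows;
#'   default `rbind(c(0.2, 1), c(1, 0.2))` on (AU5, AU26) — one component
#'   with low Upper Lid Raiser and high Jaw Drop, the other vice versa.
#' @param rho,corr_fraction Coefficient correlation and the fraction of
#'   trials it is imposed on.
#' @param noise_sd Observation noise standard deviation.
#' @param seed Optional integer seed.
#' @return List with `x` (n x 2 activation matrix), `coeff` (n x 2 true
#'   coefficients) and `basis`.
#' @export
simulate_two_au_trials <- function(n_trials = 600L,
                                   basis = rbind(c(0.2, 1), c(1, 0.2)),
                                   rho = 0.7, corr_fraction = 0.5,
                                   noise_sd = 0.02, seed = NULL) {
  basis <- as.matrix(basis)
  if (any(basis < 0)) {
    abort("Planted basis must be nonnegative.",
          class = "spacebytime_validation_error")
  }
  if (abs(det(basis)) < 1e-10) {
    abort("Planted basis is collinear.", class = "spacebytime_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n_corr <- round(corr_fraction * n_trials)
  z <- matrix(rnorm(2L * n_corr), ncol = 2L)
  z[, 2L] <- rho * z[, 1L] + sqrt(1 - rho^2) * z[, 2L]
  c_corr <- pnorm(z)                        # Gaussian copula -> uniform margins
  c_ind <- matrix(runif(2L * (n_trials - n_corr)), ncol = 2L)
  coeff <- rbind(c_ind, c_corr)
  x <- coeff %*% basis
  if (noise_sd > 0) {
    x <- x + matrix(rnorm(length(x), sd = noise_sd), nrow = n_trials)
    x[x < 0] <- 0
  }
  list(x = x, coeff = coeff, basis = basis)
}

#' Compare NMF, PCA and ICA recovery of a planted two-AU basis
#'
#' Fits three rank-2 decompositions to planted two-AU data: (i) nonnegative
#' factorization (via [fit_sbt()] with a trivial single time sample), (ii)
#' the two principal axes of the mean-centered data, (iii) two independent
#' axes by whitening plus symmetric fixed-point log-cosh iteration. For the
#' nonnegative factorization the reported loadings are its generative basis
#' (rows of `w_spa`); for PCA and ICA they are the analysis axes the methods
#' actually provide — the projection filters whose scores are the component
#' activations (the principal-axis rotation rows, and the ICA unmixing rows
#' mapped to data space). Each axis is matched to the planted basis by best
#' cosine (with sign alignment for PCA/ICA, which carry a sign
#' indeterminacy), and axes whose entries mix signs are flagged: sign-mixed
#' axes cannot be read as AU activation patterns, which is the
#' methodological point of the comparison — for a non-orthogonal nonnegative
#' basis the variance- and independence-maximizing axes necessarily violate
#' nonnegativity.
#'
#' @param n_trials,basis,rho,corr_fraction,noise_sd,seed Passed to
#'   [simulate_two_au_trials()].
#' @param restarts NMF restarts.
#' @return A tibble with one row per (method, component): columns `method`,
#'   `component`, `cosine`, `negative_loading`; the raw 2 x 2 loading
#'   matrices (components as rows) are attached as attribute `"loadings"`.
#' @export
#' @examples
#' rep <- compare_recovery_methods(n_trials = 200, seed = 1, restarts = 3)
#' dplyr::summarise(dplyr::group_by(rep, method),
#'                  any_negative = any(negative_loading))
compare_recovery_methods <- function(n_trials = 600L,
                                     basis = rbind(c(0.2, 1), c(1, 0.2)),
                                     rho = 0.7, corr_fraction = 0.5,
                                     noise_sd = 0.02, seed = NULL,
                                     restarts = 10L) {
  sim <- simulate_two_au_trials(n_trials, basis, rho, corr_fraction,
                                noise_sd, seed)
  x <- sim$x
  # (i) nonnegative factorization: N x 1 x 2 tensor, P = 1, L = 2
  arr <- array(x, dim = c(nrow(x), 1L, 2L))
  fit <- fit_sbt(arr, p = 1L, l = 2L, restarts = restarts, max_iter = 500L)
  nmf_load <- fit$w_spa                      # 2 x 2, components as rows
  # (ii) principal axes of the centered data
  pca_load <- t(prcomp(x, center = TRUE, scale. = FALSE)$rotation)
  # (iii) independent axes (unmixing filters in data space)
  ica_load <- ica_axes(x)

  loadings <- list(nmf = nmf_load, pca = pca_load, ica = ica_load)
  out <- purrr::imap(loadings, function(W, method) {
    signed <- method != "nmf"
    m <- match_axes(W, sim$basis, signed = signed)
    tibble::tibble(method = method, component = 1:2,
                   cosine = m$cosine,
                   negative_loading = m$negative)
  }) |> dplyr::bind_rows()
  attr(out, "loadings") <- loadings
  attr(out, "basis") <- sim$basis
  out
}

# best-cosine assignment of 2 recovered axes (rows of W) to 2 planted rows;
# for sign-indeterminate methods cosines are compared in absolute value and
# each axis is sign-aligned (largest-|entry| positive) before the
# mixed-sign check.
match_axes <- function(W, basis, signed) {
  cosm <- cosine_matrix(t(W), t(basis))
  score <- if (signed) abs(cosm) else cosm
  ident <- score[1L, 1L] + score[2L, 2L]
  swap <- score[1L, 2L] + score[2L, 1L]
  perm <- if (ident >= swap) c(1L, 2L) else c(2L, 1L)
  cosine <- score[cbind(1:2, perm)]
  aligned <- t(vapply(1:2, function(i) {
    v <- W[i, ]
    if (signed && v[which.max(abs(v))] < 0) v <- -v
    v
  }, numeric(2)))
  negative <- apply(aligned, 1L, function(v) min(v) < -1e-8)
  list(permutation = perm, cosine = cosine, negative = negative,
       aligned = aligned)
}

# symmetric fixed-point ICA with log-cosh contrast; returns the unmixing
# filter rows in the original data space (projecting data onto them yields
# the independent component scores).
ica_axes <- function(x, max_iter = 500L, tol = 1e-8) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  cv <- crossprod(xc) / (nrow(xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) < 1e-12) {
    abort("Data covariance is singular; ICA whitening failed.",
          class = "spacebytime_numerical_error")
  }
  Kw <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)  # whitener
  z <- xc %*% Kw
  d <- ncol(z)
  U <- qr.Q(qr(matrix(rnorm(d * d), d, d)))   # orthonormal init
  sym_decorrelate <- function(U) {
    e <- eigen(U %*% t(U), symmetric = TRUE)
    solve_sqrt <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
    solve_sqrt %*% U
  }
  for (it in seq_len(max_iter)) {
    wz <- z %*% t(U)                 # n x d source estimates
    g <- tanh(wz)
    gp <- 1 - g^2
    U_new <- crossprod(g, z) / nrow(z) - diag(colMeans(gp)) %*% U
    U_new <- sym_decorrelate(U_new)
    delta <- max(abs(abs(rowSums(U_new * U)) - 1))
    U <- U_new
    if (delta < tol) break
  }
  # sources s = z U' = xc (U Kw)': the filter rows live in data space
  W <- U %*% Kw
  W / sqrt(rowSums(W^2))
}

#' Two-class boundary and accuracy in a 2-D coefficient plane
#'
#' Convenience wrapper for the simulated two-component illustration:
#' leave-one-out LDA accuracy plus the linear categorization boundary in a
#' labeled 2-D coefficient space.
#'
#' @param table Tibble with `.label` (two classes) and two feature columns.
#' @param features Optional pair of feature columns.
#' @param shrinkage LDA shrinkage.
#' @return List with `accuracy` (percent), `boundary` (from
#'   [lda_boundary_2d()]) and the full `decoding` result.
#' @export
decode_2d <- function(table, features = NULL, shrinkage = 1e-3) {
  dec <- loo_cv_decode(table, features = features, shrinkage = shrinkage)
  bnd <- lda_boundary_2d(table, features = features, shrinkage = shrinkage)
  list(accuracy = dec$accuracy, boundary = bnd, decoding = dec)
}
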