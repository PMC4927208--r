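#' Fit the space-by-time nonnegative tri-factorization
#'
#' Factorizes every trial's time-by-AU activation matrix `M_n` (T x S) as
#' `M_n ~ W_tem %*% H_n %*% W_spa`, with `W_tem` (T x P, temporal components
#' as columns) and `W_spa` (L x S, AU components as rows) shared across
#' trials and a trial-specific nonnegative coefficient matrix `H_n` (P x L).
#' The summed squared Frobenius error `sum_n ||M_n - W_tem H_n W_spa||^2` is
#' minimized by alternating multiplicative ratio updates (each block update
#' is the standard gradient-derived numerator/denominator form, with
#' `eps_floor` added to denominators), cycling H -> W_tem -> W_spa once per
#' sweep. The best of `restarts` random initializations is kept, and the
#' returned model is normalized (unit-norm components, ordered by
#' coefficient mass; see [normalize_sbt()]).
#'
#' @param data A [trial_tensor()] or a nonnegative `N x T x S` array.
#' @param p,l Numbers of temporal (`p <= T`) and AU (`l <= S`) components.
#' @param max_iter Maximum update sweeps per restart.
#' @param rel_tol Stop when the relative objective decrease over one sweep
#'   falls below this.
#' @param restarts Independent uniform(0, 1] initializations; the lowest
#'   final objective wins.
#' @param eps_floor Denominator floor guarding against division by zero.
#' @param seed Optional integer seed controlling the whole restart cascade.
#' @return An `sbt_model` with fields `w_tem` (T x P), `w_spa` (L x S), `h`
#'   (N x P x L), `objective_trace` (per-sweep summed squared error of the
#'   winning restart), `rel_error`, `converged`, plus carried `time_grid` and
#'   `au_codes`.
#' @seealso [reconstruction_error()], [match_components()], [tidy.sbt_model()]
#' @export
#' @examples
#' pm <- planted_model(w_tem = cbind(c(0, 1, 2, 1)), w_spa = rbind(c(1, 0.3, 0)),
#'                     class_coeff_means = list(a = matrix(1)))
#' tt <- simulate_planted(pm, n_per_class = 10, seed = 1)
#' fit <- fit_sbt(tt, p = 1, l = 1, restarts = 3, seed = 1)
#' glance(fit)
fit_sbt <- function(data, p, l, max_iter = 1000L, rel_tol = 1e-6,
                    restarts = 20L, eps_floor = 1e-12, seed = NULL) {
  tt <- as_trial_tensor(data)
  d <- dim(tt$data)
  N <- d[1L]; Tn <- d[2L]; S <- d[3L]
  p <- as.integer(p); l <- as.integer(l)
  if (p < 1L || l < 1L || p > Tn || l > S) {
    abort("Need 1 <= p <= T and 1 <= l <= S.",
          class = "spacebytime_config_error")
  }
  if (max_iter < 1L || rel_tol <= 0 || restarts < 1L || eps_floor <= 0) {
    abort("Invalid fit configuration.", class = "spacebytime_config_error")
  }
  if (!is.null(seed)) set.seed(seed)

  Marr <- tensor_tsn(tt)                       # T x S x N
  Mmat <- t(matrix(Marr, Tn * S, N))           # N x (T*S), vec(M_n) t-fastest
  m_norm <- sum(Mmat^2)

  best <- NULL
  for (r in seq_len(restarts)) {
    res <- sbt_mu_run(Mmat, Marr, N, Tn, S, p, l, max_iter, rel_tol, eps_floor)
    if (is.null(best) || res$objective < best$objective) best <- res
  }

  h <- aperm(array(t(best$Hmat), c(p, l, N)), c(3L, 1L, 2L))  # N x P x L
  model <- new_sbt_model(
    w_tem = best$Wt, w_spa = best$Ws, h = h,
    objective_trace = best$trace,
    rel_error = if (m_norm > 0) best$objective / m_norm else 0,
    converged = best$converged,
    time_grid = tt$time_grid, au_codes = tt$au_codes,
    config = list(p = p, l = l, max_iter = max_iter, rel_tol = rel_tol,
                  restarts = restarts, eps_floor = eps_floor, seed = seed))
  normalize_sbt(model)
}

# One multiplicative-update run from a fresh random initialization.
# All trial-wise quantities are carried as unfoldings so each sweep is a
# handful of BLAS calls:
#   Hmat  N x (P*L)   rows vec(H_n), p-fastest
#   Mmat  N x (T*S)   rows vec(M_n), t-fastest
sbt_mu_run <- function(Mmat, Marr, N, Tn, S, P, L, max_iter, rel_tol, eps) {
  Wt <- matrix(runif(Tn * P, min = .Machine$double.eps), Tn, P)
  Ws <- matrix(runif(L * S, min = .Machine$double.eps), L, S)
  Hmat <- matrix(runif(N * P * L, min = .Machine$double.eps), N, P * L)
  Mwide <- matrix(Marr, Tn, S * N)                       # t x (s,n)
  Mstk <- matrix(aperm(Marr, c(1L, 3L, 2L)), Tn * N, S)  # (t,n) x s

  trace <- numeric(0)
  obj_prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # -- H update (W fixed): H <- H * (Wt' M_n Ws') / (Wt'Wt H Ws Ws')
    A <- crossprod(Wt)                # P x P
    B <- tcrossprod(Ws)               # L x L
    K <- t(Ws) %x% Wt                 # (T*S) x (P*L), matches vec conventions
    numH <- Mmat %*% K
    denH <- Hmat %*% (B %x% A)
    Hmat <- Hmat * numH / (denH + eps)

    H3 <- array(t(Hmat), c(P, L, N))
    Hpn <- matrix(aperm(H3, c(2L, 1L, 3L)), L, P * N)     # l x (p,n)

    # -- W_tem update: Wt <- Wt * (sum_n M_n Ws' H_n') / (Wt sum_n H_n B H_n')
    Q <- t(Ws) %*% Hpn                                     # s x (p,n)
    Qstk <- matrix(aperm(array(Q, c(S, P, N)), c(1L, 3L, 2L)), S * N, P)
    numWt <- Mwide %*% Qstk
    HB <- B %*% Hpn                                        # l x (p,n): (H_n B)'
    X1 <- matrix(aperm(array(HB, c(L, P, N)), c(1L, 3L, 2L)), L * N, P)
    X2 <- matrix(aperm(array(Hpn, c(L, P, N)), c(1L, 3L, 2L)), L * N, P)
    Cm <- crossprod(X1, X2)                                # sum_n H_n B H_n'
    Wt <- Wt * numWt / (Wt %*% Cm + eps)

    # -- W_spa update: Ws <- Ws * (sum_n H_n' Wt' M_n) / ((sum_n H_n' A H_n) Ws)
    A <- crossprod(Wt)
    Hflat <- matrix(H3, P, L * N)                          # p x (l,n)
    U <- Wt %*% Hflat                                      # t x (l,n)
    Ustk <- matrix(aperm(array(U, c(Tn, L, N)), c(1L, 3L, 2L)), Tn * N, L)
    numWs <- crossprod(Ustk, Mstk)
    AH <- A %*% Hflat
    Y1 <- matrix(aperm(array(Hflat, c(P, L, N)), c(1L, 3L, 2L)), P * N, L)
    Y2 <- matrix(aperm(array(AH, c(P, L, N)), c(1L, 3L, 2L)), P * N, L)
    Dm <- crossprod(Y1, Y2)                                # sum_n H_n' A H_n
    Ws <- Ws * numWs / (Dm %*% Ws + eps)

    # -- objective after the full sweep
    Rhat <- Hmat %*% t(t(Ws) %x% Wt)
    obj <- sum((Mmat - Rhat)^2)
    trace <- c(trace, obj)
    if (is.finite(obj_prev) && obj_prev > 0 &&
        (obj_prev - obj) / obj_prev < rel_tol) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  list(Wt = Wt, Ws = Ws, Hmat = Hmat, objective = trace[length(trace)],
       trace = trace, converged = converged)
}

as_trial_tensor <- function(data) {
  if (inherits(data, "trial_tensor")) return(data)
  if (is.array(data) && length(dim(data)) == 3L) {
    d <- dim(data)
    return(trial_tensor(data, time_grid = seq(0, 1, length.out = d[2L]),
                        au_codes = paste0("AU", seq_len(d[3L]))))
  }
  abort("`data` must be a trial_tensor or an N x T x S array.",
        class = "spacebytime_validation_error")
}

new_sbt_model <- function(w_tem, w_spa, h, objective_trace, rel_error,
                          converged, time_grid, au_codes, config,
                          labels = NULL) {
  structure(
    list(w_tem = w_tem, w_spa = w_spa, h = h,
         objective_trace = objective_trace, rel_error = rel_error,
         converged = converged, time_grid = time_grid, au_codes = au_codes,
         config = config, normalized = FALSE),
    class = "sbt_model")
}

#' @export
print.sbt_model <- function(x, ...) {
  d <- dim(x$h)
  cat(sprintf("<sbt_model> P = %d temporal, L = %d AU components, N = %d trials\n",
              d[2L], d[3L], d[1L]))
  cat(sprintf("  relative reconstruction error: %.3g (%s after %d sweeps)\n",
              x$rel_error, if (isTRUE(x$converged)) "converged" else "iteration cap",
              length(x$objective_trace)))
  invisible(x)
}

#' Relative reconstruction error of a model on data
#'
#' `sum_n ||M_n - W_tem H_n W_spa||^2 / sum_n ||M_n||^2` — 0 iff the
#' reconstruction is perfect, scale-invariant, and 1 for an all-zero model
#' on nonzero data.
#'
#' @param model An `sbt_model`.
#' @param data A [trial_tensor()] or `N x T x S` array with matching shape.
#' @return Nonnegative scalar.
#' @export
reconstruction_error <- function(model, data) {
  tt <- as_trial_tensor(data)
  d <- dim(tt$data)
  dh <- dim(model$h)
  if (d[1L] != dh[1L] || d[2L] != nrow(model$w_tem) ||
      d[3L] != ncol(model$w_spa)) {
    abort("Model and data shapes disagree.",
          class = "spacebytime_validation_error")
  }
  denom <- sum(tt$data^2)
  if (denom == 0) {
    abort("Data are all zero; relative error is undefined.",
          class = "spacebytime_degenerate_error")
  }
  sum((tt$data - reconstruct(model))^2) / denom
}

#' Reconstruct the fitted activation tensor
#' @param model An `sbt_model`.
#' @return An `N x T x S` array `W_tem %*% H_n %*% W_spa` per trial.
#' @export
reconstruct <- function(model) {
  d <- dim(model$h)
  N <- d[1L]; P <- d[2L]; L <- d[3L]
  Tn <- nrow(model$w_tem); S <- ncol(model$w_spa)
  Hmat <- matrix(aperm(model$h, c(2L, 3L, 1L)), P * L, N)  # (p,l) x n
  Rvec <- (t(model$w_spa) %x% model$w_tem) %*% Hmat        # (t,s) x n
  aperm(array(Rvec, c(Tn, S, N)), c(3L, 1L, 2L))
}

#' Normalize and order a fitted model
#'
#' Rescales every temporal column and AU row to unit Euclidean norm,
#' absorbing the inverse scales into the coefficients (reconstruction is
#' unchanged), then orders components of each type by descending total
#' coefficient mass, breaking ties by lower original index.
#'
#' @param model An `sbt_model`.
#' @return The normalized `sbt_model`.
#' @export
normalize_sbt <- function(model) {
  wt <- model$w_tem; ws <- model$w_spa; h <- model$h
  ct <- sqrt(colSums(wt^2))
  cs <- sqrt(rowSums(ws^2))
  if (any(ct == 0) || any(cs == 0)) {
    abort("All-zero component; model is degenerate.",
          class = "spacebytime_degenerate_error")
  }
  wt <- sweep(wt, 2L, ct, "/")
  ws <- sweep(ws, 1L, cs, "/")
  for (p in seq_along(ct)) h[, p, ] <- h[, p, , drop = FALSE] * ct[p]
  for (l in seq_along(cs)) h[, , l] <- h[, , l, drop = FALSE] * cs[l]

  mass_p <- apply(h, 2L, sum)
  mass_l <- apply(h, 3L, sum)
  op <- order(-mass_p, seq_along(mass_p))
  ol <- order(-mass_l, seq_along(mass_l))
  model$w_tem <- wt[, op, drop = FALSE]
  model$w_spa <- ws[ol, , drop = FALSE]
  model$h <- h[, op, ol, drop = FALSE]
  model$normalized <- TRUE
  model
}

#' Match components of two models
#'
#' Finds the one-to-one assignment of estimated to reference components
#' maximizing total cosine similarity — exhaustively over permutations for
#' up to 8 components, greedily otherwise.
#'
#' @param estimated,reference Matrices with components as columns (pass
#'   `w_tem` directly, or `t(w_spa)` for AU components), or two `sbt_model`s
#'   together with `type`.
#' @param type When models are given: `"temporal"` or `"spatial"`.
#' @return A list with `permutation` (index into reference components for
#'   each estimated component) and `cosine` (matched similarity per
#'   estimated component).
#' @export
match_components <- function(estimated, reference, type = c("temporal", "spatial")) {
  if (inherits(estimated, "sbt_model")) {
    type <- match.arg(type)
    if (type == "temporal") {
      estimated <- estimated$w_tem; reference <- reference$w_tem
    } else {
      estimated <- t(estimated$w_spa); reference <- t(reference$w_spa)
    }
  }
  E <- as.matrix(estimated); R <- as.matrix(reference)
  k <- ncol(E)
  if (ncol(R) != k) {
    abort("Component counts differ.", class = "spacebytime_validation_error")
  }
  cosm <- cosine_matrix(E, R)           # k x k, [i, j] = cos(E_i, R_j)
  if (k <= 8L) {
    perms <- permutations(k)
    scores <- vapply(seq_len(nrow(perms)), function(i) {
      sum(cosm[cbind(seq_len(k), perms[i, ])])
    }, numeric(1))
    perm <- perms[which.max(scores), ]
  } else {
    perm <- integer(k)
    avail <- seq_len(k)
    for (i in order(-apply(cosm, 1L, max))) {
      j <- avail[which.max(cosm[i, avail])]
      perm[i] <- j
      avail <- setdiff(avail, j)
    }
  }
  list(permutation = perm, cosine = cosm[cbind(seq_len(k), perm)])
}

cosine_matrix <- function(E, R) {
  ne <- sqrt(colSums(E^2)); nr <- sqrt(colSums(R^2))
  ne[ne == 0] <- 1; nr[nr == 0] <- 1
  crossprod(E, R) / (ne %o% nr)
}

permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(k - 1L)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  row <- 0L
  for (pos in seq_len(k)) {
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      rest <- sub[r, ]
      rest[rest >= pos] <- rest[rest >= pos] + 1L
      out[row, ] <- c(pos, rest)
    }
  }
  # first column cycles the leading element; recursion permutes the rest
  out
}

#' Compare two decompositions by matched component correlations
#'
#' Matches temporal and AU components across two models (by cosine) and
#' summarizes the Pearson correlation of the matched pairs as mean +/- sem
#' per factor type — the summary style used when comparing per-observer
#' decompositions with a pooled decomposition.
#'
#' @param model_a,model_b Two `sbt_model`s of equal orders.
#' @return A tibble with columns `type` (`"temporal"`/`"spatial"`),
#'   `mean_r`, `sem_r`, `n_components`.
#' @export
compare_decompositions <- function(model_a, model_b) {
  one <- function(type) {
    m <- match_components(model_a, model_b, type = type)
    A <- if (type == "temporal") model_a$w_tem else t(model_a$w_spa)
    B <- if (type == "temporal") model_b$w_tem else t(model_b$w_spa)
    rs <- vapply(seq_along(m$permutation), function(i) {
      a <- A[, i]; b <- B[, m$permutation[i]]
      if (sd(a) == 0 || sd(b) == 0) {
        abort("Constant component: correlation undefined.",
              class = "spacebytime_degenerate_error")
      }
      cor(a, b)
    }, numeric(1))
    tibble::tibble(type = type, mean_r = mean(rs),
                   sem_r = if (length(rs) > 1L) sd(rs) / sqrt(length(rs)) else 0,
                   n_components = length(rs))
  }
  dplyr::bind_rows(one("temporal"), one("spatial"))
}
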