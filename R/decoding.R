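#' Vectorize trial coefficients into a decoding table
#'
#' Flattens each trial's `P x L` coefficient matrix into a feature row
#' (column-major: temporal index fastest), yielding the `N x (P*L)` decoding
#' substrate with one column per (temporal, AU) component combination.
#'
#' @param model An `sbt_model` (or any list with an `N x P x L` array `h`).
#' @param labels Length-`N` categorical labels.
#' @return A `coefficient_table`: a tibble with column `.label` and numeric
#'   feature columns `h_p<p>_l<l>`; the (p, l) -> column map is attached as
#'   attribute `"feature_index"` and the orders as `"p"`, `"l"`.
#' @export
#' @examples
#' h <- array(runif(4 * 2 * 3), c(4, 2, 3))
#' tab <- vectorize_coefficients(list(h = h), labels = c("a", "a", "b", "b"))
#' ncol(tab) - 1L  # P * L = 6 features
vectorize_coefficients <- function(model, labels) {
  h <- model$h
  d <- dim(h)
  N <- d[1L]; P <- d[2L]; L <- d[3L]
  if (length(labels) != N) {
    abort("`labels` must have one entry per trial.",
          class = "spacebytime_validation_error")
  }
  idx <- expand.grid(p = seq_len(P), l = seq_len(L))   # p fastest
  x <- matrix(0, N, P * L)
  for (j in seq_len(nrow(idx))) x[, j] <- h[, idx$p[j], idx$l[j]]
  colnames(x) <- paste0("h_p", idx$p, "_l", idx$l)
  out <- tibble::as_tibble(x)
  out <- tibble::add_column(out, .label = as.factor(labels), .before = 1L)
  attr(out, "feature_index") <- tibble::as_tibble(idx) |>
    dplyr::mutate(column = colnames(x))
  attr(out, "p") <- P
  attr(out, "l") <- L
  class(out) <- c("coefficient_table", class(out))
  out
}

#' Rebuild the coefficient array from a coefficient table
#'
#' Inverse of [vectorize_coefficients()] (round-trips exactly).
#'
#' @param table A `coefficient_table`.
#' @return An `N x P x L` array.
#' @export
unvectorize_coefficients <- function(table) {
  fi <- attr(table, "feature_index")
  P <- attr(table, "p"); L <- attr(table, "l")
  h <- array(0, c(nrow(table), P, L))
  for (j in seq_len(nrow(fi))) {
    h[, fi$p[j], fi$l[j]] <- table[[fi$column[j]]]
  }
  h
}

# re-attach the feature-index attributes after dplyr verbs
restore_table_attrs <- function(x, template) {
  attr(x, "feature_index") <- attr(template, "feature_index")
  attr(x, "p") <- attr(template, "p")
  attr(x, "l") <- attr(template, "l")
  if (!inherits(x, "coefficient_table")) {
    class(x) <- c("coefficient_table", class(x))
  }
  x
}

table_xy <- function(table, features = NULL) {
  if (!".label" %in% names(table)) {
    abort("Table must carry a `.label` column.",
          class = "spacebytime_validation_error")
  }
  y <- droplevels(as.factor(table$.label))
  feat_cols <- setdiff(names(table), ".label")
  if (!is.null(features)) {
    if (is.numeric(features)) features <- feat_cols[features]
    miss <- setdiff(features, feat_cols)
    if (length(miss) > 0L) {
      abort(paste0("Unknown feature columns: ", paste(miss, collapse = ", ")),
            class = "spacebytime_validation_error")
    }
    feat_cols <- features
  }
  x <- as.matrix(as.data.frame(table)[feat_cols])
  if (!all(is.finite(x))) {
    abort("Features must be finite.", class = "spacebytime_validation_error")
  }
  list(x = x, y = y)
}

#' Fit a shrinkage linear discriminant model
#'
#' Gaussian classes with one shared (pooled within-class) covariance,
#' regularized as `Sigma + shrinkage * (tr(Sigma)/d) * I`, empirical class
#' priors, and prediction by the linear discriminant
#' `x' Sigma^-1 m_k - m_k' Sigma^-1 m_k / 2 + log pi_k`; argmax ties go to
#' the lowest class index.
#'
#' @param x Numeric feature matrix (N x d) or a `coefficient_table`.
#' @param y Labels (ignored when `x` is a table).
#' @param shrinkage Nonnegative ridge weight `lambda` (default `1e-3`).
#' @return An `lda_model` with `class_means`, `pooled_covariance`, `priors`,
#'   `classes`.
#' @export
fit_lda <- function(x, y = NULL, shrinkage = 1e-3) {
  if (is.data.frame(x)) {
    xy <- table_xy(x); x <- xy$x; y <- xy$y
  }
  y <- droplevels(as.factor(y))
  counts <- table(y)
  if (nlevels(y) < 2L) {
    abort("Need at least two classes.", class = "spacebytime_validation_error")
  }
  if (any(counts < 2L)) {
    abort("Every class needs at least 2 trials.",
          class = "spacebytime_insufficient_data_error")
  }
  d <- ncol(x); K <- nlevels(y); N <- nrow(x)
  means <- matrix(0, K, d, dimnames = list(levels(y), colnames(x)))
  Sw <- matrix(0, d, d)
  for (k in seq_len(K)) {
    xi <- x[y == levels(y)[k], , drop = FALSE]
    means[k, ] <- colMeans(xi)
    Sw <- Sw + crossprod(sweep(xi, 2L, means[k, ], "-"))
  }
  covm <- Sw / (N - K)
  covm <- covm + shrinkage * (sum(diag(covm)) / d) * diag(d)
  inv <- tryCatch(solve(covm), error = function(e) {
    abort("Pooled covariance is singular; increase `shrinkage`.",
          class = "spacebytime_numerical_error")
  })
  structure(
    list(class_means = means, pooled_covariance = covm, cov_inv = inv,
         priors = as.numeric(counts) / N, classes = levels(y),
         shrinkage = shrinkage),
    class = "lda_model")
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  sc <- lda_scores(x, object$class_means, object$cov_inv, object$priors)
  factor(object$classes[max.col(sc, ties.method = "first")],
         levels = object$classes)
}

lda_scores <- function(x, means, inv, priors) {
  W <- inv %*% t(means)                        # d x K
  const <- -0.5 * colSums(t(means) * W) + log(priors)
  sweep(x %*% W, 2L, const, "+")
}

#' Leave-one-out cross-validated LDA decoding
#'
#' For every trial, fits the shrinkage LDA on the other `N - 1` trials and
#' predicts the held-out one; aggregates percent-correct accuracy and the
#' row-stochastic confusion matrix over all folds. Class means and the
#' pooled scatter are downdated per fold, so the loop is O(N d^2 + N d^3)
#' rather than N full refits.
#'
#' @param table A `coefficient_table` (or any tibble with `.label` plus
#'   numeric features).
#' @param features Optional subset of feature columns (names or indices)
#'   restricting the decoder.
#' @param shrinkage Passed to [fit_lda()].
#' @return A `decoding_result`: `accuracy` (percent), `confusion` (K x K
#'   row-stochastic, rows = true class), `per_class_accuracy`, `n_trials`,
#'   plus the per-trial `predicted` and `correct` vectors.
#' @export
#' @examples
#' tab <- tibble::tibble(.label = rep(c("a", "b"), each = 20),
#'                       f = c(rnorm(20, 0), rnorm(20, 3)))
#' loo_cv_decode(tab)$accuracy
loo_cv_decode <- function(table, features = NULL, shrinkage = 1e-3) {
  xy <- table_xy(table, features)
  x <- xy$x; y <- xy$y
  K <- nlevels(y); N <- nrow(x); d <- ncol(x)
  counts <- as.numeric(base::table(y))
  if (any(counts < 2L)) {
    abort("Leave-one-out would empty a class (every class needs >= 2 trials).",
          class = "spacebytime_insufficient_data_error")
  }
  if (N < K + 2L) {
    abort("Too few trials for leave-one-out decoding.",
          class = "spacebytime_insufficient_data_error")
  }
  yi <- as.integer(y)
  XtX <- crossprod(x)
  sums <- rowsum(x, y)                         # K x d class sums
  tr_id <- diag(d)
  pred <- integer(N)
  for (i in seq_len(N)) {
    ci <- yi[i]
    n_k <- counts
    n_k[ci] <- n_k[ci] - 1
    s <- sums
    s[ci, ] <- s[ci, ] - x[i, ]
    means <- s / n_k
    Sw <- XtX - tcrossprod(x[i, ]) - crossprod(means * sqrt(n_k))
    covm <- Sw / (N - 1 - K)
    covm <- covm + shrinkage * (sum(diag(covm)) / d) * tr_id
    inv <- tryCatch(solve(covm), error = function(e) {
      abort("Singular fold covariance; increase `shrinkage`.",
            class = "spacebytime_numerical_error")
    })
    sc <- lda_scores(x[i, , drop = FALSE], means, inv, n_k / (N - 1))
    pred[i] <- max.col(sc, ties.method = "first")
  }
  predicted <- factor(levels(y)[pred], levels = levels(y))
  conf_counts <- base::table(true = y, predicted = predicted)
  confusion <- sweep(unclass(conf_counts), 1L, rowSums(conf_counts), "/")
  correct <- predicted == y
  structure(
    list(accuracy = 100 * mean(correct),
         confusion = confusion,
         per_class_accuracy = 100 * diag(confusion),
         n_trials = N,
         predicted = predicted, truth = y, correct = correct),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %.1f%% correct over %d leave-one-out folds (%d classes)\n",
              x$accuracy, x$n_trials, nrow(x$confusion)))
  invisible(x)
}

#' Discrimination power of component subspaces
#'
#' Leave-one-out decoding accuracy restricted to the coefficient columns of
#' a single unit: one (temporal, AU) combination (`"coefficient"`), all P
#' coefficients of one AU component (`"au_component"`), or all L
#' coefficients of one temporal component (`"temporal_component"`). With no
#' `index`, powers for every unit of the requested kind are returned.
#'
#' @param table A `coefficient_table`.
#' @param unit Subspace kind.
#' @param index Optional unit index: `l` for `au_component`, `p` for
#'   `temporal_component`, or `c(p, l)` for `coefficient`.
#' @param shrinkage Passed to the decoder.
#' @return A tibble with columns `unit`, `p`, `l` (NA where not applicable)
#'   and `accuracy` (percent correct).
#' @export
subspace_power <- function(table,
                           unit = c("coefficient", "au_component",
                                    "temporal_component"),
                           index = NULL, shrinkage = 1e-3) {
  unit <- match.arg(unit)
  fi <- attr(table, "feature_index")
  if (is.null(fi)) {
    abort("`table` lacks a feature index (use vectorize_coefficients()).",
          class = "spacebytime_validation_error")
  }
  P <- attr(table, "p"); L <- attr(table, "l")
  units <- switch(unit,
    coefficient = tibble::tibble(p = fi$p, l = fi$l),
    au_component = tibble::tibble(p = NA_integer_, l = seq_len(L)),
    temporal_component = tibble::tibble(p = seq_len(P), l = NA_integer_))
  if (!is.null(index)) {
    units <- switch(unit,
      coefficient = dplyr::filter(units, .data$p == index[1L], .data$l == index[2L]),
      au_component = dplyr::filter(units, .data$l == index),
      temporal_component = dplyr::filter(units, .data$p == index))
    if (nrow(units) == 0L) {
      abort("Unit index out of range.", class = "spacebytime_validation_error")
    }
  }
  units$accuracy <- vapply(seq_len(nrow(units)), function(i) {
    keep <- switch(unit,
      coefficient = fi$column[fi$p == units$p[i] & fi$l == units$l[i]],
      au_component = fi$column[fi$l == units$l[i]],
      temporal_component = fi$column[fi$p == units$p[i]])
    loo_cv_decode(table, features = keep, shrinkage = shrinkage)$accuracy
  }, numeric(1))
  tibble::add_column(units, unit = unit, .before = 1L)
}

#' Two-class LDA boundary in a 2-D coefficient plane
#'
#' Returns the line `w . x + b = 0` of the fitted two-class shrinkage LDA,
#' with `w` oriented toward the second class's mean.
#'
#' @param table Tibble with `.label` (2 classes) and exactly two feature
#'   columns (or pass `features` to select two).
#' @param features Optional pair of feature columns.
#' @param shrinkage Passed to [fit_lda()].
#' @return List with `w` (length 2), `b`, `classes`, and the fitted
#'   `lda_model`.
#' @export
lda_boundary_2d <- function(table, features = NULL, shrinkage = 1e-3) {
  xy <- table_xy(table, features)
  if (ncol(xy$x) != 2L || nlevels(xy$y) != 2L) {
    abort("Exactly two features and two classes are required.",
          class = "spacebytime_validation_error")
  }
  fit <- fit_lda(xy$x, xy$y, shrinkage = shrinkage)
  m1 <- fit$class_means[1L, ]; m2 <- fit$class_means[2L, ]
  if (sqrt(sum((m2 - m1)^2)) < 1e-12) {
    abort("Coincident class means: boundary is degenerate.",
          class = "spacebytime_degenerate_error")
  }
  w <- drop(fit$cov_inv %*% (m2 - m1))
  b <- -0.5 * sum((m1 + m2) * w) + log(fit$priors[2L] / fit$priors[1L])
  list(w = w, b = b, classes = fit$classes, model = fit)
}
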