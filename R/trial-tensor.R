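#' Trial-structured activation tensor
#'
#' The canonical carrier for trial-structured dynamic Action Unit (AU) data:
#' an `N x T x S` nonnegative array (trials x time samples x AUs) together
#' with the time grid in seconds, the AU catalog, and optional per-trial
#' categorical labels.
#'
#' @param data Numeric array of dimension `c(N, T, S)`, all entries `>= 0`.
#' @param time_grid Strictly increasing numeric vector of length `T`
#'   (seconds), starting at or after 0.
#' @param au_codes Character vector of length `S` with distinct FACS-style AU
#'   codes (e.g. `"AU5"`, `"AU6L"`).
#' @param labels Optional factor/character vector of length `N` with the
#'   trial category (e.g. the emotion a stimulus was categorized as).
#'
#' @return An object of class `trial_tensor`.
#' @seealso [simulate_experiment()], [simulate_planted()], [as_tibble.trial_tensor()]
#' @export
#' @examples
#' tt <- trial_tensor(array(runif(2 * 4 * 3), c(2, 4, 3)),
#'                    time_grid = seq(0, 1.25, length.out = 4),
#'                    au_codes = c("AU1", "AU5", "AU26"))
#' dim(tt)
trial_tensor <- function(data, time_grid, au_codes, labels = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array (trials x time x AUs).",
          class = "spacebytime_validation_error")
  }
  if (anyNA(data) || any(data < 0)) {
    abort("Activation data must be finite and nonnegative.",
          class = "spacebytime_validation_error")
  }
  d <- dim(data)
  if (length(time_grid) != d[2L] || is.unsorted(time_grid, strictly = TRUE) ||
      time_grid[1L] < 0) {
    abort("`time_grid` must be strictly increasing, start at >= 0 and match dim 2 of `data`.",
          class = "spacebytime_validation_error")
  }
  au_codes <- as.character(au_codes)
  if (length(au_codes) != d[3L] || anyDuplicated(au_codes)) {
    abort("`au_codes` must be distinct and match dim 3 of `data`.",
          class = "spacebytime_validation_error")
  }
  if (!is.null(labels)) {
    if (length(labels) != d[1L]) {
      abort("`labels` must have one entry per trial.",
            class = "spacebytime_validation_error")
    }
    labels <- as.factor(labels)
  }
  structure(
    list(data = data, time_grid = as.numeric(time_grid),
         au_codes = au_codes, labels = labels),
    class = "trial_tensor")
}

#' @export
dim.trial_tensor <- function(x) dim(x$data)

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_tensor> %d trials x %d time samples x %d AUs\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  time: [%g, %g] s; AUs: %s%s\n",
              min(x$time_grid), max(x$time_grid),
              paste(head(x$au_codes, 4L), collapse = ", "),
              if (d[3L] > 4L) ", ..." else ""))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(levels(x$labels), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a trial tensor to a long tibble
#'
#' One row per (trial, time, AU) cell, the tabular interchange format used
#' by [write_trials()].
#'
#' @param x A [trial_tensor()].
#' @param ... Unused.
#' @return A tibble with columns `trial`, `time_s`, `au_code`, `activation`
#'   and, when labels are present, `label`.
#' @method as_tibble trial_tensor
#' @export
as_tibble.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  out <- tibble::tibble(
    trial = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    time_s = rep(rep(x$time_grid, each = d[1L]), times = d[3L]),
    au_code = rep(x$au_codes, each = d[1L] * d[2L]),
    activation = as.numeric(x$data))
  if (!is.null(x$labels)) {
    out$label <- as.character(x$labels)[out$trial]
  }
  dplyr::arrange(out, .data$trial, .data$time_s, .data$au_code)
}

# internal: (T, S, N) unfolding used by the fitter
tensor_tsn <- function(x) aperm(x$data, c(2L, 3L, 1L))

#' Default synthetic Action Unit catalog
#'
#' A 42-entry FACS-style catalog of AU code strings, including lateralized
#' variants (suffix `"L"`/`"R"`). This is a synthetic stand-in naming
#' plausible core AUs; any character vector of distinct codes can be used in
#' its place throughout the package.
#'
#' @return Character vector of 42 AU codes.
#' @export
#' @examples
#' length(au_catalog())
au_catalog <- function() {
  bilateral <- c(1, 2, 4, 5, 7, 9, 10, 11, 15, 16, 17, 18, 20, 22, 23, 24,
                 25, 26, 27, 28, 38, 39, 43, 45)
  lateral <- c(2, 6, 10, 12, 13, 14, 20, 28, 46)
  c(paste0("AU", bilateral),
    paste0("AU", rep(lateral, each = 2L), c("L", "R")))
}
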