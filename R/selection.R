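#' Select the numbers of temporal and AU components by decoding gain
#'
#' Greedy forward search on the (P, L) lattice starting from one temporal
#' and one AU component: at each step the two neighbors (P+1, L) and
#' (P, L+1) are fitted and decoded (leave-one-out LDA on the vectorized
#' coefficients), and the better candidate's per-trial correctness is
#' compared with the incumbent's by a one-sided exact McNemar test on the
#' discordant trials. A candidate is accepted when `p < alpha`
#' (default 0.001); when neither candidate is significant, or the maxima are
#' reached, the search stops — the chosen order is the smallest decomposition
#' whose categorization power could not be significantly improved.
#'
#' @param data A labeled [trial_tensor()].
#' @param max_p,max_l Search maxima (`>= 1`).
#' @param alpha Significance level of the stopping test.
#' @param restarts Restarts per candidate fit during the search (kept small
#'   for speed; the chosen order is refit at `final_restarts`).
#' @param final_restarts Restarts for the returned model at the chosen order.
#' @param shrinkage LDA shrinkage passed to the decoder.
#' @param seed Optional integer seed (controls all candidate fits).
#' @param ... Further arguments to [fit_sbt()] (e.g. `max_iter`).
#' @return A `selection_trace`: tibble `visited` with one row per evaluated
#'   order (`p`, `l`, `accuracy`, `p_value` vs the incumbent at evaluation
#'   time, `accepted`), the `chosen` order, and `model`, the final refit at
#'   the chosen order.
#' @export
select_order <- function(data, max_p, max_l, alpha = 0.001,
                         restarts = 5L, final_restarts = 20L,
                         shrinkage = 1e-3, seed = NULL, ...) {
  stopifnot(inherits(data, "trial_tensor"))
  if (is.null(data$labels)) {
    abort("Order selection needs labeled data.",
          class = "spacebytime_validation_error")
  }
  if (max_p < 1L || max_l < 1L) {
    abort("Search maxima must be >= 1.", class = "spacebytime_config_error")
  }
  if (!is.null(seed)) set.seed(seed)

  evaluate <- function(p, l) {
    fit <- fit_sbt(data, p = p, l = l, restarts = restarts, ...)
    dec <- loo_cv_decode(vectorize_coefficients(fit, data$labels),
                         shrinkage = shrinkage)
    list(p = p, l = l, fit = fit, dec = dec)
  }

  inc <- evaluate(1L, 1L)
  visited <- tibble::tibble(p = 1L, l = 1L, accuracy = inc$dec$accuracy,
                            p_value = NA_real_, accepted = TRUE)
  repeat {
    cand_orders <- list()
    if (inc$p < max_p) cand_orders <- c(cand_orders, list(c(inc$p + 1L, inc$l)))
    if (inc$l < max_l) cand_orders <- c(cand_orders, list(c(inc$p, inc$l + 1L)))
    if (length(cand_orders) == 0L) break
    cands <- lapply(cand_orders, function(o) evaluate(o[1L], o[2L]))
    cands <- cands[order(-vapply(cands, function(cd) cd$dec$accuracy, numeric(1)))]
    accepted <- NULL
    for (cd in cands) {
      pv <- mcnemar_exact_p(inc$dec$correct, cd$dec$correct)
      visited <- dplyr::bind_rows(visited, tibble::tibble(
        p = cd$p, l = cd$l, accuracy = cd$dec$accuracy,
        p_value = pv, accepted = pv < alpha))
      if (pv < alpha) { accepted <- cd; break }
    }
    if (is.null(accepted)) break
    inc <- accepted
  }
  final <- fit_sbt(data, p = inc$p, l = inc$l, restarts = final_restarts, ...)
  structure(
    list(visited = visited, chosen = c(p = inc$p, l = inc$l),
         accuracy = inc$dec$accuracy, model = final, alpha = alpha),
    class = "selection_trace")
}

# One-sided exact McNemar: does the candidate classify significantly more
# held-out trials correctly than the incumbent? b = incumbent-only correct,
# c = candidate-only correct; p = P(X >= c), X ~ Binomial(b + c, 1/2).
mcnemar_exact_p <- function(correct_incumbent, correct_candidate) {
  b <- sum(correct_incumbent & !correct_candidate)
  cc <- sum(!correct_incumbent & correct_candidate)
  if (b + cc == 0L) return(1)
  binom.test(cc, b + cc, p = 0.5, alternative = "greater")$p.value
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> chosen order: P = %d temporal, L = %d AU components (%.1f%% correct)\n",
              x$chosen["p"], x$chosen["l"], x$accuracy))
  print(x$visited)
  invisible(x)
}

#' @method tidy selection_trace
#' @export
tidy.selection_trace <- function(x, ...) x$visited

#' @method glance selection_trace
#' @export
glance.selection_trace <- function(x, ...) {
  tibble::tibble(p = unname(x$chosen["p"]), l = unname(x$chosen["l"]),
                 accuracy = x$accuracy, alpha = x$alpha,
                 n_evaluated = nrow(x$visited))
}
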