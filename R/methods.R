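#' Tidy a fitted space-by-time model
#'
#' @param x An `sbt_model`.
#' @param ... Unused.
#' @return Long tibble with columns `type` (`"temporal"`/`"spatial"`),
#'   `component`, `axis` (`time_s` for temporal, `au_code` for spatial) and
#'   `value`.
#' @method tidy sbt_model
#' @export
tidy.sbt_model <- function(x, ...) {
  tem <- tidyr::expand_grid(component = seq_len(ncol(x$w_tem)),
                            i = seq_len(nrow(x$w_tem))) |>
    dplyr::mutate(type = "temporal",
                  axis = as.character(x$time_grid[.data$i]),
                  value = x$w_tem[cbind(.data$i, .data$component)]) |>
    dplyr::select("type", "component", "axis", "value")
  spa <- tidyr::expand_grid(component = seq_len(nrow(x$w_spa)),
                            i = seq_len(ncol(x$w_spa))) |>
    dplyr::mutate(type = "spatial",
                  axis = x$au_codes[.data$i],
                  value = x$w_spa[cbind(.data$component, .data$i)]) |>
    dplyr::select("type", "component", "axis", "value")
  dplyr::bind_rows(tem, spa)
}

#' One-row model summary
#' @param x An `sbt_model`.
#' @param ... Unused.
#' @return Tibble with `p`, `l`, `n_trials`, `rel_error`, `iterations`,
#'   `converged`.
#' @method glance sbt_model
#' @export
glance.sbt_model <- function(x, ...) {
  tibble::tibble(p = ncol(x$w_tem), l = nrow(x$w_spa),
                 n_trials = dim(x$h)[1L], rel_error = x$rel_error,
                 iterations = length(x$objective_trace),
                 converged = isTRUE(x$converged))
}

#' Plot the components of a fitted model
#'
#' Temporal components as activation waveforms over the trial, AU components
#' as a component-by-AU loading heat map.
#'
#' @param object An `sbt_model`.
#' @param ... Unused.
#' @return A ggplot object (faceted by factor type).
#' @method autoplot sbt_model
#' @export
autoplot.sbt_model <- function(object, ...) {
  td <- tidy(object)
  tem <- dplyr::filter(td, .data$type == "temporal") |>
    dplyr::mutate(time_s = as.numeric(.data$axis),
                  component = factor(.data$component))
  ggplot2::ggplot(tem, ggplot2::aes(x = .data$time_s, y = .data$value,
                                    color = .data$component)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (s)", y = "activation (unit-norm component)",
                  color = "temporal\ncomponent",
                  title = "Temporal components") +
    ggplot2::theme_minimal()
}

#' Heat map of AU component loadings
#' @param model An `sbt_model`.
#' @return A ggplot object.
#' @export
plot_au_components <- function(model) {
  spa <- dplyr::filter(tidy(model), .data$type == "spatial") |>
    dplyr::mutate(axis = factor(.data$axis, levels = model$au_codes),
                  component = factor(.data$component))
  ggplot2::ggplot(spa, ggplot2::aes(x = .data$axis, y = .data$component,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Action Unit", y = "AU component", fill = "loading",
                  title = "AU components") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Tidy a decoding result
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return Long tibble of the confusion matrix: `truth`, `predicted`,
#'   `proportion`.
#' @method tidy decoding_result
#' @export
tidy.decoding_result <- function(x, ...) {
  as.data.frame(as.table(x$confusion)) |>
    tibble::as_tibble() |>
    stats::setNames(c("truth", "predicted", "proportion"))
}

#' One-row decoding summary
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return Tibble with `accuracy`, `n_trials`, `n_classes`, `chance`.
#' @method glance decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  k <- nrow(x$confusion)
  tibble::tibble(accuracy = x$accuracy, n_trials = x$n_trials,
                 n_classes = k, chance = 100 / k)
}

#' Confusion-matrix heat map
#'
#' Accuracies on the diagonal, confusions off it; rows are the true class.
#'
#' @param object A `decoding_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decoding_result
#' @export
autoplot.decoding_result <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f%%", 100 * .data$proportion)), size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "decoded", y = "true", fill = "proportion",
                  title = sprintf("%.1f%% correct (leave-one-out)",
                                  object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot an order-selection trace
#' @param object A `selection_trace`.
#' @param ... Unused.
#' @return A ggplot object: decoding accuracy per visited (P, L) order.
#' @method autoplot selection_trace
#' @export
autoplot.selection_trace <- function(object, ...) {
  v <- object$visited |>
    dplyr::mutate(order = paste0("(", .data$p, ",", .data$l, ")"),
                  step = dplyr::row_number())
  ggplot2::ggplot(v, ggplot2::aes(x = .data$step, y = .data$accuracy)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$accepted), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$order), vjust = -1,
                       size = 3) +
    ggplot2::labs(x = "evaluation step", y = "LOO accuracy (%)",
                  shape = "accepted",
                  title = sprintf("Chosen order: P = %d, L = %d",
                                  object$chosen["p"], object$chosen["l"])) +
    ggplot2::theme_minimal()
}

#' Activation-coefficient bars for an emotion pair
#'
#' Per-class trial-averaged coefficients (+/- sem) for every
#' (temporal, AU-component) combination, the bar layout used in pairwise
#' discriminant summaries.
#'
#' @param object A `pair_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pair_report
#' @export
autoplot.pair_report <- function(object, ...) {
  mc <- object$mean_coefficients |>
    dplyr::filter(.data$l %in% object$active_components) |>
    dplyr::mutate(temporal = factor(.data$p), component = factor(.data$l))
  ggplot2::ggplot(mc, ggplot2::aes(x = .data$temporal, y = .data$mean,
                                   fill = .data$label)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::facet_wrap(~ component, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "temporal component", y = "activation coefficient",
                  fill = "class",
                  title = sprintf("%s vs %s (%.1f%% pairwise decoding)",
                                  object$pair[1L], object$pair[2L],
                                  object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Export pair-report bar data as CSV
#'
#' @param report A `pair_report`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_pair_report_bars <- function(report, path) {
  readr::write_csv(report$mean_coefficients, path)
  invisible(path)
}
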