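#' Active AU components for an emotion pair
#'
#' Restricted to the pair's trials, each AU component's activation is
#' summarized as the maximum over its temporal coefficients of the
#' trial-averaged coefficient; components below `threshold` times the
#' maximal activation (default 10%) are excluded from the pair analyses.
#'
#' @param table A `coefficient_table`.
#' @param pair Character vector of two class labels.
#' @param threshold Exclusion fraction of the maximal activation.
#' @return Integer vector of retained AU-component indices.
#' @export
active_components <- function(table, pair, threshold = 0.10) {
  check_pair(table, pair)
  sub <- restore_table_attrs(dplyr::filter(table, .data$.label %in% pair), table)
  act <- component_activation(sub)
  keep <- which(act >= threshold * max(act))
  as.integer(keep)
}

# max over temporal coefficients of the trial-mean coefficient, per AU comp.
component_activation <- function(table) {
  fi <- attr(table, "feature_index")
  L <- attr(table, "l")
  vapply(seq_len(L), function(l) {
    cols <- fi$column[fi$l == l]
    max(vapply(cols, function(cn) mean(table[[cn]]), numeric(1)))
  }, numeric(1))
}

check_pair <- function(table, pair) {
  if (length(pair) != 2L || anyDuplicated(pair)) {
    abort("`pair` must name two distinct classes.",
          class = "spacebytime_validation_error")
  }
  present <- pair %in% as.character(unique(table$.label))
  if (!all(present)) {
    abort(paste0("Classes absent from labels: ",
                 paste(pair[!present], collapse = ", ")),
          class = "spacebytime_validation_error")
  }
  invisible(TRUE)
}

#' Classify active components as shared or diagnostic
#'
#' For each retained AU component of a pair analysis: components active for
#' both classes whose single-component decoding power lies within the chance
#' band (default 50 +/- 5 points for a pair) are `shared` — they drive
#' confusions rather than discrimination; all others are diagnostic for the
#' class with the higher mean coefficient.
#'
#' @param table A `coefficient_table`.
#' @param pair Two class labels.
#' @param chance_band Half-width (percent points) of the band around chance.
#' @param threshold Activation-exclusion fraction (see
#'   [active_components()]).
#' @param shrinkage LDA shrinkage.
#' @return Tibble with columns `component`, `role` (`"shared"` or
#'   `"diagnostic_for_<class>"`), `power`, `mean_<class_a>`,
#'   `mean_<class_b>`.
#' @export
classify_roles <- function(table, pair, chance_band = 5, threshold = 0.10,
                           shrinkage = 1e-3) {
  check_pair(table, pair)
  active <- active_components(table, pair, threshold = threshold)
  sub <- restore_table_attrs(dplyr::filter(table, .data$.label %in% pair), table)
  sub$.label <- droplevels(factor(sub$.label, levels = levels(as.factor(table$.label))))
  sub_a <- restore_table_attrs(dplyr::filter(sub, .data$.label == pair[1L]), table)
  sub_b <- restore_table_attrs(dplyr::filter(sub, .data$.label == pair[2L]), table)
  act_a <- component_activation(sub_a)
  act_b <- component_activation(sub_b)
  overall_max <- max(component_activation(sub))

  rows <- purrr::map(active, function(l) {
    power <- subspace_power(sub, unit = "au_component", index = l,
                            shrinkage = shrinkage)$accuracy
    both_active <- act_a[l] >= threshold * overall_max &&
      act_b[l] >= threshold * overall_max
    role <- if (both_active && abs(power - 50) <= chance_band) {
      "shared"
    } else if (act_a[l] >= act_b[l]) {
      paste0("diagnostic_for_", pair[1L])
    } else {
      paste0("diagnostic_for_", pair[2L])
    }
    tibble::tibble(component = l, role = role, power = power,
                   mean_a = act_a[l], mean_b = act_b[l])
  })
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", pair[1L])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", pair[2L])
  out
}

#' Full discriminant report for an emotion pair
#'
#' Assembles, for two classes: the active AU components (10% exclusion
#' rule), per-class trial-averaged coefficients (mean +/- sem) for every
#' (temporal, AU) combination, leave-one-out decoding powers per AU
#' component, per temporal component and per combination, and shared /
#' diagnostic roles.
#'
#' @param model An `sbt_model`.
#' @param labels Length-`N` labels matching the model's trials.
#' @param pair Two class labels.
#' @param threshold,chance_band,shrinkage See [active_components()] and
#'   [classify_roles()].
#' @return A `pair_report` list with elements `pair`, `active_components`,
#'   `mean_coefficients` (tibble: label, p, l, mean, sem), `component_power`,
#'   `temporal_power`, `combination_power` (tibbles from [subspace_power()]
#'   on the pair's trials), `roles`, and `accuracy` (pairwise LOO accuracy on
#'   all active-component coefficients).
#' @export
pair_report <- function(model, labels, pair, threshold = 0.10,
                        chance_band = 5, shrinkage = 1e-3) {
  table <- vectorize_coefficients(model, labels)
  check_pair(table, pair)
  sub <- restore_table_attrs(dplyr::filter(table, .data$.label %in% pair), table)
  sub$.label <- droplevels(sub$.label)
  fi <- attr(table, "feature_index")

  mean_coefficients <- sub |>
    tidyr::pivot_longer(-".label", names_to = "column", values_to = "value") |>
    dplyr::inner_join(fi, by = "column") |>
    dplyr::group_by(.data$.label, .data$p, .data$l) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::rename(label = ".label")

  active <- active_components(table, pair, threshold = threshold)
  roles <- classify_roles(table, pair, chance_band = chance_band,
                          threshold = threshold, shrinkage = shrinkage)
  active_cols <- fi$column[fi$l %in% active]
  structure(
    list(pair = pair,
         active_components = active,
         mean_coefficients = mean_coefficients,
         component_power = subspace_power(sub, "au_component",
                                          shrinkage = shrinkage),
         temporal_power = subspace_power(sub, "temporal_component",
                                         shrinkage = shrinkage),
         combination_power = subspace_power(sub, "coefficient",
                                            shrinkage = shrinkage),
         roles = roles,
         accuracy = loo_cv_decode(sub, features = active_cols,
                                  shrinkage = shrinkage)$accuracy),
    class = "pair_report")
}

#' @export
print.pair_report <- function(x, ...) {
  cat(sprintf("<pair_report> %s vs %s — %.1f%% pairwise decoding on %d active AU components\n",
              x$pair[1L], x$pair[2L], x$accuracy, length(x$active_components)))
  print(x$roles)
  invisible(x)
}
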