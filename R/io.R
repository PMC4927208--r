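#' Write trials to disk
#'
#' `"csv"` writes the long tabular format (columns `trial`, `time_s`,
#' `au_code`, `activation`, optional `label`); `"rds"` writes the native
#' container, which round-trips bit-exactly including attributes.
#'
#' @param tensor A [trial_tensor()].
#' @param path Output file.
#' @param format `"csv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(tensor, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(tensor, "trial_tensor"))
  if (format == "rds") {
    saveRDS(tensor, path)
  } else {
    readr::write_csv(as_tibble(tensor), path)
  }
  invisible(path)
}

#' Read trials from disk
#'
#' The long-CSV reader validates nonnegativity (reporting offending rows),
#' rejects duplicate (trial, time, AU) keys, and fills cells absent from the
#' file with 0, reporting how many were filled.
#'
#' @param path File written by [write_trials()] (or any long CSV with the
#'   same schema).
#' @param format `"csv"` or `"rds"`.
#' @return A [trial_tensor()].
#' @export
read_trials <- function(path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    out <- readRDS(path)
    if (!inherits(out, "trial_tensor")) {
      abort("File does not contain a trial_tensor.",
            class = "spacebytime_validation_error")
    }
    return(out)
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("trial", "time_s", "au_code", "activation")
  if (!all(need %in% names(df))) {
    abort(paste0("Long CSV must have columns: ", paste(need, collapse = ", ")),
          class = "spacebytime_validation_error")
  }
  bad <- which(df$activation < 0)
  if (length(bad) > 0L) {
    abort(paste0("Negative activation at rows: ",
                 paste(head(bad, 10L), collapse = ", ")),
          class = "spacebytime_validation_error")
  }
  key <- paste(df$trial, df$time_s, df$au_code, sep = "\r")
  if (anyDuplicated(key)) {
    abort("Duplicate (trial, time_s, au_code) keys.",
          class = "spacebytime_validation_error")
  }
  trials <- sort(unique(df$trial))
  tg <- sort(unique(df$time_s))
  aus <- sort(unique(df$au_code))
  dat <- array(0, dim = c(length(trials), length(tg), length(aus)))
  i <- match(df$trial, trials)
  j <- match(df$time_s, tg)
  k <- match(df$au_code, aus)
  dat[cbind(i, j, k)] <- df$activation
  n_missing <- length(dat) - nrow(df)
  if (n_missing > 0L) {
    message(sprintf("Filled %d absent (trial, time, AU) cells with 0.", n_missing))
  }
  labels <- NULL
  if ("label" %in% names(df)) {
    lab_map <- dplyr::distinct(df, .data$trial, .data$label)
    if (nrow(lab_map) != length(trials)) {
      abort("Inconsistent labels within a trial.",
            class = "spacebytime_validation_error")
    }
    labels <- lab_map$label[match(trials, lab_map$trial)]
  }
  trial_tensor(dat, tg, aus, labels = labels)
}

MODEL_FORMAT_VERSION <- "1.0"

#' Serialize a fitted model to JSON
#'
#' Full-precision doubles, so numeric round trips are exact; metadata
#' (orders, objective trace, fit configuration, normalization flag) is
#' carried along and checked on read.
#'
#' @param model An `sbt_model`.
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "sbt_model"))
  payload <- list(
    format = "spacebytime_model", version = MODEL_FORMAT_VERSION,
    p = ncol(model$w_tem), l = nrow(model$w_spa), n = dim(model$h)[1L],
    w_tem = model$w_tem, w_spa = model$w_spa,
    h = model$h,          # serialized with dims via the list below
    h_dim = dim(model$h),
    objective_trace = model$objective_trace,
    rel_error = model$rel_error, converged = model$converged,
    normalized = model$normalized,
    time_grid = model$time_grid, au_codes = model$au_codes,
    config = model$config)
  payload$h <- as.numeric(model$h)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path File written by [write_model()].
#' @return An `sbt_model`.
#' @export
read_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
    abort("Model file is not valid JSON.", class = "spacebytime_format_error")
  })
  if (!identical(payload$format, "spacebytime_model")) {
    abort("Not a spacebytime model file.", class = "spacebytime_format_error")
  }
  if (!identical(payload$version, MODEL_FORMAT_VERSION)) {
    abort(sprintf("Model format version %s not supported (expected %s).",
                  payload$version, MODEL_FORMAT_VERSION),
          class = "spacebytime_version_error")
  }
  need <- c("w_tem", "w_spa", "h", "h_dim", "time_grid", "au_codes")
  if (!all(need %in% names(payload))) {
    abort("Model file metadata is corrupted (missing fields).",
          class = "spacebytime_format_error")
  }
  model <- new_sbt_model(
    w_tem = as.matrix(payload$w_tem), w_spa = as.matrix(payload$w_spa),
    h = array(payload$h, dim = payload$h_dim),
    objective_trace = payload$objective_trace,
    rel_error = payload$rel_error, converged = payload$converged,
    time_grid = payload$time_grid, au_codes = payload$au_codes,
    config = payload$config)
  model$normalized <- isTRUE(payload$normalized)
  model
}

#' Write a reproducibility manifest
#'
#' Records the command, configuration, seed and package version of a run —
#' enough to regenerate deterministic outputs bit-exactly.
#'
#' @param path Output `.json` file.
#' @param command Character tag of the pipeline stage.
#' @param config List of parameters (must be JSON-serializable).
#' @param seed Integer seed used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, seed = NULL) {
  jsonlite::write_json(
    list(command = command, config = config, seed = seed,
         package = "spacebytime",
         version = as.character(utils::packageVersion("spacebytime")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), tz = "UTC")),
    path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
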