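#' Read a dot-coordinate table
#'
#' Reads and validates the tidy coordinate CSV (`cell_id`, `t_min`,
#' `channel`, `dot_index`, and either `x_um`/`y_um`/`z_um` or
#' `x_um`/`y_um`/`z_index`). When `z_index` is supplied, the corrected
#' axial coordinate is computed via [correct_z()]. At most two dots per
#' channel per cell and time point are allowed; violations are reported
#' with the offending rows.
#'
#' @param path CSV file path
#' @param config a [classifier_config()] (for the z correction)
#' @return validated data.frame with `z_um` populated
#' @export
read_coordinates <- function(path, config = classifier_config()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty coordinate file: ", path)
    return(data.frame(cell_id = character(), t_min = numeric(),
                      channel = character(), dot_index = integer(),
                      x_um = numeric(), y_um = numeric(),
                      z_um = numeric()))
  }
  need <- c("cell_id", "t_min", "channel", "dot_index", "x_um", "y_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!("z_um" %in% names(df))) {
    if (!("z_index" %in% names(df))) stop("need a z_um or z_index column")
    df$z_um <- correct_z(df$z_index, config, units = "steps")
  }
  num <- c("t_min", "x_um", "y_um", "z_um")
  for (cl in num) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v)) {
      stop("non-numeric values in column ", cl, " at row(s) ",
           paste(head(which(is.na(v)), 5), collapse = ", "))
    }
    df[[cl]] <- v
  }
  if (!all(df$channel %in% c("tetO", "lacO"))) {
    bad <- which(!(df$channel %in% c("tetO", "lacO")))
    stop("unknown channel at row(s) ", paste(head(bad, 5), collapse = ", "))
  }
  key <- paste(df$cell_id, df$t_min, df$channel)
  n_per <- table(key)
  if (any(n_per > 2)) {
    bad_key <- names(n_per)[n_per > 2][1]
    stop("more than two dots per channel at row(s) ",
         paste(which(key == bad_key), collapse = ", "))
  }
  df
}

#' Write/read classified state tables
#'
#' State tables hold one row per cell and time point relative to NEBD with
#' the configuration state and, for brown calls, the separated channel.
#' Reading validates the state vocabulary.
#'
#' @param states data.frame: `cell_id`, `t_rel_nebd_min`, `state`,
#'   `separated_channel`
#' @param path CSV file path
#' @return `read_states` returns the validated data.frame;
#'   `write_states` returns `path` invisibly.
#' @export
write_states <- function(states, path) {
  stopifnot(all(c("cell_id", "t_rel_nebd_min", "state",
                  "separated_channel") %in% names(states)))
  write.csv(states, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_states
#' @export
read_states <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "t_rel_nebd_min", "state", "separated_channel")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!(df$state %in% state_levels()))
  if (length(bad) > 0) {
    stop("state label outside the vocabulary at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  df$separated_channel <- as.character(df$separated_channel)
  df$separated_channel[df$separated_channel == ""] <- NA_character_
  df
}

#' Write/read model-state proportion tables
#'
#' Proportion tables carry `time_min`, `p_nonresolved`, `p_resolved`,
#' `p_compacted` and optional provenance columns (`m`, `seed`,
#' `n_cells`). Reading validates that the three proportions sum to 1
#' within 1e-9 on every row.
#'
#' @param props proportion data.frame (e.g. from [simulate_population()] or
#'   [to_model_proportions()])
#' @param path CSV file path
#' @return `read_proportions` returns the validated data.frame;
#'   `write_proportions` returns `path` invisibly.
#' @export
write_proportions <- function(props, path) {
  df <- as.data.frame(props)
  if (!is.null(attr(props, "m"))) df$m <- attr(props, "m")
  if (!is.null(attr(props, "seed"))) df$seed <- attr(props, "seed")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "p_nonresolved", "p_resolved", "p_compacted")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  tot <- df$p_nonresolved + df$p_resolved + df$p_compacted
  bad <- which(abs(tot - 1) > 1e-9)
  if (length(bad) > 0) {
    stop("proportions do not sum to 1 at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  df
}

#' Read/write model parameters
#'
#' Model parameters are stored as a flat `{tau1, tau2, r1, r2}` mapping in
#' JSON or YAML, chosen by file extension.
#'
#' @param params a [model_params()] object
#' @param path file path ending in `.json`, `.yml` or `.yaml`
#' @return `read_params` returns a [model_params()]; `write_params`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  x <- unclass(params)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    stop("unsupported parameter-file extension: ", path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported parameter-file extension: ", path)
  }
  need <- c("tau1", "tau2", "r1", "r2")
  if (!all(need %in% names(x))) {
    stop("parameter file must define tau1, tau2, r1, r2")
  }
  model_params(x$tau1, x$tau2, x$r1, x$r2)
}

#' Write a fit result as JSON
#'
#' @param fit a [fit_model()] result
#' @param path output JSON path
#' @param config optional [fit_config()] whose seeds are recorded
#' @return `path`, invisibly
#' @export
write_fit_result <- function(fit, path, config = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  out <- list(params = unclass(fit$params),
              objective = fit$objective,
              convergence = fit$convergence,
              evaluations = fit$evaluations,
              derived = fit$derived)
  if (!is.null(config)) {
    out$sim_seed <- config$sim_seed
    out$m_sim <- config$m_sim
    out$window <- config$window
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write bootstrap parameter samples as CSV
#'
#' @param boot a [bootstrap_fit()] result
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_bootstrap_samples <- function(boot, path) {
  stopifnot(inherits(boot, "bootstrap_result"))
  df <- boot$samples
  df$repetition <- seq_len(nrow(df))
  df$seed <- boot$seed
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
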