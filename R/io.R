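# Delimited-text matrix I/O, config files, report serialization and
# provenance records.

#' Read / write a weight matrix as delimited text
#'
#' Matrices are stored as comma-separated values, one row per line, no
#' header.  Reading validates squareness and numeric content and reports the
#' offending line on parse failure.
#'
#' @param path File path.
#' @return `read_weight_matrix` returns a square numeric matrix.
#' @export
read_weight_matrix <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read matrix: no such file '%s'", path),
         call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(lines[i], ",")[[1]]))
    if (anyNA(vals)) {
      stop(sprintf("malformed matrix in '%s': non-numeric entry on line %d",
                   path, i), call. = FALSE)
    }
    vals
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) {
    stop(sprintf("malformed matrix in '%s': ragged rows (line %d)",
                 path, which(lens != lens[1])[1]), call. = FALSE)
  }
  m <- do.call(rbind, rows)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix in '%s' is not square (%d x %d)",
                 path, nrow(m), ncol(m)), call. = FALSE)
  }
  m
}

#' @rdname read_weight_matrix
#' @param w Square numeric matrix.
#' @export
write_weight_matrix <- function(w, path) {
  .check_square(w, "w")
  utils::write.table(w, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`), returned as a named list.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read config: no such file '%s'", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop(sprintf("unsupported config extension '.%s' (use yaml or json)",
                 ext), call. = FALSE)
  }
}

#' @rdname read_run_config
#' @param config Named list.
#' @export
write_run_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Serialize a certificate report to JSON
#'
#' Keys are emitted in a stable order (`certificate`, `passed`, `margins`,
#' `details`, `assumptions_checked`) so reports diff cleanly.
#'
#' @param report A [certificate_report()].
#' @param path Output path.
#' @export
write_certificate_report <- function(report, path) {
  stopifnot(inherits(report, "certificate_report"))
  payload <- list(
    certificate = report$certificate,
    passed = report$passed,
    margins = as.list(report$margins),
    details = report$details,
    assumptions_checked = as.list(report$assumptions_checked)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a time series as delimited text
#'
#' Tab-separated with a header row; first column is time.
#'
#' @param x A `distance_series`, `spectral_trace`, or data frame.
#' @param path Output path.
#' @export
write_series <- function(x, path) {
  df <- if (inherits(x, "distance_series")) {
    data.frame(time = x$times, distance = x$distances)
  } else if (inherits(x, "spectral_trace")) {
    data.frame(time = x$times, spec_norm_w = x$spec_norm_w,
               spec_norm_antisym = x$spec_norm_antisym,
               lambda_max_sym = x$lambda_max_sym, bound = x$bound)
  } else {
    as.data.frame(x)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a trajectory as delimited text
#'
#' Tab-separated: a time column followed by one column per flattened state
#' coordinate.
#'
#' @param result A [simulate_network()] result.
#' @param path Output path.
#' @export
write_trajectory <- function(result, path) {
  df <- data.frame(time = result$times, result$states)
  names(df) <- c("time", sprintf("s%d", seq_len(ncol(result$states))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Provenance sidecar: every parameter and seed needed to re-execute a run.
write_provenance <- function(params, path) {
  params$package_version <- as.character(utils::packageVersion("contractnet"))
  params$r_version <- R.version.string
  jsonlite::write_json(params, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
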