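#' Competition-style metrics report
#'
#' One row per run, mirroring the five ranking criteria of the benchmark
#' setting: accuracy (exact match against the plaintext oracle, or the
#' maximum deviation when not exact), security level, per-phase timings,
#' serialized storage footprint, and communication cost per direction.
#' A report cannot be constructed without an accuracy verdict.
#'
#' @param task task identifier.
#' @param accuracy_exact logical: secure output identical to the oracle.
#' @param max_deviation largest absolute deviation from the oracle.
#' @param security_bits configured security level (`NA` for plaintext).
#' @param time_s named list/vector of phase or party timings in seconds.
#' @param storage_bytes serialized ciphertext/share footprint.
#' @param comm_bytes named vector of bytes per direction (empty for
#'   plaintext runs).
#' @param n problem size descriptor (sites, keys, ...).
#' @param seed seed used, if any.
#' @param config configuration list (hashed into `config_hash`).
#' @return a `metrics_report` tibble (one row).
#' @export
metrics_report <- function(task, accuracy_exact, max_deviation = 0,
                           security_bits = NA_real_, time_s = list(),
                           storage_bytes = 0, comm_bytes = c(),
                           n = NA_integer_, seed = NA_integer_,
                           config = list()) {
  if (length(accuracy_exact) != 1 || is.na(accuracy_exact))
    abort("a metrics report requires an accuracy verdict (oracle comparison)")
  comm_total <- if (length(comm_bytes) == 0) 0 else sum(comm_bytes)
  out <- tibble::tibble(
    task = task,
    accuracy_exact = as.logical(accuracy_exact),
    max_deviation = as.numeric(max_deviation),
    security_bits = as.numeric(security_bits),
    time_total_s = if (length(time_s) == 0) NA_real_ else
      sum(unlist(time_s), na.rm = TRUE),
    storage_bytes = as.numeric(storage_bytes),
    comm_bytes_total = as.numeric(comm_total),
    n = as.integer(n),
    seed = as.integer(seed),
    config_hash = substr(cx_sha256_hex(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                        digits = NA)), 1, 16))
  out$time_s <- list(as.list(time_s))
  out$comm_bytes <- list(as.list(comm_bytes))
  structure(out, class = c("metrics_report", class(tibble::tibble())))
}

#' @export
glance.metrics_report <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("task", "accuracy_exact", "max_deviation",
                                 "security_bits", "time_total_s",
                                 "storage_bytes", "comm_bytes_total", "n")])
}

#' @export
tidy.metrics_report <- function(x, ...) {
  scalar <- glance(x)
  tidyr::pivot_longer(
    dplyr::mutate(scalar, dplyr::across(dplyr::everything(), as.character)),
    dplyr::everything(), names_to = "metric", values_to = "value")
}

#' Write a metrics report as schema-checked JSON
#'
#' @param x a `metrics_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  stopifnot(inherits(x, "metrics_report"))
  obj <- as.list(glance(x))
  obj$time_s <- x$time_s[[1]]
  obj$comm_bytes <- x$comm_bytes[[1]]
  obj$config_hash <- x$config_hash
  obj$seed <- x$seed
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Validate a metrics JSON file against the shipped schema
#'
#' Checks required fields and their types against the schema in
#' `inst/schema/metrics-schema.json`.
#'
#' @param path JSON file to validate.
#' @return `TRUE` (invisibly) or an error naming the violation.
#' @export
validate_metrics_json <- function(path) {
  schema <- jsonlite::read_json(system.file("schema", "metrics-schema.json",
                                            package = "genocrypt"))
  obj <- jsonlite::read_json(path)
  for (field in names(schema$required)) {
    if (!field %in% names(obj))
      abort(paste0("metrics JSON missing required field: ", field))
    want <- schema$required[[field]]
    val <- obj[[field]]
    ok <- switch(want,
      boolean = is.logical(val),
      number = is.numeric(val) || is.null(val),
      string = is.character(val),
      object = is.list(val),
      TRUE)
    if (!ok)
      abort(sprintf("metrics JSON field '%s' should be %s", field, want))
  }
  invisible(TRUE)
}
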