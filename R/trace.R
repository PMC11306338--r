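#' Construct a turbidity trace
#'
#' A trace is one run of a turbidimetric polymerization assay: optical density
#' (O.D., typically at 365 nm) sampled over time, optionally alongside the
#' sample temperature recorded at the measurement position.
#'
#' @param times Sample instants in seconds; strictly increasing, non-negative.
#' @param od Optical density values (absorbance units), same length as `times`.
#' @param temperature Optional temperature trace in degrees Celsius, same
#'   length as `times`.
#' @param run_id Identifier for the run (used in error messages and logs).
#' @param condition Label of the experimental condition the run belongs to.
#' @return An object of class `mt_trace`: a list with elements `times`, `od`,
#'   `temperature` (possibly `NULL`), `run_id` and `condition`.
#' @examples
#' tr <- mt_trace(0:10, (0:10) / 10)
#' tr
#' @export
mt_trace <- function(times, od, temperature = NULL, run_id = "run",
                     condition = "") {
  times <- as.numeric(times)
  od <- as.numeric(od)
  if (length(times) == 0L) {
    stop_input("trace times must be non-empty")
  }
  if (length(od) != length(times)) {
    stop_input("od and times must have equal length")
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop_input("times must be finite")
  }
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop_input(sprintf("times must be strictly increasing (violated at row %d)", bad))
  }
  if (any(times < 0)) {
    stop_input("times must be non-negative")
  }
  if (!is.null(temperature)) {
    temperature <- as.numeric(temperature)
    if (length(temperature) != length(times)) {
      stop_input("temperature and times must have equal length")
    }
  }
  structure(
    list(times = times, od = od, temperature = temperature,
         run_id = as.character(run_id), condition = as.character(condition)),
    class = "mt_trace"
  )
}

#' @export
print.mt_trace <- function(x, ...) {
  norm <- isTRUE(attr(x, "normalized"))
  cat(sprintf("<mt_trace> %s%s: %d samples over [%g, %g] s%s\n",
              x$run_id,
              if (nzchar(x$condition)) paste0(" (", x$condition, ")") else "",
              length(x$times), min(x$times), max(x$times),
              if (norm) ", normalized" else ""))
  invisible(x)
}

#' Test whether an object is a trace
#' @param x Object to test.
#' @return `TRUE` for `mt_trace` objects.
#' @export
is_mt_trace <- function(x) inherits(x, "mt_trace")

# classed error helpers -------------------------------------------------------

stop_input <- function(msg) {
  stop(errorCondition(msg, class = c("turbikin_input_error", "error")))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("turbikin_degenerate_trace", "error")))
}

stop_crossing <- function(msg) {
  stop(errorCondition(msg, class = c("turbikin_undefined_crossing", "error")))
}

stop_window <- function(msg) {
  stop(errorCondition(msg, class = c("turbikin_insufficient_window", "error")))
}

#' Read a trace from CSV
#'
#' Expects a header `time_s,od` with an optional `temp_c` column. Validation
#' errors name the offending row or column.
#'
#' @param path Path to a CSV file.
#' @param run_id,condition Metadata attached to the returned trace; `run_id`
#'   defaults to the file name without extension.
#' @return An [mt_trace()] object.
#' @export
read_trace_csv <- function(path, run_id = NULL, condition = "") {
  if (!file.exists(path)) {
    stop_input(sprintf("trace file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("time_s", "od")) {
    if (!col %in% names(df)) {
      stop_input(sprintf("%s: missing required column '%s'", path, col))
    }
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
      stop_input(sprintf("%s: non-numeric value in column '%s' at row %s",
                         path, col, ifelse(is.na(bad), "?", bad)))
    }
  }
  if (any(diff(df$time_s) <= 0)) {
    bad <- which(diff(df$time_s) <= 0)[1L] + 1L
    stop_input(sprintf("%s: non-monotone time at row %d", path, bad))
  }
  if (is.null(run_id)) {
    run_id <- sub("\\.[^.]*$", "", basename(path))
  }
  mt_trace(df$time_s, df$od,
           temperature = if ("temp_c" %in% names(df)) df$temp_c else NULL,
           run_id = run_id, condition = condition)
}

#' Write a trace to CSV
#'
#' Writes the `time_s,od[,temp_c]` layout read back by [read_trace_csv()].
#' The round trip is lossless to full double precision.
#'
#' @param trace An [mt_trace()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(is_mt_trace(trace))
  df <- data.frame(time_s = trace$times, od = trace$od)
  if (!is.null(trace$temperature)) df$temp_c <- trace$temperature
  # format() would truncate doubles; write full precision explicitly
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, function(x) sprintf("%.17g", x)),
                           sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Write or read a cohort manifest
#'
#' A manifest groups run files under one experimental condition. It is stored
#' as JSON with fields `condition`, `files`, `nominal_temp_c`, `exposure` and
#' `seed`.
#'
#' @param condition Condition label (non-empty).
#' @param files Character vector of distinct trace CSV paths.
#' @param nominal_temp_c Nominal target temperature of the condition.
#' @param exposure Free-text description of the exposure (e.g. RF settings).
#' @param seed Seed used if the cohort was simulated, else `NA`.
#' @param path Manifest path (JSON).
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   returns the manifest as a list.
#' @export
write_manifest <- function(path, condition, files, nominal_temp_c = NA_real_,
                           exposure = "", seed = NA_integer_) {
  if (!nzchar(condition)) stop_input("manifest condition label must be non-empty")
  if (anyDuplicated(files)) stop_input("manifest file paths must be distinct")
  obj <- list(condition = condition, files = as.character(files),
              nominal_temp_c = nominal_temp_c, exposure = exposure,
              seed = seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("manifest not found: %s", path))
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$condition) || !nzchar(m$condition)) {
    stop_input(sprintf("%s: manifest condition label missing", path))
  }
  if (anyDuplicated(m$files)) {
    stop_input(sprintf("%s: manifest file paths must be distinct", path))
  }
  m
}

#' Load all traces referenced by a manifest
#'
#' @param manifest A manifest list from [read_manifest()].
#' @param dir Directory that relative manifest paths are resolved against.
#' @return A list of [mt_trace()] objects labelled with the manifest condition.
#' @export
read_cohort <- function(manifest, dir = ".") {
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", manifest$files),
                  manifest$files, file.path(dir, manifest$files))
  lapply(paths, read_trace_csv, condition = manifest$condition)
}
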