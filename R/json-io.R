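#' Serialize an analysis result to JSON
#'
#' Writes a schema-versioned, key-sorted JSON file so that two runs with
#' the same inputs produce byte-identical output.  The result's class, the
#' seed and any parameters supplied are stored alongside the fields, which
#' makes every saved result self-describing and auditable.
#'
#' @param results a result object produced by this package (e.g. an
#'   [sma()] fit, a [common_slope_test()] result, a
#'   [permutation_trend_test()] result) or a plain named list.
#' @param path output path.
#' @param seed,parameters optional provenance recorded in the file.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path, seed = NULL,
                               parameters = NULL) {
  payload <- list(
    schema_version = "1.0",
    result_type = class(results)[1],
    seed = seed,
    parameters = parameters,
    result = strip_for_json(results)
  )
  payload <- sort_keys(payload)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a result written by [write_results_json()]
#'
#' Restores the stored fields and re-attaches the recorded result class.
#'
#' @param path path to a JSON file written by [write_results_json()].
#' @return A list with elements `result` (classed as when written),
#'   `result_type`, `schema_version`, `seed`, `parameters`.
#' @export
read_results_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$schema_version))
    stop("not a results file (no schema_version): ", path, call. = FALSE)
  if (!is.null(payload$result) && is.list(payload$result) &&
      !identical(payload$result_type, "list"))
    class(payload$result) <- payload$result_type
  payload
}

# drop closures / environments / heavyweight carried data, keep fields
strip_for_json <- function(x) {
  if (is.function(x) || is.environment(x)) {
    stop("unserializable field of type ", class(x)[1], call. = FALSE)
  }
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) {
    x <- unclass(x)
    x[["model"]] <- NULL   # embedded lm objects are not serialized
    x[["call"]] <- NULL
    return(lapply(x, strip_for_json))
  }
  if (is.call(x) || is.name(x)) return(deparse(x))
  x
}

sort_keys <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x))))
      x <- x[order(names(x))]
    return(lapply(x, sort_keys))
  }
  x
}
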