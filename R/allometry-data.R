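#' Construct a per-individual allometry dataset
#'
#' An `allometry_data` object is a data frame with one row per individual
#' carrying a body size measure (pupal case area in the motivating design),
#' one column per organ, and the grouping labels used downstream: genotype
#' or driver (`group`), rearing temperature and nutrition treatment.  Sizes
#' are unit-agnostic positive reals; areas and lengths are never converted.
#'
#' The object records whether sizes are on the raw or the log scale (and
#' the log base used), because every scaling analysis operates on log sizes
#' while effect sizes are reported on the raw scale.
#'
#' @param data data frame with columns `body_size` and one column per
#'   organ; optional columns `individual_id`, `group`, `temperature`,
#'   `treatment` (missing ones are filled with defaults / `NA`).
#' @param organs character vector naming the organ columns (the organ
#'   vocabulary of the dataset).  Defaults to every column of `data` that
#'   is not one of the reserved ones.
#' @param size_scale `"raw"` or `"log"`.
#' @param log_base base of the logarithm when `size_scale = "log"`.
#' @return A data frame of class `allometry_data` with attributes
#'   `organs`, `size_scale` and `log_base`.
#' @seealso [read_individuals_csv()], [log_transform()]
#' @examples
#' d <- allometry_data(data.frame(body_size = c(10, 12, 15),
#'                                wing = c(5, 6, 7.4)))
#' attr(d, "organs")
#' @export
allometry_data <- function(data, organs = NULL,
                           size_scale = c("raw", "log"), log_base = NULL) {
  size_scale <- match.arg(size_scale)
  stopifnot(is.data.frame(data))
  if (!"body_size" %in% names(data))
    stop("`data` must contain a `body_size` column", call. = FALSE)
  reserved <- c("individual_id", "group", "temperature", "treatment",
                "body_size")
  if (is.null(organs))
    organs <- setdiff(names(data), reserved)
  missing_org <- setdiff(organs, names(data))
  if (length(missing_org))
    stop("organ column(s) not found: ", paste(missing_org, collapse = ", "),
         call. = FALSE)
  if (!"individual_id" %in% names(data))
    data$individual_id <- sprintf("ind%03d", seq_len(nrow(data)))
  if (!"group" %in% names(data)) data$group <- "all"
  if (!"temperature" %in% names(data)) data$temperature <- NA_real_
  if (!"treatment" %in% names(data)) data$treatment <- NA_character_
  data <- data[, c(reserved[reserved != "body_size"], "body_size", organs)]
  for (col in c("body_size", organs)) {
    v <- data[[col]]
    if (!is.numeric(v))
      stop("column `", col, "` is not numeric", call. = FALSE)
    if (size_scale == "raw" && any(!is.na(v) & v <= 0))
      stop("column `", col, "` contains non-positive sizes", call. = FALSE)
  }
  if (all(is.na(data$body_size)))
    stop("no usable body sizes", call. = FALSE)
  if (size_scale == "log") {
    if (is.null(log_base) || log_base <= 0 || log_base == 1)
      stop("`log_base` must be positive and != 1 for log-scale data",
           call. = FALSE)
  } else {
    log_base <- NULL
  }
  structure(data,
            organs = organs, size_scale = size_scale, log_base = log_base,
            class = c("allometry_data", "data.frame"))
}

#' @export
print.allometry_data <- function(x, ...) {
  cat("Allometry dataset: ", nrow(x), " individuals, organs: ",
      paste(attr(x, "organs"), collapse = ", "),
      " [", attr(x, "size_scale"), " scale]\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

#' Subset an allometry dataset by a row mask
#'
#' Plain `[` subsetting of a data frame drops the dataset attributes;
#' `filter_records()` keeps the organ vocabulary and size-scale metadata.
#'
#' @param data an [allometry_data] object.
#' @param mask logical vector of length `nrow(data)` (or an index vector).
#' @return An `allometry_data` object with the selected rows.
#' @export
filter_records <- function(data, mask) {
  stopifnot(inherits(data, "allometry_data"))
  out <- as.data.frame(data)[mask, , drop = FALSE]
  rownames(out) <- NULL
  allometry_data(out, organs = attr(data, "organs"),
                 size_scale = attr(data, "size_scale"),
                 log_base = attr(data, "log_base"))
}

#' Read per-individual morphometric data from CSV
#'
#' Reads a comma-separated file (header row required, UTF-8, `.` decimal
#' mark) with one row per individual.  Rows whose body size or any present
#' organ size fails to parse as a positive real are rejected, and the
#' rejected row indices are reported in a warning; empty cells are treated
#' as missing organ measurements (dissection loss is routine) and kept.
#'
#' @param path path to the CSV file.
#' @param column_map named list mapping dataset fields to CSV column
#'   names.  Recognised entries: `individual_id`, `group`, `temperature`,
#'   `treatment`, `body_size` (all scalar, default to the same-named
#'   column when present) and `organs`, a named character vector
#'   `c(organ_name = csv_column, ...)`.  `organs` is required unless the
#'   CSV already uses reserved names for everything else, in which case the
#'   remaining columns are taken as organs.
#' @return An [allometry_data] object on the raw scale.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(body_size = c(10, 12), wing = c(5, 6)), f,
#'           row.names = FALSE)
#' read_individuals_csv(f)
#' @export
read_individuals_csv <- function(path, column_map = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("empty input: no data rows in ", path,
                           call. = FALSE)
  get_col <- function(field, required = FALSE) {
    nm <- if (!is.null(column_map[[field]])) column_map[[field]]
          else if (field %in% names(raw)) field else NULL
    if (is.null(nm)) {
      if (required)
        stop("no column mapped for required field `", field, "`",
             call. = FALSE)
      return(NULL)
    }
    if (!nm %in% names(raw))
      stop("mapped column `", nm, "` (field `", field,
           "`) is missing from ", path, call. = FALSE)
    raw[[nm]]
  }
  organ_map <- column_map[["organs"]]
  if (is.null(organ_map)) {
    reserved <- unlist(lapply(
      c("individual_id", "group", "temperature", "treatment", "body_size"),
      function(f) if (!is.null(column_map[[f]])) column_map[[f]] else f))
    rest <- setdiff(names(raw), reserved)
    if (!length(rest))
      stop("no organ columns: supply `column_map$organs`", call. = FALSE)
    organ_map <- stats::setNames(rest, rest)
  }
  absent <- setdiff(unname(organ_map), names(raw))
  if (length(absent))
    stop("mapped organ column(s) missing: ", paste(absent, collapse = ", "),
         call. = FALSE)

  parse_size <- function(chr) {
    # "" / NA -> missing (allowed); otherwise must parse as a positive real
    v <- suppressWarnings(as.numeric(chr))
    bad <- (!is.na(chr) & nzchar(trimws(chr))) & (is.na(v) | v <= 0)
    missing <- is.na(chr) | !nzchar(trimws(chr))
    v[missing] <- NA_real_
    list(value = v, bad = bad, missing = missing)
  }

  body <- parse_size(get_col("body_size", required = TRUE))
  bad <- body$bad | body$missing      # a record is useless without body size
  organ_vals <- list()
  for (org in names(organ_map)) {
    p <- parse_size(raw[[organ_map[[org]]]])
    organ_vals[[org]] <- p$value
    bad <- bad | p$bad
  }
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected (non-positive, unparseable or ",
            "missing body size) at index: ",
            paste(which(bad), collapse = ", "), call. = FALSE)
  }
  keep <- !bad
  if (!any(keep)) stop("empty input: no usable rows in ", path, call. = FALSE)

  out <- data.frame(body_size = body$value[keep])
  id <- get_col("individual_id")
  out$individual_id <- if (is.null(id)) sprintf("row%03d", which(keep))
                       else id[keep]
  grp <- get_col("group")
  if (!is.null(grp)) out$group <- grp[keep]
  tmp <- get_col("temperature")
  if (!is.null(tmp)) out$temperature <- suppressWarnings(as.numeric(tmp[keep]))
  trt <- get_col("treatment")
  if (!is.null(trt)) out$treatment <- trt[keep]
  for (org in names(organ_map)) out[[org]] <- organ_vals[[org]][keep]
  allometry_data(out, organs = names(organ_map))
}

#' Write an allometry dataset to CSV
#'
#' Inverse of [read_individuals_csv()] for raw-scale data: the written file
#' round-trips through `read_individuals_csv()` to an equal dataset.
#'
#' @param data an [allometry_data] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  stopifnot(inherits(data, "allometry_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Log-transform all sizes in a dataset
#'
#' Scaling relationships are linear on the log-log scale; the allometric
#' coefficient is the slope there and is invariant to the base chosen
#' (the intercept is not).  The natural log is the default base.
#'
#' @param data a raw-scale [allometry_data] object.
#' @param base positive log base, not 1.
#' @return The dataset with every body and organ size replaced by its log.
#' @export
log_transform <- function(data, base = exp(1)) {
  stopifnot(inherits(data, "allometry_data"))
  if (attr(data, "size_scale") != "raw")
    stop("dataset is already on the log scale", call. = FALSE)
  if (base <= 0 || base == 1) stop("`base` must be > 0 and != 1",
                                   call. = FALSE)
  organs <- attr(data, "organs")
  out <- as.data.frame(data)
  for (col in c("body_size", organs)) out[[col]] <- log(out[[col]], base)
  allometry_data(out, organs = organs, size_scale = "log", log_base = base)
}

#' Undo a log transform
#'
#' @param data a log-scale [allometry_data] object.
#' @return The dataset back on the raw scale.
#' @export
exp_transform <- function(data) {
  stopifnot(inherits(data, "allometry_data"))
  if (attr(data, "size_scale") != "log")
    stop("dataset is not on the log scale", call. = FALSE)
  base <- attr(data, "log_base")
  organs <- attr(data, "organs")
  out <- as.data.frame(data)
  for (col in c("body_size", organs)) out[[col]] <- base^out[[col]]
  allometry_data(out, organs = organs, size_scale = "raw")
}

# complete (x, y) pairs for an organ against a reference trait;
# reference "body" means the body_size column
complete_pairs <- function(data, organ, reference = "body") {
  organs <- attr(data, "organs")
  if (!organ %in% organs)
    stop("unknown organ `", organ, "`; vocabulary: ",
         paste(organs, collapse = ", "), call. = FALSE)
  x <- if (identical(reference, "body")) data$body_size
       else if (reference %in% organs) data[[reference]]
       else stop("unknown reference trait `", reference, "`", call. = FALSE)
  y <- data[[organ]]
  ok <- !is.na(x) & !is.na(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}
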