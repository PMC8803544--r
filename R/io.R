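parse_numeric_table <- function(path, min_cols) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  sep_comma <- grepl(",", lines[1L], fixed = TRUE)
  rows <- lapply(seq_along(lines), function(i) {
    fields <- if (sep_comma) strsplit(lines[i], ",", fixed = TRUE)[[1L]]
              else strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("parse error at line %d of %s: non-numeric field", i, path))
    if (length(vals) < min_cols)
      stop(sprintf("format error at line %d of %s: %d columns, expected >= %d",
                   i, path, length(vals), min_cols))
    vals
  })
  ncols <- vapply(rows, length, 1L)
  if (length(unique(ncols)) != 1L)
    stop("ragged rows in ", path, " (differing column counts)")
  do.call(rbind, rows)
}

#' Read a realignment-parameter file
#'
#' Realignment outputs vary across tools in rotation units (degrees vs
#' radians) and column order (rotations first vs last); both are taken as
#' explicit flags rather than guessed, since a silent unit mix-up corrupts
#' FD by a factor of ~57. Rotations are converted to radians on ingest.
#'
#' @param path whitespace- or comma-delimited numeric text, one row per
#'   volume, at least 6 columns (extra columns are dropped with a warning).
#' @param tr_s repetition time in seconds.
#' @param dialect rotation units in the file: `"radians"` or `"degrees"`.
#' @param rotation_columns `"last3"` (translations first, the canonical
#'   order) or `"first3"` (rotations first).
#' @param phase_axis,subject_id,run_id passed to [motion_trace()].
#' @return a [motion_trace()].
#' @export
read_motion <- function(path, tr_s, dialect = c("radians", "degrees"),
                        rotation_columns = c("last3", "first3"),
                        phase_axis = "y",
                        subject_id = NA_character_, run_id = NA_character_) {
  dialect <- match.arg(dialect)
  rotation_columns <- match.arg(rotation_columns)
  m <- parse_numeric_table(path, min_cols = 6L)
  if (ncol(m) > 6L) {
    warning(sprintf("%s has %d columns; using the first 6", path, ncol(m)))
    m <- m[, 1:6, drop = FALSE]
  }
  if (rotation_columns == "first3") m <- m[, c(4:6, 1:3), drop = FALSE]
  if (dialect == "degrees") m[, 4:6] <- m[, 4:6] * pi / 180
  motion_trace(m, tr_s = tr_s, phase_axis = phase_axis,
               subject_id = subject_id, run_id = run_id)
}

#' Write a motion trace as canonical 6-column text
#'
#' Rotations are written in radians; [read_motion()] round-trips the values
#' to better than 1e-9.
#'
#' @param trace a [motion_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  lines <- apply(trace$params, 1L, function(r)
    paste(sprintf("%.15e", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parcel timeseries table with its network map
#'
#' @param path TSV with a header row of parcel ids, one row per frame.
#' @param network_map_path 2-column TSV (parcel_id, network), no header
#'   required; or a named character vector given directly via `network_of`.
#' @param network_of optional named character vector overriding
#'   `network_map_path`.
#' @param tr_s repetition time in seconds.
#' @return a [parcel_timeseries()].
#' @export
read_timeseries <- function(path, network_map_path = NULL, network_of = NULL,
                            tr_s) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (is.null(network_of)) {
    if (is.null(network_map_path))
      stop("supply network_map_path or network_of")
    network_of <- read_network_map(network_map_path)
  }
  parcel_timeseries(as.matrix(tab), parcel_ids = colnames(tab),
                    network_of = network_of, tr_s = tr_s)
}

#' @rdname read_timeseries
#' @export
read_network_map <- function(network_map_path) {
  map <- read.table(network_map_path, header = FALSE, sep = "\t",
                    col.names = c("parcel_id", "network"),
                    colClasses = "character")
  stats::setNames(map$network, map$parcel_id)
}

#' Write a parcel timeseries (and optionally its network map) as TSV
#'
#' @param ts a [parcel_timeseries()].
#' @param path output TSV path (header row of parcel ids).
#' @param network_map_path optional path for the 2-column network map.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, network_map_path = NULL) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  df <- as.data.frame(ts$data)
  write.table(format(df, digits = 15, trim = TRUE, scientific = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(network_map_path))
    write.table(data.frame(ts$parcel_ids, unname(ts$network_of)),
                network_map_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write frame masks as newline-delimited 0/1 text
#'
#' @param mask a [frame_mask()].
#' @param path file path.
#' @param threshold_mm,source stored alongside when reading.
#' @return [read_mask()] returns a [frame_mask()]; [write_mask()] returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "frame_mask"))
  writeLines(as.character(as.integer(mask$keep)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, threshold_mm, source = "unfiltered") {
  v <- as.integer(readLines(path))
  if (anyNA(v) || !all(v %in% 0:1)) stop("mask file must contain only 0/1")
  frame_mask(v == 1L, threshold_mm = threshold_mm, source = source)
}

#' Write an object as a JSON report
#'
#' S3 report objects (retention reports, notch specs, ...) are flattened to
#' plain lists; numbers are written unrounded.
#'
#' @param obj a list or respkit S3 object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(obj, path) {
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
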