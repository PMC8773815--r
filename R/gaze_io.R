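#' @importFrom data.table fread fwrite as.data.table data.table setDT setDF rbindlist :=
NULL

STIMULATION_LEVELS <- c("FEF", "PPC", "SHAM")
TIMEPOINT_LEVELS <- c("T0", "T1", "T2")

fixation_fields <- c("participant", "stimulation", "timepoint", "picture",
                     "start_ms", "duration_ms", "x_px", "y_px")

#' Construct a fixation table
#'
#' A fixation table is a data frame with one row per fixation and the eight
#' canonical columns `participant`, `stimulation` (FEF/PPC/SHAM),
#' `timepoint` (T0/T1/T2), `picture`, `start_ms`, `duration_ms`, `x_px`,
#' `y_px`, carrying the screen geometry and a provenance string as
#' attributes. Coordinates are screen pixels with the origin at the top-left
#' corner; `start_ms` counts from picture onset.
#'
#' @param records Data frame with (at least) the eight fixation columns.
#' @param geometry A [screen_geometry()].
#' @param provenance Free-text description of where the records came from.
#' @return A `fixation_table` (data frame).
#' @export
fixation_table <- function(records, geometry = screen_geometry(),
                           provenance = "unspecified") {
  records <- as.data.frame(records)
  missing <- setdiff(fixation_fields, names(records))
  if (length(missing) > 0) {
    stop("fixation table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records$stimulation <- toupper(as.character(records$stimulation))
  records$timepoint <- toupper(as.character(records$timepoint))
  bad_stim <- setdiff(unique(records$stimulation), STIMULATION_LEVELS)
  if (length(bad_stim) > 0) {
    stop("unknown stimulation level(s): ", paste(bad_stim, collapse = ", "),
         call. = FALSE)
  }
  bad_tp <- setdiff(unique(records$timepoint), TIMEPOINT_LEVELS)
  if (length(bad_tp) > 0) {
    stop("unknown timepoint level(s): ", paste(bad_tp, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("start_ms", "duration_ms", "x_px", "y_px")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  if (nrow(records) > 0) {
    if (any(!is.finite(records$start_ms)) || any(records$start_ms < 0)) {
      stop("start_ms must be finite and >= 0", call. = FALSE)
    }
    if (any(!is.finite(records$duration_ms)) || any(records$duration_ms <= 0)) {
      stop("duration_ms must be finite and > 0", call. = FALSE)
    }
  }
  structure(records,
            class = c("fixation_table", "data.frame"),
            geometry = geometry, provenance = provenance)
}

#' @export
print.fixation_table <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf("<fixation_table> %d fixations, %d participant(s) [%s]\n",
              nrow(x), length(unique(x$participant)),
              attr(x, "provenance")))
  if (!is.null(g)) print(g)
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Default mapping from file headers to fixation fields
#'
#' @return Named character vector mapping canonical field names to the
#'   column names expected in the file; override entries to ingest exports
#'   from other eye-tracking software dialects.
#' @export
default_fixation_columns <- function() {
  stats::setNames(fixation_fields, fixation_fields)
}

#' Read a fixation report table from TSV or CSV
#'
#' Expects a header row, UTF-8 encoding and `.` as decimal separator. Row
#' order is preserved and no filtering is applied: fixations outside the
#' picture area are retained here and removed by [filter_out_of_bounds()].
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"csv"`.
#' @param columns Named character vector mapping the canonical fixation
#'   fields to the file's column names (see [default_fixation_columns()]).
#' @param geometry A [screen_geometry()] describing the recording display.
#' @return A [fixation_table()].
#' @export
read_fixation_table <- function(path, dialect = c("tsv", "csv"),
                                columns = default_fixation_columns(),
                                geometry = screen_geometry()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("cannot read fixation table: file not found: ", path, call. = FALSE)
  }
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- data.table::fread(path, sep = sep, header = TRUE,
                           colClasses = "character", data.table = FALSE)
  missing <- names(columns)[!columns %in% names(raw)]
  if (length(missing) > 0) {
    stop("fixation file ", path, " lacks mandatory column(s): ",
         paste(sprintf("%s (expected header '%s')", missing, columns[missing]),
               collapse = ", "),
         call. = FALSE)
  }
  out <- raw[, columns[fixation_fields], drop = FALSE]
  names(out) <- fixation_fields
  for (col in c("start_ms", "duration_ms", "x_px", "y_px")) {
    val <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(val) & !is.na(out[[col]]) & nzchar(out[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("malformed numeric value(s) in column '%s' at data row(s) %s",
                   col, paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
    }
    out[[col]] <- val
  }
  fixation_table(out, geometry = geometry, provenance = path)
}

#' Write a fixation table
#'
#' Inverse of [read_fixation_table()]: a read-write-read round trip yields an
#' identical table.
#'
#' @param table A [fixation_table()].
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_fixation_table <- function(table, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "fixation_table"))
  sep <- if (dialect == "tsv") "\t" else ","
  data.table::fwrite(as.data.frame(table)[, fixation_fields],
                     path, sep = sep)
  invisible(path)
}
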