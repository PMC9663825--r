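#' Default in-band missing-value codes
#'
#' `-9999` is the recommended sentinel for missing numeric observations;
#' the empty string and `N/A` are the documented text-missing convention.
#' Individual files can extend this set through their file-level metadata
#' `missing_value_codes`.
#'
#' @return Character vector of codes.
#' @export
default_missing_codes <- function() c("-9999", "", "N/A")

#' Parse a CSV file into a table document
#'
#' RFC 4180 dialect: comma-delimited, double-quote escaping, `\n` or
#' `\r\n` newlines. All cells are kept as verbatim text (no type coercion,
#' no header normalization, empty string preserved). Ragged rows are parse
#' errors, not silently padded; the reported row number counts the header
#' line as row 1.
#'
#' @param file Path to a CSV file, or literal CSV text wrapped in [I()].
#' @param source_name Name recorded in the document and in issue locations;
#'   defaults to the file's base name.
#' @param encoding Encoding hint; default `"UTF-8"`.
#' @return A `table_document`: list with `source_name`, `header`, `data`
#'   (tibble of character columns, verbatim names), `encoding`, `dialect`.
#' @export
#' @examples
#' doc <- parse_csv(I("a,b\n1,2\n"))
#' doc$header
parse_csv <- function(file, source_name = NULL, encoding = "UTF-8") {
  if (is.null(source_name)) {
    source_name <- if (inherits(file, "AsIs")) "<text>" else basename(file)
  }
  if (!inherits(file, "AsIs") && (!file.exists(file) || file.size(file) == 0)) {
    stop("cannot parse '", source_name, "': ",
         if (!file.exists(file)) "file not found" else "file is empty",
         call. = FALSE)
  }
  if (inherits(file, "AsIs") && !nzchar(paste(file, collapse = ""))) {
    stop("cannot parse '", source_name, "': input is empty", call. = FALSE)
  }
  dat <- suppressWarnings(readr::read_csv(
    file,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),
    trim_ws = FALSE,
    skip_empty_rows = FALSE,
    name_repair = "minimal",
    progress = FALSE,
    locale = readr::locale(encoding = encoding),
    show_col_types = FALSE
  ))
  probs <- readr::problems(dat)
  ragged <- probs[grepl("columns", probs$expected), , drop = FALSE]
  if (nrow(ragged) > 0) {
    stop("ragged row in '", source_name, "' at row ", ragged$row[1],
         ": expected ", ragged$expected[1], ", got ", ragged$actual[1],
         call. = FALSE)
  }
  if (ncol(dat) == 0) {
    stop("cannot parse '", source_name, "': no columns", call. = FALSE)
  }
  structure(
    list(
      source_name = source_name,
      header = names(dat),
      data = tibble::as_tibble(dat, .name_repair = "minimal"),
      encoding = encoding,
      dialect = list(delimiter = ",", quote = "\"", newline = "\n")
    ),
    class = "table_document"
  )
}

#' @export
print.table_document <- function(x, ...) {
  cat(sprintf("<table_document> '%s': %d column(s) x %d row(s)\n",
              x$source_name, length(x$header), nrow(x$data)))
  print(utils::head(x$data))
  invisible(x)
}

#' Write a table document back to CSV
#'
#' Inverse of [parse_csv()]: `parse_csv(write_table_csv(doc, f))` yields an
#' identical document (round-trip invariant).
#'
#' @param doc A `table_document`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(doc, path) {
  stopifnot(inherits(doc, "table_document"))
  readr::write_csv(doc$data, path, na = "", quote = "needed", eol = "\n",
                   progress = FALSE)
  invisible(path)
}

# Build a table_document in memory from a tibble of character columns.
as_table_document <- function(data, source_name = "<memory>") {
  data <- tibble::as_tibble(data, .name_repair = "minimal")
  data[] <- lapply(data, as.character)
  structure(
    list(
      source_name = source_name, header = names(data), data = data,
      encoding = "UTF-8",
      dialect = list(delimiter = ",", quote = "\"", newline = "\n")
    ),
    class = "table_document"
  )
}

DATE_PATTERN <- "^\\d{4}-\\d{2}-\\d{2}$"

#' Check cells against the harmonized date convention
#'
#' The harmonized convention is exact: zero-padded `YYYY-MM-DD` naming a
#' real calendar date (leap years honoured). Anything else fails, with a
#' reason token: `bad_pattern` for a shape violation, `bad_calendar_date`
#' for a well-formed string that names no real date.
#'
#' @param x Character vector of cells.
#' @return Tibble with columns `input`, `valid`, `reason` (`NA` when
#'   valid), `date` (the parsed `Date`, `NA` on failure).
#' @export
#' @examples
#' check_date(c("2021-03-05", "03/05/2021", "2021-02-30"))
check_date <- function(x) {
  x <- as.character(x)
  shaped <- grepl(DATE_PATTERN, x)
  parsed <- as.Date(rep(NA_character_, length(x)))
  parsed[shaped] <- as.Date(x[shaped], format = "%Y-%m-%d", optional = TRUE)
  # as.Date silently rolls/NA's impossible dates; require exact round-trip
  ok <- shaped & !is.na(parsed) & format(parsed, "%Y-%m-%d") == x
  reason <- dplyr::case_when(
    ok ~ NA_character_,
    !shaped ~ "bad_pattern",
    .default = "bad_calendar_date"
  )
  parsed[!ok] <- NA
  tibble::tibble(input = x, valid = ok, reason = reason, date = parsed)
}

DATETIME_PATTERN <- paste0(
  "^(\\d{4}-\\d{2}-\\d{2})",
  "([T ](\\d{2}):(\\d{2})(:(\\d{2})(\\.\\d+)?)?(Z|[+-]\\d{2}:?\\d{2})?)?$"
)

#' Check cells against ISO 8601 timestamp syntax
#'
#' Accepts a harmonized date, optionally followed by a time of day and a
#' UTC offset. A timestamp with a time but no offset is syntactically valid
#' but flagged `naive` (validators downgrade this to a warning).
#'
#' @param x Character vector of cells.
#' @return Tibble with `input`, `valid`, `naive`, `reason`.
#' @export
check_datetime <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec(DATETIME_PATTERN, x))
  parts <- purrr::map(m, identity)
  shaped <- lengths(parts) > 0
  date_ok <- rep(FALSE, length(x))
  time_ok <- rep(TRUE, length(x))
  has_time <- rep(FALSE, length(x))
  has_offset <- rep(FALSE, length(x))
  for (i in which(shaped)) {
    p <- parts[[i]]
    date_ok[i] <- check_date(p[2])$valid
    if (nzchar(p[3])) {
      has_time[i] <- TRUE
      hh <- as.integer(p[4]); mm <- as.integer(p[5])
      ss <- if (nzchar(p[7])) as.integer(p[7]) else 0L
      time_ok[i] <- hh < 24 && mm < 60 && ss < 61
      has_offset[i] <- nzchar(p[9])
    }
  }
  valid <- shaped & date_ok & time_ok
  reason <- dplyr::case_when(
    valid ~ NA_character_,
    !shaped ~ "bad_pattern",
    !date_ok ~ "bad_calendar_date",
    .default = "bad_time"
  )
  tibble::tibble(
    input = x, valid = valid,
    naive = valid & has_time & !has_offset,
    reason = reason
  )
}

#' Check decimal-degree coordinates against the harmonized bounds
#'
#' Latitude must lie in the closed interval \eqn{[-90, 90]} and longitude
#' in \eqn{[-180, 180]}; the boundary values pass.
#'
#' @param value Numeric vector of parsed decimal degrees.
#' @param axis `"latitude"` or `"longitude"`.
#' @return Logical vector; `NA` input gives `NA`.
#' @export
#' @examples
#' check_coordinate(c(90, 90.0001), "latitude")
check_coordinate <- function(value, axis = c("latitude", "longitude")) {
  axis <- match.arg(axis)
  lim <- if (axis == "latitude") 90 else 180
  value >= -lim & value <= lim
}

INT_PATTERN <- "^[+-]?\\d+$"
NUM_PATTERN <- "^[+-]?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?$"

# Scalar type of each non-missing cell: integer/decimal/date/datetime/text.
# Syntactically date-shaped strings count as dates even when the calendar
# date is impossible (type inference classifies the format family; the
# calendar check is a separate validation).
infer_cell_type <- function(x) {
  dplyr::case_when(
    grepl(INT_PATTERN, x) ~ "integer",
    grepl(NUM_PATTERN, x) ~ "decimal",
    grepl(DATE_PATTERN, x) ~ "date",
    grepl(DATETIME_PATTERN, x) ~ "datetime",
    .default = "text"
  )
}

# Column type from the set of cell types present, with promotions
# (integer+decimal -> decimal, date+datetime -> datetime). Any other
# combination of two or more types is a mix.
resolve_column_type <- function(types) {
  u <- unique(types)
  if (length(u) == 0) return(list(type = "empty", mixed = FALSE))
  if (length(u) == 1) return(list(type = u, mixed = FALSE))
  if (setequal(u, c("integer", "decimal"))) {
    return(list(type = "decimal", mixed = FALSE))
  }
  if (setequal(u, c("date", "datetime"))) {
    return(list(type = "datetime", mixed = FALSE))
  }
  list(type = "text", mixed = TRUE)
}

#' Profile the columns of a table document
#'
#' Infers a scalar type per column, counts missing and distinct values, and
#' flags columns that mix incompatible types. Cells equal to a missing code
#' do not influence the inferred type. Integer and decimal cells coexist
#' (promoted to decimal), as do date and datetime cells; any other mixture
#' flags the column.
#'
#' @param doc A `table_document`.
#' @param missing_codes Character vector of in-band missing codes;
#'   defaults to [default_missing_codes()].
#' @return Tibble with one row per column: `name`, `inferred_type`,
#'   `mixed_type`, `missing_count`, `distinct_count`.
#' @export
#' @examples
#' doc <- parse_csv(I("depth\n1.2\n-9999\n3.4\n"))
#' profile_columns(doc)
profile_columns <- function(doc, missing_codes = default_missing_codes()) {
  stopifnot(inherits(doc, "table_document"))
  purrr::map_dfr(seq_along(doc$header), function(j) {
    cells <- doc$data[[j]]
    missing <- cells %in% missing_codes
    present <- cells[!missing]
    res <- resolve_column_type(infer_cell_type(present))
    tibble::tibble(
      name = doc$header[j],
      inferred_type = res$type,
      mixed_type = res$mixed,
      missing_count = sum(missing),
      distinct_count = dplyr::n_distinct(present)
    )
  })
}
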