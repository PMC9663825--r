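# Schema-driven validation of a single table document.
#
# The engine is deliberately total: bad data never throws, it only adds
# issues to the report. Issue locations use 1-based file rows counting the
# header line as row 1, so data row i is file row i + 1.

NUMERIC_TYPES <- c("integer", "decimal", "latitude", "longitude")

# Normalized header form used for the forgiving (warning-level) match.
normalize_header <- function(x) gsub("[[:space:]_]+", "", tolower(x))

# Match schema fields to document columns. Exact match wins; otherwise a
# case/whitespace-insensitive match is accepted with a HDR-FUZZY warning.
match_fields <- function(schema, header) {
  if (length(schema$fields) == 0) {
    return(tibble::tibble(field = integer(), name = character(),
                          col = integer(), fuzzy = logical()))
  }
  purrr::imap_dfr(schema$fields, function(f, i) {
    col <- match(f$name, header)
    fuzzy <- FALSE
    if (is.na(col)) {
      col <- match(normalize_header(f$name), normalize_header(header))
      fuzzy <- !is.na(col)
    }
    tibble::tibble(field = i, name = f$name, col = col, fuzzy = fuzzy)
  })
}

# Issues for the non-missing cells of one schema-typed column.
check_field_cells <- function(cells, field, file, colname, schema_id,
                              missing_codes) {
  rows <- seq_along(cells) + 1L
  missing <- cells %in% missing_codes
  issues <- list()
  add <- function(idx, code, message) {
    if (!any(idx)) return()
    if (length(message) > 1) message <- message[idx]
    issues[[length(issues) + 1]] <<- new_issues(
      code = rep(code, sum(idx)), file = file, row = rows[idx],
      column = colname, message = message, schema_id = schema_id
    )
  }
  if (field$value_type %in% c("date", "datetime")) {
    add(cells == "-9999", "DATE-MISSING-CODE",
        "-9999 used as missing marker in a date column; leave blank instead")
  }
  x <- cells[!missing]
  rows <- rows[!missing]
  if (length(x) == 0) return(dplyr::bind_rows(issues))

  vt <- field$value_type
  numeric_vals <- NULL
  if (vt == "integer") {
    add_local <- !grepl(INT_PATTERN, x)
    add(add_local, "TYPE-MISMATCH",
        sprintf("expected integer, got '%s'", x))
    numeric_vals <- suppressWarnings(as.numeric(x))
  } else if (vt %in% c("decimal", "latitude", "longitude")) {
    bad <- !grepl(NUM_PATTERN, x)
    add(bad, "TYPE-MISMATCH", sprintf("expected decimal, got '%s'", x))
    numeric_vals <- suppressWarnings(as.numeric(x))
    numeric_vals[bad] <- NA
  } else if (vt == "date") {
    chk <- check_date(x)
    add(!chk$valid & chk$reason == "bad_pattern", "DATE-FORMAT",
        sprintf("'%s' is not in YYYY-MM-DD format", x))
    add(!chk$valid & chk$reason == "bad_calendar_date", "DATE-CALENDAR",
        sprintf("'%s' is not a real calendar date", x))
  } else if (vt == "datetime") {
    chk <- check_datetime(x)
    add(!chk$valid, "DATETIME-FORMAT",
        sprintf("'%s' is not an ISO 8601 timestamp", x))
    add(chk$naive, "DATETIME-NAIVE",
        sprintf("'%s' has a time of day but no UTC offset", x))
  } else if (vt == "identifier") {
    add(!grepl("^\\S+$", x), "TYPE-MISMATCH",
        sprintf("identifier '%s' is empty or contains whitespace", x))
  } else if (vt == "controlled") {
    out <- !(x %in% field$vocabulary)
    if (field$vocabulary_open) {
      add(out, "VOCAB-NOVEL",
          sprintf("'%s' is not a known term (open vocabulary; accepted)", x))
    } else {
      add(out, "VOCAB",
          sprintf("'%s' not in {%s}", x,
                  paste(field$vocabulary, collapse = ", ")))
    }
  }

  if (vt %in% c("latitude", "longitude")) {
    lim <- if (vt == "latitude") 90 else 180
    out <- !is.na(numeric_vals) & !check_coordinate(numeric_vals, vt)
    add(out, "COORD-BOUNDS",
        sprintf("%s %s outside [-%d, %d]", vt, x, lim, lim))
  } else if (!is.null(field$bounds) && !is.null(numeric_vals)) {
    out <- !is.na(numeric_vals) &
      (numeric_vals < field$bounds[1] | numeric_vals > field$bounds[2])
    add(out, "BOUNDS",
        sprintf("%s outside [%s, %s]", x, field$bounds[1], field$bounds[2]))
  }
  if (nzchar(field$pattern)) {
    add(!grepl(field$pattern, x), "PATTERN",
        sprintf("'%s' does not match pattern %s", x, field$pattern))
  }
  dplyr::bind_rows(issues)
}

# Table-rule layer: header uniqueness, mixed types, missing-code hygiene,
# ISO dates in date-named columns outside the schema's own date fields.
check_table_rules <- function(doc, schema, matched, missing_codes) {
  issues <- list()
  file <- doc$source_name
  rules <- schema$table_rules
  header <- doc$header

  if ("unique-column-names" %in% rules && anyDuplicated(header)) {
    dup <- which(duplicated(header))
    issues[[length(issues) + 1]] <- new_issues(
      "DUP-COLUMN", file, row = 1L, column = header[dup],
      message = sprintf("column name '%s' appears more than once", header[dup]),
      schema_id = schema$id
    )
  }

  unmatched <- setdiff(seq_along(header), matched$col[!is.na(matched$col)])

  if ("no-mixed-type-columns" %in% rules) {
    prof <- profile_columns(doc, missing_codes)
    mixed <- which(prof$mixed_type)
    issues[[length(issues) + 1]] <- new_issues(
      rep("MIXED-TYPE", length(mixed)), file, row = NA_integer_,
      column = header[mixed],
      message = sprintf("column '%s' mixes incompatible value types",
                        header[mixed]),
      schema_id = schema$id
    )
  }

  if ("missing-code-numeric" %in% rules) {
    prof <- profile_columns(doc, missing_codes)
    numeric_cols <- which(prof$inferred_type %in% c("integer", "decimal"))
    for (j in numeric_cols) {
      bad <- which(doc$data[[j]] %in% c("", "N/A"))
      issues[[length(issues) + 1]] <- new_issues(
        rep("MISSING-CODE", length(bad)), file, row = bad + 1L,
        column = header[j],
        message = "blank/text missing marker in a numeric column; use -9999",
        schema_id = schema$id
      )
    }
  }

  if ("iso-date-format" %in% rules) {
    datelike <- unmatched[grepl("date", header[unmatched], ignore.case = TRUE) &
                          !grepl("datetime", header[unmatched], ignore.case = TRUE)]
    for (j in datelike) {
      cells <- doc$data[[j]]
      keep <- !(cells %in% missing_codes)
      chk <- check_date(cells[keep])
      rows <- (seq_along(cells) + 1L)[keep]
      bad_pat <- !chk$valid & chk$reason == "bad_pattern"
      bad_cal <- !chk$valid & chk$reason == "bad_calendar_date"
      issues[[length(issues) + 1]] <- new_issues(
        rep("DATE-FORMAT", sum(bad_pat)), file, row = rows[bad_pat],
        column = header[j],
        message = sprintf("'%s' is not in YYYY-MM-DD format",
                          chk$input[bad_pat]),
        schema_id = schema$id
      )
      issues[[length(issues) + 1]] <- new_issues(
        rep("DATE-CALENDAR", sum(bad_cal)), file, row = rows[bad_cal],
        column = header[j],
        message = sprintf("'%s' is not a real calendar date",
                          chk$input[bad_cal]),
        schema_id = schema$id
      )
    }
  }

  dplyr::bind_rows(issues)
}

#' Validate a table document against a reporting-format schema
#'
#' Applies the schema's declarative rules: one `REQ-MISSING` error per
#' absent required column; per-cell type, format, bounds, vocabulary and
#' pattern checks for every matched field; then the schema's table rules
#' (header uniqueness, mixed-type columns, missing-code hygiene, ISO
#' dates). Columns not declared by the schema are never errors — formats
#' are extensible — they are reported at info severity only. Validation is
#' deterministic; issues come back sorted by (file, row, column, code).
#'
#' @param doc A `table_document` from [parse_csv()].
#' @param schema A `reporting_format_schema` (see [get_schema()]).
#' @param missing_codes Extra in-band missing codes for this file (for
#'   example from its file-level metadata), merged with
#'   [default_missing_codes()].
#' @return A [validation_report()].
#' @export
#' @examples
#' reg <- load_registry()
#' doc <- parse_csv(I("location_id,latitude,longitude\nL1,95,10\n"))
#' tidy(validate_table(doc, get_schema(reg, "location_metadata")))
validate_table <- function(doc, schema, missing_codes = NULL) {
  stopifnot(inherits(doc, "table_document"),
            inherits(schema, "reporting_format_schema"))
  codes <- union(default_missing_codes(), missing_codes %||% character())
  file <- doc$source_name
  matched <- match_fields(schema, doc$header)
  issues <- list()

  required <- purrr::map_chr(schema$fields, "requirement") == "required"
  miss <- matched$field[is.na(matched$col) & required[matched$field]]
  if (length(miss)) {
    issues[[length(issues) + 1]] <- new_issues(
      rep("REQ-MISSING", length(miss)), file, row = 1L,
      column = matched$name[match(miss, matched$field)],
      message = sprintf("required column '%s' is missing",
                        matched$name[match(miss, matched$field)]),
      schema_id = schema$id
    )
  }
  fz <- matched[matched$fuzzy & !is.na(matched$col), , drop = FALSE]
  if (nrow(fz)) {
    issues[[length(issues) + 1]] <- new_issues(
      rep("HDR-FUZZY", nrow(fz)), file, row = 1L,
      column = doc$header[fz$col],
      message = sprintf("column '%s' matched canonical name '%s'; rename it",
                        doc$header[fz$col], fz$name),
      schema_id = schema$id
    )
  }
  if (length(schema$fields) > 0 && schema$extra_columns != "sample_counts") {
    unknown <- setdiff(seq_along(doc$header),
                       matched$col[!is.na(matched$col)])
    issues[[length(issues) + 1]] <- new_issues(
      rep("COL-UNKNOWN", length(unknown)), file, row = 1L,
      column = doc$header[unknown],
      message = sprintf("column '%s' is not part of the schema (kept as extra context)",
                        doc$header[unknown]),
      schema_id = schema$id
    )
  }

  for (k in seq_len(nrow(matched))) {
    if (is.na(matched$col[k])) next
    issues[[length(issues) + 1]] <- check_field_cells(
      doc$data[[matched$col[k]]], schema$fields[[matched$field[k]]],
      file, doc$header[matched$col[k]], schema$id, codes
    )
  }

  issues[[length(issues) + 1]] <- check_table_rules(doc, schema, matched, codes)

  validation_report(
    issues = dplyr::bind_rows(issues),
    files_checked = file,
    schemas_applied = schema$id
  )
}
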