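#' Validation reports
#'
#' A `validation_report` bundles the coded findings of one validation run
#' (a tibble of issues), the files checked and the schemas applied. A
#' report with zero error-severity issues is a pass. Issues are kept in a
#' canonical sort order (file, row, column, code) so reports for the same
#' input are identical across runs.
#'
#' @param issues Tibble of issues as produced by the validators.
#' @param files_checked Character vector of file names covered by the run.
#' @param schemas_applied Character vector of schema ids applied.
#' @return An object of class `validation_report`.
#' @export
validation_report <- function(issues = empty_issues(), files_checked = character(),
                              schemas_applied = character()) {
  if (is.null(issues) || nrow(issues) == 0) issues <- empty_issues()
  issues <- sort_issues(issues)
  structure(
    list(
      issues = issues,
      files_checked = sort(unique(files_checked)),
      schemas_applied = sort(unique(schemas_applied))
    ),
    class = "validation_report"
  )
}

sort_issues <- function(issues) {
  dplyr::arrange(
    issues,
    .data$file,
    dplyr::coalesce(.data$row, 0L),
    dplyr::coalesce(.data$column, ""),
    .data$code,
    .data$message
  )
}

# Merge any number of reports (or NULLs) into one.
combine_reports <- function(...) {
  reports <- purrr::compact(list(...))
  validation_report(
    issues = dplyr::bind_rows(purrr::map(reports, "issues")),
    files_checked = unlist(purrr::map(reports, "files_checked")),
    schemas_applied = unlist(purrr::map(reports, "schemas_applied"))
  )
}

#' @export
print.validation_report <- function(x, ...) {
  g <- generics::glance(x)
  cat(sprintf(
    "<validation_report> %d file(s), %d schema(s): %d error(s), %d warning(s), %d info\n",
    length(x$files_checked), length(x$schemas_applied),
    g$n_error, g$n_warning, g$n_info
  ))
  if (nrow(x$issues) > 0) {
    print(x$issues, n = 20)
  } else {
    cat("No issues found.\n")
  }
  invisible(x)
}

#' Tidy a validation report into its issue table
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return The issues tibble (`code`, `severity`, `file`, `row`, `column`,
#'   `message`, `schema_id`).
#' @export
tidy.validation_report <- function(x, ...) {
  x$issues
}

#' One-row summary of a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return Tibble with per-severity counts, total files/schemas, and `pass`
#'   (TRUE iff no error-severity issues).
#' @export
glance.validation_report <- function(x, ...) {
  sev <- x$issues$severity
  tibble::tibble(
    n_issues = length(sev),
    n_error = sum(sev == "error"),
    n_warning = sum(sev == "warning"),
    n_info = sum(sev == "info"),
    n_files = length(x$files_checked),
    n_schemas = length(x$schemas_applied),
    pass = sum(sev == "error") == 0L
  )
}

#' Plot issue counts by code and severity
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.validation_report <- function(object, ...) {
  issues <- object$issues
  if (nrow(issues) == 0) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "No issues") +
        ggplot2::theme_void()
    )
  }
  counts <- dplyr::count(issues, .data$code, .data$severity)
  ggplot2::ggplot(counts, ggplot2::aes(
    x = stats::reorder(.data$code, .data$n),
    y = .data$n, fill = .data$severity
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(
      error = "#b2182b", warning = "#ef8a62", info = "#67a9cf"
    )) +
    ggplot2::labs(x = NULL, y = "Issues", fill = "Severity") +
    ggplot2::theme_minimal()
}

#' Serialize a validation report to its canonical JSON form
#'
#' The JSON structure is versioned and deterministic: the same report
#' always serializes to the same bytes, so reports can be diffed and
#' hashed.
#'
#' @param report A `validation_report`.
#' @param path Optional file to write to (UTF-8, `\n` line ending).
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  g <- generics::glance(report)
  issues <- purrr::pmap(report$issues, function(code, severity, file, row,
                                                column, message, schema_id) {
    list(
      code = code, severity = severity, file = file,
      row = if (is.na(row)) NULL else row,
      column = if (is.na(column)) NULL else column,
      message = message,
      schema_id = if (is.na(schema_id)) NULL else schema_id
    )
  })
  doc <- list(
    report_version = "1.0",
    files_checked = as.list(report$files_checked),
    schemas_applied = as.list(report$schemas_applied),
    summary = list(
      n_issues = g$n_issues, n_error = g$n_error,
      n_warning = g$n_warning, n_info = g$n_info, pass = g$pass
    ),
    issues = issues
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA)
  json <- as.character(json)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(json))
  }
  json
}

#' Render a validation report as human-readable text lines
#'
#' @param report A `validation_report`.
#' @return Character vector of lines (same issue set as the JSON form).
#' @export
report_to_text <- function(report) {
  g <- generics::glance(report)
  head_line <- sprintf(
    "%s: %d error(s), %d warning(s), %d info",
    if (g$pass) "PASS" else "FAIL", g$n_error, g$n_warning, g$n_info
  )
  if (nrow(report$issues) == 0) return(c(head_line, "  no issues"))
  lines <- purrr::pmap_chr(report$issues, function(code, severity, file, row,
                                                   column, message, schema_id) {
    loc <- file
    if (!is.na(row)) loc <- paste0(loc, ":", row)
    if (!is.na(column)) loc <- paste0(loc, " [", column, "]")
    sprintf("  %-7s %-22s %s  %s", severity, code, loc, message)
  })
  c(head_line, lines)
}
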