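#' Catalogue of validation issue codes
#'
#' Every finding a validator can emit carries a stable code from this
#' catalogue. Codes are namespaced by the layer that raises them: bare codes
#' come from the generic table engine and bundle cross-checks, `AMP-`,
#' `GAS-`, `CHEM-`, `HYD-`, `MODEL-` and `META-` prefixes mark
#' format-specific rules. The `mutable` flag marks codes for which the
#' fixture module ships a violation generator (see [mutate_bundle()]).
#'
#' @return A tibble with columns `code`, `severity`, `mutable`,
#'   `description`.
#' @export
#' @examples
#' issue_catalogue()
issue_catalogue <- function() {
  tribble_args <- list(
    # code, severity, mutable, description
    c("REQ-MISSING",          "error",   TRUE,  "A required field/column is absent"),
    c("DUP-COLUMN",           "error",   TRUE,  "Duplicate column name in header"),
    c("HDR-FUZZY",            "warning", TRUE,  "Column matches a schema field only case/whitespace-insensitively"),
    c("COL-UNKNOWN",          "info",    TRUE,  "Column not declared by the schema (extra context is allowed)"),
    c("TYPE-MISMATCH",        "error",   TRUE,  "Cell value does not parse as the declared type"),
    c("MIXED-TYPE",           "error",   TRUE,  "Column mixes incompatible scalar types"),
    c("MISSING-CODE",         "warning", TRUE,  "Empty/text missing marker in a numeric column; use -9999"),
    c("DATE-FORMAT",          "error",   TRUE,  "Date not in zero-padded YYYY-MM-DD form"),
    c("DATE-CALENDAR",        "error",   TRUE,  "Date is well-formed but not a real calendar date"),
    c("DATE-MISSING-CODE",    "warning", TRUE,  "-9999 used as missing marker in a date column"),
    c("DATETIME-FORMAT",      "error",   TRUE,  "Timestamp is not ISO 8601"),
    c("DATETIME-NAIVE",       "warning", TRUE,  "Timestamp has a time of day but no UTC offset"),
    c("COORD-BOUNDS",         "error",   TRUE,  "Latitude/longitude outside closed bounds (+-90 / +-180)"),
    c("BOUNDS",               "error",   TRUE,  "Numeric value outside the bounds declared by the schema"),
    c("VOCAB",                "error",   TRUE,  "Value not in the field's closed controlled vocabulary"),
    c("VOCAB-NOVEL",          "warning", TRUE,  "Value not in the field's open vocabulary (accepted, collected)"),
    c("PATTERN",              "error",   TRUE,  "Value does not match the field's declared pattern"),
    c("LEN-SHORT",            "warning", TRUE,  "Free-text metadata field shorter than the recommended minimum"),
    c("META-TEMPORAL-ORDER",  "error",   TRUE,  "Temporal coverage start is after its end"),
    c("META-PARSE",           "error",   FALSE, "Dataset metadata document could not be parsed"),
    c("DUP-FILE",             "error",   TRUE,  "Duplicate file_name rows in file-level metadata"),
    c("FILE-MISSING",         "error",   TRUE,  "File-level metadata names a file absent from the bundle"),
    c("FILE-UNDESCRIBED",     "warning", TRUE,  "Bundle file not described in file-level metadata"),
    c("REF-UNRESOLVED",       "error",   TRUE,  "Sample/location identifier not defined in its registry table"),
    c("IGSN-SYNTAX",          "error",   TRUE,  "Identifier does not follow IGSN syntax"),
    c("IGSN-CASE",            "warning", TRUE,  "IGSN valid after case normalization"),
    c("AMP-NEG-COUNT",        "error",   TRUE,  "Negative count in an amplicon abundance column"),
    c("AMP-COUNT-TYPE",       "error",   TRUE,  "Non-integer value in an amplicon abundance column"),
    c("AMP-DUP-FEATURE",      "error",   TRUE,  "Duplicated feature_id in an amplicon table"),
    c("AMP-SEQ-IUPAC",        "warning", TRUE,  "Representative sequence uses IUPAC ambiguity codes beyond ACGTN"),
    c("AMP-META-BLOCK",       "error",   FALSE, "Sequencing or processing metadata block missing"),
    c("GAS-INSTRUMENT-UNKNOWN","error",  TRUE,  "Instrument token not present in the translation table"),
    c("CHEM-BDL-EMBEDDED",    "error",   TRUE,  "'<x' below-detection string embedded in a numeric value cell"),
    c("CHEM-BDL-LIMIT-MISSING","warning",FALSE, "Below-detection row without a reported detection limit"),
    c("HYD-TIME-ORDER",       "warning", TRUE,  "Non-monotonic timestamps within a monitoring site"),
    c("HYD-TIME-DUP",         "error",   TRUE,  "Duplicated timestamp within a monitoring site"),
    c("MODEL-ITEM-ABSENT",    "warning", TRUE,  "Model-archiving checklist item marked absent")
  )
  m <- do.call(rbind, tribble_args)
  tibble::tibble(
    code = m[, 1],
    severity = m[, 2],
    mutable = as.logical(m[, 3]),
    description = m[, 4]
  )
}

#' Issue codes with a violation generator
#'
#' @return Character vector of codes accepted by [mutate_bundle()].
#' @export
mutable_issue_codes <- function() {
  cat <- issue_catalogue()
  cat$code[cat$mutable]
}

# Severity for a catalogue code (internal).
issue_severity <- function(code) {
  cat <- issue_catalogue()
  sev <- cat$severity[match(code, cat$code)]
  if (anyNA(sev)) {
    stop("unknown issue code(s): ", paste(code[is.na(sev)], collapse = ", "))
  }
  sev
}

# Construct a block of issues as a tibble. `row` counts the header line of
# the source file as row 1 (what a spreadsheet user sees); NA means the
# issue locates a whole column or file.
new_issues <- function(code, file, row = NA_integer_, column = NA_character_,
                       message = "", schema_id = NA_character_) {
  if (length(code) == 0) return(empty_issues())
  tibble::tibble(
    code = code,
    severity = issue_severity(code),
    file = file,
    row = as.integer(row),
    column = as.character(column),
    message = message,
    schema_id = schema_id
  )
}

empty_issues <- function() {
  tibble::tibble(
    code = character(), severity = character(), file = character(),
    row = integer(), column = character(), message = character(),
    schema_id = character()
  )
}
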