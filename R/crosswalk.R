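# Term crosswalks: tabular mappings from (external standard, term) to a
# harmonized reporting-format term, with optional affine unit conversion.
# The packaged crosswalks are synthetic curations shipped as data (see
# the package vignette); the mechanism is independent of their content.

#' Load a crosswalk table from CSV
#'
#' Expects the documented layout: `source_standard`, `source_term`,
#' `target_term`, `unit_factor`, `unit_offset`, `notes`. Duplicate
#' `(source_standard, source_term)` pairs are load errors. When the
#' target schema is known, target terms absent from its field list are
#' reported as orphans in a load warning (the table still loads).
#' Identity rows (`source_term == target_term`) must not declare a unit
#' conversion, so translation is idempotent.
#'
#' @param path Crosswalk CSV.
#' @param target_format Target schema id; inferred from the file name when
#'   omitted.
#' @param registry Registry used for the orphan check; `NULL` skips it.
#' @return A `crosswalk_table`: list with `target_format` and `entries`
#'   (tibble).
#' @export
load_crosswalk <- function(path, target_format = NULL,
                           registry = load_registry()) {
  doc <- parse_csv(path)
  need <- c("source_standard", "source_term", "target_term")
  if (!all(need %in% doc$header)) {
    stop("malformed crosswalk '", doc$source_name, "': must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  d <- doc$data
  entries <- tibble::tibble(
    source_standard = d$source_standard,
    source_term = d$source_term,
    target_term = d$target_term,
    unit_factor = if ("unit_factor" %in% names(d)) {
      suppressWarnings(as.numeric(d$unit_factor))
    } else NA_real_,
    unit_offset = if ("unit_offset" %in% names(d)) {
      suppressWarnings(as.numeric(d$unit_offset))
    } else NA_real_,
    notes = if ("notes" %in% names(d)) d$notes else ""
  )
  key <- paste(entries$source_standard, entries$source_term, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- entries[duplicated(key), , drop = FALSE]
    stop("duplicate (source_standard, source_term) pair(s) in '",
         doc$source_name, "': ",
         paste(dup$source_standard, dup$source_term, sep = ":", collapse = ", "),
         call. = FALSE)
  }
  identity_rows <- entries$source_term == entries$target_term
  bad_identity <- identity_rows &
    ((!is.na(entries$unit_factor) & entries$unit_factor != 1) |
       (!is.na(entries$unit_offset) & entries$unit_offset != 0))
  if (any(bad_identity)) {
    stop("identity row(s) with a non-trivial unit conversion in '",
         doc$source_name, "'", call. = FALSE)
  }
  if (is.null(target_format)) {
    base <- tools::file_path_sans_ext(basename(path))
    base <- sub("_synthetic$", "", base)
    base <- sub("_instruments$", "", base)
    target_format <- base
  }
  if (!is.null(registry) && target_format %in% names(registry$schemas)) {
    fields <- purrr::map_chr(get_schema(registry, target_format)$fields, "name")
    orphans <- setdiff(unique(entries$target_term), fields)
    if (length(orphans)) {
      warning("crosswalk target term(s) not in schema '", target_format,
              "': ", paste(orphans, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(target_format = target_format, entries = entries),
            class = "crosswalk_table")
}

#' Packaged crosswalk for a reporting format
#'
#' @param format_id Schema id with a packaged crosswalk
#'   (`hydrologic_monitoring` or `water_soil_chemistry`).
#' @return A `crosswalk_table`.
#' @export
default_crosswalk <- function(format_id) {
  path <- system.file("extdata", "crosswalks",
                      paste0(format_id, "_synthetic.csv"),
                      package = "reportfmt")
  if (!nzchar(path)) {
    stop("no packaged crosswalk for format '", format_id, "'", call. = FALSE)
  }
  load_crosswalk(path, target_format = format_id)
}

#' Packaged instrument translation table for leaf-level gas exchange
#'
#' Maps the standard output column names of ten commonly used gas-exchange
#' instruments onto the harmonized variable names, with unit conversion
#' factors where the instrument reports different units.
#'
#' @return A `crosswalk_table` with `source_standard` holding instrument
#'   tokens.
#' @export
default_instrument_table <- function() {
  path <- system.file("extdata", "crosswalks",
                      "leaf_gas_exchange_instruments_synthetic.csv",
                      package = "reportfmt", mustWork = TRUE)
  load_crosswalk(path, target_format = "leaf_gas_exchange")
}

#' @export
print.crosswalk_table <- function(x, ...) {
  cat(sprintf("<crosswalk_table> -> %s: %d entr%s from %d standard(s)\n",
              x$target_format, nrow(x$entries),
              if (nrow(x$entries) == 1) "y" else "ies",
              dplyr::n_distinct(x$entries$source_standard)))
  invisible(x)
}

#' Tidy a crosswalk table into its entries
#'
#' @param x A `crosswalk_table`.
#' @param ... Unused.
#' @export
tidy.crosswalk_table <- function(x, ...) x$entries

#' Map one external term to its harmonized equivalent
#'
#' Exact, case-sensitive match on `(source_standard, term)` (optionally
#' case-insensitive). Not-found is a value (`NA`), not an error; an
#' unknown source standard is an error listing the standards in the
#' table.
#'
#' @param table A `crosswalk_table`.
#' @param source_standard Standard token as it appears in the table.
#' @param term Term to translate.
#' @param case_insensitive Fall back to case-insensitive matching.
#' @return The harmonized term, or `NA_character_` when not found.
#' @export
#' @examples
#' cw <- default_crosswalk("hydrologic_monitoring")
#' map_term(cw, "wqx", "ValueDateTime")
map_term <- function(table, source_standard, term, case_insensitive = FALSE) {
  stopifnot(inherits(table, "crosswalk_table"))
  known <- unique(table$entries$source_standard)
  if (!source_standard %in% known) {
    stop("unknown source standard '", source_standard, "'; standards in table: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  e <- table$entries[table$entries$source_standard == source_standard, ]
  hit <- match(term, e$source_term)
  if (is.na(hit) && case_insensitive) {
    hit <- match(tolower(term), tolower(e$source_term))
  }
  if (is.na(hit)) NA_character_ else e$target_term[hit]
}

#' Translate foreign column headers onto the harmonized vocabulary
#'
#' Renames every column with a crosswalk entry for `source_standard` to
#' its harmonized term and applies declared affine unit conversions
#' (`value * factor + offset`) to the renamed columns' numeric cells.
#' Unmapped columns are untouched and listed. When two source columns map
#' to one target the translation is refused (no rename applied). The
#' translated document is re-validated under the target schema when it is
#' in the registry. Translation is idempotent: applying the same
#' crosswalk twice equals applying it once.
#'
#' @param doc A `table_document`.
#' @param table A `crosswalk_table`.
#' @param source_standard Standard the document's headers come from.
#' @param registry Registry used for re-validation; `NULL` to skip.
#' @param case_insensitive Match headers case-insensitively.
#' @return A `translation_result`: list with `document` (translated),
#'   `mapping` (tibble source/target/factor/offset), `unmapped`
#'   (character), `report` (revalidation [validation_report()] or `NULL`).
#' @export
translate_headers <- function(doc, table, source_standard,
                              registry = load_registry(),
                              case_insensitive = FALSE) {
  stopifnot(inherits(doc, "table_document"), inherits(table, "crosswalk_table"))
  e <- table$entries[table$entries$source_standard == source_standard, ]
  if (nrow(table$entries) > 0 && nrow(e) == 0 &&
      !source_standard %in% table$entries$source_standard) {
    # still allow translating with a standard absent from a non-empty
    # table only if the caller asks for an identity transform? No:
    # consistent with map_term, unknown standards are errors.
    stop("unknown source standard '", source_standard, "'; standards in table: ",
         paste(unique(table$entries$source_standard), collapse = ", "),
         call. = FALSE)
  }
  match_src <- if (case_insensitive) {
    match(tolower(doc$header), tolower(e$source_term))
  } else {
    match(doc$header, e$source_term)
  }
  mapped <- !is.na(match_src)
  targets <- doc$header
  targets[mapped] <- e$target_term[match_src[mapped]]
  if (anyDuplicated(targets[mapped]) ||
      any(targets[mapped] %in% doc$header[!mapped])) {
    collided <- unique(targets[mapped][duplicated(targets[mapped]) |
                                         targets[mapped] %in% doc$header[!mapped]])
    stop("header collision after mapping: multiple columns would be named ",
         paste(collided, collapse = ", "), "; no rename applied",
         call. = FALSE)
  }
  out <- doc
  out$header <- targets
  names(out$data) <- targets
  mapping <- tibble::tibble(
    source = doc$header[mapped],
    target = targets[mapped],
    unit_factor = e$unit_factor[match_src[mapped]],
    unit_offset = e$unit_offset[match_src[mapped]]
  )
  for (k in seq_len(nrow(mapping))) {
    fac <- mapping$unit_factor[k]
    off <- mapping$unit_offset[k]
    if (is.na(fac) && is.na(off)) next
    fac <- if (is.na(fac)) 1 else fac
    off <- if (is.na(off)) 0 else off
    j <- match(mapping$target[k], out$header)
    cells <- out$data[[j]]
    keep <- !(cells %in% default_missing_codes()) & grepl(NUM_PATTERN, cells)
    vals <- as.numeric(cells[keep]) * fac + off
    cells[keep] <- as.character(vals)
    out$data[[j]] <- cells
  }
  report <- NULL
  if (!is.null(registry) && table$target_format %in% names(registry$schemas)) {
    schema <- get_schema(registry, table$target_format)
    report <- if (table$target_format %in% DOMAIN_SPECIFIC_IDS) {
      validate_domain_table(out, table$target_format, registry)
    } else {
      validate_table(out, schema)
    }
  }
  structure(
    list(document = out, mapping = mapping,
         unmapped = doc$header[!mapped], report = report),
    class = "translation_result"
  )
}

#' @export
print.translation_result <- function(x, ...) {
  cat(sprintf("<translation_result> %d column(s) renamed, %d unmapped\n",
              nrow(x$mapping), length(x$unmapped)))
  if (nrow(x$mapping)) print(x$mapping)
  if (length(x$unmapped)) {
    cat("unmapped:", paste(x$unmapped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Translate raw instrument output onto the harmonized gas-exchange terms
#'
#' Renames an instrument's standard output columns to the harmonized
#' leaf-level gas-exchange variable names and converts units where the
#' translation table declares a factor. Columns the table does not know
#' are preserved verbatim and listed as unmapped. Already-harmonized
#' input comes back unchanged (idempotence).
#'
#' @param doc A `table_document` of instrument output.
#' @param instrument Instrument token (see [default_instrument_table()]).
#' @param table Instrument translation table; defaults to the packaged one.
#' @param registry Registry for re-validation.
#' @return A `translation_result`.
#' @export
translate_instrument_output <- function(doc, instrument,
                                        table = default_instrument_table(),
                                        registry = load_registry()) {
  known <- unique(table$entries$source_standard)
  if (!instrument %in% known) {
    stop("unknown instrument '", instrument, "'; known instruments: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  translate_headers(doc, table, instrument, registry = registry)
}
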