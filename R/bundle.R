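# File-level metadata (FLMD), IGSN checks, the model-archiving checklist,
# bundle role assignment and whole-bundle validation with cross-file
# consistency checks.

#' Parse a validated file-level metadata table into records
#'
#' The FLMD table is itself a CSV validated against its own schema before
#' interpretation. On schema errors no records are returned; duplicated
#' `file_name` rows are `DUP-FILE` errors. The resulting records carry the
#' per-file missing-value codes that feed column profiling of the
#' described files.
#'
#' @param doc A `table_document` holding the FLMD table.
#' @param registry A schema registry.
#' @return A tibble of records (`file_name`, `file_description`,
#'   `file_format`, `column_or_row_name_position`, `missing_value_codes`
#'   (list column), `notes`) with the validation report in
#'   `attr(, "report")`; zero rows if the table fails its schema.
#' @export
parse_flmd <- function(doc, registry = load_registry()) {
  schema <- get_schema(registry, "file_level_metadata")
  rep <- validate_table(doc, schema)
  empty <- tibble::tibble(
    file_name = character(), file_description = character(),
    file_format = character(), column_or_row_name_position = integer(),
    missing_value_codes = list(), notes = character()
  )
  if (generics::glance(rep)$n_error > 0) {
    return(structure(empty, report = rep))
  }
  d <- doc$data
  col <- function(name) {
    if (name %in% names(d)) d[[name]] else rep("", nrow(d))
  }
  records <- tibble::tibble(
    file_name = col("file_name"),
    file_description = col("file_description"),
    file_format = col("file_format"),
    column_or_row_name_position = suppressWarnings(
      as.integer(col("column_or_row_name_position"))
    ),
    missing_value_codes = purrr::map(col("missing_value_codes"), function(x) {
      out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
      out[nzchar(out)]
    }),
    notes = col("notes")
  )
  dup <- which(duplicated(records$file_name))
  if (length(dup)) {
    rep <- combine_reports(rep, validation_report(
      new_issues(rep("DUP-FILE", length(dup)), doc$source_name,
                 row = dup + 1L, column = "file_name",
                 message = sprintf("file '%s' described more than once",
                                   records$file_name[dup]),
                 schema_id = schema$id),
      files_checked = doc$source_name, schemas_applied = schema$id
    ))
  }
  structure(records, report = rep)
}

IGSN_BODY <- "^[A-Z]{2,5}[0-9A-Z]{4,}$"

#' Syntactic IGSN check
#'
#' Checks International Generic Sample Number syntax only (no network
#' resolution): an optional `IGSN:` scheme prefix, a 2-5 letter namespace,
#' then at least four alphanumerics. Matching is case-insensitive; inputs
#' valid only after case normalization are flagged so a warning can be
#' raised.
#'
#' @param x Character vector of identifiers.
#' @return Tibble with `input`, `valid`, `case_normalized`, `reason`
#'   (`empty` or `bad_syntax` on failure), `normalized` (upper-case form,
#'   `NA` on failure).
#' @export
#' @examples
#' validate_igsn(c("IGSN:IEXYZ0001", "igsn:iexyz0001", ""))
validate_igsn <- function(x) {
  x <- as.character(x)
  upper <- toupper(x)
  body <- sub("^IGSN:", "", upper)
  valid <- nzchar(x) & grepl(IGSN_BODY, body)
  tibble::tibble(
    input = x,
    valid = valid,
    case_normalized = valid & x != upper,
    reason = dplyr::case_when(
      valid ~ NA_character_,
      !nzchar(x) ~ "empty",
      .default = "bad_syntax"
    ),
    normalized = ifelse(valid, upper, NA_character_)
  )
}

#' Read a model-archiving checklist table
#'
#' @param path CSV with columns `item`, `status`, `evidence`.
#' @return Tibble of checklist rows.
#' @export
read_model_checklist <- function(path) {
  doc <- parse_csv(path)
  stopifnot(all(c("item", "status") %in% doc$header))
  tibble::tibble(
    item = doc$data$item,
    status = doc$data$status,
    evidence = if ("evidence" %in% doc$header) doc$data$evidence else ""
  )
}

#' Evaluate a model-archiving checklist (advisory only)
#'
#' The archiving guidelines are decision guidance, not a data dictionary:
#' evaluation never raises errors and never changes a bundle's pass/fail
#' status. Items marked `absent` get a warning with guidance; unknown
#' items or unrecognized statuses are also warnings; `not_applicable`
#' items produce nothing.
#'
#' @param checklist Tibble from [read_model_checklist()].
#' @param file File name used in issue locations.
#' @param registry A schema registry.
#' @return A [validation_report()] containing warnings/info only.
#' @export
evaluate_model_checklist <- function(checklist, file = "model_archiving.csv",
                                     registry = load_registry()) {
  schema <- get_schema(registry, "model_archiving")
  known <- purrr::map_chr(schema$fields, "name")
  issues <- list()
  for (i in seq_len(nrow(checklist))) {
    item <- checklist$item[i]
    status <- checklist$status[i]
    guidance <- if (item %in% known) {
      schema$fields[[match(item, known)]]$description
    } else {
      "item not part of the archiving checklist"
    }
    if (!item %in% known || !status %in% c("present", "absent", "not_applicable")) {
      issues[[length(issues) + 1]] <- new_issues(
        "MODEL-ITEM-ABSENT", file, row = i + 1L, column = "item",
        message = sprintf("unrecognized checklist entry '%s' (status '%s')",
                          item, status),
        schema_id = schema$id
      )
    } else if (status == "absent") {
      issues[[length(issues) + 1]] <- new_issues(
        "MODEL-ITEM-ABSENT", file, row = i + 1L, column = "item",
        message = sprintf("'%s' not archived: %s", item, guidance),
        schema_id = schema$id
      )
    }
  }
  missing_items <- setdiff(known, checklist$item)
  if (length(missing_items)) {
    issues[[length(issues) + 1]] <- new_issues(
      rep("MODEL-ITEM-ABSENT", length(missing_items)), file, row = 1L,
      column = missing_items,
      message = sprintf("checklist does not mention '%s'", missing_items),
      schema_id = schema$id
    )
  }
  validation_report(dplyr::bind_rows(issues), files_checked = file,
                    schemas_applied = schema$id)
}

# file -> schema assignment for a bundle directory. A manifest.json (as
# written by generate_bundle) is authoritative; otherwise roles are
# inferred from conventional file names (<format_id>.csv etc.).
#' Read a dataset bundle directory and assign file roles
#'
#' @param dir Bundle directory.
#' @param registry A schema registry.
#' @return A `dataset_bundle`: list with `dir` and `files`
#'   (tibble `file`, `format`).
#' @export
read_bundle <- function(dir, registry = load_registry()) {
  stopifnot(dir.exists(dir))
  on_disk <- sort(setdiff(list.files(dir), "manifest.json"))
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path)) {
    m <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
    files <- purrr::map_dfr(m$files, function(f) {
      tibble::tibble(file = f$file, format = f$format %||% NA_character_)
    })
    extra <- setdiff(on_disk, files$file)
    files <- dplyr::bind_rows(
      files, tibble::tibble(file = extra,
                            format = rep(NA_character_, length(extra)))
    )
  } else {
    known <- names(registry$schemas)
    files <- tibble::tibble(
      file = on_disk,
      format = dplyr::case_when(
        grepl("^dataset_metadata\\.(json|csv)$", on_disk) ~ "dataset_metadata",
        on_disk %in% c("flmd.csv", "file_level_metadata.csv") ~ "file_level_metadata",
        on_disk == "amplicon_metadata.csv" ~ "amplicon_metadata",
        tools::file_path_sans_ext(on_disk) %in% known ~
          tools::file_path_sans_ext(on_disk),
        .default = NA_character_
      )
    )
  }
  structure(list(dir = dir, files = files), class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("<dataset_bundle>", x$dir, "\n")
  print(x$files)
  invisible(x)
}

# Reference columns scanned for cross-file resolution: declared explicitly
# per schema so the scan never guesses from arbitrary column names.
REFERENCE_DECLS <- function() {
  tibble::tibble(
    format = c("water_soil_chemistry", "hydrologic_monitoring", "sample_metadata"),
    column = c("sample_id", "site_id", "parent_sample"),
    registry_format = c("sample_metadata", "location_metadata", "sample_metadata"),
    registry_column = c("sample_id", "location_id", "sample_id")
  )
}

#' Cross-file consistency checks on a dataset bundle
#'
#' Checks that the file-level metadata and the files on disk agree (the
#' symmetric difference of the two sets maps one-to-one onto
#' `FILE-MISSING` errors and `FILE-UNDESCRIBED` warnings), that sample and
#' location identifiers referenced from data tables resolve in their
#' registry tables, and that IGSN-formatted sample identifiers are
#' syntactically valid.
#'
#' @param bundle A `dataset_bundle` from [read_bundle()].
#' @param registry A schema registry.
#' @return A [validation_report()].
#' @export
crosscheck_bundle <- function(bundle, registry = load_registry()) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  dir <- bundle$dir
  issues <- list()
  on_disk <- sort(setdiff(list.files(dir), "manifest.json"))

  flmd_file <- bundle$files$file[bundle$files$format %in% "file_level_metadata"]
  records <- NULL
  if (length(flmd_file) == 1 && file.exists(file.path(dir, flmd_file))) {
    doc <- parse_csv(file.path(dir, flmd_file))
    records <- parse_flmd(doc, registry)
    flmd_usable <- !(nrow(records) == 0 &&
                       generics::glance(attr(records, "report"))$n_error > 0)
  }
  if (!is.null(records) && flmd_usable) {
    listed <- unique(records$file_name)
    absent <- setdiff(listed, on_disk)
    for (f in absent) {
      row <- which(records$file_name == f)[1] + 1L
      issues[[length(issues) + 1]] <- new_issues(
        "FILE-MISSING", flmd_file, row = row, column = "file_name",
        message = sprintf("file '%s' is described but absent from the bundle", f),
        schema_id = "file_level_metadata"
      )
    }
    undescribed <- setdiff(on_disk, listed)
    issues[[length(issues) + 1]] <- new_issues(
      rep("FILE-UNDESCRIBED", length(undescribed)), flmd_file,
      row = NA_integer_, column = undescribed,
      message = sprintf("bundle file '%s' is not described in the file-level metadata",
                        undescribed),
      schema_id = "file_level_metadata"
    )
  }

  # identifier registries present in the bundle
  get_column <- function(format, column) {
    f <- bundle$files$file[bundle$files$format %in% format]
    if (length(f) != 1 || !file.exists(file.path(dir, f))) return(NULL)
    doc <- parse_csv(file.path(dir, f))
    if (!column %in% doc$header) return(NULL)
    list(file = f, values = doc$data[[column]])
  }

  decls <- REFERENCE_DECLS()
  for (i in seq_len(nrow(decls))) {
    reg_col <- get_column(decls$registry_format[i], decls$registry_column[i])
    ref_col <- get_column(decls$format[i], decls$column[i])
    if (is.null(reg_col) || is.null(ref_col)) next
    refs <- ref_col$values
    bad <- which(!(refs %in% c(reg_col$values, "")) &
                   !(refs %in% default_missing_codes()))
    issues[[length(issues) + 1]] <- new_issues(
      rep("REF-UNRESOLVED", length(bad)), ref_col$file, row = bad + 1L,
      column = decls$column[i],
      message = sprintf("'%s' not defined in %s (%s)", refs[bad],
                        decls$registry_format[i], decls$registry_column[i]),
      schema_id = decls$format[i]
    )
  }

  # IGSN syntax on sample identifiers that claim the IGSN scheme
  samples <- get_column("sample_metadata", "sample_id")
  if (!is.null(samples)) {
    claim <- grepl("^igsn:", samples$values, ignore.case = TRUE)
    chk <- validate_igsn(samples$values)
    bad <- which(claim & !chk$valid)
    issues[[length(issues) + 1]] <- new_issues(
      rep("IGSN-SYNTAX", length(bad)), samples$file, row = bad + 1L,
      column = "sample_id",
      message = sprintf("'%s' is not a valid IGSN (%s)",
                        samples$values[bad], chk$reason[bad]),
      schema_id = "sample_metadata"
    )
    warn <- which(claim & chk$case_normalized)
    issues[[length(issues) + 1]] <- new_issues(
      rep("IGSN-CASE", length(warn)), samples$file, row = warn + 1L,
      column = "sample_id",
      message = sprintf("'%s' valid after case normalization to '%s'",
                        samples$values[warn], chk$normalized[warn]),
      schema_id = "sample_metadata"
    )
  }

  validation_report(dplyr::bind_rows(issues),
                    files_checked = bundle$files$file,
                    schemas_applied = character())
}

#' Validate a whole dataset bundle
#'
#' Runs every applicable validator over a bundle directory: dataset
#' metadata checks, the file-level metadata's own schema, each data table
#' under its assigned reporting format (with the per-file missing-value
#' codes declared in the file-level metadata feeding column profiling),
#' the advisory model-archiving checklist, amplicon companion metadata,
#' and the cross-file consistency checks of [crosscheck_bundle()].
#'
#' @param x Bundle directory path or a `dataset_bundle`.
#' @param registry A schema registry.
#' @return A combined [validation_report()].
#' @export
validate_bundle <- function(x, registry = load_registry()) {
  bundle <- if (inherits(x, "dataset_bundle")) x else read_bundle(x, registry)
  dir <- bundle$dir
  reports <- list()
  files <- bundle$files

  md_file <- files$file[files$format %in% "dataset_metadata"]
  if (length(md_file) == 1) {
    md <- tryCatch(read_dataset_metadata(file.path(dir, md_file)),
                   error = function(e) e)
    if (inherits(md, "error")) {
      reports[[length(reports) + 1]] <- validation_report(
        new_issues("META-PARSE", md_file,
                   message = conditionMessage(md),
                   schema_id = "dataset_metadata"),
        files_checked = md_file, schemas_applied = "dataset_metadata"
      )
    } else {
      reports[[length(reports) + 1]] <- validate_dataset_metadata(md, md_file)
    }
  }

  flmd_file <- files$file[files$format %in% "file_level_metadata"]
  missing_codes_for <- function(file) character()
  if (length(flmd_file) == 1 && file.exists(file.path(dir, flmd_file))) {
    doc <- parse_csv(file.path(dir, flmd_file))
    records <- parse_flmd(doc, registry)
    reports[[length(reports) + 1]] <- attr(records, "report")
    missing_codes_for <- function(file) {
      hit <- match(file, records$file_name)
      if (is.na(hit)) character() else records$missing_value_codes[[hit]]
    }
  }

  # amplicon companion metadata (and optional FASTA-referenced sequences)
  amp_meta <- NULL
  amp_meta_file <- files$file[files$format %in% "amplicon_metadata"]
  if (length(amp_meta_file) == 1 && file.exists(file.path(dir, amp_meta_file))) {
    amp_meta <- parse_csv(file.path(dir, amp_meta_file))
    reports[[length(reports) + 1]] <- check_amplicon_metadata(amp_meta)
  }

  tabular_formats <- c("csv_guidelines", "sample_metadata", "location_metadata",
                       DOMAIN_SPECIFIC_IDS)
  for (i in seq_len(nrow(files))) {
    fmt <- files$format[i]
    fname <- files$file[i]
    if (is.na(fmt) || !fmt %in% tabular_formats) next
    path <- file.path(dir, fname)
    if (!file.exists(path)) next  # crosscheck reports FILE-MISSING
    doc <- parse_csv(path)
    codes <- missing_codes_for(fname)
    if (fmt %in% DOMAIN_SPECIFIC_IDS) {
      sequences <- NULL
      if (fmt == "amplicon_abundance" && !is.null(amp_meta)) {
        sequences <- amplicon_fasta_sequences(amp_meta, dir)
      }
      reports[[length(reports) + 1]] <- validate_domain_table(
        doc, fmt, registry, missing_codes = codes, sequences = sequences
      )
    } else {
      reports[[length(reports) + 1]] <- validate_table(
        doc, get_schema(registry, fmt), missing_codes = codes
      )
    }
  }

  mc_file <- files$file[files$format %in% "model_archiving"]
  if (length(mc_file) == 1 && file.exists(file.path(dir, mc_file))) {
    reports[[length(reports) + 1]] <- evaluate_model_checklist(
      read_model_checklist(file.path(dir, mc_file)), mc_file, registry
    )
  }

  reports[[length(reports) + 1]] <- crosscheck_bundle(bundle, registry)
  do.call(combine_reports, reports)
}
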