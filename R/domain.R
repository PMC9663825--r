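# Format-specific rules layered on top of the generic table engine for
# the five domain formats. Issue codes are namespaced by format (AMP-,
# GAS-, CHEM-, HYD-).

IUPAC_EXTRA <- "URYSWKMBDHV"  # tolerated beyond the strict ACGTN alphabet

#' Validate a table under a domain-specific reporting format
#'
#' Runs the generic schema validation ([validate_table()]) under the
#' domain schema, then the format's own invariants: amplicon count
#' columns (non-negative integers, unique feature ids, sequence
#' alphabet), gas-exchange instrument resolution, water/soil-chemistry
#' below-detection conventions and IGSN syntax, and hydrologic timestamp
#' ordering per site. Every issue the base CSV rules would raise is also
#' raised here (domain validation is a superset).
#'
#' @param doc A `table_document`.
#' @param format_id One of the five domain schema ids.
#' @param registry A schema registry.
#' @param missing_codes Extra missing codes for this file.
#' @param sequences Optional named character vector of representative
#'   sequences read from a FASTA file (names are feature ids); used when
#'   an amplicon table references its sequences externally instead of
#'   carrying a `representative_sequence` column.
#' @param instruments Instrument translation table (a `crosswalk_table`);
#'   defaults to the packaged one.
#' @return A [validation_report()].
#' @export
validate_domain_table <- function(doc, format_id, registry = load_registry(),
                                  missing_codes = NULL, sequences = NULL,
                                  instruments = NULL) {
  if (!format_id %in% DOMAIN_SPECIFIC_IDS) {
    stop("unknown domain format '", format_id, "'; valid ids: ",
         paste(DOMAIN_SPECIFIC_IDS, collapse = ", "), call. = FALSE)
  }
  schema <- get_schema(registry, format_id)
  base <- validate_table(doc, schema, missing_codes = missing_codes)
  codes <- union(default_missing_codes(), missing_codes %||% character())
  extra <- switch(
    format_id,
    amplicon_abundance = check_amplicon(doc, schema, codes, sequences),
    leaf_gas_exchange = check_gas_exchange(doc, schema, codes, instruments),
    soil_respiration = empty_issues(),
    water_soil_chemistry = check_water_chem(doc, schema, codes),
    hydrologic_monitoring = check_hydro(doc, schema, codes)
  )
  if (format_id == "amplicon_abundance" && !is.null(sequences) &&
      !"representative_sequence" %in% doc$header) {
    # sequences supplied externally: the column is legitimately absent
    base$issues <- base$issues[!(base$issues$code == "REQ-MISSING" &
                                   base$issues$column == "representative_sequence"), ]
  }
  combine_reports(base, validation_report(extra, files_checked = doc$source_name,
                                          schemas_applied = format_id))
}

check_amplicon <- function(doc, schema, codes, sequences = NULL) {
  file <- doc$source_name
  issues <- list()
  declared <- purrr::map_chr(schema$fields, "name")
  count_cols <- which(!normalize_header(doc$header) %in% normalize_header(declared))
  for (j in count_cols) {
    cells <- doc$data[[j]]
    keep <- !(cells %in% codes)
    rows <- (seq_along(cells) + 1L)[keep]
    x <- cells[keep]
    non_int <- !grepl(INT_PATTERN, x)
    issues[[length(issues) + 1]] <- new_issues(
      rep("AMP-COUNT-TYPE", sum(non_int)), file, row = rows[non_int],
      column = doc$header[j],
      message = sprintf("count '%s' is not an integer", x[non_int]),
      schema_id = schema$id
    )
    neg <- !non_int & suppressWarnings(as.numeric(x)) < 0
    issues[[length(issues) + 1]] <- new_issues(
      rep("AMP-NEG-COUNT", sum(neg)), file, row = rows[neg],
      column = doc$header[j],
      message = sprintf("negative count '%s'", x[neg]),
      schema_id = schema$id
    )
  }
  if ("feature_id" %in% doc$header) {
    ids <- doc$data$feature_id
    dup <- which(duplicated(ids) & !(ids %in% codes))
    issues[[length(issues) + 1]] <- new_issues(
      rep("AMP-DUP-FEATURE", length(dup)), file, row = dup + 1L,
      column = "feature_id",
      message = sprintf("feature_id '%s' is duplicated", ids[dup]),
      schema_id = schema$id
    )
  }
  seqs <- NULL; seq_rows <- NULL; seq_col <- "representative_sequence"
  if ("representative_sequence" %in% doc$header) {
    cells <- doc$data$representative_sequence
    keep <- !(cells %in% codes)
    seqs <- cells[keep]
    seq_rows <- (seq_along(cells) + 1L)[keep]
  } else if (!is.null(sequences) && "feature_id" %in% doc$header) {
    hit <- match(doc$data$feature_id, names(sequences))
    missing <- which(is.na(hit))
    issues[[length(issues) + 1]] <- new_issues(
      rep("REF-UNRESOLVED", length(missing)), file, row = missing + 1L,
      column = "feature_id",
      message = sprintf("feature '%s' has no sequence in the referenced FASTA",
                        doc$data$feature_id[missing]),
      schema_id = schema$id
    )
    seqs <- sequences[hit[!is.na(hit)]]
    seq_rows <- which(!is.na(hit)) + 1L
    bad <- !grepl("^[ACGTURYSWKMBDHVN]+$", seqs)
    issues[[length(issues) + 1]] <- new_issues(
      rep("PATTERN", sum(bad)), file, row = seq_rows[bad], column = seq_col,
      message = "FASTA sequence contains characters outside the IUPAC alphabet",
      schema_id = schema$id
    )
  }
  if (length(seqs)) {
    iupac <- grepl(sprintf("[%s]", IUPAC_EXTRA), seqs) &
      grepl("^[ACGTURYSWKMBDHVN]+$", seqs)
    issues[[length(issues) + 1]] <- new_issues(
      rep("AMP-SEQ-IUPAC", sum(iupac)), file, row = seq_rows[iupac],
      column = seq_col,
      message = "sequence uses IUPAC ambiguity codes beyond ACGTN",
      schema_id = schema$id
    )
  }
  dplyr::bind_rows(issues)
}

check_gas_exchange <- function(doc, schema, codes, instruments = NULL) {
  if (!"instrument" %in% doc$header) return(empty_issues())
  if (is.null(instruments)) instruments <- default_instrument_table()
  known <- unique(instruments$entries$source_standard)
  cells <- doc$data$instrument
  bad <- which(!(cells %in% c(known, codes)))
  new_issues(
    rep("GAS-INSTRUMENT-UNKNOWN", length(bad)), doc$source_name,
    row = bad + 1L, column = "instrument",
    message = sprintf("instrument '%s' not in the translation table (known: %s)",
                      cells[bad], paste(known, collapse = ", ")),
    schema_id = schema$id
  )
}

check_water_chem <- function(doc, schema, codes) {
  file <- doc$source_name
  issues <- list()
  if ("value" %in% doc$header) {
    cells <- doc$data$value
    bdl <- which(grepl("^<\\s*", cells))
    issues[[length(issues) + 1]] <- new_issues(
      rep("CHEM-BDL-EMBEDDED", length(bdl)), file, row = bdl + 1L,
      column = "value",
      message = sprintf(paste0("'%s' embeds a below-detection marker in the value;",
                               " set below_detection=TRUE and report detection_limit"),
                        cells[bdl]),
      schema_id = schema$id
    )
  }
  if (all(c("below_detection", "detection_limit") %in% doc$header)) {
    flag <- doc$data$below_detection == "TRUE"
    nolimit <- which(flag & doc$data$detection_limit %in% codes)
    issues[[length(issues) + 1]] <- new_issues(
      rep("CHEM-BDL-LIMIT-MISSING", length(nolimit)), file,
      row = nolimit + 1L, column = "detection_limit",
      message = "below-detection row without a reported detection limit",
      schema_id = schema$id
    )
  }
  if ("igsn" %in% doc$header) {
    cells <- doc$data$igsn
    keep <- !(cells %in% codes)
    chk <- validate_igsn(cells)
    bad <- which(keep & !chk$valid)
    issues[[length(issues) + 1]] <- new_issues(
      rep("IGSN-SYNTAX", length(bad)), file, row = bad + 1L, column = "igsn",
      message = sprintf("'%s' is not a valid IGSN (%s)", cells[bad],
                        chk$reason[bad]),
      schema_id = schema$id
    )
    warn <- which(keep & chk$case_normalized)
    issues[[length(issues) + 1]] <- new_issues(
      rep("IGSN-CASE", length(warn)), file, row = warn + 1L, column = "igsn",
      message = sprintf("'%s' valid after case normalization to '%s'",
                        cells[warn], chk$normalized[warn]),
      schema_id = schema$id
    )
  }
  dplyr::bind_rows(issues)
}

# Parse ISO timestamps to epoch seconds for ordering checks; NA when the
# cell is invalid (format errors are reported elsewhere, not here).
iso_to_epoch <- function(x) {
  x <- sub(" ", "T", x, fixed = TRUE)
  date_only <- grepl(DATE_PATTERN, x)
  x[date_only] <- paste0(x[date_only], "T00:00:00")
  x <- sub("\\.\\d+", "", x)
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", x)
  has_offset <- grepl("[+-]\\d{4}$", x)
  x[!has_offset] <- paste0(x[!has_offset], "+0000")
  x <- sub("^(\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2})([+-]\\d{4})$", "\\1:00\\2", x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  as.numeric(out)
}

check_hydro <- function(doc, schema, codes) {
  if (!all(c("datetime", "site_id") %in% doc$header)) return(empty_issues())
  file <- doc$source_name
  epochs <- iso_to_epoch(doc$data$datetime)
  epochs[doc$data$datetime %in% codes] <- NA
  issues <- list()
  for (site in unique(doc$data$site_id)) {
    idx <- which(doc$data$site_id == site & !is.na(epochs))
    if (length(idx) < 2) next
    t <- epochs[idx]
    dup <- which(diff(t) == 0) + 1L
    issues[[length(issues) + 1]] <- new_issues(
      rep("HYD-TIME-DUP", length(dup)), file, row = idx[dup] + 1L,
      column = "datetime",
      message = sprintf("timestamp '%s' duplicated within site '%s'",
                        doc$data$datetime[idx[dup]], site),
      schema_id = schema$id
    )
    dec <- which(diff(t) < 0) + 1L
    issues[[length(issues) + 1]] <- new_issues(
      rep("HYD-TIME-ORDER", length(dec)), file, row = idx[dec] + 1L,
      column = "datetime",
      message = sprintf("timestamp '%s' goes backwards within site '%s'",
                        doc$data$datetime[idx[dec]], site),
      schema_id = schema$id
    )
  }
  dplyr::bind_rows(issues)
}

# Companion key-value metadata for an amplicon table: must carry both a
# sequencing block and a bioinformatic processing block (the format keeps
# them distinguished).
check_amplicon_metadata <- function(doc) {
  file <- doc$source_name
  issues <- list()
  if (!all(c("block", "field", "value") %in% doc$header)) {
    issues[[length(issues) + 1]] <- new_issues(
      "AMP-META-BLOCK", file, row = 1L,
      message = "amplicon metadata must have block, field, value columns",
      schema_id = "amplicon_abundance"
    )
  } else {
    for (blk in c("sequencing", "processing")) {
      if (!blk %in% doc$data$block) {
        issues[[length(issues) + 1]] <- new_issues(
          "AMP-META-BLOCK", file, row = NA_integer_, column = "block",
          message = sprintf("no '%s' metadata block present", blk),
          schema_id = "amplicon_abundance"
        )
      }
    }
  }
  validation_report(dplyr::bind_rows(issues), files_checked = file,
                    schemas_applied = "amplicon_abundance")
}

# Representative sequences referenced from the processing block as
# fasta_file, read from disk when present.
amplicon_fasta_sequences <- function(amp_meta, dir) {
  if (!all(c("block", "field", "value") %in% amp_meta$header)) return(NULL)
  hit <- which(amp_meta$data$block == "processing" &
                 amp_meta$data$field == "fasta_file")
  if (length(hit) == 0) return(NULL)
  path <- file.path(dir, amp_meta$data$value[hit[1]])
  if (!file.exists(path)) return(NULL)
  read_fasta_sequences(path)
}

#' Read a FASTA file as a named vector of sequences
#'
#' @param path FASTA file.
#' @return Named character vector (names are record ids, sequences
#'   upper-cased).
#' @export
read_fasta_sequences <- function(path) {
  if (!requireNamespace("seqinr", quietly = TRUE)) {
    stop("reading FASTA sequence files requires the 'seqinr' package",
         call. = FALSE)
  }
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  stats::setNames(toupper(unlist(seqs)), names(seqs))
}

#' Per-variable summary of a validated series table
#'
#' A QA aid: for every numeric column, the number of observations, the
#' number of missing-coded cells, and the extremes with missing codes
#' excluded; `start`/`end` give the table's time range when a datetime or
#' date column is present.
#'
#' @param doc A `table_document`.
#' @param missing_codes In-band missing codes; defaults to
#'   [default_missing_codes()].
#' @return Tibble with columns `variable`, `n`, `n_missing`, `min`, `max`,
#'   `start`, `end`; zero rows for a table with no numeric columns.
#' @export
#' @examples
#' doc <- parse_csv(I("flux\n1\n-9999\n3\n"))
#' summarize_series(doc)
summarize_series <- function(doc, missing_codes = default_missing_codes()) {
  stopifnot(inherits(doc, "table_document"))
  prof <- profile_columns(doc, missing_codes)
  time_col <- which(prof$inferred_type %in% c("datetime", "date"))[1]
  time_range <- c(NA_character_, NA_character_)
  if (!is.na(time_col)) {
    cells <- doc$data[[time_col]]
    cells <- cells[!(cells %in% missing_codes)]
    ep <- iso_to_epoch(cells)
    if (any(!is.na(ep))) {
      time_range <- c(cells[which.min(ep)], cells[which.max(ep)])
    }
  }
  numeric_cols <- which(prof$inferred_type %in% c("integer", "decimal"))
  purrr::map_dfr(numeric_cols, function(j) {
    cells <- doc$data[[j]]
    vals <- suppressWarnings(as.numeric(cells[!(cells %in% missing_codes)]))
    vals <- vals[!is.na(vals)]
    tibble::tibble(
      variable = doc$header[j],
      n = length(cells),
      n_missing = sum(cells %in% missing_codes),
      min = if (length(vals)) min(vals) else NA_real_,
      max = if (length(vals)) max(vals) else NA_real_,
      start = time_range[1],
      end = time_range[2]
    )
  })
}
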