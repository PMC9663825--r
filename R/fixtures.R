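# Synthetic dataset-bundle generator with controlled violation injection.
# Fixtures emulate format structure, not scientific signal: values are
# drawn from simple documented distributions (dates uniform in range,
# coordinates uniform in the box, amplicon counts negative binomial,
# sequences uniform over ACGT) so that every schema rule is exercisable
# offline and byte-identically reproducible from a seed.

#' Specify a synthetic dataset bundle
#'
#' @param formats Schema ids to include; default all 11.
#' @param n_rows Rows per data table (default 20, desk scale).
#' @param n_samples Number of physical samples (default 5).
#' @param seed Integer seed; fully determines the bundle's bytes.
#' @param violations Character vector of issue codes to inject (repeat a
#'   code to inject it more than once); each must be in
#'   [mutable_issue_codes()].
#' @param coord_box Named numeric: `lat_min`, `lat_max`, `lon_min`,
#'   `lon_max`.
#' @param date_range Character vector of two `YYYY-MM-DD` dates.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(formats = c(CROSS_DOMAIN_IDS, DOMAIN_SPECIFIC_IDS),
                         n_rows = 20, n_samples = 5, seed = 1L,
                         violations = character(),
                         coord_box = c(lat_min = 37, lat_max = 39,
                                       lon_min = -123, lon_max = -121),
                         date_range = c("2021-01-01", "2021-12-31")) {
  bad <- setdiff(formats, c(CROSS_DOMAIN_IDS, DOMAIN_SPECIFIC_IDS))
  if (length(bad)) {
    stop("unknown format id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(violations, mutable_issue_codes())
  if (length(bad)) {
    stop("no violation generator for issue code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stopifnot(n_rows >= 6, n_samples >= 2, all(check_date(date_range)$valid))
  structure(
    list(formats = unique(formats), n_rows = as.integer(n_rows),
         n_samples = as.integer(n_samples), seed = as.integer(seed),
         violations = violations, coord_box = coord_box,
         date_range = date_range),
    class = "fixture_spec"
  )
}

fmt_num <- function(x, digits) formatC(x, format = "f", digits = digits)

r_dates <- function(n, range) {
  d <- as.Date(range)
  format(d[1] + sample.int(as.integer(d[2] - d[1]) + 1L, n, replace = TRUE) - 1L)
}

r_lat <- function(n, box) fmt_num(stats::runif(n, box["lat_min"], box["lat_max"]), 5)
r_lon <- function(n, box) fmt_num(stats::runif(n, box["lon_min"], box["lon_max"]), 5)

# Deterministic data-row choice for mutations, away from the first and
# last rows so order/duplicate edits have neighbours on both sides.
pick_row <- function(n, seed) {
  stopifnot(n >= 4)
  2L + (abs(seed) * 7919L) %% (n - 2L)
}

write_fixture_csv <- function(df, dir, file) {
  readr::write_csv(df, file.path(dir, file), na = "", quote = "needed",
                   eol = "\n", progress = FALSE)
  file
}

gen_sample_metadata <- function(ctx) {
  tibble::tibble(
    sample_id = ctx$sample_ids,
    sample_name = sprintf("SOIL-CORE-%02d", seq_along(ctx$sample_ids)),
    material = sample(c("soil", "water", "sediment"),
                      length(ctx$sample_ids), replace = TRUE),
    collection_date = r_dates(length(ctx$sample_ids), ctx$date_range),
    latitude = r_lat(length(ctx$sample_ids), ctx$coord_box),
    longitude = r_lon(length(ctx$sample_ids), ctx$coord_box),
    parent_sample = ""
  )
}

gen_location_metadata <- function(ctx) {
  n <- length(ctx$location_ids)
  tibble::tibble(
    location_id = ctx$location_ids,
    location_name = sprintf("Monitoring site %d", seq_len(n)),
    latitude = r_lat(n, ctx$coord_box),
    longitude = r_lon(n, ctx$coord_box),
    elevation_m = fmt_num(stats::runif(n, 100, 500), 1),
    location_description = "Synthetic headwater catchment site"
  )
}

gen_csv_guidelines <- function(ctx) {
  n <- ctx$n_rows
  tibble::tibble(
    record_id = as.character(seq_len(n)),
    sample_date = r_dates(n, ctx$date_range),
    depth_m = fmt_num(stats::runif(n, 0, 1.5), 2),
    treatment = sample(c("control", "warmed"), n, replace = TRUE),
    replicate = as.character(sample.int(3, n, replace = TRUE))
  )
}

gen_water_soil_chemistry <- function(ctx) {
  n <- ctx$n_rows
  ids <- sample(ctx$sample_ids, n, replace = TRUE)
  tibble::tibble(
    sample_id = ids,
    igsn = ids,
    analyte = sample(c("nitrate", "ammonium", "sulfate", "chloride",
                       "dissolved_organic_carbon", "calcium"),
                     n, replace = TRUE),
    value = fmt_num(abs(stats::rnorm(n, 5, 3)), 3),
    units = "mg/L",
    method = "IC (EPA 300.0)",
    below_detection = "FALSE",
    detection_limit = "",
    matrix = sample(c("water", "soil", "sediment"), n, replace = TRUE)
  )
}

gen_amplicon <- function(ctx) {
  n <- ctx$n_rows
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  }, character(1))
  out <- tibble::tibble(
    feature_id = sprintf("ASV%04d", seq_len(n)),
    representative_sequence = seqs
  )
  for (s in sprintf("samp%02d", seq_len(ctx$n_samples))) {
    out[[s]] <- as.character(stats::rnbinom(n, size = 1, mu = 50))
  }
  out
}

gen_amplicon_metadata <- function(ctx) {
  tibble::tibble(
    block = c(rep("sequencing", 5), rep("processing", 5)),
    field = c("target_gene", "target_subfragment", "primers",
              "sequencing_platform", "run_id",
              "pipeline", "pipeline_version", "method",
              "truncation_length", "reference_database"),
    value = c("16S rRNA", "V4", "515F/806R", "Illumina MiSeq", "RUN0001",
              "dada2", "1.30.0", "asv_denoising", "150", "SILVA 138")
  )
}

gen_leaf_gas_exchange <- function(ctx) {
  n <- ctx$n_rows
  tibble::tibble(
    instrument = "li6800",
    raw_or_processed = "processed",
    net_assimilation = fmt_num(stats::runif(n, 2, 30), 2),
    stomatal_conductance = fmt_num(stats::runif(n, 0.05, 0.8), 3),
    intercellular_co2 = fmt_num(stats::runif(n, 150, 350), 1),
    leaf_temperature = fmt_num(stats::runif(n, 18, 34), 2),
    par = fmt_num(stats::runif(n, 50, 1900), 0)
  )
}

gen_soil_respiration <- function(ctx) {
  n <- ctx$n_rows
  t0 <- as.POSIXct(paste0(ctx$date_range[1], " 00:00:00"), tz = "UTC")
  tibble::tibble(
    timestamp = format(t0 + 3600 * (seq_len(n) - 1), "%Y-%m-%dT%H:%M:%SZ"),
    chamber_id = sprintf("CH%02d", sample.int(4, n, replace = TRUE)),
    gas_species = sample(c("CO2", "CH4"), n, replace = TRUE),
    flux = fmt_num(abs(stats::rnorm(n, 3, 1)), 3),
    flux_units = "umol m-2 s-1",
    soil_temperature = fmt_num(stats::runif(n, 8, 24), 1),
    soil_moisture = fmt_num(stats::runif(n, 5, 45), 1)
  )
}

gen_hydrologic_monitoring <- function(ctx) {
  n <- ctx$n_rows
  t0 <- as.POSIXct(paste0(ctx$date_range[1], " 08:00:00"), tz = "UTC")
  tibble::tibble(
    datetime = format(t0 + 900 * (seq_len(n) - 1), "%Y-%m-%dT%H:%M:%SZ"),
    site_id = ctx$location_ids[1],
    water_level = fmt_num(stats::runif(n, 0.4, 2.1), 3),
    water_temperature = fmt_num(stats::runif(n, 4, 22), 2),
    ph = fmt_num(stats::runif(n, 6.2, 8.4), 2)
  )
}

gen_model_archiving <- function(ctx) {
  tibble::tibble(
    item = c("code_reference", "inputs", "configuration", "outputs",
             "postprocessing_scripts", "documentation"),
    status = "present",
    evidence = ""
  )
}

gen_dataset_metadata <- function(ctx, dir) {
  md <- list(
    title = "Synthetic multi-domain environmental observations for reporting-format validation",
    abstract = paste(
      "A synthetic dataset bundle exercising the community (meta)data",
      "reporting formats: tabular observations, sample and location",
      "metadata, and domain tables generated from a fixed random seed for",
      "offline validator testing."
    ),
    creators = list(
      list(name = "Ada Fixture", affiliation = "Synthetic Data Lab",
           identifier = "https://orcid.org/0000-0000-0000-0001"),
      list(name = "Grace Bundle", affiliation = "Synthetic Data Lab",
           identifier = "")
    ),
    keywords = list("synthetic", "validation", "reporting format"),
    temporal_coverage = list(start = ctx$date_range[1], end = ctx$date_range[2]),
    spatial_coverage = list(list(
      latitude = round(mean(ctx$coord_box[c("lat_min", "lat_max")]), 5),
      longitude = round(mean(ctx$coord_box[c("lon_min", "lon_max")]), 5),
      description = "Synthetic study area centroid"
    )),
    funding = "Synthetic fixture (no funding)",
    related_identifiers = list("doi:10.0000/synthetic-bundle")
  )
  jsonlite::write_json(md, file.path(dir, "dataset_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  "dataset_metadata.json"
}

# file writers by format id, in deterministic generation order
FIXTURE_WRITERS <- list(
  sample_metadata = gen_sample_metadata,
  location_metadata = gen_location_metadata,
  csv_guidelines = gen_csv_guidelines,
  water_soil_chemistry = gen_water_soil_chemistry,
  amplicon_abundance = gen_amplicon,
  leaf_gas_exchange = gen_leaf_gas_exchange,
  soil_respiration = gen_soil_respiration,
  hydrologic_monitoring = gen_hydrologic_monitoring,
  model_archiving = gen_model_archiving
)

#' Generate a synthetic dataset bundle
#'
#' Writes a complete bundle to `out_dir`: dataset metadata, a file-level
#' metadata table covering every emitted file, and one table per
#' requested format. With no violations requested the bundle validates
#' with zero issues under all requested schemas; each requested violation
#' is injected by its generator and recorded in the returned ledger. The
#' same spec and seed always produce byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a manifest list: `dir`, `files` (tibble `file`,
#'   `format`), `ledger` (tibble of injected issues, zero rows when no
#'   violations were requested).
#' @export
#' @examples
#' \donttest{
#' dir <- tempfile(); m <- generate_bundle(fixture_spec(seed = 7), dir)
#' glance(validate_bundle(dir))
#' }
generate_bundle <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  ctx <- list(
    n_rows = spec$n_rows, n_samples = spec$n_samples,
    coord_box = spec$coord_box, date_range = spec$date_range,
    sample_ids = sprintf("IGSN:IEAWH%04d", seq_len(spec$n_samples)),
    location_ids = sprintf("LOC%03d", 1:6)
  )

  files <- tibble::tibble(file = character(), format = character())
  add_file <- function(file, format) {
    files <<- dplyr::bind_rows(files, tibble::tibble(file = file,
                                                     format = format))
  }
  add_file(gen_dataset_metadata(ctx, out_dir), "dataset_metadata")

  for (fmt in names(FIXTURE_WRITERS)) {
    if (!fmt %in% spec$formats) next
    df <- FIXTURE_WRITERS[[fmt]](ctx)
    add_file(write_fixture_csv(df, out_dir, paste0(fmt, ".csv")), fmt)
    if (fmt == "amplicon_abundance") {
      add_file(write_fixture_csv(gen_amplicon_metadata(ctx), out_dir,
                                 "amplicon_metadata.csv"),
               "amplicon_metadata")
    }
  }

  flmd <- tibble::tibble(
    file_name = c("dataset_metadata.json", "flmd.csv", files$file[-1]),
    file_description = c(
      "Dataset-level metadata for citation and discovery",
      "File-level metadata describing every file in this bundle",
      sprintf("Synthetic %s table", files$format[-1])
    ),
    file_format = c("json", "csv", rep("csv", nrow(files) - 1)),
    column_or_row_name_position = c("", "1", rep("1", nrow(files) - 1)),
    missing_value_codes = c("", "", rep("-9999", nrow(files) - 1)),
    notes = ""
  )
  write_fixture_csv(flmd, out_dir, "flmd.csv")
  files <- dplyr::bind_rows(
    files[1, ],
    tibble::tibble(file = "flmd.csv", format = "file_level_metadata"),
    files[-1, ]
  )

  ledger <- empty_ledger()
  for (i in seq_along(spec$violations)) {
    ledger <- dplyr::bind_rows(
      ledger,
      mutate_bundle(out_dir, spec$violations[i], seed = spec$seed + i)
    )
  }
  # orphan files written by mutations join the manifest without a format
  extra <- setdiff(setdiff(list.files(out_dir), "manifest.json"), files$file)
  files <- dplyr::bind_rows(
    files, tibble::tibble(file = extra, format = rep(NA_character_,
                                                     length(extra)))
  )

  manifest <- list(
    generator = "reportfmt", seed = spec$seed,
    formats = as.list(spec$formats),
    files = purrr::pmap(files, function(file, format) {
      list(file = file, format = if (is.na(format)) NULL else format)
    }),
    violations = purrr::pmap(ledger, function(code, file, row, column) {
      list(code = code, file = file,
           row = if (is.na(row)) NULL else row,
           column = if (is.na(column)) NULL else column)
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dir = out_dir, files = files, ledger = ledger))
}

empty_ledger <- function() {
  tibble::tibble(code = character(), file = character(), row = integer(),
                 column = character())
}

ledger_row <- function(code, file, row = NA_integer_, column = NA_character_) {
  tibble::tibble(code = code, file = file, row = as.integer(row),
                 column = as.character(column))
}

# Edit one data cell of a bundle table; returns the file row (header = 1).
edit_cell <- function(dir, file, column, value, data_row) {
  doc <- parse_csv(file.path(dir, file))
  j <- match(column, doc$header)
  stopifnot(!is.na(j))
  doc$data[data_row, j] <- value
  write_table_csv(doc, file.path(dir, file))
  data_row + 1L
}

read_doc <- function(dir, file) parse_csv(file.path(dir, file))

# One generator per mutable issue code. Each takes (dir, seed), edits the
# bundle deterministically, and returns the exact ledger of issues the
# mutation introduces (some edits legitimately trip more than one rule).
VIOLATION_GENERATORS <- list(
  `REQ-MISSING` = function(dir, seed) {
    f <- "location_metadata.csv"
    doc <- read_doc(dir, f)
    keep <- doc$header != "latitude"
    doc$header <- doc$header[keep]
    doc$data <- doc$data[, keep, drop = FALSE]
    write_table_csv(doc, file.path(dir, f))
    ledger_row("REQ-MISSING", f, 1L, "latitude")
  },
  `HDR-FUZZY` = function(dir, seed) {
    f <- "location_metadata.csv"
    doc <- read_doc(dir, f)
    j <- match("longitude", doc$header)
    doc$header[j] <- "Longitude"
    names(doc$data) <- doc$header
    write_table_csv(doc, file.path(dir, f))
    ledger_row("HDR-FUZZY", f, 1L, "Longitude")
  },
  `COL-UNKNOWN` = function(dir, seed) {
    f <- "location_metadata.csv"
    doc <- read_doc(dir, f)
    doc$data$surveyor <- "J. Doe"
    doc$header <- names(doc$data)
    write_table_csv(doc, file.path(dir, f))
    ledger_row("COL-UNKNOWN", f, 1L, "surveyor")
  },
  `TYPE-MISMATCH` = function(dir, seed) {
    f <- "flmd.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "column_or_row_name_position", "abc",
                     pick_row(n, seed))
    ledger_row("TYPE-MISMATCH", f, row, "column_or_row_name_position")
  },
  `DATE-FORMAT` = function(dir, seed) {
    f <- "sample_metadata.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "collection_date", "03/05/2021",
                     pick_row(n, seed))
    dplyr::bind_rows(
      ledger_row("DATE-FORMAT", f, row, "collection_date"),
      ledger_row("MIXED-TYPE", f, NA, "collection_date")
    )
  },
  `DATE-CALENDAR` = function(dir, seed) {
    f <- "sample_metadata.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "collection_date", "2021-02-30",
                     pick_row(n, seed))
    ledger_row("DATE-CALENDAR", f, row, "collection_date")
  },
  `DATE-MISSING-CODE` = function(dir, seed) {
    f <- "sample_metadata.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "collection_date", "-9999", pick_row(n, seed))
    ledger_row("DATE-MISSING-CODE", f, row, "collection_date")
  },
  `DATETIME-FORMAT` = function(dir, seed) {
    f <- "hydrologic_monitoring.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "datetime", "06/01/2021 10:00",
                     pick_row(n, seed))
    dplyr::bind_rows(
      ledger_row("DATETIME-FORMAT", f, row, "datetime"),
      ledger_row("MIXED-TYPE", f, NA, "datetime")
    )
  },
  `DATETIME-NAIVE` = function(dir, seed) {
    f <- "soil_respiration.csv"
    doc <- read_doc(dir, f)
    r <- pick_row(nrow(doc$data), seed)
    row <- edit_cell(dir, f, "timestamp",
                     sub("Z$", "", doc$data$timestamp[r]), r)
    ledger_row("DATETIME-NAIVE", f, row, "timestamp")
  },
  `COORD-BOUNDS` = function(dir, seed) {
    f <- "location_metadata.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "latitude", "95.00000", pick_row(n, seed))
    ledger_row("COORD-BOUNDS", f, row, "latitude")
  },
  `BOUNDS` = function(dir, seed) {
    f <- "hydrologic_monitoring.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "ph", "20.10", pick_row(n, seed))
    ledger_row("BOUNDS", f, row, "ph")
  },
  `VOCAB` = function(dir, seed) {
    f <- "water_soil_chemistry.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "matrix", "plasma", pick_row(n, seed))
    ledger_row("VOCAB", f, row, "matrix")
  },
  `VOCAB-NOVEL` = function(dir, seed) {
    f <- "water_soil_chemistry.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "analyte", "unobtainium", pick_row(n, seed))
    ledger_row("VOCAB-NOVEL", f, row, "analyte")
  },
  `PATTERN` = function(dir, seed) {
    f <- "amplicon_abundance.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "representative_sequence", "ACGTJACGTA",
                     pick_row(n, seed))
    ledger_row("PATTERN", f, row, "representative_sequence")
  },
  `AMP-SEQ-IUPAC` = function(dir, seed) {
    f <- "amplicon_abundance.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "representative_sequence", "ACGTRACGTA",
                     pick_row(n, seed))
    ledger_row("AMP-SEQ-IUPAC", f, row, "representative_sequence")
  },
  `AMP-NEG-COUNT` = function(dir, seed) {
    f <- "amplicon_abundance.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "samp01", "-3", pick_row(n, seed))
    ledger_row("AMP-NEG-COUNT", f, row, "samp01")
  },
  `AMP-COUNT-TYPE` = function(dir, seed) {
    f <- "amplicon_abundance.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "samp02", "7.5", pick_row(n, seed))
    ledger_row("AMP-COUNT-TYPE", f, row, "samp02")
  },
  `AMP-DUP-FEATURE` = function(dir, seed) {
    f <- "amplicon_abundance.csv"
    doc <- read_doc(dir, f)
    row <- edit_cell(dir, f, "feature_id", doc$data$feature_id[1],
                     pick_row(nrow(doc$data), seed))
    ledger_row("AMP-DUP-FEATURE", f, row, "feature_id")
  },
  `GAS-INSTRUMENT-UNKNOWN` = function(dir, seed) {
    f <- "leaf_gas_exchange.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "instrument", "tricorder", pick_row(n, seed))
    ledger_row("GAS-INSTRUMENT-UNKNOWN", f, row, "instrument")
  },
  `CHEM-BDL-EMBEDDED` = function(dir, seed) {
    f <- "water_soil_chemistry.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "value", "<0.5", pick_row(n, seed))
    dplyr::bind_rows(
      ledger_row("CHEM-BDL-EMBEDDED", f, row, "value"),
      ledger_row("TYPE-MISMATCH", f, row, "value"),
      ledger_row("MIXED-TYPE", f, NA, "value")
    )
  },
  `HYD-TIME-ORDER` = function(dir, seed) {
    f <- "hydrologic_monitoring.csv"
    doc <- read_doc(dir, f)
    r <- pick_row(nrow(doc$data) - 1L, seed)
    tmp <- doc$data$datetime[r]
    doc$data$datetime[r] <- doc$data$datetime[r + 1]
    doc$data$datetime[r + 1] <- tmp
    write_table_csv(doc, file.path(dir, f))
    ledger_row("HYD-TIME-ORDER", f, r + 2L, "datetime")
  },
  `HYD-TIME-DUP` = function(dir, seed) {
    f <- "hydrologic_monitoring.csv"
    doc <- read_doc(dir, f)
    r <- pick_row(nrow(doc$data), seed)
    row <- edit_cell(dir, f, "datetime", doc$data$datetime[r - 1], r)
    ledger_row("HYD-TIME-DUP", f, row, "datetime")
  },
  `IGSN-SYNTAX` = function(dir, seed) {
    f <- "water_soil_chemistry.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "igsn", "IGSN:X1", pick_row(n, seed))
    ledger_row("IGSN-SYNTAX", f, row, "igsn")
  },
  `IGSN-CASE` = function(dir, seed) {
    f <- "water_soil_chemistry.csv"
    doc <- read_doc(dir, f)
    r <- pick_row(nrow(doc$data), seed)
    row <- edit_cell(dir, f, "igsn", tolower(doc$data$igsn[r]), r)
    ledger_row("IGSN-CASE", f, row, "igsn")
  },
  `REF-UNRESOLVED` = function(dir, seed) {
    f <- "water_soil_chemistry.csv"
    stopifnot(file.exists(file.path(dir, "sample_metadata.csv")))
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "sample_id", "S-9999", pick_row(n, seed))
    ledger_row("REF-UNRESOLVED", f, row, "sample_id")
  },
  `DUP-FILE` = function(dir, seed) {
    f <- "flmd.csv"
    doc <- read_doc(dir, f)
    n <- nrow(doc$data)
    doc$data <- dplyr::bind_rows(doc$data, doc$data[n, ])
    write_table_csv(doc, file.path(dir, f))
    ledger_row("DUP-FILE", f, n + 2L, "file_name")
  },
  `FILE-MISSING` = function(dir, seed) {
    f <- "flmd.csv"
    doc <- read_doc(dir, f)
    ghost <- doc$data[nrow(doc$data), ]
    ghost$file_name <- "ghost.csv"
    ghost$file_description <- "File described but never written"
    doc$data <- dplyr::bind_rows(doc$data, ghost)
    write_table_csv(doc, file.path(dir, f))
    ledger_row("FILE-MISSING", f, nrow(doc$data) + 1L, "file_name")
  },
  `FILE-UNDESCRIBED` = function(dir, seed) {
    writeLines(c("note", "orphan file"), file.path(dir, "orphan.csv"))
    ledger_row("FILE-UNDESCRIBED", "flmd.csv", NA, "orphan.csv")
  },
  `LEN-SHORT` = function(dir, seed) {
    p <- file.path(dir, "dataset_metadata.json")
    md <- jsonlite::fromJSON(p, simplifyVector = FALSE)
    md$abstract <- "Too short."
    jsonlite::write_json(md, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ledger_row("LEN-SHORT", "dataset_metadata.json", NA, "abstract")
  },
  `META-TEMPORAL-ORDER` = function(dir, seed) {
    p <- file.path(dir, "dataset_metadata.json")
    md <- jsonlite::fromJSON(p, simplifyVector = FALSE)
    tc <- md$temporal_coverage
    md$temporal_coverage <- list(start = tc$end, end = tc$start)
    jsonlite::write_json(md, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ledger_row("META-TEMPORAL-ORDER", "dataset_metadata.json", NA,
               "temporal_coverage_start")
  },
  `MIXED-TYPE` = function(dir, seed) {
    f <- "csv_guidelines.csv"
    n <- nrow(read_doc(dir, f)$data)
    edit_cell(dir, f, "depth_m", "deep", pick_row(n, seed))
    ledger_row("MIXED-TYPE", f, NA, "depth_m")
  },
  `MISSING-CODE` = function(dir, seed) {
    f <- "csv_guidelines.csv"
    n <- nrow(read_doc(dir, f)$data)
    row <- edit_cell(dir, f, "depth_m", "", pick_row(n, seed))
    ledger_row("MISSING-CODE", f, row, "depth_m")
  },
  `DUP-COLUMN` = function(dir, seed) {
    f <- "csv_guidelines.csv"
    doc <- read_doc(dir, f)
    j <- match("replicate", doc$header)
    doc$header[j] <- "depth_m"
    names(doc$data) <- doc$header
    write_table_csv(doc, file.path(dir, f))
    ledger_row("DUP-COLUMN", f, 1L, "depth_m")
  },
  `MODEL-ITEM-ABSENT` = function(dir, seed) {
    f <- "model_archiving.csv"
    doc <- read_doc(dir, f)
    r <- match("outputs", doc$data$item)
    row <- edit_cell(dir, f, "status", "absent", r)
    ledger_row("MODEL-ITEM-ABSENT", f, row, "item")
  }
)

#' Inject one violation into a valid bundle
#'
#' Applies the named issue code's mutation generator to the bundle in
#' `dir` and returns the exact ledger of issues the mutation introduces
#' (some single edits legitimately trip more than one rule, e.g. a
#' non-numeric cell in a numeric column is both a cell type mismatch and
#' a mixed-type column). Validating the mutated bundle and diffing
#' against the pre-mutation report yields exactly the ledger.
#'
#' @param dir Bundle directory (as produced by [generate_bundle()]).
#' @param issue_code A code from [mutable_issue_codes()].
#' @param seed Integer controlling which row the mutation hits.
#' @return Ledger tibble (`code`, `file`, `row`, `column`).
#' @export
mutate_bundle <- function(dir, issue_code, seed = 1L) {
  gen <- VIOLATION_GENERATORS[[issue_code]]
  if (is.null(gen)) {
    stop("issue code '", issue_code, "' has no mutation generator; see ",
         "mutable_issue_codes()", call. = FALSE)
  }
  gen(dir, as.integer(seed))
}
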