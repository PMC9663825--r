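test_that("amplicon count checks equal a brute-force cell scan", {
  reg <- test_registry()
  set.seed(21)
  for (trial in 1:20) {
    n <- sample(3:10, 1)
    counts1 <- as.character(sample(c(0:50, -3, -1), n, replace = TRUE))
    counts2 <- as.character(sample(c(0:50, "7.5", "many"), n, replace = TRUE))
    df <- tibble::tibble(
      feature_id = sprintf("ASV%03d", seq_len(n)),
      representative_sequence = strrep("ACGT", 10),
      s1 = counts1, s2 = counts2
    )
    doc <- reportfmt:::as_table_document(df, "amp.csv")
    iss <- tidy(validate_domain_table(doc, "amplicon_abundance", reg))
    # oracle: scan every count cell by hand
    brute_neg <- 0; brute_type <- 0
    for (col in c("s1", "s2")) for (cell in df[[col]]) {
      if (grepl("^[+-]?\\d+$", cell)) {
        if (as.numeric(cell) < 0) brute_neg <- brute_neg + 1
      } else brute_type <- brute_type + 1
    }
    expect_equal(sum(iss$code == "AMP-NEG-COUNT"), brute_neg)
    expect_equal(sum(iss$code == "AMP-COUNT-TYPE"), brute_type)
  }
})

test_that("amplicon feature ids and sequence alphabet rules", {
  reg <- test_registry()
  df <- tibble::tibble(
    feature_id = c("ASV1", "ASV2", "ASV1"),
    representative_sequence = c("ACGTACGT", "ACGTRYACGT", "ACGTJX"),
    s1 = c("1", "2", "3")
  )
  doc <- reportfmt:::as_table_document(df, "amp.csv")
  iss <- tidy(validate_domain_table(doc, "amplicon_abundance", reg))
  expect_equal(sum(iss$code == "AMP-DUP-FEATURE"), 1)
  expect_equal(iss$row[iss$code == "AMP-SEQ-IUPAC"], 3L)  # data row 2
  expect_equal(iss$severity[iss$code == "AMP-SEQ-IUPAC"], "warning")
  expect_equal(iss$row[iss$code == "PATTERN"], 4L)        # invalid chars
})

test_that("representative sequences may live in a referenced FASTA file", {
  d <- copy_bundle()
  amp <- parse_csv(file.path(d, "amplicon_abundance.csv"))
  seqs <- amp$data$representative_sequence
  ids <- amp$data$feature_id
  keep <- amp$header != "representative_sequence"
  amp$header <- amp$header[keep]
  amp$data <- amp$data[, keep, drop = FALSE]
  write_table_csv(amp, file.path(d, "amplicon_abundance.csv"))
  writeLines(paste0(">", ids, "\n", seqs), file.path(d, "rep_seqs.fasta"))
  meta <- parse_csv(file.path(d, "amplicon_metadata.csv"))
  meta$data <- dplyr::bind_rows(
    meta$data, tibble::tibble(block = "processing", field = "fasta_file",
                              value = "rep_seqs.fasta")
  )
  write_table_csv(meta, file.path(d, "amplicon_metadata.csv"))
  flmd <- parse_csv(file.path(d, "flmd.csv"))
  flmd$data <- dplyr::bind_rows(flmd$data, tibble::tibble(
    file_name = "rep_seqs.fasta",
    file_description = "Representative sequences for the amplicon table",
    file_format = "fasta", column_or_row_name_position = "",
    missing_value_codes = "", notes = ""
  ))
  write_table_csv(flmd, file.path(d, "flmd.csv"))
  iss <- tidy(validate_bundle(d))
  expect_false("REQ-MISSING" %in% iss$code)
  expect_equal(sum(iss$severity == "error"), 0)
})

test_that("unknown instruments error and list the known ones", {
  reg <- test_registry()
  df <- tibble::tibble(instrument = c("li6800", "tricorder"),
                       raw_or_processed = "processed",
                       net_assimilation = c("10.0", "11.0"))
  doc <- reportfmt:::as_table_document(df, "gas.csv")
  iss <- tidy(validate_domain_table(doc, "leaf_gas_exchange", reg))
  hit <- iss[iss$code == "GAS-INSTRUMENT-UNKNOWN", ]
  expect_equal(hit$row, 3L)
  expect_match(hit$message, "li6400")
})

test_that("embedded below-detection strings are flagged with a fix-it", {
  reg <- test_registry()
  df <- tibble::tibble(sample_id = "S1", analyte = "nitrate",
                       value = "<0.5", units = "mg/L", matrix = "water")
  doc <- reportfmt:::as_table_document(df, "chem.csv")
  iss <- tidy(validate_domain_table(doc, "water_soil_chemistry", reg))
  hit <- iss[iss$code == "CHEM-BDL-EMBEDDED", ]
  expect_equal(nrow(hit), 1)
  expect_match(hit$message, "below_detection=TRUE")
})

test_that("hydrologic timestamps: out-of-order warns, duplicates error", {
  reg <- test_registry()
  df <- tibble::tibble(
    datetime = c("2021-06-01T10:00:00Z", "2021-06-01T10:30:00Z",
                 "2021-06-01T10:15:00Z", "2021-06-01T10:15:00Z",
                 "2021-06-01T11:00:00Z"),
    site_id = "LOC001", water_level = "1.0"
  )
  doc <- reportfmt:::as_table_document(df, "hydro.csv")
  iss <- tidy(validate_domain_table(doc, "hydrologic_monitoring", reg))
  expect_equal(iss$row[iss$code == "HYD-TIME-ORDER"], 4L)
  expect_equal(iss$severity[iss$code == "HYD-TIME-ORDER"], "warning")
  expect_equal(iss$row[iss$code == "HYD-TIME-DUP"], 5L)
  expect_equal(iss$severity[iss$code == "HYD-TIME-DUP"], "error")
  # per-site: the same times at another site are fine
  df$site_id <- c("A", "B", "A", "B", "A")
  df$datetime <- c("2021-06-01T10:00:00Z", "2021-06-01T10:00:00Z",
                   "2021-06-01T10:30:00Z", "2021-06-01T10:30:00Z",
                   "2021-06-01T11:00:00Z")
  doc <- reportfmt:::as_table_document(df, "hydro.csv")
  iss <- tidy(validate_domain_table(doc, "hydrologic_monitoring", reg))
  expect_false(any(grepl("^HYD-", iss$code)))
})

test_that("domain validation is a superset of the base CSV validation", {
  reg <- test_registry()
  df <- tibble::tibble(
    datetime = c("2021-06-01T10:00:00Z", "junk", "2021-06-01T11:00:00Z"),
    site_id = "LOC001", ph = c("7.0", "7.2", "20.5")
  )
  doc <- reportfmt:::as_table_document(df, "hydro.csv")
  base <- tidy(validate_table(doc, get_schema(reg, "hydrologic_monitoring")))
  domain <- tidy(validate_domain_table(doc, "hydrologic_monitoring", reg))
  expect_true(all(
    paste(base$code, base$row, base$column) %in%
      paste(domain$code, domain$row, domain$column)
  ))
})

test_that("series summaries exclude missing codes from the extremes", {
  doc <- doc_from_text(
    "datetime,flux\n2021-06-01T00:00:00Z,1\n2021-06-01T01:00:00Z,-9999\n2021-06-01T02:00:00Z,3\n"
  )
  s <- summarize_series(doc)
  expect_equal(s$n, 3)
  expect_equal(s$n_missing, 1)
  expect_equal(s$min, 1)
  expect_equal(s$max, 3)
  expect_equal(s$start, "2021-06-01T00:00:00Z")
  expect_equal(s$end, "2021-06-01T02:00:00Z")
  # no numeric columns -> zero-row summary
  expect_equal(nrow(summarize_series(doc_from_text("a\nx\n"))), 0)
  # fixture round-trip: injected extremes are recovered
  d <- base_bundle_dir()
  s <- summarize_series(parse_csv(file.path(d, "hydrologic_monitoring.csv")))
  ph <- s[s$variable == "ph", ]
  expect_true(ph$min >= 6.2 && ph$max <= 8.4)
})
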