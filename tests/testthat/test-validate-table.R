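test_that("missing required columns give exactly one REQ-MISSING each", {
  reg <- test_registry()
  doc <- doc_from_text("location_id,longitude\nL1,10\n", "loc.csv")
  rep <- validate_table(doc, get_schema(reg, "location_metadata"))
  iss <- tidy(rep)
  expect_equal(sum(iss$code == "REQ-MISSING"), 1)
  expect_equal(iss$column[iss$code == "REQ-MISSING"], "latitude")
  expect_equal(iss$row[iss$code == "REQ-MISSING"], 1L)
})

test_that("out-of-bounds coordinates are cell-located errors", {
  reg <- test_registry()
  doc <- doc_from_text(
    "location_id,latitude,longitude\nL1,95,10\nL2,45.5,-200\n", "loc.csv"
  )
  iss <- tidy(validate_table(doc, get_schema(reg, "location_metadata")))
  cb <- iss[iss$code == "COORD-BOUNDS", ]
  expect_equal(nrow(cb), 2)
  expect_equal(cb$row, c(2L, 3L))
  expect_equal(cb$column, c("latitude", "longitude"))
  expect_true(all(cb$severity == "error"))
})

test_that("extra columns are info, never errors; missing codes never type-error", {
  reg <- test_registry()
  doc <- doc_from_text(
    "location_id,latitude,longitude,elevation_m,my_extra\nL1,45,10,-9999,hi\n",
    "loc.csv"
  )
  iss <- tidy(validate_table(doc, get_schema(reg, "location_metadata")))
  expect_equal(iss$code, "COL-UNKNOWN")
  expect_equal(iss$severity, "info")
})

test_that("case-insensitive header matches warn and still validate cells", {
  reg <- test_registry()
  doc <- doc_from_text(
    "location_id,Latitude,longitude\nL1,95,10\n", "loc.csv"
  )
  iss <- tidy(validate_table(doc, get_schema(reg, "location_metadata")))
  expect_true("HDR-FUZZY" %in% iss$code)
  expect_false("REQ-MISSING" %in% iss$code)
  expect_true("COORD-BOUNDS" %in% iss$code)  # cell check ran on fuzzy match
})

test_that("controlled vocabularies: closed errors, open warns", {
  reg <- test_registry()
  schema <- get_schema(reg, "water_soil_chemistry")
  doc <- doc_from_text(paste0(
    "sample_id,analyte,value,units,matrix\n",
    "S1,unobtainium,1.0,mg/L,plasma\n"
  ), "chem.csv")
  iss <- tidy(validate_table(doc, schema))
  expect_equal(iss$severity[iss$code == "VOCAB"], "error")
  expect_equal(iss$column[iss$code == "VOCAB"], "matrix")
  expect_equal(iss$severity[iss$code == "VOCAB-NOVEL"], "warning")
  expect_equal(iss$column[iss$code == "VOCAB-NOVEL"], "analyte")
})

test_that("table rules catch mixed types, stray missing codes, non-ISO dates", {
  reg <- test_registry()
  schema <- get_schema(reg, "csv_guidelines")
  doc <- doc_from_text(paste0(
    "record_id,obs_date,depth\n",
    "1,2021-01-05,0.3\n",
    "2,01/06/2021,N/A\n",
    "3,2021-02-30,deep\n"
  ), "data.csv")
  iss <- tidy(validate_table(doc, schema))
  expect_true("DATE-FORMAT" %in% iss$code)
  expect_true("DATE-CALENDAR" %in% iss$code)
  expect_true("MIXED-TYPE" %in% iss$code)
  # the guidelines schema declares no columns, so nothing is "unknown"
  expect_false("COL-UNKNOWN" %in% iss$code)
})

test_that("validation is deterministic and sorted by (file, row, column, code)", {
  reg <- test_registry()
  doc <- doc_from_text(
    "location_id,latitude,longitude\nL1,95,-200\nL2,91,181\n", "loc.csv"
  )
  r1 <- tidy(validate_table(doc, get_schema(reg, "location_metadata")))
  r2 <- tidy(validate_table(doc, get_schema(reg, "location_metadata")))
  expect_identical(r1, r2)
  key <- paste(r1$file, sprintf("%05d", dplyr::coalesce(r1$row, 0L)),
               dplyr::coalesce(r1$column, ""), r1$code)
  expect_equal(key, sort(key))
})

test_that("report summaries recount the issue table and define pass", {
  rep <- base_bundle_report()
  g <- glance(rep)
  iss <- tidy(rep)
  expect_equal(g$n_error, sum(iss$severity == "error"))
  expect_equal(g$n_warning, sum(iss$severity == "warning"))
  expect_equal(g$n_info, sum(iss$severity == "info"))
  expect_equal(g$pass, g$n_error == 0)
  expect_s3_class(autoplot(rep), "ggplot")
})
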