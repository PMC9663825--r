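test_that("packaged crosswalks load with their invariants", {
  cw <- default_crosswalk("hydrologic_monitoring")
  expect_gte(dplyr::n_distinct(cw$entries$source_standard), 1)
  expect_equal(cw$target_format, "hydrologic_monitoring")
  # the classic renaming example: a foreign ValueDateTime is the
  # harmonized datetime
  expect_equal(map_term(cw, "wqx", "ValueDateTime"), "datetime")
  expect_true(is.na(map_term(cw, "wqx", "nonexistent")))
  expect_error(map_term(cw, "unknown-standard", "x"), "standards in table")

  instruments <- default_instrument_table()
  expect_equal(dplyr::n_distinct(instruments$entries$source_standard), 10)
})

test_that("crosswalk load rejects duplicates and warns on orphans", {
  p <- tempfile(fileext = ".csv")
  writeLines(c(
    "source_standard,source_term,target_term,unit_factor,unit_offset,notes",
    "std,a,datetime,,,",
    "std,a,site_id,,,"
  ), p)
  expect_error(load_crosswalk(p, "hydrologic_monitoring"), "duplicate")
  writeLines(c(
    "source_standard,source_term,target_term,unit_factor,unit_offset,notes",
    "std,a,not_a_field,,,"
  ), p)
  expect_warning(load_crosswalk(p, "hydrologic_monitoring"), "not_a_field")
})

test_that("map_term agrees with a brute-force linear scan", {
  cw <- default_crosswalk("hydrologic_monitoring")
  e <- cw$entries
  set.seed(33)
  terms <- unique(c(e$source_term, "datetime", "bogus", "valuedatetime"))
  for (trial in 1:200) {
    std <- sample(unique(e$source_standard), 1)
    term <- sample(terms, 1)
    # oracle: first row matching both keys, scanning top to bottom
    oracle <- NA_character_
    for (i in seq_len(nrow(e))) {
      if (e$source_standard[i] == std && e$source_term[i] == term) {
        oracle <- e$target_term[i]; break
      }
    }
    expect_identical(map_term(cw, std, term), oracle)
  }
})

test_that("translate_headers renames, converts units, reports residue", {
  cw <- default_crosswalk("hydrologic_monitoring")
  doc <- doc_from_text(
    "ValueDateTime,00065,extra\n2021-06-01T00:00:00Z,3.0,x\n", "w.csv"
  )
  # 00065 belongs to another standard; under wqx only ValueDateTime maps
  res <- translate_headers(doc, cw, "wqx")
  expect_equal(res$document$header, c("datetime", "00065", "extra"))
  expect_setequal(res$unmapped, c("00065", "extra"))
  # under the gauge standard the stage column converts feet to metres
  res <- translate_headers(doc, cw, "usgs_nwis")
  expect_equal(res$document$header[2], "water_level")
  expect_equal(as.numeric(res$document$data$water_level), 3.0 * 0.3048)
  # cell values elsewhere untouched, column count preserved
  expect_equal(res$document$data$extra, "x")
  expect_equal(length(res$document$header), 3)
})

test_that("empty crosswalk is the identity transform", {
  p <- tempfile(fileext = ".csv")
  writeLines("source_standard,source_term,target_term,unit_factor,unit_offset,notes", p)
  cw <- load_crosswalk(p, "hydrologic_monitoring")
  doc <- doc_from_text("a,b\n1,2\n")
  res <- translate_headers(doc, cw, "anything", registry = NULL)
  expect_identical(res$document$data, doc$data)
  expect_equal(res$unmapped, c("a", "b"))
})

test_that("two source columns mapping to one target is a refused collision", {
  p <- tempfile(fileext = ".csv")
  writeLines(c(
    "source_standard,source_term,target_term,unit_factor,unit_offset,notes",
    "std,colA,datetime,,,",
    "std,colB,datetime,,,"
  ), p)
  cw <- load_crosswalk(p, "hydrologic_monitoring")
  doc <- doc_from_text("colA,colB\n1,2\n")
  expect_error(translate_headers(doc, cw, "std", registry = NULL),
               "collision.*no rename applied")
})

test_that("translation is idempotent and affine conversions invert", {
  cw <- default_crosswalk("hydrologic_monitoring")
  set.seed(14)
  for (trial in 1:25) {
    std <- sample(unique(cw$entries$source_standard), 1)
    pool <- cw$entries$source_term[cw$entries$source_standard == std]
    cols <- unique(c(sample(pool, min(2, length(pool))), "untouched"))
    df <- stats::setNames(
      as.data.frame(matrix(as.character(round(stats::runif(3 * length(cols)), 3)),
                           nrow = 3)), cols)
    doc <- reportfmt:::as_table_document(df, "t.csv")
    once <- translate_headers(doc, cw, std, registry = NULL)
    twice <- translate_headers(once$document, cw, std, registry = NULL)
    expect_identical(twice$document, once$document)
  }
  # Fahrenheit -> Celsius and back within 1e-9 relative error
  e <- cw$entries[cw$entries$source_term == "temp_F", ]
  f <- 68.3
  c_val <- f * e$unit_factor + e$unit_offset
  back <- (c_val - e$unit_offset) / e$unit_factor
  expect_lt(abs(back - f) / f, 1e-9)
})

test_that("identity rows with non-trivial conversions are rejected at load", {
  p <- tempfile(fileext = ".csv")
  writeLines(c(
    "source_standard,source_term,target_term,unit_factor,unit_offset,notes",
    "std,datetime,datetime,2,0,"
  ), p)
  expect_error(load_crosswalk(p, "hydrologic_monitoring"), "identity row")
})
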