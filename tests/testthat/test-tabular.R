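test_that("parse_csv keeps cells verbatim and rejects ragged/empty input", {
  doc <- doc_from_text("a,b\n1,2\n")
  expect_equal(doc$header, c("a", "b"))
  expect_equal(nrow(doc$data), 1)
  # RFC 4180 quoted embedded comma stays one cell
  doc <- doc_from_text("x,y\n\"1,5\",2\n")
  expect_equal(doc$data$x, "1,5")
  # header names preserved verbatim, no repair
  doc <- doc_from_text("My Column,other name\n1,2\n")
  expect_equal(doc$header, c("My Column", "other name"))
  expect_error(doc_from_text("a,b\n1\n"), "ragged row.*row 2")
  expect_error(doc_from_text(""), "empty")
  expect_error(parse_csv(tempfile()), "not found")
})

test_that("CSV write/parse round-trips a document identically", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(1:15, 1)
    df <- tibble::tibble(
      id = as.character(seq_len(n)),
      txt = replicate(n, paste(sample(c(letters, ",", "\"", " "),
                                      sample(1:8, 1), replace = TRUE),
                               collapse = "")),
      num = as.character(round(stats::rnorm(n), 3))
    )
    doc <- reportfmt:::as_table_document(df, "rt.csv")
    path <- tempfile(fileext = ".csv")
    write_table_csv(doc, path)
    doc2 <- parse_csv(path, source_name = "rt.csv")
    expect_identical(doc2$header, doc$header)
    expect_identical(as.data.frame(doc2$data), as.data.frame(doc$data))
  }
})

test_that("check_date accepts exactly zero-padded real calendar dates", {
  res <- check_date(c("2021-03-05", "03/05/2021", "2021-02-30",
                      "2021-3-05", "2020-02-29", "2021-13-01", ""))
  expect_equal(res$valid,
               c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(res$reason[2], "bad_pattern")
  expect_equal(res$reason[3], "bad_calendar_date")  # Feb has 28 days in 2021
  expect_equal(res$reason[4], "bad_pattern")        # not zero-padded
  expect_equal(res$reason[6], "bad_calendar_date")  # month 13
  expect_equal(res$date[1], as.Date("2021-03-05"))
})

test_that("check_datetime accepts ISO 8601 and flags naive times", {
  res <- check_datetime(c(
    "2021-06-01T10:00:00Z", "2021-06-01 10:00:00", "2021-06-01",
    "2021-06-01T25:00:00Z", "2021-06-01T10:00:00+02:00", "June 1 2021"
  ))
  expect_equal(res$valid, c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(res$naive, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(res$reason[4], "bad_time")
})

test_that("coordinate bounds are closed intervals", {
  expect_true(check_coordinate(90, "latitude"))
  expect_true(check_coordinate(-90, "latitude"))
  expect_false(check_coordinate(90.0001, "latitude"))
  expect_true(check_coordinate(-180, "longitude"))
  expect_true(check_coordinate(180, "longitude"))
  expect_false(check_coordinate(-180.0001, "longitude"))
})

test_that("profiling respects missing codes and mixes", {
  doc <- doc_from_text("v\n1.2\n-9999\n3.4\n")
  p <- profile_columns(doc)
  expect_equal(p$inferred_type, "decimal")
  expect_false(p$mixed_type)
  expect_equal(p$missing_count, 1)

  p <- profile_columns(doc_from_text("v\n1.2\nabc\n3.4\n"))
  expect_true(p$mixed_type)

  p <- profile_columns(doc_from_text("v\n\n\n\n"))
  expect_equal(p$inferred_type, "empty")
  expect_equal(p$missing_count, 3)

  # integers promote into decimals, dates into datetimes: not a mix
  p <- profile_columns(doc_from_text("a,b\n1,2021-01-01\n2.5,2021-01-01T10:00:00Z\n"))
  expect_equal(p$inferred_type, c("decimal", "datetime"))
  expect_false(any(p$mixed_type))
})
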