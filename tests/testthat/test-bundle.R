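test_that("parse_flmd returns one record per row and flags duplicates", {
  reg <- test_registry()
  doc <- doc_from_text(paste0(
    "file_name,file_description,file_format,missing_value_codes\n",
    "a.csv,first file,csv,-9999;NA\n",
    "b.csv,second file,csv,\n",
    "c.csv,third file,csv,-9999\n"
  ), "flmd.csv")
  rec <- parse_flmd(doc, reg)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$missing_value_codes[[1]], c("-9999", "NA"))
  expect_true(glance(attr(rec, "report"))$pass)

  dup <- doc_from_text(paste0(
    "file_name,file_description,file_format\n",
    "a.csv,first,csv\na.csv,again,csv\n"
  ), "flmd.csv")
  rec <- parse_flmd(dup, reg)
  expect_true("DUP-FILE" %in% tidy(attr(rec, "report"))$code)

  # schema failure (required column absent) -> report, no records
  bad <- doc_from_text("file_name,notes\na.csv,x\n", "flmd.csv")
  rec <- parse_flmd(bad, reg)
  expect_equal(nrow(rec), 0)
  expect_false(glance(attr(rec, "report"))$pass)
})

test_that("FLMD missing codes feed profiling of the described file", {
  d <- copy_bundle()
  # declare 'n.d.' as a missing code for the chemistry table, then use it
  flmd <- parse_csv(file.path(d, "flmd.csv"))
  j <- flmd$data$file_name == "water_soil_chemistry.csv"
  flmd$data$missing_value_codes[j] <- "-9999;n.d."
  write_table_csv(flmd, file.path(d, "flmd.csv"))
  chem <- parse_csv(file.path(d, "water_soil_chemistry.csv"))
  chem$data$value[3] <- "n.d."
  write_table_csv(chem, file.path(d, "water_soil_chemistry.csv"))
  iss <- tidy(validate_bundle(d))
  # the coded cell is treated as missing: no type error, no mixed column
  expect_false(any(iss$code %in% c("TYPE-MISMATCH", "MIXED-TYPE")))
})

test_that("IGSN syntax: prefix optional, case-insensitive with warning", {
  res <- validate_igsn(c("IGSN:IEXYZ0001", "IEXYZ0001", "igsn:iexyz0001",
                         "", "IGSN:X1", "IE XYZ001"))
  expect_equal(res$valid, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$case_normalized[3], TRUE)
  expect_equal(res$normalized[3], "IGSN:IEXYZ0001")
  expect_equal(res$reason[4], "empty")
  expect_equal(res$reason[5], "bad_syntax")
})

test_that("bundle cross-check is symmetric-complete on the file sets", {
  d <- copy_bundle()
  # one described-but-absent file, one on-disk-but-undescribed file
  flmd <- parse_csv(file.path(d, "flmd.csv"))
  extra <- flmd$data[nrow(flmd$data), ]
  extra$file_name <- "ghost.csv"
  flmd$data <- dplyr::bind_rows(flmd$data, extra)
  write_table_csv(flmd, file.path(d, "flmd.csv"))
  writeLines(c("x", "1"), file.path(d, "orphan.csv"))

  iss <- tidy(crosscheck_bundle(read_bundle(d, test_registry()), test_registry()))
  on_disk <- setdiff(list.files(d), "manifest.json")
  listed <- parse_flmd(parse_csv(file.path(d, "flmd.csv")),
                       test_registry())$file_name
  expect_setequal(iss$column[iss$code == "FILE-UNDESCRIBED"],
                  setdiff(on_disk, listed))
  expect_equal(sum(iss$code == "FILE-MISSING"), length(setdiff(listed, on_disk)))
  expect_true(all(grepl("ghost.csv",
                        iss$message[iss$code == "FILE-MISSING"])))
})

test_that("unresolved sample references name cell and registry", {
  d <- copy_bundle()
  chem <- parse_csv(file.path(d, "water_soil_chemistry.csv"))
  chem$data$sample_id[4] <- "S-003"
  write_table_csv(chem, file.path(d, "water_soil_chemistry.csv"))
  iss <- tidy(validate_bundle(d))
  hit <- iss[iss$code == "REF-UNRESOLVED", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$row, 5L)  # data row 4, header counts as row 1
  expect_equal(hit$column, "sample_id")
  expect_match(hit$message, "S-003")
  expect_match(hit$message, "sample_metadata")
})

test_that("model checklist evaluation is advisory only", {
  reg <- test_registry()
  cl <- tibble::tibble(
    item = c("code_reference", "inputs", "configuration", "outputs",
             "postprocessing_scripts", "documentation"),
    status = c("present", "present", "not_applicable", "absent",
               "present", "present"),
    evidence = ""
  )
  rep <- evaluate_model_checklist(cl, registry = reg)
  iss <- tidy(rep)
  expect_true(glance(rep)$pass)            # warnings never fail a bundle
  expect_equal(iss$code, "MODEL-ITEM-ABSENT")
  expect_match(iss$message, "outputs")
  all_present <- cl; all_present$status <- "present"
  expect_equal(nrow(tidy(evaluate_model_checklist(all_present, registry = reg))), 0)
})
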