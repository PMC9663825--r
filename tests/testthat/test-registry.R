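test_that("packaged registry holds the 11 formats, 6 cross-domain + 5 domain", {
  reg <- test_registry()
  info <- tidy(reg)
  expect_equal(nrow(info), 11)
  expect_equal(sum(info$category == "cross_domain"), 6)
  expect_equal(sum(info$category == "domain_specific"), 5)
  # deterministic ordering: cross-domain first, alphabetical within category
  expect_equal(info$id[1:6], sort(info$id[1:6]))
  expect_equal(info$id[7:11], sort(info$id[7:11]))
  expect_true(all(info$category[1:6] == "cross_domain"))
  # lookup is total over the published ids
  for (id in info$id) expect_s3_class(get_schema(reg, id), "reporting_format_schema")
  expect_error(get_schema(reg, "nope"), "unknown schema id")
})

test_that("schema invariants are enforced at load time", {
  d <- tempfile(); dir.create(d)
  expect_error(load_registry(d), "no schema files")
  # controlled type without vocabulary is rejected, naming the file
  writeLines(c(
    "id: broken", "title: Broken", "category: cross_domain",
    "version: '1'", "table_rules: []", "fields:",
    "  - name: x", "    requirement: required", "    value_type: controlled"
  ), file.path(d, "broken.yaml"))
  expect_error(load_registry(d), "broken.yaml.*vocabulary")
  # bounds with min > max rejected
  writeLines(c(
    "id: b2", "title: B2", "category: cross_domain",
    "version: '1'", "fields:",
    "  - name: x", "    requirement: required", "    value_type: decimal",
    "    bounds: [5, 1]"
  ), file.path(d, "broken.yaml"))
  expect_error(load_registry(d), "min <= max")
})

test_that("recommend_formats walks the applicability workflow", {
  reg <- test_registry()
  expect_equal(recommend_formats(dataset_profile(), reg), "dataset_metadata")
  expect_equal(
    recommend_formats(dataset_profile(
      has_tabular_data = TRUE, has_samples = TRUE,
      domain_data_types = "water_soil_chemistry"
    ), reg),
    c("dataset_metadata", "file_level_metadata", "csv_guidelines",
      "sample_metadata", "water_soil_chemistry")
  )
  # an amplicon study with samples pulls in both the sample-id format and
  # the amplicon format (IGSN linkage between them)
  got <- recommend_formats(dataset_profile(
    has_samples = TRUE, domain_data_types = "amplicon"
  ), reg)
  expect_true(all(c("sample_metadata", "amplicon_abundance") %in% got))
  expect_error(dataset_profile(domain_data_types = "seismology"),
               "valid tags")
})

test_that("recommend_formats is monotone and resolves in the registry", {
  reg <- test_registry()
  flags <- c("has_tabular_data", "has_samples", "has_locations",
             "has_model_output")
  tags <- c("amplicon", "leaf_gas_exchange", "soil_respiration",
            "water_soil_chemistry", "hydrologic_monitoring")
  set.seed(11)
  for (i in 1:30) {
    on <- sample(c(TRUE, FALSE), 4, replace = TRUE)
    tg <- sample(tags, sample(0:5, 1))
    args <- as.list(stats::setNames(on, flags))
    args$domain_data_types <- tg
    base <- recommend_formats(do.call(dataset_profile, args), reg)
    expect_true(all(base %in% names(reg$schemas)))
    expect_false(anyDuplicated(base) > 0)
    # adding one more flag or tag never removes a recommendation
    off <- which(!on)
    if (length(off)) {
      args2 <- args; args2[[flags[off[1]]]] <- TRUE
      grown <- recommend_formats(do.call(dataset_profile, args2), reg)
      expect_true(all(base %in% grown))
    }
    more <- setdiff(tags, tg)
    if (length(more)) {
      args3 <- args; args3$domain_data_types <- c(tg, more[1])
      grown <- recommend_formats(do.call(dataset_profile, args3), reg)
      expect_true(all(base %in% grown))
    }
  }
})
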