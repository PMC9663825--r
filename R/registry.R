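#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

CROSS_DOMAIN_IDS <- c(
  "dataset_metadata", "file_level_metadata", "csv_guidelines",
  "sample_metadata", "location_metadata", "model_archiving"
)
DOMAIN_SPECIFIC_IDS <- c(
  "amplicon_abundance", "leaf_gas_exchange", "soil_respiration",
  "water_soil_chemistry", "hydrologic_monitoring"
)
DOMAIN_TAGS <- c(
  amplicon = "amplicon_abundance",
  leaf_gas_exchange = "leaf_gas_exchange",
  soil_respiration = "soil_respiration",
  water_soil_chemistry = "water_soil_chemistry",
  hydrologic_monitoring = "hydrologic_monitoring"
)

VALUE_TYPES <- c(
  "text", "integer", "decimal", "date", "datetime",
  "latitude", "longitude", "identifier", "controlled"
)

# Read and check one schema YAML file. Violated invariants name the file.
read_schema_file <- function(path) {
  s <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("malformed schema file '", basename(path), "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fail <- function(what) {
    stop("schema file '", basename(path), "' violates invariant: ", what,
         call. = FALSE)
  }
  for (key in c("id", "title", "category", "version")) {
    if (is.null(s[[key]]) || !nzchar(s[[key]])) fail(paste0("missing ", key))
  }
  if (!s$category %in% c("cross_domain", "domain_specific")) {
    fail("category must be cross_domain or domain_specific")
  }
  fields <- purrr::map(s$fields, function(f) {
    if (is.null(f$name) || !nzchar(f$name)) fail("field with empty name")
    if (!f$requirement %in% c("required", "optional")) {
      fail(paste0("field '", f$name, "' has invalid requirement"))
    }
    if (!f$value_type %in% VALUE_TYPES) {
      fail(paste0("field '", f$name, "' has invalid value_type"))
    }
    vocab <- as.character(f$vocabulary %||% character())
    if ((f$value_type == "controlled") != (length(vocab) > 0)) {
      fail(paste0("field '", f$name,
                  "': vocabulary must be non-empty iff value_type=controlled"))
    }
    bounds <- f$bounds
    if (!is.null(bounds)) {
      if (!f$value_type %in% c("integer", "decimal", "latitude", "longitude")) {
        fail(paste0("field '", f$name, "': bounds on non-numeric type"))
      }
      bounds <- as.numeric(bounds)
      if (length(bounds) != 2 || bounds[1] > bounds[2]) {
        fail(paste0("field '", f$name, "': bounds must be (min, max), min <= max"))
      }
    }
    list(
      name = f$name,
      requirement = f$requirement,
      value_type = f$value_type,
      units = f$units %||% "",
      vocabulary = vocab,
      vocabulary_open = isTRUE(f$vocabulary_open),
      pattern = f$pattern %||% "",
      bounds = bounds,
      description = f$description %||% ""
    )
  })
  names_ <- purrr::map_chr(fields, "name")
  if (anyDuplicated(names_)) fail("duplicate field names")
  table_rules <- as.character(s$table_rules %||% character())
  n_required <- sum(purrr::map_chr(fields, "requirement") == "required")
  if (n_required == 0 && length(table_rules) == 0) {
    fail("schema must declare at least one required field or table rule")
  }
  structure(
    list(
      id = s$id, title = s$title, category = s$category,
      version = s$version, fields = fields, table_rules = table_rules,
      applies_to = as.character(s$applies_to %||% character()),
      extra_columns = s$extra_columns %||% "context"
    ),
    class = "reporting_format_schema"
  )
}

#' Load the reporting-format schema registry
#'
#' Reads every schema file in `schema_dir` (by default the registry of 11
#' formats packaged with reportfmt), checks each schema's invariants, and
#' asserts the registry-level invariants: exactly 11 schemas partitioned
#' into 6 cross-domain and 5 domain-specific formats when the packaged
#' directory is used. Schemas are ordered deterministically: cross-domain
#' first, then domain-specific, alphabetically by id within each category.
#'
#' @param schema_dir Directory of schema YAML files; `NULL` for the
#'   packaged registry.
#' @return A `schema_registry` object.
#' @export
#' @examples
#' reg <- load_registry()
#' tidy(reg)
load_registry <- function(schema_dir = NULL) {
  packaged <- is.null(schema_dir)
  if (packaged) {
    schema_dir <- system.file("schemas", package = "reportfmt", mustWork = TRUE)
  }
  files <- sort(list.files(schema_dir, pattern = "\\.ya?ml$", full.names = TRUE))
  if (length(files) == 0) {
    stop("no schema files found in '", schema_dir, "'", call. = FALSE)
  }
  schemas <- purrr::map(files, read_schema_file)
  ids <- purrr::map_chr(schemas, "id")
  if (anyDuplicated(ids)) {
    stop("duplicate schema ids in registry: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  cats <- purrr::map_chr(schemas, "category")
  ord <- order(match(cats, c("cross_domain", "domain_specific")), ids)
  schemas <- schemas[ord]
  names(schemas) <- ids[ord]
  if (packaged) {
    stopifnot(
      length(schemas) == 11,
      sum(cats == "cross_domain") == 6,
      sum(cats == "domain_specific") == 5,
      all(sort(ids) == sort(c(CROSS_DOMAIN_IDS, DOMAIN_SPECIFIC_IDS)))
    )
  }
  crosswalk_dir <- system.file("extdata", "crosswalks", package = "reportfmt")
  crosswalks <- sort(list.files(crosswalk_dir, pattern = "\\.csv$",
                                full.names = TRUE))
  structure(
    list(schemas = schemas, crosswalks = crosswalks),
    class = "schema_registry"
  )
}

#' Look up one schema in a registry
#'
#' @param registry A `schema_registry`.
#' @param id Schema id (one of the 11 published slugs).
#' @return A `reporting_format_schema`.
#' @export
get_schema <- function(registry, id) {
  stopifnot(inherits(registry, "schema_registry"))
  s <- registry$schemas[[id]]
  if (is.null(s)) {
    stop("unknown schema id '", id, "'; valid ids: ",
         paste(names(registry$schemas), collapse = ", "), call. = FALSE)
  }
  s
}

#' @export
print.schema_registry <- function(x, ...) {
  cat("<schema_registry> of", length(x$schemas), "reporting formats\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a schema registry into a one-row-per-format tibble
#'
#' @param x A `schema_registry`.
#' @param ... Unused.
#' @export
tidy.schema_registry <- function(x, ...) {
  purrr::map_dfr(x$schemas, function(s) {
    tibble::tibble(
      id = s$id, title = s$title, category = s$category,
      version = s$version,
      n_fields = length(s$fields),
      n_required = sum(purrr::map_chr(s$fields, "requirement") == "required"),
      table_rules = paste(s$table_rules, collapse = ";")
    )
  })
}

#' Tidy a reporting-format schema into its field table
#'
#' @param x A `reporting_format_schema`.
#' @param ... Unused.
#' @return Tibble with one row per field: name, requirement, value_type,
#'   units, vocabulary, pattern, bounds, description.
#' @export
tidy.reporting_format_schema <- function(x, ...) {
  purrr::map_dfr(x$fields, function(f) {
    tibble::tibble(
      name = f$name, requirement = f$requirement,
      value_type = f$value_type, units = f$units,
      vocabulary = paste(f$vocabulary, collapse = "|"),
      pattern = f$pattern,
      bounds = if (is.null(f$bounds)) "" else paste(f$bounds, collapse = ".."),
      description = f$description
    )
  })
}

#' @export
print.reporting_format_schema <- function(x, ...) {
  cat(sprintf("<reporting_format_schema> %s (%s, %s) v%s\n",
              x$id, x$title, x$category, x$version))
  if (length(x$table_rules)) {
    cat("table rules:", paste(x$table_rules, collapse = ", "), "\n")
  }
  if (length(x$fields)) print(tidy(x)[, 1:4])
  invisible(x)
}

#' Describe a dataset for format recommendation
#'
#' Captures the yes/no answers of the applicability workflow: does the
#' dataset contain tabular data files, physical samples, named research
#' locations, model output, and which of the five domain data types.
#'
#' @param has_tabular_data,has_samples,has_locations,has_model_output Flags.
#' @param domain_data_types Character subset of
#'   `c("amplicon", "leaf_gas_exchange", "soil_respiration",
#'   "water_soil_chemistry", "hydrologic_monitoring")`.
#' @return A `dataset_profile` object.
#' @export
dataset_profile <- function(has_tabular_data = FALSE, has_samples = FALSE,
                            has_locations = FALSE, has_model_output = FALSE,
                            domain_data_types = character()) {
  bad <- setdiff(domain_data_types, names(DOMAIN_TAGS))
  if (length(bad)) {
    stop("unknown domain data type(s): ", paste(bad, collapse = ", "),
         "; valid tags: ", paste(names(DOMAIN_TAGS), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      has_tabular_data = isTRUE(has_tabular_data),
      has_samples = isTRUE(has_samples),
      has_locations = isTRUE(has_locations),
      has_model_output = isTRUE(has_model_output),
      domain_data_types = unique(domain_data_types)
    ),
    class = "dataset_profile"
  )
}

#' Recommend the reporting formats that apply to a dataset
#'
#' Walks the applicability workflow: dataset metadata always applies;
#' tabular data pulls in file-level metadata and the CSV guidelines;
#' samples, locations and model output pull in their respective formats;
#' each declared domain data type pulls in its domain format. Any domain
#' data type implies tabular data (all five domain formats are CSV-based).
#'
#' @param profile A [dataset_profile()].
#' @param registry A loaded [load_registry()] (defaults to the packaged one).
#' @return Character vector of schema ids in workflow order, no duplicates.
#' @export
#' @examples
#' recommend_formats(dataset_profile(has_tabular_data = TRUE,
#'                                   has_samples = TRUE,
#'                                   domain_data_types = "water_soil_chemistry"))
recommend_formats <- function(profile, registry = load_registry()) {
  stopifnot(inherits(profile, "dataset_profile"),
            inherits(registry, "schema_registry"))
  ids <- "dataset_metadata"
  tabular <- profile$has_tabular_data || length(profile$domain_data_types) > 0
  if (tabular) ids <- c(ids, "file_level_metadata", "csv_guidelines")
  if (profile$has_samples) ids <- c(ids, "sample_metadata")
  if (profile$has_locations) ids <- c(ids, "location_metadata")
  if (profile$has_model_output) ids <- c(ids, "model_archiving")
  domain <- unname(DOMAIN_TAGS[intersect(names(DOMAIN_TAGS),
                                         profile$domain_data_types)])
  ids <- unique(c(ids, domain))
  stopifnot(all(ids %in% names(registry$schemas)))
  ids
}

`%||%` <- function(x, y) if (is.null(x)) y else x
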