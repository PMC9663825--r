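# Dataset-level metadata: the citation/discovery record every bundle
# carries. Accepted as JSON (canonical) or a flat CSV field/value
# template; both land in the same in-memory structure.

new_dataset_metadata <- function(title = "", abstract = "", creators = list(),
                                 keywords = character(),
                                 temporal_coverage = list(start = "", end = ""),
                                 spatial_coverage = list(),
                                 funding = "", related_identifiers = character()) {
  structure(
    list(
      title = title %||% "", abstract = abstract %||% "",
      creators = creators %||% list(),
      keywords = as.character(keywords %||% character()),
      temporal_coverage = list(
        start = temporal_coverage$start %||% "",
        end = temporal_coverage$end %||% ""
      ),
      spatial_coverage = spatial_coverage %||% list(),
      funding = funding %||% "",
      related_identifiers = as.character(related_identifiers %||% character())
    ),
    class = "dataset_metadata"
  )
}

#' Read dataset metadata from JSON or the flat CSV template
#'
#' @param path A `.json` document or a two-column `field,value` CSV
#'   template. In the CSV template, creators are `name|affiliation|id`
#'   triples separated by `;`, spatial points `latitude|longitude|description`
#'   triples separated by `;`, keywords and related identifiers `;`-separated.
#' @return A `dataset_metadata` object.
#' @export
read_dataset_metadata <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    creators <- purrr::map(x$creators, function(p) {
      list(name = p$name %||% "", affiliation = p$affiliation %||% "",
           identifier = p$identifier %||% "")
    })
    spatial <- purrr::map(x$spatial_coverage, function(p) {
      list(latitude = as.numeric(p$latitude), longitude = as.numeric(p$longitude),
           description = p$description %||% "")
    })
    return(new_dataset_metadata(
      title = x$title, abstract = x$abstract, creators = creators,
      keywords = unlist(x$keywords),
      temporal_coverage = list(start = x$temporal_coverage$start %||% "",
                               end = x$temporal_coverage$end %||% ""),
      spatial_coverage = spatial, funding = x$funding,
      related_identifiers = unlist(x$related_identifiers)
    ))
  }
  doc <- parse_csv(path)
  if (!all(c("field", "value") %in% doc$header)) {
    stop("dataset metadata CSV template must have 'field' and 'value' columns",
         call. = FALSE)
  }
  kv <- stats::setNames(doc$data$value, doc$data$field)
  get <- function(k) unname(kv[k] %|NA|% "")
  split_multi <- function(x) {
    x <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    x[nzchar(x)]
  }
  creators <- purrr::map(split_multi(get("creators")), function(s) {
    p <- trimws(strsplit(s, "|", fixed = TRUE)[[1]])
    list(name = p[1] %|NA|% "", affiliation = p[2] %|NA|% "",
         identifier = p[3] %|NA|% "")
  })
  spatial <- purrr::map(split_multi(get("spatial_coverage")), function(s) {
    p <- trimws(strsplit(s, "|", fixed = TRUE)[[1]])
    list(latitude = as.numeric(p[1]), longitude = as.numeric(p[2]),
         description = p[3] %|NA|% "")
  })
  new_dataset_metadata(
    title = get("title"), abstract = get("abstract"), creators = creators,
    keywords = split_multi(get("keywords")),
    temporal_coverage = list(start = get("temporal_coverage_start"),
                             end = get("temporal_coverage_end")),
    spatial_coverage = spatial, funding = get("funding"),
    related_identifiers = split_multi(get("related_identifiers"))
  )
}

`%|NA|%` <- function(x, y) {
  if (length(x) == 0 || is.na(x)) y else x
}

# Length-check defaults (warnings only): a title should carry roughly a
# sentence of information, an abstract at least a short paragraph.
TITLE_MIN_CHARS <- 40
ABSTRACT_MIN_CHARS <- 100

#' Validate dataset-level metadata
#'
#' Checks field presence (title, abstract, at least one creator), format
#' (harmonized dates, coordinate bounds, temporal ordering) and length
#' (configurable minimums, warnings only).
#'
#' @param md A `dataset_metadata` object.
#' @param file File name used in issue locations.
#' @param title_min,abstract_min Minimum lengths (characters) below which a
#'   `LEN-SHORT` warning is raised.
#' @return A [validation_report()].
#' @export
validate_dataset_metadata <- function(md, file = "dataset_metadata.json",
                                      title_min = TITLE_MIN_CHARS,
                                      abstract_min = ABSTRACT_MIN_CHARS) {
  stopifnot(inherits(md, "dataset_metadata"))
  sid <- "dataset_metadata"
  issues <- list()
  add <- function(code, column, message) {
    issues[[length(issues) + 1]] <<- new_issues(code, file, NA_integer_,
                                                column, message, sid)
  }
  if (!nzchar(md$title)) add("REQ-MISSING", "title", "title is required")
  if (!nzchar(md$abstract)) add("REQ-MISSING", "abstract", "abstract is required")
  if (length(md$creators) == 0) {
    add("REQ-MISSING", "creators", "at least one creator is required")
  }
  if (nzchar(md$title) && nchar(md$title) < title_min) {
    add("LEN-SHORT", "title",
        sprintf("title has %d characters; at least %d recommended",
                nchar(md$title), title_min))
  }
  if (nzchar(md$abstract) && nchar(md$abstract) < abstract_min) {
    add("LEN-SHORT", "abstract",
        sprintf("abstract has %d characters; at least %d recommended",
                nchar(md$abstract), abstract_min))
  }
  tc <- md$temporal_coverage
  dates_ok <- c(start = FALSE, end = FALSE)
  for (k in c("start", "end")) {
    if (!nzchar(tc[[k]])) next
    chk <- check_date(tc[[k]])
    if (!chk$valid) {
      add(if (chk$reason == "bad_pattern") "DATE-FORMAT" else "DATE-CALENDAR",
          paste0("temporal_coverage_", k),
          sprintf("'%s' is not a valid YYYY-MM-DD date", tc[[k]]))
    } else {
      dates_ok[k] <- TRUE
    }
  }
  if (all(dates_ok) && as.Date(tc$start) > as.Date(tc$end)) {
    add("META-TEMPORAL-ORDER", "temporal_coverage_start",
        sprintf("temporal coverage start %s is after end %s", tc$start, tc$end))
  }
  for (i in seq_along(md$spatial_coverage)) {
    p <- md$spatial_coverage[[i]]
    if (!is.na(p$latitude) && !check_coordinate(p$latitude, "latitude")) {
      add("COORD-BOUNDS", "spatial_coverage",
          sprintf("latitude %s outside [-90, 90] (point %d)", p$latitude, i))
    }
    if (!is.na(p$longitude) && !check_coordinate(p$longitude, "longitude")) {
      add("COORD-BOUNDS", "spatial_coverage",
          sprintf("longitude %s outside [-180, 180] (point %d)", p$longitude, i))
    }
  }
  validation_report(dplyr::bind_rows(issues), files_checked = file,
                    schemas_applied = sid)
}

#' Export dataset metadata as schema.org Dataset JSON-LD
#'
#' Emits a schema.org-`Dataset`-profiled JSON-LD document with a fixed,
#' deterministic key order; the harmonized `title` maps to schema.org
#' `name`, `abstract` to `description`. Export is refused when presence
#' checks fail (the refusal condition carries the validation report).
#' Lossless for all populated fields: [import_dataset_metadata_jsonld()]
#' inverts it.
#'
#' @param md A `dataset_metadata` object.
#' @param path Optional file to write the JSON to.
#' @return The JSON-LD document as a named list (invisibly if `path` given).
#' @export
export_dataset_metadata_jsonld <- function(md, path = NULL) {
  rep <- validate_dataset_metadata(md)
  presence <- rep$issues[rep$issues$code == "REQ-MISSING", , drop = FALSE]
  if (nrow(presence) > 0) {
    rlang::abort(
      paste0("cannot export JSON-LD: missing required field(s): ",
             paste(presence$column, collapse = ", ")),
      class = "reportfmt_export_refused", report = rep
    )
  }
  doc <- list(
    `@context` = "https://schema.org/",
    `@type` = "Dataset",
    name = md$title,
    description = md$abstract,
    creator = purrr::map(md$creators, function(p) {
      list(`@type` = "Person", name = p$name,
           affiliation = p$affiliation, identifier = p$identifier)
    }),
    keywords = as.list(md$keywords),
    temporalCoverage = if (nzchar(md$temporal_coverage$start) ||
                           nzchar(md$temporal_coverage$end)) {
      paste0(md$temporal_coverage$start, "/", md$temporal_coverage$end)
    } else {
      ""
    },
    spatialCoverage = purrr::map(md$spatial_coverage, function(p) {
      list(`@type` = "Place", description = p$description,
           geo = list(`@type` = "GeoCoordinates",
                      latitude = p$latitude, longitude = p$longitude))
    }),
    funder = md$funding,
    citation = as.list(md$related_identifiers)
  )
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(doc))
  }
  doc
}

#' Import dataset metadata from its JSON-LD export
#'
#' @param x A file path to a JSON-LD document or the list produced by
#'   [export_dataset_metadata_jsonld()].
#' @return A `dataset_metadata` object.
#' @export
import_dataset_metadata_jsonld <- function(x) {
  if (is.character(x)) x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  tc <- strsplit(x$temporalCoverage %||% "/", "/", fixed = TRUE)[[1]]
  new_dataset_metadata(
    title = x$name, abstract = x$description,
    creators = purrr::map(x$creator, function(p) {
      list(name = p$name %||% "", affiliation = p$affiliation %||% "",
           identifier = p$identifier %||% "")
    }),
    keywords = unlist(x$keywords),
    temporal_coverage = list(start = tc[1] %|NA|% "", end = tc[2] %|NA|% ""),
    spatial_coverage = purrr::map(x$spatialCoverage, function(p) {
      list(latitude = as.numeric(p$geo$latitude),
           longitude = as.numeric(p$geo$longitude),
           description = p$description %||% "")
    }),
    funding = x$funder,
    related_identifiers = unlist(x$citation)
  )
}

#' @export
print.dataset_metadata <- function(x, ...) {
  cat("<dataset_metadata>", x$title, "\n")
  cat(" ", length(x$creators), "creator(s);",
      length(x$spatial_coverage), "spatial point(s)\n")
  invisible(x)
}
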