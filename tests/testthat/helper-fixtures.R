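# Shared fixtures built in code. The full valid bundle (all 11 formats,
# fixed seed) is generated once per test run and copied where a test
# needs to mutate it.

.fixture_cache <- new.env(parent = emptyenv())

base_bundle_dir <- function() {
  if (is.null(.fixture_cache$dir)) {
    dir <- file.path(tempdir(), "reportfmt-base-bundle")
    unlink(dir, recursive = TRUE)
    generate_bundle(fixture_spec(seed = 42), dir)
    .fixture_cache$dir <- dir
  }
  .fixture_cache$dir
}

base_bundle_report <- function() {
  if (is.null(.fixture_cache$report)) {
    .fixture_cache$report <- validate_bundle(base_bundle_dir())
  }
  .fixture_cache$report
}

copy_bundle <- function(from = base_bundle_dir()) {
  to <- tempfile("bundle")
  dir.create(to)
  file.copy(list.files(from, full.names = TRUE), to)
  to
}

test_registry <- function() {
  if (is.null(.fixture_cache$registry)) {
    .fixture_cache$registry <- load_registry()
  }
  .fixture_cache$registry
}

doc_from_text <- function(text, source_name = "<text>") {
  parse_csv(I(text), source_name = source_name)
}
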