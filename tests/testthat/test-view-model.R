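simple_view_json <- '{
  "resource": "Patient",
  "select": [{"column": [
    {"name": "id", "path": "id"},
    {"name": "birth_date", "path": "birthDate"}
  ]}]
}'

test_that("view documents parse with defaults applied", {
  v <- parse_view(simple_view_json)
  expect_s3_class(v, "fhir_view")
  expect_identical(v$resource, "Patient")
  expect_length(v$selects, 1L)
  expect_length(v$selects[[1L]]$columns, 2L)
  expect_false(v$selects[[1L]]$columns[[1L]]$collection)
  expect_identical(v$profiles, "base")
})

test_that("structural faults raise parse errors with JSON-pointer locations", {
  no_select <- tryCatch(parse_view('{"resource": "Patient"}'),
                        error = function(e) e)
  expect_s3_class(no_select, "fhir_view_parse_error")
  expect_identical(no_select$location, "/select")

  no_resource <- tryCatch(
    parse_view('{"select": [{"column": [{"name": "id", "path": "id"}]}]}'),
    error = function(e) e
  )
  expect_identical(no_resource$location, "/resource")

  bad_coll <- tryCatch(
    parse_view('{"resource": "Patient", "select": [{"column":
      [{"name": "id", "path": "id", "collection": "yes"}]}]}'),
    error = function(e) e
  )
  expect_s3_class(bad_coll, "fhir_view_parse_error")
  expect_match(bad_coll$location, "collection")

  expect_warning(
    parse_view('{"resource": "Patient", "frobnicate": 1,
      "select": [{"column": [{"name": "id", "path": "id"}]}]}'),
    "frobnicate"
  )
})

test_that("parse-serialize-parse is structurally stable for bundled views", {
  for (v in example_views()) {
    v2 <- parse_view(serialize_view(v))
    expect_identical(v2$selects, v$selects, info = v$name)
    expect_identical(v2$wheres, v$wheres, info = v$name)
    expect_identical(v2$resource, v$resource, info = v$name)
    expect_identical(v2$profiles, v$profiles, info = v$name)
  }
})

test_that("parse-serialize-parse is stable on random views", {
  set.seed(77)
  for (k in 1:50) {
    v <- random_view()
    v2 <- parse_view(serialize_view(v))
    expect_identical(v2$selects, v$selects)
    expect_identical(v2$wheres, v$wheres)
  }
})

test_that("flattened schema follows depth-first document order", {
  v <- example_view("patient_addresses")
  expect_identical(flattened_schema(v)$name,
                   c("id", "address_line", "address_city", "address_state",
                     "address_postal_code"))
  v2 <- parse_view(simple_view_json)
  expect_identical(flattened_schema(v2)$name, c("id", "birth_date"))
  vu <- example_view("patient_contacts_union")
  expect_identical(flattened_schema(vu)$name,
                   c("id", "name", "family", "contact_phone"))
})

test_that("schema is invariant under execution", {
  v <- example_view("patient_addresses_or_null")
  pats <- example_resources("Patient")
  h0 <- execute_view(v, list())$schema
  h1 <- execute_view(v, pats[1L])$schema
  hn <- execute_view(v, pats)$schema
  expect_identical(h0, flattened_schema(v))
  expect_identical(h1, h0)
  expect_identical(hn, h0)
})

make_view <- function(json) suppressWarnings(parse_view(json))

test_that("each base validation code triggers on its construction", {
  cases <- list(
    BAD_COLUMN_NAME = '{"resource": "Patient", "select": [{"column":
      [{"name": "1bad", "path": "id"}]}]}',
    DUPLICATE_COLUMN = '{"resource": "Patient", "select": [
      {"column": [{"name": "id", "path": "id"}]},
      {"column": [{"name": "id", "path": "birthDate"}]}]}',
    UNION_COLUMN_MISMATCH = '{"resource": "Patient", "select": [{"unionAll": [
      {"column": [{"name": "id", "path": "id"}, {"name": "phone", "path": "telecom.first().value"}]},
      {"column": [{"name": "id", "path": "id"}, {"name": "fax", "path": "telecom.first().value"}]}
    ]}]}',
    INVALID_EXPRESSION = '{"resource": "Patient", "select": [{"column":
      [{"name": "id", "path": "resolve()"}]}]}',
    FOREACH_CONFLICT = '{"resource": "Patient", "select": [{
      "forEach": "address", "forEachOrNull": "address",
      "column": [{"name": "city", "path": "city"}]}]}',
    NO_COLUMNS = '{"resource": "Patient", "select": [
      {"column": [{"name": "id", "path": "id"}]},
      {"forEach": "address"}]}'
  )
  for (code in names(cases)) {
    issues <- validate_view(make_view(cases[[code]]))
    expect_identical(sum(issues$code == code), 1L, info = code)
    expect_true(all(issues$severity[issues$code == code] == "error"), info = code)
  }
})

test_that("shareable and tabular profile codes trigger on their constructions", {
  bare <- '{"resource": "Patient", "select": [{"column":
    [{"name": "id", "path": "id"}]}]}'
  issues <- validate_view(make_view(bare), profiles = "shareable")
  for (code in c("MISSING_NAME", "MISSING_VERSION", "MISSING_FHIR_VERSION",
                 "MISSING_COLUMN_TYPE")) {
    expect_identical(sum(issues$code == code), 1L, info = code)
  }

  complex_col <- '{"resource": "Patient", "name": "v", "version": "1",
    "fhirVersion": "4.0.1", "select": [{"column":
    [{"name": "nm", "path": "name.first()", "type": "HumanName"}]}]}'
  issues <- validate_view(make_view(complex_col), profiles = "tabular")
  expect_identical(sum(issues$code == "TABULAR_NONPRIMITIVE"), 1L)

  coll_col <- '{"resource": "Patient", "name": "v", "version": "1",
    "fhirVersion": "4.0.1", "select": [{"column":
    [{"name": "cities", "path": "address.city", "collection": true,
      "type": "string"}]}]}'
  issues <- validate_view(make_view(coll_col), profiles = "tabular")
  expect_identical(sum(issues$code == "TABULAR_COLLECTION"), 1L)
})

test_that("validation is monotone across profile levels", {
  set.seed(31)
  views <- c(
    example_views(),
    lapply(1:20, function(k) random_view()),
    list(make_view('{"resource": "Patient", "select": [{"column":
      [{"name": "nm", "path": "name.first()", "type": "HumanName"}]}]}'))
  )
  for (v in views) {
    base <- validate_view(v, profiles = "base")
    shareable <- validate_view(v, profiles = "shareable")
    tabular <- validate_view(v, profiles = c("shareable", "tabular"))
    key <- function(df) paste(df$code, df$location)
    expect_true(all(key(base) %in% key(shareable)))
    expect_true(all(key(shareable) %in% key(tabular)))
  }
})

test_that("every bundled view passes the shareable profile", {
  for (v in example_views()) {
    issues <- validate_view(v, profiles = "shareable")
    expect_identical(nrow(issues[issues$severity == "error", ]), 0L,
                     info = v$name)
  }
})
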