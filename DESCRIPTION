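Package: fhirtable
Title: Tabular View Definitions over FHIR Resources
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evaluates declarative, FHIRPath-based view definitions over FHIR
    R4 resources and emits tabular output. Implements a view runner for a
    JSON view-definition dialect: column projection, forEach and
    forEachOrNull unnesting, unionAll concatenation, where-based inclusion
    criteria, progressive validation profiles (base, shareable, tabular), and
    the getResourceKey()/getReferenceKey() join-key abstraction that lets
    views of referencing resource types be combined with an equijoin. Reads
    newline-delimited JSON or JSON-array resource files, writes RFC 4180 CSV
    or row-stream NDJSON, and ships a seeded synthetic corpus generator plus a
    declarative test-case runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
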