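# fhirtable

Clinical data exchanged as FHIR (Fast Healthcare Interoperability
Resources) arrives as deeply nested JSON: a single Patient resource can
carry repeating names, addresses and telecom entries, and analytic work —
statistics in R, SQL queries, spreadsheets, ML feature tables — wants flat,
rectangular tables instead. `fhirtable` is a **view runner**: it executes
declarative *view definitions* — JSON documents that describe a tabular
projection of one FHIR resource type using FHIRPath expressions — over
streams of FHIR R4 resources, and emits CSV or row-stream NDJSON.

It is aimed at health-informatics engineers and analysts who need a
portable, dependency-light way to turn bulk FHIR exports (NDJSON files)
into analysis-ready tables without standing up a FHIR server or a Spark
cluster.

## The model

A view definition names a resource type and contains:

* **`select`** directives, each holding `column` definitions
  (`name` + FHIRPath `path`), and optionally:
  * **`forEach` / `forEachOrNull`** — unnest a collection, producing one
    row per element. `forEach` behaves like an SQL `INNER JOIN` (a resource
    with an empty collection is omitted); `forEachOrNull` behaves like an
    `OUTER JOIN` (one row with nulls is kept).
  * **`unionAll`** — concatenate several selections that share one column
    list.
  * nested **`select`** — recursive unnesting of deeper structures.
* **`where`** directives — FHIRPath inclusion criteria; a resource is kept
  only if every expression evaluates to `true`.

Sibling selects are combined by cross-join (Cartesian product), so the row
count for one resource is `Σ_items Π_nested × Σ_union` per select,
multiplied across sibling selects — an algebra `count_rows()` implements
directly and the tests verify against materialized output.

Cross-resource joins are handled by two FHIRPath functions evaluated by the
runner: `getResourceKey()` yields a key unique to each resource, and
`getReferenceKey(Type)` yields the key of the resource a Reference points
at, so two views can be combined with an ordinary equijoin
(`table_equijoin()`).

Views declare conformance **profiles** that `validate_view()` enforces
progressively: *base* (structural rules only), *shareable* (adds naming,
versioning, FHIR version and a declared type per column), and *tabular*
(scalar primitive columns only, so the output is CSV-safe).

The FHIRPath dialect is the subset these views need: path navigation with
choice-type (`value[x]`) resolution, `[n]` indexing, literals, `= != < <= >
>= and or`, and `where() exists() empty() first() not() ofType()
extension()` plus the two key functions. Anything outside the subset (for
example `resolve()`) is rejected at parse time with a character offset.

## Worked example

```r
library(fhirtable)

view <- example_view("patient_addresses")    # forEach over Patient.address
patients <- example_resources("Patient")
as.data.frame(execute_view(view, patients))
#>          id  address_line address_city address_state address_postal_code
#> 1 patient-1     1 Main St  Springfield            IL               62701
#> 2 patient-1 42 Second Ave      Chicago            IL               60601
#> 3 patient-1  789 Third St       Peoria            IL               61602
#> 4 patient-3 42 Second Ave      Chicago            IL               60601
```

Patient `patient-1` has three addresses, so `forEach` gives it three rows;
`patient-2` has none and is omitted. Switching the view to
`example_view("patient_addresses_or_null")` keeps `patient-2` as a fifth
row of nulls. Joining two key-bearing views:

```r
pv <- execute_view(example_view("patient_join"), patients, key_strategy("display"))
ev <- execute_view(example_view("encounter_join"),
                   example_resources("Encounter"), key_strategy("display"))
as.data.frame(table_equijoin(pv, ev, "patient_id"))
#>   patient_id  name    family encounter_id encounter_date
#> 1  patient-1 Aisha      Khan  encounter-1     2023-01-01
#> 2  patient-1 Aisha      Khan  encounter-3     2023-03-10
#> 3  patient-2  Juan Rodriguez  encounter-2     2023-02-15
```

`patient-3` has no encounters and drops out of the inner join. From a
shell, the same run is:

```sh
Rscript inst/exec/fhirtable run \
  --view inst/extdata/views/patient_addresses.json \
  --data export.ndjson --format csv --output addresses.csv
```

(`validate` and `test` subcommands check views against profiles and run
directories of declarative test cases.)

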