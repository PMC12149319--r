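---
title: "Flattening FHIR resources with view definitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flattening FHIR resources with view definitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhirtable)
```

## The problem

FHIR represents health data as nested JSON resources. The nesting is
essential for interoperability — a Patient can have any number of names,
addresses and telecom entries, an Observation can carry components with
their own coding systems — but it is hostile to the flat tables that
statistics, SQL and spreadsheets expect. A *view definition* is a small
declarative JSON document that fixes, once, how one resource type is
projected into a table; a *view runner* (this package) executes it over any
stream of resources. Because the view document carries no implementation
detail, the same definition can run against NDJSON files here, or be
transpiled to SQL elsewhere, and produce the same table.

## Execution semantics

One resource contributes rows as follows.

1. **Inclusion.** Every `where` expression is evaluated with the resource
   root as focus and mapped to a two-valued boolean: a collection holding
   exactly one `true` passes; an empty collection or a single `false`
   fails; anything else (non-boolean, multiple items) is an error rather
   than a silent guess. Absence of evidence is never inclusion.
2. **Per-select rows.** Each `select` has an iteration axis: none (the
   focus itself), `forEach(expr)` or `forEachOrNull(expr)`. For every
   iteration item, the select's row-set is the cross-join of
   (a) the one-row fragment of its own `column`s evaluated with the item as
   focus, (b) each nested select's recursive row-set, and (c) the
   concatenation of the `unionAll` branches' row-sets, in that order. The
   item row-sets are concatenated in collection order.
3. **Outer-join escape.** If a `forEachOrNull` iteration is empty, the
   select emits exactly one fragment of nulls spanning *its own subtree's*
   columns — sibling selects are unaffected.
4. **Resource rows.** Sibling top-level selects cross-join, left select
   varying slowest. Table rows follow input resource order.

Three consequences are worth calling out because they are genuine design
decisions rather than forced moves:

* **A zero-row sibling annihilates the product.** The cross-join is taken
  literally: if one sibling select yields no rows for a resource, the
  resource yields no rows. `forEachOrNull` is the documented escape hatch.
* **`forEachOrNull` guards only its own axis.** If the iterated collection
  is non-empty but an inner `forEach` eliminates every row, no null row is
  produced; the null row answers "the iterated collection was empty" and
  nothing else. The declarative test-case format lets this be pinned (or
  revisited) as an explicit expectation.
* **`where` clauses always see the resource root**, never an iteration
  item, so filtering is independent of select structure.

Row order is fully deterministic (input order, then traversal order), which
is why the bundled test cases compare ordered by default.

## The FHIRPath subset

Published view specifications constrain runners to a FHIRPath subset but do
not enumerate it in prose; the subset implemented here is the minimal
closure over what view documents actually need, and is documented as such:
identifier paths with `.` chaining, `[n]` indexing (0-based), literals
(string, integer, decimal, boolean, `@date`, `@dateTime`), operators
`= != < <= > >= and or`, and the functions `where`, `exists`, `empty`,
`first`, `not`, `ofType`, `extension('url')`, `getResourceKey`,
`getReferenceKey`. The parser is hand-written recursive descent with the
precedence `or < and < (=, !=) < (<, <=, >, >=)`, left-associative, and
reports character offsets; unknown functions such as `resolve()` fail at
parse time so a view can never silently degrade.

Numerical and semantic choices:

* **Tri-state logic.** An empty operand makes a comparison empty, and
  `and`/`or` follow three-valued logic; the `where`-directive boolean then
  maps empty to *excluded*. This keeps `active = true` false-not-crashing
  for patients with no `active` element.
* **Equality across kinds** (string vs boolean, etc.) is `false`;
  relational operators across kinds are type errors, as is any relational
  use of booleans or complex values.
* **Dates compare as ISO-8601 text** and only at equal precision;
  comparing `@1970-01-01` with a `dateTime` string of different length is a
  type error rather than a wrong answer. Equal-precision ISO text sorts
  correctly as plain text, so no date arithmetic is needed.
* **Choice types** (`value[x]`): a step `value` on an object lacking the
  key `value` resolves to the *unique* key formed by `value` plus an
  upper-case-initial suffix (`valueQuantity`); `ofType(Quantity)` filters
  on that suffix. This is a heuristic that avoids embedding the full FHIR
  structure-definition model; it cannot distinguish types for elements the
  resource does not instantiate, and it is the documented limitation of the
  engine.
* **Cardinality.** A `collection = false` column whose path yields more
  than one value aborts execution with an error naming the resource and
  column; a `collection = true` column always stores an array, storing an
  empty array (not null) when nothing matched, so downstream cell types are
  stable.

## Join keys

`getResourceKey()` / `getReferenceKey(Type)` deliberately hide the key
representation. The canonical strategy emits `"Type/id"`, which is unique
across resource types within a dataset; reference keys resolve literal
relative references and absolute URLs (taking the final `Type/id` path
segments), return nothing for fragment (`#...`) or logical-identifier
references, and respect the optional type filter. A second, `display`,
strategy emits the bare `id` — the shorter form convenient in
human-readable tables — and is safe whenever a single referenced type is
involved. The invariant that matters is strategy-independent and is tested
over whole synthetic corpora: a reference's key equals its target's
resource key, so equijoins behave identically under either strategy.
Whether `Reference.type` should be consulted when `reference` is absent is
left open by published dialects; this runner returns empty.

## Validation profiles

`validate_view()` applies progressively stricter profiles and returns
issues rather than raising: *base* checks structure (column-name syntax and
uniqueness, `unionAll` column parity, `forEach`/`forEachOrNull` mutual
exclusion, parseability of every expression); *shareable* adds
identification metadata (`name`, `version`), a declared `fhirVersion` and a
FHIR type per column; *tabular* restricts columns to scalar FHIR R4
primitives (the 20-type primitive list is fixed in the package since the
profile prose only says "primitive"). Two deliberate strictnesses:
`unionAll` parity requires identical column *order*, not just names, which
makes row concatenation well-defined without reindexing; and the flattened
schema orders a select's own columns before its nested selects and
`unionAll` block, mirroring execution order, so the header is a pure
function of the document and never of the data.

The view dialect's field spellings (`resource`, `select[]`, `column[]`,
`forEach`, `forEachOrNull`, `unionAll[]`, `where[]`, `meta.profile[]`) are
fixed by this package's schema; divergences from any externally published
dialect should be treated as dialect differences, not silently papered
over.

## The synthetic corpus generator

`generate_corpus()` exists so that every test and the acceptance script run
without any real or downloadable patient data. It emulates the structural
features the engine exercises: repeating names/addresses/telecoms with
configurable per-patient count distributions, an inactive fraction, and
encounters that only ever reference generated patients (which makes join
closure a provable property of the corpus, not an assumption). Defaults —
100 patients, 0–2 addresses (20% none), 0–2 telecoms, 0–3 encounters, 20%
inactive — were chosen once as a plausible small primary-care panel.

What the generator does *not* emulate matters for interpreting green tests:
real FHIR carries extensions, contained resources, primitive-element
(`_field`) annotations, mixed-version data, absolute and logical
references, and sheer vocabulary breadth. Passing tests demonstrate the
*semantics* of the runner (unnesting, cross-join, union, null rows, keys)
and its robustness to structurally adversarial JSON (a second random-tree
generator feeds the property tests), not full FHIR R4 coverage.

## Problem sizes and determinism

The property suites run at sizes chosen to give the laws room to fail while
keeping the suite quick: 1000 random (view, resource) cases for the
row-count algebra, 500 random (expression, resource) pairs and 200 random
(view, corpus) pairs against an independently written naive evaluator and
enumerator, corpora of 100–300 patients for the join and inner/outer laws,
and one 100,000-resource NDJSON file for the streaming check, processed in
1000-resource chunks under a 512 MB peak-allocation ceiling with output
required to be byte-identical to batch execution. All randomness flows
through fixed seeds; `generate_corpus()` restores the caller's RNG state.

## Known limitations

* The FHIRPath subset excludes aggregates, arithmetic, `resolve()`,
  environment variables and units; out-of-subset expressions are parse
  errors by design.
* Choice-type resolution is the prefix heuristic described above.
* Primitive extensions (`_element`) and FHIR XML are not handled.
* `equijoin` is a test-and-analysis convenience (nested-loop, scalar keys),
  not a query engine; real deployments would join view outputs in their
  analytic store.
* Constants/parameter substitution in view documents is not supported.
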