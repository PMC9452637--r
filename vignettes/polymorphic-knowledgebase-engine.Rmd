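---
title: "A polymorphic-reference knowledgebase engine: model, guarantees, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A polymorphic-reference knowledgebase engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polykb)
```

## The data model

A `polykb` knowledgebase is a pair of stores. The *meta-database* holds
runtime-defined table definitions: each table is an ordered list of typed
fields, each field carrying a free-text annotation and a list of declarative
constraints. The *entity base* holds the records filed under those
definitions. Alongside them sit per-table id counters and an append-only
migration log. Nothing about the schema is fixed at package build time; the
schema is data, curated interactively, and schema curation and content entry
may alternate freely — the engine's operations are usable in any order.

Field types are `TEXT`, `INTEGER`, `DECIMAL`, `BOOLEAN`, `DATE` (ISO-8601
text of the form `YYYY-MM-DD`), `ENUM` (text restricted to a declared value
set), and `REFERENCE`. The first six carry scalar values. A `REFERENCE`
field carries the engine's core construct, the **polymorphic reference**: a
stored pair of a table identifier and a record identifier. Unlike a
relational foreign key, whose target table is fixed in the schema, the pair
can point at a record of any table, so a single field can model an abstract
concept — "the next step of this decision flow" — whose concrete realizations
live in different tables, including tables that do not exist yet.

Every table is created with a system key field `id`: a self-incrementing
positive integer, issued 1, 2, 3, …, immutable, and never reused even after
deletion (the counter only moves forward). This makes the pair (table, id) a
stable identity for a record — the identity shown on a mind-map canvas and
quoted by every reference — and makes serialized exports deterministic. Only
tables exposing such a single unique key may be reference targets; every
table this engine creates qualifies, so the rule is actively checked only
for imported material.

Identifiers (table and field names) must match `[A-Za-z_][A-Za-z0-9_]*`, are
compared case-insensitively for uniqueness, and preserve their display case.
This avoids silently distinct `Judgement`/`judgement` tables whose exported
SQL would collide in case-insensitive database backends.

## The mutation interface and its invariants

All mutators take the knowledgebase as their first argument and return the
updated value, so sessions compose with the pipe. Three invariants shape the
interface:

* **Blank-then-link.** `kb_insert()` refuses values for reference fields
  (`reference-at-insert`); references are wired afterwards with
  `kb_set_ref()`, which verifies the target's existence and linkability at
  the moment the link is made. This mirrors how a curator records a decision
  step before its "next step" exists, and it is what makes dangling
  references unreachable through the interface.
* **One target per field.** Setting a reference replaces the previous one;
  the stored value is always exactly one pair or blank.
* **Closure under errors.** Because the knowledgebase is an immutable value,
  a failed operation cannot leave a partially mutated state: the caller
  still holds the pre-call value, byte-identical under the canonical
  serialization. The test suite asserts this for every error path, and the
  same property gives transactional extensions for free.

Deletion takes a caller-chosen policy, defaulting to `restrict` (refuse if
any inbound reference exists, naming the blockers) with `nullify` as the
alternative (blank all inbound references, then remove). Restrict is the
safer default for curation: accidentally orphaning links in a decision flow
should require an explicit choice. Record-level self-references are allowed
in storage — re-test loops are legitimate clinical flows — and are reported
by traversal as cycles rather than rejected.

Constraints (`required`, `unique`, `enum_values`, `pattern`, `min_value`,
`max_value`, `max_length`) are validated for applicability when a field is
defined, but enforced in batch by `validate_kb()`, not at insert. Two
deliberate choices follow. First, violations are data (a tibble with a
machine-readable code and a (table, record, field) locator), never
exceptions: a curator wants the full report. Second, a `required` constraint
on a reference field is allowed but only surfaces in validation — forbidding
the blank intermediate state at insert would contradict blank-then-link.
Similarly, an `ENUM` field must declare its `enum_values` at definition
time, since an enumeration without values cannot validate anything.
Uniqueness treats nulls as non-conflicting, the standard relational
convention; duplicates are reported from the second occurrence on, in id
order. `validate_kb()`'s report order is deterministic (per-value checks,
then uniqueness, then dangling references, then non-linkable targets, each
swept in table-creation/id/field order), so repeated validation of an
unmutated knowledgebase is identical — tooling can diff reports.

## Additive evolution and its audit instruments

The engine's central guarantee is that a new knowledge category integrates
by **addition only**: `kb_extend()` creates one new table, inserts its
records, and rewires named reference fields of existing records into the new
branch. No pre-existing table definition changes and no pre-existing value
changes outside the explicitly listed rewires.

Two instruments make the guarantee checkable rather than rhetorical:

* `schema_fingerprint()` renders a table definition (name, linkability,
  ordered fields with types, annotations, constraints) to canonical text.
  Equal fingerprints mean structurally identical definitions; record content
  never enters the fingerprint. `kb_extend()` recomputes every pre-existing
  fingerprint after applying an extension and aborts on any change — by
  construction this cannot trigger, which is exactly why it is asserted.
* The migration log records every mutation; `kb_replay()` rebuilds the
  knowledgebase from it, and the rebuilt state is serialization-equal to the
  original. An auditor can read the log of an evolved knowledgebase and see
  only additions and rewires.

Extensions are atomic: any underlying failure (unknown rewire source,
duplicate table name) propagates as an error and, by value semantics, the
caller's knowledgebase is untouched — verified in tests by byte-comparing
serializations.

## Serialization, traversal and rendering

The interchange form is a versioned YAML **mind-map document**: full schema,
all records with references written as explicit two-part locators, and the
id counters. It is canonical — fixed key order, tables in creation order,
records in id order, doubles rendered at 15 significant digits — and two
knowledgebases are defined to be *serialization-equal* when these texts are
byte-identical. The migration log is provenance rather than content and is
excluded; round-trip equality therefore never compares logs. Loading
re-validates every reference (single-unique-key rule included): strict mode
rejects a document with unresolvable references, naming the first offending
reference; permissive mode loads them as stored so `validate_kb()` can
report them. A load synthesizes a replayable migration log by inserting ids
`1..counter` in order and deleting the gaps, so the never-reuse property
survives import; values or references that cannot pass the mutation
interface (possible only in permissive loads of corrupted documents) are
stored through a logged raw-store step so that detection, not concealment,
is what the validator does.

`traverse_flow()` follows one reference field from a starting record until
the field is blank or absent (`BLANK_REF`), the reference does not resolve
(`MISSING_TARGET`), or the next step was already visited (`CYCLE`). Visited
steps are tracked by (table, id), so the path length is bounded by the
number of records and traversal terminates on every input. `render_dot()`
emits a deterministic DOT description — one node per record labelled
`Table#id`, clustered per table (sorted by name, records by id), one
labelled edge per stored reference; layout is delegated to DOT consumers,
and the optional table filter is the data-model equivalent of collapsing
downstream tables on a canvas.

## Relational export

`export_ddl()`/`export_dml()` emit SQLite-compatible SQL: the system key as
`INTEGER PRIMARY KEY`; `TEXT`/`ENUM`/`DATE` as `TEXT`, `INTEGER` as
`INTEGER`, `DECIMAL` as `REAL`, `BOOLEAN` as `INTEGER` 0/1; each reference
field `f` as two nullable columns `f_table`/`f_id` with a CHECK that both
are null or both set. A single packed `Table:id` text column was rejected as
unqueryable; the pair encoding keeps the target addressable in SQL. No
native FOREIGN KEY is emitted for references — a relational key cannot range
over all tables, which is the very limitation the engine exists to work
around — so referential integrity remains the validator's job, a fact stated
here rather than hidden.

Plain DDL cannot carry annotations, constraint declarations, linkability or
exact counters, so the dump opens with one `-- polykb-meta: {json}` comment
line holding them; SQL engines ignore it, and `import_dump()` uses it for a
lossless round trip. For dumps produced elsewhere the schema is inferred
from the `CREATE TABLE` statements and counters fall back to the per-table
maximum id (the information a foreign dump actually contains). On import,
a reference pair pointing into a table without a single integer primary key
fails with `target-table-not-linkable`; such a table without inbound
references is simply not representable and is rejected as
`unrecognized-schema-shape`. Exports are refused while `validate_kb()`
reports violations (a `force` flag overrides), because a dump is a handoff
to systems that will not run this validator.

One numerical note: decimal values are rendered with 15 significant digits
both in YAML and SQL. Values entered as decimal text of at most 15
significant digits round-trip exactly; the random generator used by the
property checks emits at most 6, matching how decimal measurements enter
curated knowledgebases as typed text.

## The worked example and the generators

`build_cds_fixture()` encodes a thiopurine (6-mercaptopurine) dosing
decision flow guided by TPMT and NUDT15 genotypes, organized as published
pharmacogenomic guidelines organize point-of-care decision support: three
categories of clinical action — judgement, drug order suggestion, test alert
suggestion — hence three tables, with `Judgement.Next` as the one
polymorphic "next step" field. The record wording is a representative,
non-normative paraphrase for demonstrating the modelling pattern, not a
clinical source, and the record counts (4 judgements, 2 drug orders, 1
alert) are internal fixture choices asserted only for self-consistency.
Since only judgements carry a `Next` field, any single traversal ends at the
first non-judgement record; "the flow covers all three categories" is
therefore checked as the union of traversals from every judgement, which is
how the full decision graph is read off the model. `build_itpa_extension()`
is the late-arriving-knowledge scenario — an ITPA genotype with its own
therapy table — whose one rewire (the intermediate/poor-metabolizer
judgement's `Next` moves to the new therapy) is one representative reading
of the scenario's decision-flow change.

Two generators drive the property checks. `kb_simulate()` produces random
*clean* knowledgebases: 3 tables by default, up to 6 records each, all
scalar types exercised, constraints generated consistently with the
generated content, ~60% of reference slots wired across random tables, and
~10% of records deleted under nullify so id sequences carry realistic gaps.
`kb_fuzz()` applies random interleavings of all mutators (weighted toward
inserts and links) starting from empty. What they emulate is the *shape* of
curated knowledgebases — small tables, mixed types, cross-table links,
deletions; what they do not emulate is real curation content: no natural
language, no semantically meaningful flows, no adversarial identifier
choices beyond case. Passing round-trip and integrity properties on them
demonstrates the engine's mechanics, not the clinical adequacy of any
knowledgebase built with it.

The shipped property checks use problem sizes chosen to exercise the
invariants at desk scale: 1,000 fuzzed operation sequences of 25 operations,
100 planted-corruption documents, 200 round trips per serialization route
with 20 dumps executed on an embedded SQLite engine, and ~60 random
knowledgebases' worth of exhaustive traversals.

## Known limitations

* Single-user, in-memory: no concurrency, access control, or streaming of
  very large entity bases. The intended scale is knowledge curation, not
  transaction processing.
* No cross-field or conditional constraints; no field removal/renaming or
  type-narrowing migrations (evolution is deliberately additive).
* One SQL dialect (SQLite-compatible) is normative; the mind-map format is
  versioned at `1.0` and other versions are rejected rather than migrated.
* `DATE` is validated as a calendar date but stored as text; time zones and
  times are out of scope.
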