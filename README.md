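# polykb

`polykb` is an embeddable R engine (plus a small command-line interface) for
**prototyping knowledgebases whose structure is still evolving** — the normal
situation in precision medicine, where new kinds of evidence (a new genotype
test, a new therapy class) keep arriving after the knowledgebase is designed.

## The problem and the core construct

A relational foreign key is bound to *one* target table when the schema is
designed. Modelling a concept like "the next step of a clinical decision
flow" with foreign keys therefore requires one key column per possible kind
of next step, and every newly discovered kind of step forces edits to
existing tables and rewrites of existing rows.

`polykb` instead stores links as a **polymorphic reference**: a pair

```
(target table identifier, target record identifier)
```

held in a single field, so one field can point at a record in *any* table.
Each table gets a unique self-incrementing integer key `id` (ids are never
reused), and only tables exposing such a single unique key may be reference
targets. On top of this construct the engine provides:

* a runtime-defined schema (the *meta-database*) and record store (the
  *entity base*), mutated through a validated, pipe-friendly functional API —
  schema curation and content entry can alternate in any order;
* blank-then-link content entry: reference fields are left blank at insert
  and wired afterwards, so every stored link is validated when it is made;
* batch integrity validation (`validate_kb()`) returning machine-readable
  violations as a tibble, never exceptions;
* **additive schema evolution**: `kb_extend()` integrates a new knowledge
  category as a new table plus reference rewiring, with an internally
  asserted guarantee that no pre-existing table definition (checked by
  canonical `schema_fingerprint()`) and no unrewired value changes;
* a mind-map document serialization (versioned YAML, exact round trip), flow
  traversal, and DOT graph rendering;
* SQLite-compatible SQL export/import (references become `f_table`/`f_id`
  column pairs with a paired-null CHECK) with an exact round trip.

## Worked example: a thiopurine dosing decision flow

The shipped fixture encodes a point-of-care clinical decision support (CDS)
flow for 6-mercaptopurine dosing guided by TPMT and NUDT15 genotypes, in the
CPIC guideline's organization. The flow has three categories of clinical
action — judgements, drug order suggestions, test alert suggestions — so the
whole CDS lives in three tables, with a single `Next` reference field
modelling "next step" across all of them:

```r
library(polykb)
kb <- build_cds_fixture()
kb_tables(kb)
#> # A tibble: 3 × 5
#>   table        n_fields n_records counter linkable
#>   <chr>           <int>     <int>   <int> <lgl>
#> 1 Judgement           2         4       4 TRUE
#> 2 DrugOrder           1         2       2 TRUE
#> 3 CDSTestAlert        1         1       1 TRUE

traverse_flow(kb, "Judgement", 1)
#> Judgement#1 -> Judgement#2 -> DrugOrder#1 [BLANK_REF]
```

The traversal chains a judgement to a further judgement (a self-table link)
and on to a drug order; it ends with `BLANK_REF` because drug orders have no
onward step. When new evidence arrives — say an ITPA genotype with its own
therapy — the change is purely additive:

```r
kb2 <- kb_extend(kb, build_itpa_extension())
attr(kb2, "extension_report")
#> # A tibble: 1 × 3
#>   table       n_records n_rewires
#>   <chr>           <int>     <int>
#> 1 ITPATherapy         1         1

identical(schema_fingerprint(kb, "Judgement"), schema_fingerprint(kb2, "Judgement"))
#> [1] TRUE
```

One table was added, one judgement's `Next` was rewired into the new branch,
and every pre-existing table definition is fingerprint-identical — no
migration of existing structures or records.

The same session is available from a shell via the installed wrapper:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "polykb.R", package = "polykb"))')
Rscript "$CLI" --session cds.yaml demo cds
Rscript "$CLI" --session cds.yaml extend \
  --spec $(Rscript -e 'cat(system.file("extdata", "itpa-extension.yaml", package = "polykb"))')
Rscript "$CLI" --session cds.yaml validate
```

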