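test_that("table creation prepends the system key and preserves order", {
  kb <- kb_new() |>
    kb_create_table("Judgement", list(
      kb_field("criterion", "TEXT"),
      kb_field("Next", "REFERENCE")
    ))
  expect_identical(kb_fields(kb, "Judgement")$field, c("id", "criterion", "Next"))
  expect_true(kb_fields(kb, "Judgement")$system_key[1])

  kb <- kb_create_table(kb, "Empty", list())
  expect_identical(kb_fields(kb, "Empty")$field, "id")

  # creation order is preserved in the schema listing
  expect_identical(kb_tables(kb)$table, c("Judgement", "Empty"))
})

test_that("table and field names are validated and unique case-insensitively", {
  kb <- kb_create_table(kb_new(), "Judgement", list(kb_field("criterion", "TEXT")))
  expect_kb_error(kb_create_table(kb, "judgement", list()), "duplicate-table-name")
  expect_kb_error(kb_create_table(kb, "2bad", list()), "invalid-identifier")
  expect_kb_error(kb_create_table(kb, "T", list(kb_field("ID", "TEXT"))),
                  "reserved-field-name")
  expect_kb_error(
    kb_create_table(kb, "T", list(kb_field("a", "TEXT"), kb_field("A", "TEXT"))),
    "duplicate-field-name")
  expect_kb_error(kb_add_field(kb, "nope", kb_field("x", "TEXT")), "unknown-table")
  expect_kb_error(kb_add_field(kb, "Judgement", kb_field("Criterion", "TEXT")),
                  "duplicate-field-name")
  # case-preserving display, case-insensitive lookup
  expect_identical(kb_table_def(kb, "JUDGEMENT")$name, "Judgement")
})

test_that("adding a field back-fills existing records with null", {
  kb <- kb_new() |>
    kb_create_table("T", list(kb_field("a", "TEXT"))) |>
    kb_insert("T", list(a = "x")) |>
    kb_insert("T", list(a = "y")) |>
    kb_add_field("T", kb_field("b", "TEXT"))
  expect_true(all(is.na(kb_records(kb, "T")$b)))
})

test_that("ids are issued 1,2,3,... and never reused after deletion", {
  kb <- kb_new() |> kb_create_table("T", list(kb_field("a", "TEXT")))
  kb <- kb_insert(kb, "T", list(a = "1"))
  expect_identical(kb_last_id(kb, "T"), 1L)
  kb <- kb_insert(kb, "T") |> kb_insert("T")
  kb <- kb_delete(kb, "T", 2)
  kb <- kb_insert(kb, "T")
  expect_identical(kb_last_id(kb, "T"), 4L)
  expect_identical(kb_records(kb, "T")$id, c(1L, 3L, 4L))
})

test_that("insert rejects unknown fields, bad types, and supplied references", {
  kb <- kb_new() |>
    kb_create_table("T", list(kb_field("n", "INTEGER"), kb_field("r", "REFERENCE")))
  expect_kb_error(kb_insert(kb, "nope", list()), "unknown-table")
  expect_kb_error(kb_insert(kb, "T", list(zzz = 1)), "unknown-field")
  expect_kb_error(kb_insert(kb, "T", list(n = "abc")), "type-mismatch")
  expect_kb_error(kb_insert(kb, "T", list(r = kb_ref("T", 1))), "reference-at-insert")
  # blank-then-link: omitted and explicit-NULL reference fields are fine
  kb <- kb_insert(kb, "T", list(n = 7))
  expect_null(kb_record(kb, "T", 1)$values$r)
})

test_that("set/clear reference enforce targets and keep exactly one ref", {
  kb <- mini_kb()
  rec <- kb_resolve(kb, kb_record(kb, "Step", 1)$values$Next)
  expect_identical(rec$values$note, "done")

  # self-table links are allowed
  kb <- kb_insert(kb, "Step", list(label = "second"))
  kb <- kb_set_ref(kb, "Step", 1, "Next", "Step", 2)
  expect_identical(format(kb_record(kb, "Step", 1)$values$Next), "Step#2")

  expect_kb_error(kb_set_ref(kb, "Step", 99, "Next", "Step", 1), "unknown-source")
  expect_kb_error(kb_set_ref(kb, "Step", 1, "label", "Step", 1), "not-a-reference-field")
  expect_kb_error(kb_set_ref(kb, "Step", 1, "Next", "Ghost", 1), "unknown-target-table")
  expect_kb_error(kb_set_ref(kb, "Step", 1, "Next", "Outcome", 99), "unknown-target-record")

  # last-write-wins after set, clear, set
  kb <- kb_clear_ref(kb, "Step", 1, "Next")
  expect_null(kb_record(kb, "Step", 1)$values$Next)
  kb <- kb_clear_ref(kb, "Step", 1, "Next")  # clearing a blank ref is a no-op
  kb <- kb_set_ref(kb, "Step", 1, "Next", "Outcome", 1)
  expect_identical(format(kb_record(kb, "Step", 1)$values$Next), "Outcome#1")
})

test_that("resolution distinguishes missing table from missing record", {
  kb <- mini_kb()
  expect_kb_error(kb_resolve(kb, "Ghost", 1), "unknown-target-table")
  kb2 <- kb_clear_ref(kb, "Step", 1, "Next") |> kb_delete("Outcome", 1)
  expect_kb_error(kb_resolve(kb2, "Outcome", 1), "unknown-target-record")
})

test_that("delete honours restrict and nullify policies", {
  kb <- mini_kb()
  blocked <- expect_kb_error(kb_delete(kb, "Outcome", 1), "restricted-by-inbound-refs")
  expect_identical(blocked$blockers,
                   tibble::tibble(table = "Step", id = 1L, field = "Next"))

  inbound <- kb_inbound_refs(kb, "Outcome", 1)
  expect_identical(nrow(inbound), 1L)
  kb <- kb_delete(kb, "Outcome", 1, policy = "nullify")
  expect_null(kb_record(kb, "Step", 1)$values$Next)
  expect_identical(nrow(validate_kb(kb)), 0L)

  # unreferenced record deletes cleanly under restrict
  kb <- kb_insert(kb, "Step", list(label = "loose"))
  expect_identical(nrow(kb_inbound_refs(kb, "Step", kb_last_id(kb, "Step"))), 0L)
  kb <- kb_delete(kb, "Step", kb_last_id(kb, "Step"))
  expect_kb_error(kb_delete(kb, "Step", 99), "unknown-record")
})

test_that("failed operations leave the knowledgebase byte-identical", {
  kb <- mini_kb()
  before <- kb_serialize(kb)
  for (bad in list(
    function() kb_create_table(kb, "Step", list()),
    function() kb_insert(kb, "Step", list(zzz = 1)),
    function() kb_set_ref(kb, "Step", 1, "Next", "Outcome", 99),
    function() kb_delete(kb, "Outcome", 1),
    function() kb_add_field(kb, "Step", kb_field("label", "TEXT"))
  )) {
    try(bad(), silent = TRUE)
    expect_identical(kb_serialize(kb), before)
  }
})

test_that("constraint applicability is checked at definition time", {
  expect_kb_error(kb_field("x", "TEXT", constraints = list(kb_constraint("min_value", value = 1))),
                  "invalid-constraint")
  expect_kb_error(kb_field("r", "REFERENCE", constraints = list(kb_constraint("unique"))),
                  "invalid-constraint")
  expect_kb_error(kb_field("e", "ENUM"), "invalid-constraint")  # ENUM needs its values
  f <- kb_field("e", "ENUM",
                constraints = list(kb_constraint("enum_values", values = c("a", "b"))))
  expect_identical(f$constraints[[1]]$params$values, c("a", "b"))
  # a REFERENCE field may be marked required (enforced only by validate_kb)
  expect_silent(kb_field("r", "REFERENCE", constraints = list(kb_constraint("required"))))
})

test_that("randomized operation sequences never leave dangling references", {
  set.seed(101)
  for (i in 1:30) {
    kb <- kb_fuzz(30)
    v <- validate_kb(kb)
    expect_false(any(v$code %in% dangling_codes))
    # id monotonicity: counters never fall below the largest live id
    tabs <- kb_tables(kb)
    for (tn in tabs$table) {
      ids <- kb_records(kb, tn)$id
      expect_true(kb_last_id(kb, tn) >= max(c(0L, ids)))
      expect_identical(ids, sort(unique(ids)))
    }
  }
})
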