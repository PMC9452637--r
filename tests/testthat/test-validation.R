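test_that("validate_value reports type and constraint violations as data", {
  int_f <- kb_field("n", "INTEGER")
  expect_identical(validate_value(int_f, "abc")$code, "TYPE_MISMATCH")
  expect_identical(nrow(validate_value(int_f, 3L)), 0L)

  txt_f <- kb_field("level", "TEXT",
                    constraints = list(kb_constraint("enum_values",
                                                     values = c("low", "normal", "high"))))
  expect_identical(nrow(validate_value(txt_f, "normal")), 0L)
  expect_identical(validate_value(txt_f, "extreme")$code, "ENUM_VIOLATION")

  dec_f <- kb_field("x", "DECIMAL",
                    constraints = list(kb_constraint("min_value", value = 0),
                                       kb_constraint("max_value", value = 10)))
  expect_identical(validate_value(dec_f, -1)$code, "RANGE_VIOLATION")
  expect_identical(validate_value(dec_f, 11)$code, "RANGE_VIOLATION")
  expect_identical(nrow(validate_value(dec_f, 5)), 0L)

  pat_f <- kb_field("code", "TEXT",
                    constraints = list(kb_constraint("pattern", pattern = "^[A-Z]{2}\\d+$"),
                                       kb_constraint("max_length", value = 5L)))
  expect_identical(nrow(validate_value(pat_f, "AB123")), 0L)
  expect_identical(validate_value(pat_f, "nope")$code, "PATTERN_VIOLATION")
  expect_identical(validate_value(pat_f, "AB1234")$code, "LENGTH_VIOLATION")

  date_f <- kb_field("d", "DATE")
  expect_identical(nrow(validate_value(date_f, "2022-08-25")), 0L)
  expect_identical(validate_value(date_f, "2022-13-40")$code, "TYPE_MISMATCH")

  # null passes everything except required
  req_f <- kb_field("a", "TEXT", constraints = list(kb_constraint("required")))
  expect_identical(validate_value(req_f, NULL)$code, "REQUIRED_NULL")
  expect_identical(nrow(validate_value(pat_f, NULL)), 0L)
})

test_that("a required field added late flags every pre-existing record", {
  kb <- kb_new() |>
    kb_create_table("T", list(kb_field("a", "TEXT"))) |>
    kb_insert("T", list(a = "x")) |>
    kb_insert("T", list(a = "y")) |>
    kb_add_field("T", kb_field("b", "TEXT",
                               constraints = list(kb_constraint("required"))))
  v <- validate_kb(kb)
  expect_identical(v$code, rep("REQUIRED_NULL", 2))
  expect_identical(v$record_id, c(1L, 2L))
  expect_identical(unique(v$field), "b")
})

test_that("uniqueness flags duplicates beyond the first and ignores nulls", {
  kb <- kb_new() |>
    kb_create_table("T", list(kb_field("code", "INTEGER",
                                       constraints = list(kb_constraint("unique"))))) |>
    kb_insert("T", list(code = 5)) |>
    kb_insert("T", list(code = 5)) |>
    kb_insert("T", list(code = 5)) |>
    kb_insert("T") |>
    kb_insert("T")
  v <- validate_kb(kb)
  expect_identical(v$code, rep("UNIQUE_VIOLATION", 2))
  expect_identical(v$record_id, c(2L, 3L))  # first occurrence is not a violation
})

test_that("validate_kb is idempotent and empty on an empty knowledgebase", {
  expect_identical(nrow(validate_kb(kb_new())), 0L)
  set.seed(5)
  kb <- kb_fuzz(25)
  expect_identical(validate_kb(kb), validate_kb(kb))
})

test_that("mutation-interface knowledgebases never yield dangling refs; the fixture is clean", {
  expect_identical(nrow(validate_kb(build_cds_fixture())), 0L)
  set.seed(11)
  for (i in 1:10) {
    v <- validate_kb(kb_fuzz(40))
    expect_false(any(v$code %in% dangling_codes))
  }
})

test_that("planted corruptions in serialized documents are detected at their location", {
  set.seed(23)
  found_table <- 0L; found_record <- 0L
  for (i in 1:25) {
    kb <- kb_simulate()
    doc <- unclass(to_mindmap(kb))
    # find a stored reference to corrupt
    target <- NULL
    for (tn in names(doc$records)) {
      for (ri in seq_along(doc$records[[tn]])) {
        for (fn in names(doc$records[[tn]][[ri]]$values)) {
          v <- doc$records[[tn]][[ri]]$values[[fn]]
          if (is.list(v) && !is.null(v$table) && !is.null(v$id) && is.null(target))
            target <- list(tn = tn, ri = ri, fn = fn)
        }
      }
    }
    if (is.null(target)) next
    rid <- doc$records[[target$tn]][[target$ri]]$id
    if (i %% 2 == 0) {
      doc$records[[target$tn]][[target$ri]]$values[[target$fn]]$table <- "GhostTable"
      want <- "DANGLING_REF_TABLE"
      found_table <- found_table + 1L
    } else {
      tgt <- doc$records[[target$tn]][[target$ri]]$values[[target$fn]]$table
      key <- names(doc$counters)[tolower(names(doc$counters)) == tolower(tgt)]
      doc$records[[target$tn]][[target$ri]]$values[[target$fn]]$id <-
        doc$counters[[key]] + 100L
      want <- "DANGLING_REF_RECORD"
      found_record <- found_record + 1L
    }
    v <- validate_kb(from_mindmap(doc, permissive = TRUE))
    hit <- v[v$code == want & v$table == target$tn & v$record_id == rid &
               v$field == target$fn, ]
    expect_identical(nrow(hit), 1L)
  }
  expect_gt(found_table, 3L)
  expect_gt(found_record, 3L)
})

test_that("references into a non-linkable table surface as TARGET_NOT_LINKABLE", {
  doc <- unclass(to_mindmap(
    mini_kb()
  ))
  # mark the referenced table as violating the single-unique-key rule
  doc$tables[[2]]$linkable <- FALSE
  expect_kb_error(from_mindmap(doc), "malformed-document")
  kb <- from_mindmap(doc, permissive = TRUE)
  v <- validate_kb(kb)
  expect_identical(v$code, "TARGET_NOT_LINKABLE")
  expect_kb_error(kb_set_ref(kb, "Step", 1, "Next", "Outcome", 1),
                  "target-table-not-linkable")
})
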