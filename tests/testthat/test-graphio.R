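test_that("mind-map round trips are exact, from empty to fixture to random", {
  empty <- kb_new()
  expect_identical(kb_serialize(from_mindmap(to_mindmap(empty))), kb_serialize(empty))

  cds <- build_cds_fixture()
  expect_identical(kb_serialize(from_mindmap(kb_serialize(cds))), kb_serialize(cds))

  set.seed(31)
  for (i in 1:15) {
    kb <- kb_simulate()
    s <- kb_serialize(kb)
    expect_identical(kb_serialize(from_mindmap(s)), s)
  }
})

test_that("file round trip via atomic write is exact", {
  kb <- build_cds_fixture()
  path <- file.path(tempdir(), "cds.mmkb.yaml")
  kb_write_mindmap(kb, path)
  expect_identical(kb_serialize(kb_read_mindmap(path)), kb_serialize(kb))
  unlink(path)
})

test_that("strict loading rejects dangling refs, bad versions and malformed docs", {
  doc <- unclass(to_mindmap(mini_kb()))
  doc$records$Step[[1]]$values$Next$table <- "Ghost"
  err <- expect_kb_error(from_mindmap(doc), "malformed-document")
  expect_match(conditionMessage(err), "Ghost")
  expect_identical(nrow(validate_kb(from_mindmap(doc, permissive = TRUE))), 1L)

  doc2 <- unclass(to_mindmap(mini_kb()))
  doc2$format_version <- "99.0"
  expect_kb_error(from_mindmap(doc2), "version-unsupported")

  expect_kb_error(from_mindmap(list(tables = list())), "malformed-document")
  doc3 <- unclass(to_mindmap(mini_kb()))
  doc3$counters$Step <- 0L  # counter below the highest id
  expect_kb_error(from_mindmap(doc3), "malformed-document")
})

test_that("flow traversal follows Next until blank, across tables", {
  kb <- kb_new() |>
    kb_create_table("Judgement", list(kb_field("criterion", "TEXT"),
                                      kb_field("Next", "REFERENCE"))) |>
    kb_create_table("DrugOrder", list(kb_field("description", "TEXT"))) |>
    kb_insert("Judgement", list(criterion = "first?")) |>
    kb_insert("Judgement", list(criterion = "second?")) |>
    kb_insert("DrugOrder", list(description = "dose"))

  # single record with blank Next
  f0 <- traverse_flow(kb, "Judgement", 2)
  expect_identical(nrow(f0$steps), 1L)
  expect_identical(f0$terminated_by, "BLANK_REF")

  kb <- kb |>
    kb_set_ref("Judgement", 1, "Next", "Judgement", 2) |>
    kb_set_ref("Judgement", 2, "Next", "DrugOrder", 1)
  f <- traverse_flow(kb, "Judgement", 1)
  expect_identical(f$steps$table, c("Judgement", "Judgement", "DrugOrder"))
  expect_identical(f$steps$id, c(1L, 2L, 1L))
  expect_identical(f$terminated_by, "BLANK_REF")  # DrugOrder has no Next field

  expect_kb_error(traverse_flow(kb, "Judgement", 99), "unknown-start")
  td <- tidy(f)
  expect_identical(td$step, 1:3)
  expect_identical(unique(td$terminated_by), "BLANK_REF")
})

test_that("cycles and missing targets are classified, never errors", {
  kb <- kb_new() |>
    kb_create_table("S", list(kb_field("Next", "REFERENCE"))) |>
    kb_insert("S") |> kb_insert("S")

  # record-level self-loop: 1-step path, CYCLE
  kb1 <- kb_set_ref(kb, "S", 1, "Next", "S", 1)
  f1 <- traverse_flow(kb1, "S", 1)
  expect_identical(nrow(f1$steps), 1L)
  expect_identical(f1$terminated_by, "CYCLE")

  # two-record loop
  kb2 <- kb_set_ref(kb, "S", 1, "Next", "S", 2) |> kb_set_ref("S", 2, "Next", "S", 1)
  f2 <- traverse_flow(kb2, "S", 1)
  expect_identical(f2$steps$id, c(1L, 2L))
  expect_identical(f2$terminated_by, "CYCLE")

  # dangling ref planted through a permissive document load
  doc <- unclass(to_mindmap(kb1))
  doc$records$S[[1]]$values$Next$id <- 99L
  doc$counters$S <- 99L
  f3 <- traverse_flow(from_mindmap(doc, permissive = TRUE), "S", 1)
  expect_identical(f3$terminated_by, "MISSING_TARGET")
})

test_that("traversal terminates within the record-count bound on random kbs", {
  set.seed(47)
  for (i in 1:20) {
    kb <- kb_simulate(p_ref = 0.9)
    total <- sum(kb_tables(kb)$n_records)
    for (tn in kb_tables(kb)$table) {
      reffields <- with(kb_fields(kb, tn), field[type == "REFERENCE"])
      ids <- kb_records(kb, tn)$id
      if (length(reffields) == 0 || length(ids) == 0) next
      f <- traverse_flow(kb, tn, ids[1], field = reffields[1])
      expect_lte(nrow(f$steps), total + 1L)
      expect_true(f$terminated_by %in% c("BLANK_REF", "CYCLE", "MISSING_TARGET"))
    }
  }
})

test_that("DOT output matches record and reference counts and is deterministic", {
  kb <- mini_kb()
  dot <- render_dot(kb)
  expect_identical(sum(grepl("^    \"", strsplit(dot, "\n")[[1]])), 2L)  # node lines
  expect_identical(sum(grepl("->", strsplit(dot, "\n")[[1]])), 1L)       # edge lines
  expect_identical(render_dot(kb), dot)

  cds <- build_cds_fixture()
  lines <- strsplit(render_dot(cds), "\n")[[1]]
  n_refs <- sum(!is.na(kb_records(cds, "Judgement")$Next))
  expect_identical(sum(grepl("->", lines)), as.integer(n_refs))
  expect_identical(sum(grepl("^    \"", lines)), sum(kb_tables(cds)$n_records))
  expect_identical(sum(grepl("subgraph cluster_", lines)), 3L)

  # table filter drops excluded tables and edges into them
  only_j <- render_dot(cds, tables = "Judgement")
  jlines <- strsplit(only_j, "\n")[[1]]
  expect_identical(sum(grepl("subgraph cluster_", jlines)), 1L)
  expect_false(any(grepl("DrugOrder", jlines)))
})
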