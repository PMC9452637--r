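expect_kb_error <- function(expr, code) {
  err <- tryCatch({ expr; NULL }, polykb_error = function(e) e)
  expect_false(is.null(err), label = sprintf("expected error with code '%s'", code))
  if (!is.null(err)) expect_identical(kb_error_code(err), code)
  invisible(err)
}

# a tiny two-table kb with one wired reference, used across tests
mini_kb <- function() {
  kb_new() |>
    kb_create_table("Step", list(
      kb_field("label", "TEXT"),
      kb_field("Next", "REFERENCE")
    )) |>
    kb_create_table("Outcome", list(kb_field("note", "TEXT"))) |>
    kb_insert("Step", list(label = "start")) |>
    kb_insert("Outcome", list(note = "done")) |>
    kb_set_ref("Step", 1, "Next", "Outcome", 1)
}

dangling_codes <- c("DANGLING_REF_TABLE", "DANGLING_REF_RECORD", "TARGET_NOT_LINKABLE")

# run a SQL dump file through Python's sqlite3 (the independent embedded
# engine available on this system); returns TRUE if it executes cleanly
sqlite_executes <- function(path) {
  script <- sprintf(
    "import sqlite3,sys\ncon = sqlite3.connect(':memory:')\ncon.executescript(open(%s).read())\nprint('OK')",
    deparse(path))
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = TRUE))
  identical(tail(out, 1), "OK")
}
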