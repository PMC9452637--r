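#' Canonical fingerprint of a table definition
#'
#' A deterministic text rendering of a table's full structural definition —
#' name, linkability, and every field with its type, annotation and
#' constraints in order. Two tables have equal fingerprints iff their
#' definitions are structurally identical; record content never enters the
#' fingerprint. This is the instrument behind the engine's central guarantee:
#' extending a knowledgebase with a new table leaves the fingerprint of every
#' pre-existing table unchanged.
#'
#' @param kb A knowledgebase.
#' @param table Table name.
#' @return A single canonical text string.
#' @export
schema_fingerprint <- function(kb, table) {
  key <- need_table(kb, table)
  tdef <- kb$tables[[key]]
  lines <- c(
    sprintf("table %s linkable=%s", tdef$name, tolower(isTRUE(tdef$linkable))),
    vapply(tdef$fields, fingerprint_field, "")
  )
  paste(lines, collapse = "\n")
}

fingerprint_field <- function(f) {
  cons <- vapply(f$constraints, function(con) {
    if (length(con$params) == 0) con$kind
    else sprintf("%s(%s)", con$kind,
                 paste(vapply(unlist(con$params), as.character, ""), collapse = ","))
  }, "")
  sprintf("field %s type=%s annotation=%s constraints=[%s]%s",
          f$name, f$type, deparse(f$annotation), paste(cons, collapse = ";"),
          if (isTRUE(f$system_key)) " system_key" else "")
}

#' Build an extension specification
#'
#' A declarative description of one evolution step: a new table, its initial
#' records, and the reference rewires that splice the new branch into the
#' existing decision flow.
#'
#' @param name New table name.
#' @param fields List of [kb_field()] definitions for the new table.
#' @param records List of value maps to insert into the new table.
#' @param rewires List of rewires; each is a list with `table`, `id`,
#'   `field`, and either `target_table` + `target_id` (relink) or
#'   `target_table = NULL` (clear the link).
#' @return A `polykb_extension` object consumable by [kb_extend()].
#' @export
kb_extension <- function(name, fields = list(), records = list(), rewires = list()) {
  structure(list(table = list(name = name, fields = fields),
                 records = records, rewires = rewires),
            class = "polykb_extension")
}

#' @export
print.polykb_extension <- function(x, ...) {
  cat(sprintf("<polykb extension: table '%s' (+%d fields), %d record(s), %d rewire(s)>\n",
              x$table$name, length(x$table$fields), length(x$records),
              length(x$rewires)))
  invisible(x)
}

#' Extend a knowledgebase with a new knowledge category
#'
#' Atomically creates the new table, inserts its records, and applies the
#' reference rewires. New knowledge categories are integrated purely by
#' addition and rewiring: no pre-existing table definition is modified and no
#' pre-existing record changes outside the explicitly rewired reference
#' fields. That no-touch property is asserted internally after every
#' extension (fingerprints of all pre-existing tables must be unchanged); any
#' failure — an invalid rewire target, a duplicate table name, a fingerprint
#' change — aborts the whole extension, and because the knowledgebase is a
#' value, the caller's copy is untouched.
#'
#' @param kb A knowledgebase.
#' @param extension A `polykb_extension` (see [kb_extension()] or
#'   [build_itpa_extension()]).
#' @return The extended knowledgebase, with an `extension_report` attribute
#'   (tibble: table, records inserted, rewires applied).
#' @export
kb_extend <- function(kb, extension) {
  stopifnot(inherits(kb, "polykb"))
  if (!inherits(extension, "polykb_extension"))
    kb_abort("invalid-extension", "extension must be a polykb_extension")
  pre_tables <- names(kb$tables)
  pre_fp <- vapply(pre_tables, function(t) schema_fingerprint(kb, t), "")

  kb2 <- kb_create_table(kb, extension$table$name, extension$table$fields)
  for (vals in extension$records) {
    kb2 <- kb_insert(kb2, extension$table$name, vals)
  }
  for (rw in extension$rewires) {
    kb2 <- if (is.null(rw$target_table)) {
      kb_clear_ref(kb2, rw$table, rw$id, rw$field)
    } else {
      kb_set_ref(kb2, rw$table, rw$id, rw$field, rw$target_table, rw$target_id)
    }
  }

  post_fp <- vapply(pre_tables, function(t) schema_fingerprint(kb2, t), "")
  if (!identical(pre_fp, post_fp)) {
    kb_abort("no-touch-violation",
             "extension altered a pre-existing table definition; rolled back")
  }
  attr(kb2, "extension_report") <- tibble::tibble(
    table = extension$table$name,
    n_records = length(extension$records),
    n_rewires = length(extension$rewires)
  )
  kb2
}

#' Rebuild a knowledgebase by replaying a migration log
#'
#' Every mutation appends one entry to the knowledgebase's migration log;
#' replaying the log against an empty knowledgebase reproduces the current
#' state exactly (the canonical serializations are equal). This makes the
#' no-touch evolution property auditable: the log records additions and
#' rewires, never edits to existing table structures.
#'
#' @param log A log as stored in `kb$log` or the `details` rows of
#'   [kb_log()] output — i.e. a list of entries with `op` and `details`.
#' @return The reconstructed knowledgebase.
#' @export
kb_replay <- function(log) {
  kb <- kb_new()
  for (entry in log) {
    d <- entry$details
    kb <- switch(entry$op,
      CREATE_TABLE = kb_create_table(kb, d$name, d$fields,
                                     linkable = !isFALSE(d$linkable)),
      ADD_FIELD    = kb_add_field(kb, d$table, d$field),
      INSERT       = kb_insert(kb, d$table,
                               Filter(Negate(is.null), d$values)),
      SET_REF      = kb_set_ref(kb, d$table, d$id, d$field,
                                d$target_table, d$target_id),
      CLEAR_REF    = kb_clear_ref(kb, d$table, d$id, d$field),
      DELETE       = kb_delete(kb, d$table, d$id, d$policy),
      SET_RAW      = kb_set_raw(kb, d$table, d$id, d$field, d$value),
      SET_REF_RAW  = kb_set_raw(kb, d$table, d$id, d$field, d$value),
      kb_abort("unknown-log-op", sprintf("cannot replay op '%s'", entry$op))
    )
  }
  kb
}
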