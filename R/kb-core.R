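#' Create an empty knowledgebase
#'
#' A knowledgebase holds a runtime-defined schema (the meta-database: named
#' tables with typed, annotated, constrained fields) and the records filed
#' under it (the entity base), together with per-table id counters and an
#' append-only migration log. It is a plain R value: every mutator takes the
#' knowledgebase as its first argument and returns the updated copy, so
#' curation sessions chain naturally with the pipe and a failed operation
#' can never leave a half-mutated state behind.
#'
#' @return An empty `polykb` object.
#' @examples
#' kb <- kb_new() |>
#'   kb_create_table("Judgement", list(
#'     kb_field("criterion", "TEXT", constraints = list(kb_constraint("required"))),
#'     kb_field("Next", "REFERENCE")
#'   ))
#' kb_tables(kb)
#' @export
kb_new <- function() {
  structure(
    list(
      tables   = list(),
      records  = list(),
      counters = integer(0),
      log      = list()
    ),
    class = "polykb"
  )
}

#' @export
print.polykb <- function(x, ...) {
  cat(sprintf(
    "<polykb knowledgebase: %d table(s), %d record(s), %d log entries>\n",
    length(x$tables), sum(vapply(x$records, length, 1L)), length(x$log)
  ))
  if (length(x$tables) > 0) print(kb_tables(x))
  invisible(x)
}

# ---- errors -----------------------------------------------------------------

kb_abort <- function(code, message, ...) {
  rlang::abort(
    message,
    class = c(paste0("polykb_error_", gsub("-", "_", code)), "polykb_error"),
    code = code,
    ...
  )
}

#' Machine-readable code of an engine error
#'
#' Every condition signalled by the engine carries a stable, hyphenated code
#' (e.g. `"duplicate-table-name"`, `"unknown-target-record"`) alongside its
#' human-readable message, so callers can branch on failures without parsing
#' message text.
#'
#' @param cnd A condition caught from a polykb operation.
#' @return The code as a character scalar, or `NA_character_` for foreign
#'   conditions.
#' @export
kb_error_code <- function(cnd) {
  if (!is.null(cnd$code)) cnd$code else NA_character_
}

# ---- identifiers ------------------------------------------------------------

SYSTEM_KEY_NAME <- "id"

is_identifier <- function(x) {
  is.character(x) && length(x) == 1 && !is.na(x) &&
    grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)
}

check_identifier <- function(x, what) {
  if (!is_identifier(x)) {
    kb_abort("invalid-identifier",
             sprintf("%s %s is not a valid identifier", what,
                     deparse(as.character(x)[1])))
  }
  x
}

# Identifiers are case-insensitive for uniqueness but case-preserving for
# display; lookups go through these resolvers.
resolve_table_name <- function(kb, name) {
  nm <- names(kb$tables)
  hit <- nm[tolower(nm) == tolower(name)]
  if (length(hit) == 0) NA_character_ else hit[[1]]
}

resolve_field_name <- function(tdef, name) {
  nm <- vapply(tdef$fields, `[[`, "", "name")
  hit <- nm[tolower(nm) == tolower(name)]
  if (length(hit) == 0) NA_character_ else hit[[1]]
}

field_def <- function(tdef, name) {
  for (f in tdef$fields) if (tolower(f$name) == tolower(name)) return(f)
  NULL
}

user_fields <- function(tdef) Filter(function(f) !isTRUE(f$system_key), tdef$fields)

need_table <- function(kb, table, code = "unknown-table") {
  key <- resolve_table_name(kb, table)
  if (is.na(key)) kb_abort(code, sprintf("table '%s' does not exist", table))
  key
}

# ---- field and constraint constructors --------------------------------------

FIELD_TYPES <- c("TEXT", "INTEGER", "DECIMAL", "BOOLEAN", "DATE", "ENUM", "REFERENCE")
SCALAR_TYPES <- setdiff(FIELD_TYPES, "REFERENCE")
CONSTRAINT_KINDS <- c("required", "unique", "enum_values", "pattern",
                      "min_value", "max_value", "max_length")

#' Define a field constraint
#'
#' Constraints are declared on a field and enforced in batch by
#' [validate_kb()]; they never abort content entry, so a curator can record
#' partial knowledge first and clean it up later.
#'
#' @param kind One of `required`, `unique`, `enum_values`, `pattern`,
#'   `min_value`, `max_value`, `max_length`.
#' @param ... Kind-dependent parameters: `values` (character vector) for
#'   `enum_values`, `pattern` (regular expression) for `pattern`, `value`
#'   (numeric bound or integer length) for the min/max/length kinds.
#' @return A `polykb_constraint` object.
#' @export
kb_constraint <- function(kind, ...) {
  kind <- match.arg(kind, CONSTRAINT_KINDS)
  params <- list(...)
  if (kind == "enum_values") {
    if (is.null(params$values) || length(params$values) == 0)
      kb_abort("invalid-constraint", "enum_values needs a nonempty 'values' vector")
    params <- list(values = as.character(params$values))
  } else if (kind == "pattern") {
    if (!is.character(params$pattern) || length(params$pattern) != 1)
      kb_abort("invalid-constraint", "pattern needs a 'pattern' string")
    params <- list(pattern = params$pattern)
  } else if (kind %in% c("min_value", "max_value")) {
    if (!is.numeric(params$value) || length(params$value) != 1)
      kb_abort("invalid-constraint", sprintf("%s needs a numeric 'value'", kind))
    params <- list(value = as.numeric(params$value))
  } else if (kind == "max_length") {
    if (!is.numeric(params$value) || length(params$value) != 1 || params$value < 0)
      kb_abort("invalid-constraint", "max_length needs a nonnegative integer 'value'")
    params <- list(value = as.integer(params$value))
  } else {
    params <- list()
  }
  structure(list(kind = kind, params = params), class = "polykb_constraint")
}

# which constraint kinds may sit on which field type
constraint_applicable <- function(kind, type) {
  switch(kind,
    required    = TRUE,
    unique      = type %in% SCALAR_TYPES,
    enum_values = type %in% c("ENUM", "TEXT"),
    pattern     = type == "TEXT",
    min_value   = type %in% c("INTEGER", "DECIMAL"),
    max_value   = type %in% c("INTEGER", "DECIMAL"),
    max_length  = type %in% c("TEXT", "ENUM"),
    FALSE
  )
}

#' Define a field
#'
#' @param name Field name; a valid identifier, unique within its table
#'   (case-insensitively), and not the reserved system-key name `id`.
#' @param type One of `TEXT`, `INTEGER`, `DECIMAL`, `BOOLEAN`, `DATE`,
#'   `ENUM`, `REFERENCE`. `REFERENCE` fields hold polymorphic references —
#'   a stored (table, record id) pair that may point into any table — and
#'   are always left blank at insert time and wired up with [kb_set_ref()].
#'   `DATE` values are ISO-8601 text (`YYYY-MM-DD`).
#' @param annotation Free-text manual annotation shown alongside the field.
#' @param constraints List of [kb_constraint()] objects.
#' @return A `polykb_field` object.
#' @export
kb_field <- function(name, type, annotation = "", constraints = list()) {
  check_identifier(name, "field name")
  if (!is.character(type) || length(type) != 1 || !(type %in% FIELD_TYPES))
    kb_abort("invalid-field-type", sprintf("unknown field type '%s'", type))
  if (!is.character(annotation) || length(annotation) != 1)
    kb_abort("invalid-field", "annotation must be a single string")
  if (inherits(constraints, "polykb_constraint")) constraints <- list(constraints)
  for (con in constraints) {
    if (!inherits(con, "polykb_constraint"))
      kb_abort("invalid-constraint", "constraints must be kb_constraint() objects")
    if (con$kind != "required" && type == "REFERENCE")
      kb_abort("invalid-constraint",
               sprintf("constraint '%s' cannot apply to a REFERENCE field", con$kind))
    if (!constraint_applicable(con$kind, type))
      kb_abort("invalid-constraint",
               sprintf("constraint '%s' does not apply to type %s", con$kind, type))
  }
  if (type == "ENUM" &&
      !any(vapply(constraints, function(c) c$kind == "enum_values", TRUE)))
    kb_abort("invalid-constraint", "an ENUM field must carry an enum_values constraint")
  structure(
    list(name = name, type = type, annotation = annotation,
         constraints = constraints, system_key = FALSE),
    class = "polykb_field"
  )
}

system_key_field <- function() {
  structure(
    list(name = SYSTEM_KEY_NAME, type = "INTEGER", annotation = "",
         constraints = list(), system_key = TRUE),
    class = "polykb_field"
  )
}

#' Construct a polymorphic reference value
#'
#' @param table Target table name.
#' @param id Target record id (positive integer).
#' @return A `polykb_ref`: the stored pair of identifiers.
#' @export
kb_ref <- function(table, id) {
  id <- suppressWarnings(as.integer(id))
  if (length(id) != 1 || is.na(id) || id < 1)
    kb_abort("invalid-ref", "record id must be a positive integer")
  structure(list(table = as.character(table), id = id), class = "polykb_ref")
}

is_ref <- function(x) inherits(x, "polykb_ref")

#' @export
format.polykb_ref <- function(x, ...) sprintf("%s#%d", x$table, x$id)

#' @export
print.polykb_ref <- function(x, ...) {
  cat("<ref ", format(x), ">\n", sep = "")
  invisible(x)
}

# ---- logging ----------------------------------------------------------------

log_entry <- function(kb, op, details) {
  kb$log[[length(kb$log) + 1L]] <-
    list(seq = length(kb$log) + 1L, op = op, details = details)
  kb
}

#' Migration log of a knowledgebase
#'
#' @param kb A knowledgebase.
#' @return A tibble with one row per logged mutation (`seq`, `op`, and an
#'   op-specific `details` list-column). Replaying the log from an empty
#'   knowledgebase with [kb_replay()] reproduces the current state.
#' @export
kb_log <- function(kb) {
  tibble::tibble(
    seq = vapply(kb$log, `[[`, 1L, "seq"),
    op = vapply(kb$log, `[[`, "", "op"),
    details = lapply(kb$log, `[[`, "details")
  )
}

# ---- create_table / add_field -----------------------------------------------

check_new_field <- function(field, existing_names) {
  if (!inherits(field, "polykb_field"))
    kb_abort("invalid-field", "fields must be kb_field() objects")
  if (tolower(field$name) == SYSTEM_KEY_NAME)
    kb_abort("reserved-field-name",
             sprintf("'%s' is reserved for the system key", field$name))
  if (tolower(field$name) %in% tolower(existing_names))
    kb_abort("duplicate-field-name",
             sprintf("field '%s' already defined", field$name))
  invisible(field)
}

#' Create a table
#'
#' Registers a new table in the meta-database. A system key field named
#' `id` — a unique self-incrementing integer, starting at 1 and never
#' reused — is prepended automatically; user fields may not use that name.
#'
#' @param kb A knowledgebase.
#' @param name Table name (valid identifier, unique case-insensitively).
#' @param fields List of [kb_field()] definitions, in display order.
#' @param linkable Whether the table may be the target of polymorphic
#'   references. Tables created by this engine always expose a single unique
#'   key and so are linkable; `FALSE` only occurs when reconstructing
#'   imported tables that violate the single-unique-key rule.
#' @return The updated knowledgebase.
#' @export
kb_create_table <- function(kb, name, fields = list(), linkable = TRUE) {
  stopifnot(inherits(kb, "polykb"))
  check_identifier(name, "table name")
  if (!is.na(resolve_table_name(kb, name)))
    kb_abort("duplicate-table-name", sprintf("table '%s' already exists", name))
  if (inherits(fields, "polykb_field")) fields <- list(fields)
  seen <- character(0)
  for (f in fields) {
    check_new_field(f, seen)
    seen <- c(seen, f$name)
  }
  tdef <- list(name = name, linkable = isTRUE(linkable),
               fields = c(list(system_key_field()), fields))
  kb$tables[[name]] <- tdef
  kb$records[[name]] <- list()
  kb$counters[[name]] <- 0L
  log_entry(kb, "CREATE_TABLE",
            list(name = name, fields = fields, linkable = isTRUE(linkable)))
}

# Internal bypass used only when reconstructing a knowledgebase from a
# serialized document or relational dump: stores a value (or an unresolvable
# reference, in permissive loads) without the mutation-interface checks so
# that validate_kb can report the problem instead of the load hiding it.
# Logged with its own op codes so the migration log stays replayable.
kb_set_raw <- function(kb, table, record_id, field, value) {
  key <- resolve_table_name(kb, table)
  kb$records[[key]][[as.character(record_id)]][field] <- list(value)
  op <- if (is_ref(value)) "SET_REF_RAW" else "SET_RAW"
  log_entry(kb, op, list(table = key, id = as.integer(record_id),
                         field = field, value = value))
}

#' Append a field to an existing table
#'
#' Every existing record of the table gains a blank (null) entry for the new
#' field; a `required` constraint on it will therefore surface one violation
#' per pre-existing record in [validate_kb()] until the blanks are filled.
#'
#' @param kb A knowledgebase.
#' @param table Table name.
#' @param field A [kb_field()] definition.
#' @return The updated knowledgebase.
#' @export
kb_add_field <- function(kb, table, field) {
  stopifnot(inherits(kb, "polykb"))
  key <- need_table(kb, table)
  tdef <- kb$tables[[key]]
  check_new_field(field, vapply(user_fields(tdef), `[[`, "", "name"))
  tdef$fields <- c(tdef$fields, list(field))
  kb$tables[[key]] <- tdef
  kb$records[[key]] <- lapply(kb$records[[key]], function(vals) {
    vals[field$name] <- list(NULL)
    vals
  })
  log_entry(kb, "ADD_FIELD", list(table = key, field = field))
}

# ---- scalar typing ----------------------------------------------------------

# Checks a scalar against a field type; returns the coerced value, or the
# sentinel `type_mismatch` if incompatible. NULL always passes.
coerce_scalar <- function(type, value) {
  if (is.null(value)) return(NULL)
  bad <- structure(list(), class = "polykb_type_mismatch")
  if (is_ref(value)) return(if (type == "REFERENCE") value else bad)
  if (length(value) != 1 || is.na(value)) return(bad)
  switch(type,
    TEXT = if (is.character(value)) value else bad,
    ENUM = if (is.character(value)) value else bad,
    INTEGER = if (is.numeric(value) && value == as.integer(value)) as.integer(value) else bad,
    DECIMAL = if (is.numeric(value)) as.numeric(value) else bad,
    BOOLEAN = if (is.logical(value)) value else bad,
    DATE = if (is.character(value) && grepl("^\\d{4}-\\d{2}-\\d{2}$", value) &&
               !is.na(suppressWarnings(as.Date(value, format = "%Y-%m-%d"))))
             value else bad,
    REFERENCE = bad,  # refs are linked, never supplied as scalars
    bad
  )
}

is_type_mismatch <- function(x) inherits(x, "polykb_type_mismatch")

# ---- insert -----------------------------------------------------------------

#' Insert a record
#'
#' Assigns the next id from the table's counter (ids are monotonically
#' increasing and never reused, even after deletion). Fields omitted from
#' `values` are stored as null — the blank-then-link workflow: reference
#' fields in particular must be left blank here and wired afterwards with
#' [kb_set_ref()], which is what keeps every stored reference validated at
#' creation.
#'
#' @param kb A knowledgebase.
#' @param table Table name.
#' @param values Named list mapping field names to scalar values (or `NULL`).
#' @return The updated knowledgebase; the id just issued is
#'   `kb_last_id(kb, table)`.
#' @export
kb_insert <- function(kb, table, values = list()) {
  stopifnot(inherits(kb, "polykb"))
  key <- need_table(kb, table)
  tdef <- kb$tables[[key]]
  if (length(values) > 0 &&
      (is.null(names(values)) || any(names(values) == "")))
    kb_abort("unknown-field", "values must be a fully named list")
  stored <- list()
  for (vn in names(values)) {
    fn <- resolve_field_name(tdef, vn)
    if (is.na(fn) || tolower(fn) == SYSTEM_KEY_NAME)
      kb_abort("unknown-field",
               sprintf("table '%s' has no user field '%s'", key, vn))
    fdef <- field_def(tdef, fn)
    v <- values[[vn]]
    if (fdef$type == "REFERENCE" && !is.null(v))
      kb_abort("reference-at-insert",
               sprintf("field '%s' is a reference; insert blank, then kb_set_ref()", fn))
    v <- coerce_scalar(fdef$type, v)
    if (is_type_mismatch(v))
      kb_abort("type-mismatch",
               sprintf("value for '%s' is not a valid %s", fn, fdef$type))
    stored[fn] <- list(v)
  }
  vals <- list()
  for (f in user_fields(tdef)) {
    vals[f$name] <- if (f$name %in% names(stored)) stored[f$name] else list(NULL)
  }
  id <- kb$counters[[key]] + 1L
  kb$counters[[key]] <- id
  kb$records[[key]][[as.character(id)]] <- vals
  log_entry(kb, "INSERT", list(table = key, id = id, values = vals))
}

# ---- references -------------------------------------------------------------

locate_record <- function(kb, table, id, code = "unknown-source") {
  key <- resolve_table_name(kb, table)
  if (is.na(key))
    kb_abort(code, sprintf("table '%s' does not exist", table))
  id <- suppressWarnings(as.integer(id))
  if (length(id) != 1 || is.na(id) ||
      is.null(kb$records[[key]][[as.character(id)]]))
    kb_abort(code, sprintf("record %s#%s does not exist", key, id))
  list(key = key, id = id)
}

need_ref_field <- function(kb, key, field) {
  tdef <- kb$tables[[key]]
  fn <- resolve_field_name(tdef, field)
  if (is.na(fn) || field_def(tdef, fn)$type != "REFERENCE")
    kb_abort("not-a-reference-field",
             sprintf("'%s.%s' is not a REFERENCE field", key, field))
  fn
}

#' Link a reference field to a target record
#'
#' Stores exactly one polymorphic reference — the pair (target table, target
#' record id) — in the named field, replacing any previous link. The target
#' must exist and its table must satisfy the single-unique-key rule (always
#' true for tables created by this engine; checked because imported tables
#' may carry a foreign key shape that is not linkable). Self-table and
#' self-record links are allowed; traversal reports record-level loops as
#' cycles.
#'
#' @param kb A knowledgebase.
#' @param table,record_id Source record.
#' @param field Source REFERENCE field name.
#' @param target_table,target_id Target record.
#' @return The updated knowledgebase.
#' @export
kb_set_ref <- function(kb, table, record_id, field, target_table, target_id) {
  stopifnot(inherits(kb, "polykb"))
  src <- locate_record(kb, table, record_id, "unknown-source")
  fn <- need_ref_field(kb, src$key, field)
  tkey <- resolve_table_name(kb, target_table)
  if (is.na(tkey))
    kb_abort("unknown-target-table",
             sprintf("target table '%s' does not exist", target_table))
  if (!isTRUE(kb$tables[[tkey]]$linkable))
    kb_abort("target-table-not-linkable",
             sprintf("table '%s' does not expose a single unique key", tkey))
  tid <- suppressWarnings(as.integer(target_id))
  if (length(tid) != 1 || is.na(tid) ||
      is.null(kb$records[[tkey]][[as.character(tid)]]))
    kb_abort("unknown-target-record",
             sprintf("record %s#%s does not exist", tkey, target_id))
  kb$records[[src$key]][[as.character(src$id)]][[fn]] <- kb_ref(tkey, tid)
  log_entry(kb, "SET_REF", list(table = src$key, id = src$id, field = fn,
                                target_table = tkey, target_id = tid))
}

#' Blank a reference field
#'
#' The inverse of [kb_set_ref()]; clearing an already-blank field is a no-op.
#'
#' @inheritParams kb_set_ref
#' @return The updated knowledgebase.
#' @export
kb_clear_ref <- function(kb, table, record_id, field) {
  stopifnot(inherits(kb, "polykb"))
  src <- locate_record(kb, table, record_id, "unknown-source")
  fn <- need_ref_field(kb, src$key, field)
  kb$records[[src$key]][[as.character(src$id)]][fn] <- list(NULL)
  log_entry(kb, "CLEAR_REF", list(table = src$key, id = src$id, field = fn))
}

#' Resolve a polymorphic reference
#'
#' Resolution of a dangling reference is a legitimate query: it fails with a
#' distinct machine-readable code (`unknown-target-table` vs
#' `unknown-target-record`) rather than silently returning null, which is
#' what lets [validate_kb()] classify dangling references precisely.
#'
#' @param kb A knowledgebase.
#' @param ref A `polykb_ref` (see [kb_ref()]), or a table name if `id` is
#'   given.
#' @param id Target record id when `ref` is a table name.
#' @return The record as a list with elements `table`, `id`, `values`.
#' @export
kb_resolve <- function(kb, ref, id = NULL) {
  stopifnot(inherits(kb, "polykb"))
  if (!is_ref(ref)) ref <- kb_ref(ref, id)
  key <- resolve_table_name(kb, ref$table)
  if (is.na(key))
    kb_abort("unknown-target-table",
             sprintf("table '%s' does not exist", ref$table))
  rec <- kb$records[[key]][[as.character(ref$id)]]
  if (is.null(rec))
    kb_abort("unknown-target-record",
             sprintf("record %s#%d does not exist", key, ref$id))
  list(table = key, id = ref$id, values = rec)
}

#' Inbound references to a record
#'
#' @param kb A knowledgebase.
#' @param table,record_id The target record.
#' @return A tibble (`table`, `id`, `field`) of every stored reference that
#'   points at the target, in schema order. Useful before a delete to see
#'   what would be affected.
#' @export
kb_inbound_refs <- function(kb, table, record_id) {
  key <- resolve_table_name(kb, table)
  record_id <- as.integer(record_id)
  out <- list()
  for (tname in names(kb$tables)) {
    reffields <- vapply(
      Filter(function(f) f$type == "REFERENCE", user_fields(kb$tables[[tname]])),
      `[[`, "", "name")
    if (length(reffields) == 0) next
    recs <- kb$records[[tname]]
    for (rid in as.integer(names(recs))) {
      for (fn in reffields) {
        v <- recs[[as.character(rid)]][[fn]]
        if (is_ref(v) && !is.na(key) && tolower(v$table) == tolower(key) &&
            v$id == record_id) {
          out[[length(out) + 1L]] <- tibble::tibble(table = tname, id = rid, field = fn)
        }
      }
    }
  }
  if (length(out) == 0) {
    tibble::tibble(table = character(0), id = integer(0), field = character(0))
  } else {
    dplyr::bind_rows(out)
  }
}

#' Delete a record
#'
#' @param kb A knowledgebase.
#' @param table,record_id The record to delete.
#' @param policy `"restrict"` (default) refuses to delete a record that is
#'   still the target of any stored reference, naming the blockers in the
#'   error condition's `blockers` tibble; `"nullify"` blanks every inbound
#'   reference and then removes the record. The freed id is never reissued.
#' @return The updated knowledgebase.
#' @export
kb_delete <- function(kb, table, record_id, policy = c("restrict", "nullify")) {
  stopifnot(inherits(kb, "polykb"))
  policy <- match.arg(policy)
  loc <- locate_record(kb, table, record_id, "unknown-record")
  inbound <- kb_inbound_refs(kb, loc$key, loc$id)
  if (policy == "restrict" && nrow(inbound) > 0) {
    kb_abort("restricted-by-inbound-refs",
             sprintf("record %s#%d is referenced by: %s", loc$key, loc$id,
                     paste(sprintf("%s#%d.%s", inbound$table, inbound$id,
                                   inbound$field), collapse = ", ")),
             blockers = inbound)
  }
  if (nrow(inbound) > 0) {
    for (i in seq_len(nrow(inbound))) {
      kb$records[[inbound$table[i]]][[as.character(inbound$id[i])]][inbound$field[i]] <-
        list(NULL)
    }
  }
  kb$records[[loc$key]][[as.character(loc$id)]] <- NULL
  log_entry(kb, "DELETE", list(table = loc$key, id = loc$id, policy = policy))
}

# ---- accessors --------------------------------------------------------------

#' Schema summary
#'
#' @param kb A knowledgebase.
#' @return A tibble with one row per table, in creation order: name, number
#'   of user fields, number of live records, highest id ever issued, and
#'   whether the table can be the target of a polymorphic reference.
#' @export
kb_tables <- function(kb) {
  stopifnot(inherits(kb, "polykb"))
  tibble::tibble(
    table = names(kb$tables),
    n_fields = vapply(kb$tables, function(t) length(user_fields(t)), 1L),
    n_records = vapply(names(kb$tables), function(n) length(kb$records[[n]]), 1L),
    counter = vapply(names(kb$tables), function(n) kb$counters[[n]], 1L),
    linkable = vapply(kb$tables, function(t) isTRUE(t$linkable), TRUE)
  )
}

#' Field definitions of a table
#'
#' @param kb A knowledgebase.
#' @param table Table name.
#' @return A tibble: field name, type, annotation, a compact text rendering
#'   of its constraints, and the system-key flag.
#' @export
kb_fields <- function(kb, table) {
  key <- need_table(kb, table)
  fs <- kb$tables[[key]]$fields
  tibble::tibble(
    field = vapply(fs, `[[`, "", "name"),
    type = vapply(fs, `[[`, "", "type"),
    annotation = vapply(fs, `[[`, "", "annotation"),
    constraints = vapply(fs, function(f) constraints_text(f$constraints), ""),
    system_key = vapply(fs, function(f) isTRUE(f$system_key), TRUE)
  )
}

constraints_text <- function(cons) {
  if (length(cons) == 0) return("")
  paste(vapply(cons, function(con) {
    if (length(con$params) == 0) con$kind
    else sprintf("%s(%s)", con$kind,
                 paste(unlist(con$params), collapse = ","))
  }, ""), collapse = "; ")
}

#' Full stored definition of a table
#'
#' @param kb A knowledgebase.
#' @param table Table name.
#' @return The internal table definition (name, linkable flag, ordered field
#'   definitions with the system key first).
#' @export
kb_table_def <- function(kb, table) {
  kb$tables[[need_table(kb, table)]]
}

#' Fetch one record
#'
#' @param kb A knowledgebase.
#' @param table,record_id The record.
#' @return A list with `table`, `id`, `values`.
#' @export
kb_record <- function(kb, table, record_id) {
  loc <- locate_record(kb, table, record_id, "unknown-record")
  list(table = loc$key, id = loc$id,
       values = kb$records[[loc$key]][[as.character(loc$id)]])
}

#' Records of a table as a tibble
#'
#' Scalar fields become typed columns; reference fields are rendered as
#' `"Table#id"` text; blanks become `NA`.
#'
#' @param kb A knowledgebase.
#' @param table Table name.
#' @return A tibble with an `id` column plus one column per user field, in
#'   id order.
#' @export
kb_records <- function(kb, table) {
  key <- need_table(kb, table)
  tdef <- kb$tables[[key]]
  recs <- kb$records[[key]]
  ids <- sort(as.integer(names(recs)))
  cols <- list(id = ids)
  for (f in user_fields(tdef)) {
    vals <- lapply(ids, function(i) recs[[as.character(i)]][[f$name]])
    cols[[f$name]] <- if (f$type == "REFERENCE") {
      vapply(vals, function(v) if (is_ref(v)) format(v) else NA_character_, "")
    } else {
      proto <- switch(f$type, INTEGER = NA_integer_, DECIMAL = NA_real_,
                      BOOLEAN = NA, NA_character_)
      vapply(vals, function(v) if (is.null(v)) proto else v, proto)
    }
  }
  tibble::as_tibble(cols)
}

#' Highest id issued for a table
#'
#' Equals the id of the most recent insert; deletions do not lower it.
#'
#' @param kb A knowledgebase.
#' @param table Table name.
#' @return Integer counter value.
#' @export
kb_last_id <- function(kb, table) {
  kb$counters[[need_table(kb, table)]]
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row summary of a knowledgebase
#'
#' @param x A knowledgebase.
#' @param ... Unused.
#' @return A tibble: table count, live record count, stored (non-null)
#'   reference count, and current violation count from [validate_kb()].
#' @method glance polykb
#' @export
glance.polykb <- function(x, ...) {
  n_refs <- 0L
  for (tname in names(x$tables)) {
    for (rec in x$records[[tname]]) {
      n_refs <- n_refs + sum(vapply(rec, is_ref, TRUE))
    }
  }
  tibble::tibble(
    n_tables = length(x$tables),
    n_records = sum(vapply(x$records, length, 1L)),
    n_refs = n_refs,
    n_violations = nrow(validate_kb(x))
  )
}
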