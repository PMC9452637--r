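MINDMAP_FORMAT_VERSION <- "1.0"

# ---- document construction ---------------------------------------------------

field_to_doc <- function(f) {
  if (isTRUE(f$system_key)) {
    return(list(name = f$name, type = f$type, system_key = TRUE))
  }
  list(
    name = f$name,
    type = f$type,
    annotation = f$annotation,
    constraints = lapply(f$constraints, function(con) c(list(kind = con$kind), con$params))
  )
}

encode_value <- function(v) {
  if (is.null(v)) NULL
  else if (is_ref(v)) list(table = v$table, id = v$id)
  else v
}

#' Serialize a knowledgebase to a mind-map document
#'
#' The mind-map document is the knowledgebase's canonical interchange form: a
#' versioned, ordered, human-diffable structured-text record of the full
#' schema, every record (with polymorphic references written as explicit
#' two-part table/id locators, matching how nodes are identified on a
#' mind-map canvas), and the id counters. It is self-contained:
#' `from_mindmap(to_mindmap(kb))` reproduces the knowledgebase exactly.
#'
#' @param kb A knowledgebase.
#' @return A `polykb_mindmap` document (a nested list; render it to text with
#'   [kb_serialize()] or write it with [kb_write_mindmap()]).
#' @export
to_mindmap <- function(kb) {
  stopifnot(inherits(kb, "polykb"))
  tables <- lapply(names(kb$tables), function(tn) {
    tdef <- kb$tables[[tn]]
    list(name = tdef$name, linkable = isTRUE(tdef$linkable),
         fields = lapply(tdef$fields, field_to_doc))
  })
  records <- list()
  counters <- list()
  for (tn in names(kb$tables)) {
    recs <- kb$records[[tn]]
    ids <- sort(as.integer(names(recs)))
    records[[tn]] <- lapply(ids, function(i) {
      vals <- recs[[as.character(i)]]
      enc <- list()
      for (fn in names(vals)) enc[fn] <- list(encode_value(vals[[fn]]))
      list(id = i, values = enc)
    })
    counters[[tn]] <- kb$counters[[tn]]
  }
  structure(
    list(format_version = MINDMAP_FORMAT_VERSION, tables = tables,
         records = records, counters = counters),
    class = "polykb_mindmap"
  )
}

#' Canonical text serialization of a knowledgebase
#'
#' Deterministic YAML rendering of the mind-map document. Two knowledgebases
#' are "serialization-equal" iff these texts are byte-identical; this is the
#' equality used by the round-trip and atomicity guarantees. The migration
#' log is provenance, not content, and is not part of the serialization.
#'
#' @param kb A knowledgebase.
#' @return A single string of YAML text.
#' @export
kb_serialize <- function(kb) {
  yaml::as.yaml(unclass(to_mindmap(kb)), precision = 15L)
}

#' @export
print.polykb_mindmap <- function(x, ...) {
  cat(sprintf("<polykb mind-map document v%s: %d table(s), %d record(s)>\n",
              x$format_version, length(x$tables),
              sum(vapply(x$records, length, 1L))))
  invisible(x)
}

# ---- document parsing --------------------------------------------------------

malformed <- function(where, why) {
  kb_abort("malformed-document", sprintf("malformed document at %s: %s", where, why))
}

doc_to_field <- function(fdoc, where) {
  if (!is.list(fdoc) || is.null(fdoc$name) || is.null(fdoc$type))
    malformed(where, "field needs 'name' and 'type'")
  cons <- lapply(fdoc$constraints, function(cd) {
    if (!is.list(cd) || is.null(cd$kind)) malformed(where, "constraint needs 'kind'")
    do.call(kb_constraint, c(list(kind = cd$kind), cd[setdiff(names(cd), "kind")]))
  })
  tryCatch(
    kb_field(fdoc$name, fdoc$type,
             annotation = if (is.null(fdoc$annotation)) "" else fdoc$annotation,
             constraints = cons),
    polykb_error = function(e) malformed(where, conditionMessage(e))
  )
}

#' Load a knowledgebase from a mind-map document
#'
#' Rebuilds the schema, records, counters and references from a document
#' produced by [to_mindmap()] (or its YAML text). References are re-validated
#' on load, including the single-unique-key rule for their target tables. In
#' strict mode (the default) a document containing a reference whose target
#' table or record does not exist — or whose target table is not linkable —
#' is rejected with a `malformed-document` error naming the reference; in
#' permissive mode such references are loaded as stored and surface through
#' [validate_kb()] instead.
#'
#' @param doc A `polykb_mindmap` document, a nested list of the same shape,
#'   or a string of mind-map YAML.
#' @param permissive Load documents with unresolvable references instead of
#'   rejecting them.
#' @return A knowledgebase. Its migration log is synthesized so that
#'   [kb_replay()] reproduces the loaded state.
#' @export
from_mindmap <- function(doc, permissive = FALSE) {
  if (is.character(doc)) {
    doc <- tryCatch(yaml::yaml.load(paste(doc, collapse = "\n")),
                    error = function(e) malformed("document text", conditionMessage(e)))
  }
  if (!is.list(doc)) malformed("document root", "not a mapping")
  ver <- doc$format_version
  if (is.null(ver)) malformed("document root", "missing format_version")
  if (!identical(as.character(ver), MINDMAP_FORMAT_VERSION))
    kb_abort("version-unsupported",
             sprintf("mind-map format version '%s' is not supported", ver))
  if (!is.list(doc$tables)) malformed("tables", "missing or not a sequence")

  # schema
  kb <- kb_new()
  for (tdoc in doc$tables) {
    if (!is.list(tdoc) || is.null(tdoc$name)) malformed("tables", "table needs a 'name'")
    where <- sprintf("table '%s'", tdoc$name)
    fdocs <- tdoc$fields
    if (is.null(fdocs)) fdocs <- list()
    sys <- Filter(function(fd) isTRUE(fd$system_key), fdocs)
    if (length(sys) != 1 || tolower(sys[[1]]$name) != SYSTEM_KEY_NAME ||
        !identical(sys[[1]]$type, "INTEGER") ||
        !isTRUE(fdocs[[1]]$system_key))
      malformed(where, "must have exactly one leading INTEGER system key named 'id'")
    ufs <- lapply(fdocs[-1], doc_to_field, where = where)
    kb <- tryCatch(
      kb_create_table(kb, tdoc$name, ufs, linkable = !isFALSE(tdoc$linkable)),
      polykb_error_malformed_document = function(e) rlang::cnd_signal(e),
      polykb_error = function(e) malformed(where, conditionMessage(e))
    )
  }

  # strict reference pre-check against the document itself
  doc_ids <- lapply(doc$records, function(rl) {
    vapply(rl, function(r) {
      v <- suppressWarnings(as.integer(r$id))
      if (length(v) != 1) NA_integer_ else v
    }, 1L)
  })
  names(doc_ids) <- names(doc$records)
  if (!permissive) {
    for (tn in names(doc$records)) {
      for (rdoc in doc$records[[tn]]) {
        for (fn in names(rdoc$values)) {
          v <- rdoc$values[[fn]]
          fd <- field_def(kb$tables[[resolve_table_name(kb, tn)]] , fn)
          if (is.null(fd) || fd$type != "REFERENCE" || is.null(v)) next
          if (!is.list(v) || is.null(v$table) || is.null(v$id)) next
          ref_txt <- sprintf("%s#%s.%s -> %s#%s", tn, rdoc$id, fn, v$table, v$id)
          tkey <- resolve_table_name(kb, v$table)
          if (is.na(tkey))
            malformed(ref_txt, "reference targets a table that does not exist")
          if (!isTRUE(kb$tables[[tkey]]$linkable))
            malformed(ref_txt, "reference targets a table without a single unique key")
          if (!(as.integer(v$id) %in% doc_ids[[tkey]]))
            malformed(ref_txt, "reference targets a record that does not exist")
        }
      }
    }
  }

  # records: insert ids 1..counter in order, then delete the gaps, so the
  # synthesized log replays to the exact same state (ids are never reused)
  deferred <- list()
  for (tn in names(doc$records)) {
    key <- resolve_table_name(kb, tn)
    if (is.na(key)) malformed(sprintf("records of '%s'", tn), "table not declared")
    tdef <- kb$tables[[key]]
    rdocs <- doc$records[[tn]]
    ids <- doc_ids[[tn]]
    if (any(is.na(ids)) || any(ids < 1) || anyDuplicated(ids))
      malformed(sprintf("records of '%s'", tn), "ids must be unique positive integers")
    counter <- doc$counters[[tn]]
    if (is.null(counter) || is.na(suppressWarnings(as.integer(counter))) ||
        as.integer(counter) < max(c(0L, ids)))
      malformed(sprintf("counter of '%s'", tn), "missing or below the highest record id")
    counter <- as.integer(counter)
    by_id <- rdocs
    names(by_id) <- as.character(ids)
    for (i in seq_len(counter)) {
      rdoc <- by_id[[as.character(i)]]
      scalars <- list(); raw <- list()
      if (!is.null(rdoc)) {
        vals <- rdoc$values
        if (any(!(names(vals) %in% vapply(user_fields(tdef), `[[`, "", "name"))))
          malformed(sprintf("%s#%d", tn, i), "value for an undeclared field")
        for (fn in names(vals)) {
          fd <- field_def(tdef, fn)
          v <- vals[[fn]]
          if (is.null(v)) next
          if (fd$type == "REFERENCE") {
            if (is.list(v) && !is.null(v$table) && !is.null(v$id)) {
              deferred[[length(deferred) + 1L]] <-
                list(table = key, id = i, field = fn,
                     target_table = as.character(v$table), target_id = as.integer(v$id))
            } else {
              raw[fn] <- list(v)  # garbage in a ref slot: keep for validate_kb
            }
          } else {
            cv <- coerce_scalar(fd$type, v)
            if (is_type_mismatch(cv)) raw[fn] <- list(v) else scalars[fn] <- list(cv)
          }
        }
      }
      kb <- kb_insert(kb, key, scalars)
      for (fn in names(raw)) kb <- kb_set_raw(kb, key, i, fn, raw[[fn]])
    }
    for (i in setdiff(seq_len(counter), ids)) kb <- kb_delete(kb, key, i, "nullify")
  }

  # references last, once every target exists
  for (d in deferred) {
    kb <- tryCatch(
      kb_set_ref(kb, d$table, d$id, d$field, d$target_table, d$target_id),
      polykb_error = function(e) {
        if (!permissive) {
          malformed(sprintf("%s#%d.%s", d$table, d$id, d$field), conditionMessage(e))
        }
        kb_set_raw(kb, d$table, d$id, d$field, kb_ref(d$target_table, d$target_id))
      }
    )
  }
  kb
}

#' Write / read a mind-map document file
#'
#' Files are written atomically (temp file + rename) so an interrupted write
#' never leaves a corrupt document.
#'
#' @param kb A knowledgebase.
#' @param path File path.
#' @param permissive Passed to [from_mindmap()].
#' @return `kb_write_mindmap()` returns the path invisibly;
#'   `kb_read_mindmap()` returns a knowledgebase.
#' @export
kb_write_mindmap <- function(kb, path) {
  tmp <- tempfile("mindmap", tmpdir = dirname(path))
  writeLines(kb_serialize(kb), tmp, sep = "")
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname kb_write_mindmap
#' @export
kb_read_mindmap <- function(path, permissive = FALSE) {
  if (!file.exists(path)) kb_abort("malformed-document", sprintf("no such file: %s", path))
  from_mindmap(paste(readLines(path, warn = FALSE), collapse = "\n"),
               permissive = permissive)
}

# ---- flow traversal ----------------------------------------------------------

#' Walk a decision flow along a reference field
#'
#' Starting from one record, repeatedly follows the named reference field —
#' the "next step" of a stepwise decision flow — collecting the (table, id)
#' steps visited. The walk stops when the field is blank or the current table
#' does not define it (`BLANK_REF`), when the stored reference does not
#' resolve (`MISSING_TARGET`), or when the next step has already been visited
#' (`CYCLE`); cycles are reported, never an error, since decision flows may
#' legitimately loop (e.g. re-test cycles). The path length is therefore
#' bounded by the record count, and traversal terminates on every input.
#'
#' @param kb A knowledgebase.
#' @param start_table,start_id The starting record.
#' @param field The reference field to follow (default `"Next"`).
#' @return A `polykb_flow`: `steps` (tibble of `table`, `id`) and
#'   `terminated_by` (one of `BLANK_REF`, `CYCLE`, `MISSING_TARGET`).
#' @export
traverse_flow <- function(kb, start_table, start_id, field = "Next") {
  stopifnot(inherits(kb, "polykb"))
  loc <- locate_record(kb, start_table, start_id, "unknown-start")
  steps <- list(c(loc$key, loc$id))
  seen <- sprintf("%s#%d", tolower(loc$key), loc$id)
  cur <- loc
  terminated <- NULL
  repeat {
    tdef <- kb$tables[[cur$key]]
    fn <- resolve_field_name(tdef, field)
    if (is.na(fn) || field_def(tdef, fn)$type != "REFERENCE") {
      terminated <- "BLANK_REF"; break
    }
    v <- kb$records[[cur$key]][[as.character(cur$id)]][[fn]]
    if (!is_ref(v)) { terminated <- "BLANK_REF"; break }
    tkey <- resolve_table_name(kb, v$table)
    if (is.na(tkey) || is.null(kb$records[[tkey]][[as.character(v$id)]])) {
      terminated <- "MISSING_TARGET"; break
    }
    nxt <- sprintf("%s#%d", tolower(tkey), v$id)
    if (nxt %in% seen) { terminated <- "CYCLE"; break }
    seen <- c(seen, nxt)
    cur <- list(key = tkey, id = v$id)
    steps[[length(steps) + 1L]] <- c(tkey, v$id)
  }
  structure(
    list(
      steps = tibble::tibble(
        table = vapply(steps, `[[`, "", 1),
        id = as.integer(vapply(steps, `[[`, "", 2))
      ),
      terminated_by = terminated
    ),
    class = "polykb_flow"
  )
}

#' @export
print.polykb_flow <- function(x, ...) {
  cat(paste(sprintf("%s#%d", x$steps$table, x$steps$id), collapse = " -> "),
      sprintf("[%s]\n", x$terminated_by))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a traversal path
#'
#' @param x A `polykb_flow` from [traverse_flow()].
#' @param ... Unused.
#' @return A tibble with `step`, `table`, `id`, `terminated_by` (the
#'   terminator repeated on each row for filtering convenience).
#' @method tidy polykb_flow
#' @export
tidy.polykb_flow <- function(x, ...) {
  dplyr::mutate(x$steps, step = dplyr::row_number(),
                terminated_by = x$terminated_by,
                .before = 1)
}

# ---- DOT rendering -----------------------------------------------------------

#' Render the knowledgebase as a DOT graph
#'
#' One node per record labelled `Table#id` (the identity shown on a mind-map
#' canvas), grouped in one cluster per table, with one directed edge per
#' stored reference labelled by its field name. Output is deterministic —
#' tables sorted by name, records by id — so renders diff cleanly. Layout is
#' delegated to DOT consumers; this engine emits the description only.
#'
#' @param kb A knowledgebase.
#' @param tables Optional character vector restricting the render to these
#'   tables (edges into excluded tables are dropped with their targets).
#' @return DOT text as a single string.
#' @export
render_dot <- function(kb, tables = NULL) {
  stopifnot(inherits(kb, "polykb"))
  tnames <- sort(names(kb$tables), method = "radix")
  if (!is.null(tables)) {
    keep <- vapply(tables, function(t) resolve_table_name(kb, t), "")
    tnames <- tnames[tolower(tnames) %in% tolower(keep)]
  }
  lines <- c("digraph knowledgebase {", "  rankdir=LR;", "  node [shape=box];")
  edges <- character(0)
  for (ti in seq_along(tnames)) {
    tn <- tnames[[ti]]
    ids <- sort(as.integer(names(kb$records[[tn]])))
    lines <- c(lines,
               sprintf("  subgraph cluster_%d {", ti - 1L),
               sprintf("    label=\"%s\";", tn),
               sprintf("    \"%s#%d\";", tn, ids),
               "  }")
    reffields <- vapply(
      Filter(function(f) f$type == "REFERENCE", user_fields(kb$tables[[tn]])),
      `[[`, "", "name")
    for (i in ids) {
      for (fn in reffields) {
        v <- kb$records[[tn]][[as.character(i)]][[fn]]
        if (!is_ref(v)) next
        tkey <- resolve_table_name(kb, v$table)
        if (!is.null(tables) &&
            (is.na(tkey) || !(tkey %in% tnames))) next
        edges <- c(edges, sprintf("  \"%s#%d\" -> \"%s#%d\" [label=\"%s\"];",
                                  tn, i, if (is.na(tkey)) v$table else tkey,
                                  v$id, fn))
      }
    }
  }
  paste(c(lines, edges, "}"), collapse = "\n")
}
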