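# Relational export/import. One dialect (sqlite-compatible) is normative.
#
# Mapping: the system key becomes INTEGER PRIMARY KEY; scalar types map
# TEXT/ENUM/DATE -> TEXT, INTEGER -> INTEGER, DECIMAL -> REAL,
# BOOLEAN -> INTEGER (0/1). Each REFERENCE field f becomes two nullable
# columns f_table (TEXT) and f_id (INTEGER) plus a CHECK that both are null
# or both non-null: the standard relational realization of a stored pair of
# identifiers. No native FOREIGN KEY is emitted for polymorphic references —
# the relational model cannot express a key whose target table varies per
# row, which is the very gap this engine exists to fill; referential
# integrity lives in validate_kb() and the paired-null CHECK.
#
# A dump additionally opens with one `-- polykb-meta: {json}` comment line
# carrying annotations, constraints, linkability and exact id counters, none
# of which plain DDL can hold. SQL engines ignore the comment; import_dump()
# uses it to reconstruct the schema losslessly, and falls back to parsing the
# CREATE TABLE statements (counters then default to the per-table max id)
# for dumps produced elsewhere.

SQL_TYPE_MAP <- c(TEXT = "TEXT", ENUM = "TEXT", DATE = "TEXT",
                  INTEGER = "INTEGER", DECIMAL = "REAL", BOOLEAN = "INTEGER")

sql_ident <- function(x) paste0('"', x, '"')
sql_quote <- function(x) paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
sql_num <- function(x) formatC(x, digits = 15, format = "g")

require_clean <- function(kb, force) {
  if (!force && nrow(validate_kb(kb)) > 0)
    kb_abort("unclean-kb",
             "knowledgebase has outstanding violations; fix them or use force = TRUE")
}

sql_columns <- function(tdef) {
  cols <- list(list(sql = paste(sql_ident(SYSTEM_KEY_NAME), "INTEGER PRIMARY KEY")))
  checks <- character(0)
  for (f in user_fields(tdef)) {
    if (f$type == "REFERENCE") {
      ct <- paste0(f$name, "_table"); ci <- paste0(f$name, "_id")
      cols <- c(cols, list(list(sql = paste(sql_ident(ct), "TEXT")),
                           list(sql = paste(sql_ident(ci), "INTEGER"))))
      checks <- c(checks, sprintf("CHECK ((%s IS NULL) = (%s IS NULL))",
                                  sql_ident(ct), sql_ident(ci)))
    } else {
      cols <- c(cols, list(list(sql = paste(sql_ident(f$name),
                                            SQL_TYPE_MAP[[f$type]]))))
    }
  }
  c(vapply(cols, `[[`, "", "sql"), checks)
}

#' Export the schema as DDL statements
#'
#' @param kb A knowledgebase; must validate clean unless `force = TRUE`
#'   (exports of inconsistent knowledge are refused by default).
#' @param dialect Target dialect; `"sqlite"` is the only normative one.
#' @param force Export despite outstanding violations.
#' @return Character vector: one metadata comment line followed by one
#'   `CREATE TABLE` statement per table, in table creation order.
#' @export
export_ddl <- function(kb, dialect = "sqlite", force = FALSE) {
  stopifnot(inherits(kb, "polykb"))
  dialect <- match.arg(dialect)
  require_clean(kb, force)
  doc <- to_mindmap(kb)
  meta <- jsonlite::toJSON(list(tables = doc$tables, counters = doc$counters),
                           auto_unbox = TRUE, digits = NA, null = "null")
  stmts <- vapply(names(kb$tables), function(tn) {
    sprintf("CREATE TABLE %s (%s);", sql_ident(tn),
            paste(sql_columns(kb$tables[[tn]]), collapse = ", "))
  }, "")
  c(paste0("-- polykb-meta: ", as.character(meta)), unname(stmts))
}

sql_value <- function(type, v) {
  if (is.null(v)) return("NULL")
  if (is_ref(v)) return(c(sql_quote(v$table), as.character(v$id)))
  if (type %in% c("TEXT", "ENUM", "DATE") && is.character(v)) return(sql_quote(v))
  if (type == "INTEGER" && is.numeric(v)) return(as.character(as.integer(v)))
  if (type == "DECIMAL" && is.numeric(v)) return(sql_num(v))
  if (type == "BOOLEAN" && is.logical(v)) return(if (v) "1" else "0")
  # mistyped content (force-exported unclean kb): emit by value class
  if (is.character(v)) sql_quote(v)
  else if (is.logical(v)) (if (v) "1" else "0")
  else if (is.numeric(v)) sql_num(v)
  else sql_quote(paste(format(v), collapse = " "))
}

#' Export the records as DML statements
#'
#' @inheritParams export_ddl
#' @return Character vector of `INSERT` statements with explicit ids,
#'   references in the two-column (table, id) encoding and explicit `NULL`s,
#'   ordered by table creation order then id.
#' @export
export_dml <- function(kb, dialect = "sqlite", force = FALSE) {
  stopifnot(inherits(kb, "polykb"))
  dialect <- match.arg(dialect)
  require_clean(kb, force)
  out <- character(0)
  for (tn in names(kb$tables)) {
    tdef <- kb$tables[[tn]]
    colnames <- SYSTEM_KEY_NAME
    for (f in user_fields(tdef)) {
      colnames <- c(colnames, if (f$type == "REFERENCE")
        c(paste0(f$name, "_table"), paste0(f$name, "_id")) else f$name)
    }
    ids <- sort(as.integer(names(kb$records[[tn]])))
    for (i in ids) {
      vals <- kb$records[[tn]][[as.character(i)]]
      cells <- as.character(i)
      for (f in user_fields(tdef)) {
        v <- vals[[f$name]]
        cell <- sql_value(f$type, v)
        if (f$type == "REFERENCE" && is.null(v)) cell <- c("NULL", "NULL")
        cells <- c(cells, cell)
      }
      out <- c(out, sprintf("INSERT INTO %s (%s) VALUES (%s);", sql_ident(tn),
                            paste(sql_ident(colnames), collapse = ", "),
                            paste(cells, collapse = ", ")))
    }
  }
  out
}

# ---- import ------------------------------------------------------------------

# split "a, b, (c, d)" on top-level commas
split_top_commas <- function(x) {
  depth <- 0L; instr <- FALSE
  chars <- strsplit(x, "")[[1]]
  parts <- character(0); cur <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (instr) {
      if (ch == "'") {
        if (i < length(chars) && chars[i + 1] == "'") { cur <- c(cur, "''"); i <- i + 2L; next }
        instr <- FALSE
      }
      cur <- c(cur, ch)
    } else if (ch == "'") { instr <- TRUE; cur <- c(cur, ch)
    } else if (ch == "(") { depth <- depth + 1L; cur <- c(cur, ch)
    } else if (ch == ")") { depth <- depth - 1L; cur <- c(cur, ch)
    } else if (ch == "," && depth == 0L) {
      parts <- c(parts, trimws(paste(cur, collapse = ""))); cur <- character(0)
    } else cur <- c(cur, ch)
    i <- i + 1L
  }
  c(parts, trimws(paste(cur, collapse = "")))
}

# one SQL literal -> list(kind = "null"|"number"|"string", value)
parse_sql_literal <- function(tok) {
  tok <- trimws(tok)
  if (toupper(tok) == "NULL") return(list(kind = "null", value = NULL))
  if (grepl("^'", tok)) {
    if (!grepl("'$", tok) || nchar(tok) < 2)
      kb_abort("unrecognized-schema-shape", sprintf("bad string literal: %s", tok))
    inner <- substr(tok, 2, nchar(tok) - 1)
    return(list(kind = "string", value = gsub("''", "'", inner, fixed = TRUE)))
  }
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v))
    kb_abort("unrecognized-schema-shape", sprintf("bad literal: %s", tok))
  list(kind = "number", value = v)
}

parse_create_table <- function(stmt) {
  m <- regmatches(stmt, regexec('^CREATE TABLE "([^"]+)" \\((.*)\\);?$', stmt))[[1]]
  if (length(m) != 3)
    kb_abort("unrecognized-schema-shape", sprintf("cannot parse: %s", stmt))
  name <- m[2]
  parts <- split_top_commas(m[3])
  cols <- list()
  standard_pk <- FALSE
  for (p in parts) {
    if (grepl("^CHECK", p, ignore.case = TRUE)) next
    cm <- regmatches(p, regexec('^"([^"]+)"\\s+([A-Za-z]+)(\\s+PRIMARY KEY)?$', p))[[1]]
    if (length(cm) == 0)
      kb_abort("unrecognized-schema-shape", sprintf("cannot parse column: %s", p))
    cols[[length(cols) + 1L]] <- list(name = cm[2], type = toupper(cm[3]),
                                      pk = nzchar(cm[4]))
  }
  if (length(cols) > 0 && tolower(cols[[1]]$name) == "id" &&
      cols[[1]]$type == "INTEGER" && cols[[1]]$pk &&
      !any(vapply(cols[-1], function(c) c$pk, TRUE)))
    standard_pk <- TRUE
  list(name = name, cols = cols, standard_pk = standard_pk)
}

# columns (beyond id) -> field docs, pairing trailing f_table/f_id into refs
cols_to_field_docs <- function(cols) {
  revmap <- c(TEXT = "TEXT", INTEGER = "INTEGER", REAL = "DECIMAL")
  docs <- list()
  i <- 2L
  while (i <= length(cols)) {
    c1 <- cols[[i]]
    c2 <- if (i < length(cols)) cols[[i + 1]] else NULL
    if (!is.null(c2) && grepl("_table$", c1$name) && c1$type == "TEXT" &&
        identical(c2$name, paste0(sub("_table$", "", c1$name), "_id")) &&
        c2$type == "INTEGER") {
      docs[[length(docs) + 1L]] <- list(name = sub("_table$", "", c1$name),
                                        type = "REFERENCE", annotation = "",
                                        constraints = list())
      i <- i + 2L
    } else {
      if (!(c1$type %in% names(revmap)))
        kb_abort("unrecognized-schema-shape",
                 sprintf("unsupported column type %s", c1$type))
      docs[[length(docs) + 1L]] <- list(name = c1$name, type = revmap[[c1$type]],
                                        annotation = "", constraints = list())
      i <- i + 1L
    }
  }
  docs
}

#' Import a relational dump
#'
#' Reconstructs a knowledgebase from statements produced by [export_ddl()] +
#' [export_dml()], or any dump following the same conventions (first column
#' `id INTEGER PRIMARY KEY`; reference fields as adjacent `f_table`/`f_id`
#' column pairs). Per the single-unique-key rule, a referenced table must
#' expose exactly one integer primary key: a ref pair pointing into a table
#' of any other shape fails with `target-table-not-linkable`, and such a
#' table is otherwise not representable (`unrecognized-schema-shape`).
#' Dangling reference pairs load as stored — integrity problems are reported,
#' not hidden — and the validation report is attached as the `violations`
#' attribute of the returned knowledgebase.
#'
#' @param statements Character vector of SQL lines (DDL and DML together or
#'   concatenated; comment and blank lines are ignored except the polykb
#'   metadata comment).
#' @return A knowledgebase with a `violations` attribute.
#' @export
import_dump <- function(statements) {
  statements <- trimws(unlist(strsplit(statements, "\n", fixed = TRUE)))
  meta_line <- grep("^-- polykb-meta: ", statements, value = TRUE)
  stmts <- statements[nzchar(statements) & !grepl("^--", statements)]

  creates <- grep("^CREATE TABLE ", stmts, value = TRUE)
  inserts <- grep("^INSERT INTO ", stmts, value = TRUE)
  if (length(setdiff(stmts, c(creates, inserts))) > 0)
    kb_abort("unrecognized-schema-shape", "dump contains unsupported statements")

  parsed <- lapply(creates, parse_create_table)
  names(parsed) <- vapply(parsed, `[[`, "", "name")

  # schema: exact from metadata when present, inferred from DDL otherwise
  if (length(meta_line) > 0) {
    meta <- jsonlite::fromJSON(sub("^-- polykb-meta: ", "", meta_line[[1]]),
                               simplifyVector = FALSE)
    tdocs <- meta$tables
    counters <- meta$counters
  } else {
    tdocs <- lapply(parsed, function(p) {
      if (!p$standard_pk) {
        targeted <- any(vapply(inserts, function(s) {
          grepl(sprintf("'%s'", p$name), s, fixed = TRUE)
        }, TRUE))
        if (targeted)
          kb_abort("target-table-not-linkable",
                   sprintf("table '%s' lacks a single integer unique key", p$name))
        kb_abort("unrecognized-schema-shape",
                 sprintf("table '%s' lacks the standard system key", p$name))
      }
      list(name = p$name, linkable = TRUE,
           fields = c(list(list(name = "id", type = "INTEGER", system_key = TRUE)),
                      cols_to_field_docs(p$cols)))
    })
    counters <- NULL  # fall back to per-table max id below
  }

  # records
  rec_docs <- lapply(tdocs, function(td) list())
  names(rec_docs) <- vapply(tdocs, function(td) td$name, "")
  for (stmt in inserts) {
    m <- regmatches(stmt, regexec('^INSERT INTO "([^"]+)" \\((.*?)\\) VALUES \\((.*)\\);?$',
                                  stmt))[[1]]
    if (length(m) != 4)
      kb_abort("unrecognized-schema-shape", sprintf("cannot parse: %s", stmt))
    tn <- m[2]
    if (!(tn %in% names(rec_docs)))
      kb_abort("unrecognized-schema-shape", sprintf("INSERT into undeclared table '%s'", tn))
    colnames <- gsub('"', "", split_top_commas(m[3]))
    toks <- lapply(split_top_commas(m[4]), parse_sql_literal)
    if (length(toks) != length(colnames))
      kb_abort("unrecognized-schema-shape", sprintf("column/value mismatch: %s", stmt))
    names(toks) <- colnames

    td <- tdocs[[which(vapply(tdocs, function(t) t$name, "") == tn)]]
    idv <- toks[[SYSTEM_KEY_NAME]]
    if (is.null(idv) || idv$kind != "number")
      kb_abort("unrecognized-schema-shape", sprintf("missing id in: %s", stmt))
    vals <- list()
    for (fd in td$fields) {
      if (isTRUE(fd$system_key)) next
      if (fd$type == "REFERENCE") {
        vt <- toks[[paste0(fd$name, "_table")]]; vi <- toks[[paste0(fd$name, "_id")]]
        if (is.null(vt) || is.null(vi)) next
        if (vt$kind == "null" && vi$kind == "null") {
          vals[fd$name] <- list(NULL)
        } else if (vt$kind == "string" && vi$kind == "number") {
          vals[fd$name] <- list(list(table = vt$value, id = as.integer(vi$value)))
        } else {
          kb_abort("unrecognized-schema-shape",
                   sprintf("half-null reference pair for '%s' in: %s", fd$name, stmt))
        }
      } else {
        tok <- toks[[fd$name]]
        if (is.null(tok) || tok$kind == "null") { vals[fd$name] <- list(NULL); next }
        v <- tok$value
        if (fd$type == "BOOLEAN" && tok$kind == "number" && v %in% c(0, 1)) v <- v == 1
        vals[fd$name] <- list(v)  # mistyped content surfaces via validate_kb
      }
    }
    rec_docs[[tn]] <- c(rec_docs[[tn]], list(list(id = as.integer(idv$value),
                                                  values = vals)))
  }

  if (is.null(counters)) {
    counters <- lapply(rec_docs, function(rl) {
      max(c(0L, vapply(rl, function(r) r$id, 1L)))
    })
  }
  doc <- list(format_version = MINDMAP_FORMAT_VERSION, tables = tdocs,
              records = rec_docs, counters = counters)
  kb <- from_mindmap(doc, permissive = TRUE)
  attr(kb, "violations") <- validate_kb(kb)
  kb
}

#' Write / read a SQL dump directory
#'
#' `kb_export_sql()` writes `schema.sql` (DDL with the metadata comment) and
#' `data.sql` (DML) into `dir`; `kb_import_sql()` reads them back.
#'
#' @param kb A knowledgebase.
#' @param dir Directory for the two dump files (created if missing).
#' @param force Export despite outstanding violations.
#' @return `kb_export_sql()` returns `dir` invisibly; `kb_import_sql()`
#'   returns the imported knowledgebase (see [import_dump()]).
#' @export
kb_export_sql <- function(kb, dir, force = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(export_ddl(kb, force = force), file.path(dir, "schema.sql"))
  writeLines(export_dml(kb, force = force), file.path(dir, "data.sql"))
  invisible(dir)
}

#' @rdname kb_export_sql
#' @export
kb_import_sql <- function(dir) {
  paths <- file.path(dir, c("schema.sql", "data.sql"))
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0)
    kb_abort("unrecognized-schema-shape", sprintf("no dump files under %s", dir))
  import_dump(unlist(lapply(paths, readLines, warn = FALSE)))
}
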