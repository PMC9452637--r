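VIOLATION_CODES <- c("DANGLING_REF_TABLE", "DANGLING_REF_RECORD", "REQUIRED_NULL",
                     "TYPE_MISMATCH", "ENUM_VIOLATION", "PATTERN_VIOLATION",
                     "RANGE_VIOLATION", "LENGTH_VIOLATION", "UNIQUE_VIOLATION",
                     "TARGET_NOT_LINKABLE")

violation <- function(code, table = NA_character_, record_id = NA_integer_,
                      field = NA_character_, message = "") {
  tibble::tibble(code = code, table = table,
                 record_id = as.integer(record_id), field = field,
                 message = message)
}

empty_violations <- function() {
  tibble::tibble(code = character(0), table = character(0),
                 record_id = integer(0), field = character(0),
                 message = character(0))
}

#' Check one value against a field definition
#'
#' Violations are returned as data, never raised: curation tooling needs the
#' full report, not a first-failure abort. A null value passes every
#' constraint except `required` — partially entered knowledge is a normal
#' intermediate state in this workflow.
#'
#' @param field A [kb_field()] definition.
#' @param value A scalar, a [kb_ref()] value, or `NULL`.
#' @return A tibble of violations (`code`, `message`; locator columns blank),
#'   empty iff the value satisfies the field's type and all its constraints.
#' @export
validate_value <- function(field, value) {
  out <- list()
  add <- function(code, msg) out[[length(out) + 1L]] <<- violation(code, message = msg)

  if (is.null(value)) {
    for (con in field$constraints) {
      if (con$kind == "required")
        add("REQUIRED_NULL", sprintf("'%s' is required but blank", field$name))
    }
    return(bind_violations(out))
  }

  coerced <- coerce_scalar(field$type, value)
  if (is_type_mismatch(coerced)) {
    add("TYPE_MISMATCH", sprintf("'%s' holds a value that is not a valid %s",
                                 field$name, field$type))
    return(bind_violations(out))
  }
  value <- coerced
  if (is_ref(value)) return(bind_violations(out))  # resolution is kb-level

  for (con in field$constraints) {
    k <- con$kind
    p <- con$params
    if (k == "enum_values" && !(value %in% p$values)) {
      add("ENUM_VIOLATION",
          sprintf("'%s' value %s not among {%s}", field$name,
                  deparse(value), paste(p$values, collapse = ", ")))
    } else if (k == "pattern" && !grepl(p$pattern, value)) {
      add("PATTERN_VIOLATION",
          sprintf("'%s' value %s does not match /%s/", field$name,
                  deparse(value), p$pattern))
    } else if (k == "min_value" && value < p$value) {
      add("RANGE_VIOLATION",
          sprintf("'%s' value %s below minimum %s", field$name, value, p$value))
    } else if (k == "max_value" && value > p$value) {
      add("RANGE_VIOLATION",
          sprintf("'%s' value %s above maximum %s", field$name, value, p$value))
    } else if (k == "max_length" && nchar(value) > p$value) {
      add("LENGTH_VIOLATION",
          sprintf("'%s' value exceeds max length %d", field$name, p$value))
    }
  }
  bind_violations(out)
}

bind_violations <- function(lst) {
  if (length(lst) == 0) empty_violations() else dplyr::bind_rows(lst)
}

#' Validate a whole knowledgebase
#'
#' Batch integrity check over the entity base: per-value type and constraint
#' checks, uniqueness (nulls never conflict, per the usual relational
#' convention), dangling polymorphic references, and references into tables
#' that do not satisfy the single-unique-key rule (possible only for imported
#' tables; every table this engine creates is linkable). The report order is
#' deterministic: per-value violations first, then uniqueness, then dangling
#' references, then non-linkable targets, each group swept in (table, id,
#' field) schema order.
#'
#' A knowledgebase built purely through the mutation interface can produce
#' value/constraint violations (constraints are deliberately enforced late),
#' but never a dangling reference: links are validated when they are made and
#' deletion either refuses or nullifies.
#'
#' @param kb A knowledgebase.
#' @return A tibble of violations (`code`, `table`, `record_id`, `field`,
#'   `message`); empty for a clean knowledgebase.
#' @export
validate_kb <- function(kb) {
  stopifnot(inherits(kb, "polykb"))
  value_v <- list(); unique_v <- list(); dangling_v <- list(); linkable_v <- list()

  for (tname in names(kb$tables)) {
    tdef <- kb$tables[[tname]]
    recs <- kb$records[[tname]]
    ids <- sort(as.integer(names(recs)))
    ufields <- user_fields(tdef)

    for (rid in ids) {
      vals <- recs[[as.character(rid)]]
      for (f in ufields) {
        vv <- validate_value(f, vals[[f$name]])
        if (nrow(vv) > 0) {
          vv$table <- tname; vv$record_id <- rid; vv$field <- f$name
          value_v[[length(value_v) + 1L]] <- vv
        }
      }
    }

    for (f in ufields) {
      if (!any(vapply(f$constraints, function(c) c$kind == "unique", TRUE)))
        next
      seen <- character(0)
      for (rid in ids) {
        v <- recs[[as.character(rid)]][[f$name]]
        if (is.null(v) || is_ref(v)) next
        keyv <- paste0(class(v)[1], ":", as.character(v))
        if (keyv %in% seen) {
          unique_v[[length(unique_v) + 1L]] <- violation(
            "UNIQUE_VIOLATION", tname, rid, f$name,
            sprintf("duplicate value %s in unique field '%s'",
                    deparse(as.character(v)), f$name))
        } else {
          seen <- c(seen, keyv)
        }
      }
    }

    reffields <- Filter(function(f) f$type == "REFERENCE", ufields)
    for (rid in ids) {
      for (f in reffields) {
        v <- recs[[as.character(rid)]][[f$name]]
        if (!is_ref(v)) next
        tkey <- resolve_table_name(kb, v$table)
        if (is.na(tkey)) {
          dangling_v[[length(dangling_v) + 1L]] <- violation(
            "DANGLING_REF_TABLE", tname, rid, f$name,
            sprintf("reference %s points at a table that does not exist", format(v)))
        } else if (is.null(kb$records[[tkey]][[as.character(v$id)]])) {
          dangling_v[[length(dangling_v) + 1L]] <- violation(
            "DANGLING_REF_RECORD", tname, rid, f$name,
            sprintf("reference %s points at a record that does not exist", format(v)))
        } else if (!isTRUE(kb$tables[[tkey]]$linkable)) {
          linkable_v[[length(linkable_v) + 1L]] <- violation(
            "TARGET_NOT_LINKABLE", tname, rid, f$name,
            sprintf("reference %s targets a table without a single unique key", format(v)))
        }
      }
    }
  }

  dplyr::bind_rows(empty_violations(), bind_violations(value_v),
                   bind_violations(unique_v), bind_violations(dangling_v),
                   bind_violations(linkable_v))
}
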