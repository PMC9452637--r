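# Random knowledgebase generators. Both draw from R's RNG, so callers seed
# with set.seed(); they back the property tests and the reproducibility
# checks (round trips, fuzzed operation sequences).

# sample() treats a length-1 numeric as 1:n; this never does
resample <- function(x) x[sample.int(length(x), 1)]

rand_ident <- function(prefix) {
  paste0(prefix, "_", paste(sample(letters, 5, replace = TRUE), collapse = ""))
}

SIM_ENUM_LEVELS <- c("low", "normal", "high")

sim_field <- function(type, name) {
  cons <- list()
  if (stats::runif(1) < 0.4) cons <- c(cons, list(kb_constraint("required")))
  cons <- switch(type,
    TEXT = c(cons, if (stats::runif(1) < 0.3) list(kb_constraint("pattern", pattern = "^[a-z ]*$")),
             if (stats::runif(1) < 0.3) list(kb_constraint("max_length", value = 64L))),
    INTEGER = c(cons, if (stats::runif(1) < 0.4)
      list(kb_constraint("min_value", value = 0), kb_constraint("max_value", value = 1000))),
    DECIMAL = c(cons, if (stats::runif(1) < 0.4)
      list(kb_constraint("min_value", value = 0), kb_constraint("max_value", value = 1000))),
    ENUM = c(cons, list(kb_constraint("enum_values", values = SIM_ENUM_LEVELS))),
    cons
  )
  kb_field(name, type, annotation = if (stats::runif(1) < 0.5) rand_ident("note") else "",
           constraints = cons)
}

sim_value <- function(type) {
  switch(type,
    TEXT = paste(sample(letters, sample(3:12, 1), replace = TRUE), collapse = ""),
    # <= 6 significant digits so decimal text survives every round trip exactly
    DECIMAL = round(stats::runif(1, 0, 1000), 3),
    INTEGER = sample(0:1000, 1),
    BOOLEAN = sample(c(TRUE, FALSE), 1),
    DATE = format(as.Date("2015-01-01") + sample(0:3000, 1), "%Y-%m-%d"),
    ENUM = sample(SIM_ENUM_LEVELS, 1),
    NULL
  )
}

#' Generate a random clean knowledgebase
#'
#' Builds a schema of `n_tables` tables with randomly typed, annotated and
#' constrained fields (every scalar type is drawn from; constraints are
#' generated so that the generated content satisfies them), fills each table
#' with records, wires random polymorphic references between tables, and
#' deletes a few records under the nullify policy so that id sequences carry
#' realistic gaps. The result always passes [validate_kb()] cleanly, which is
#' what the round-trip properties require of their inputs.
#'
#' @param n_tables Number of tables.
#' @param max_records Maximum records per table (actual counts vary).
#' @param p_ref Probability that a reference field of a record gets linked.
#' @return A knowledgebase.
#' @export
kb_simulate <- function(n_tables = 3, max_records = 6, p_ref = 0.6) {
  kb <- kb_new()
  tnames <- character(n_tables)
  for (i in seq_len(n_tables)) {
    tnames[i] <- rand_ident(paste0("T", i))
    n_scalar <- sample(1:3, 1)
    types <- sample(c("TEXT", "INTEGER", "DECIMAL", "BOOLEAN", "DATE", "ENUM"),
                    n_scalar, replace = TRUE)
    fields <- lapply(seq_along(types), function(j) {
      sim_field(types[j], paste0("f", j, "_", tolower(types[j])))
    })
    for (k in seq_len(sample(0:2, 1))) {
      fields <- c(fields, list(kb_field(paste0("ref", k), "REFERENCE")))
    }
    kb <- kb_create_table(kb, tnames[i], fields)
  }
  for (tn in tnames) {
    for (r in seq_len(sample(0:max_records, 1))) {
      vals <- list()
      for (f in user_fields(kb$tables[[tn]])) {
        if (f$type == "REFERENCE") next
        vals[[f$name]] <- sim_value(f$type)
      }
      kb <- kb_insert(kb, tn, vals)
    }
  }
  for (tn in tnames) {
    ids <- as.integer(names(kb$records[[tn]]))
    reffields <- vapply(
      Filter(function(f) f$type == "REFERENCE", user_fields(kb$tables[[tn]])),
      `[[`, "", "name")
    for (i in ids) {
      for (fn in reffields) {
        if (stats::runif(1) > p_ref) next
        tt <- sample(tnames, 1)
        tids <- as.integer(names(kb$records[[tt]]))
        if (length(tids) == 0) next
        kb <- kb_set_ref(kb, tn, i, fn, tt, resample(tids))
      }
    }
  }
  for (tn in tnames) {
    for (i in as.integer(names(kb$records[[tn]]))) {
      if (stats::runif(1) < 0.1) kb <- kb_delete(kb, tn, i, "nullify")
    }
  }
  kb
}

#' Apply a random sequence of mutation operations
#'
#' Interleaves table creation, field addition, inserts, reference linking and
#' clearing, and nullify-policy deletions with randomly chosen valid
#' arguments, starting from an empty knowledgebase. Used to check that no
#' reachable state ever stores a dangling reference and that ids stay
#' monotonic under arbitrary operation orderings — the engine's guarantee
#' that schema curation and content entry can alternate freely.
#'
#' @param n_ops Number of operations to apply.
#' @return The resulting knowledgebase.
#' @export
kb_fuzz <- function(n_ops = 40) {
  kb <- kb_new()
  n_created <- 0L
  new_table <- function(kb) {
    n_created <<- n_created + 1L
    fields <- list(kb_field("label", "TEXT"), kb_field("next_step", "REFERENCE"))
    if (stats::runif(1) < 0.5) fields <- c(fields, list(sim_field("INTEGER", "rank")))
    kb_create_table(kb, paste0("Fz", n_created, "_", rand_ident("t")), fields)
  }
  pick_record <- function(kb) {
    withrec <- names(kb$records)[vapply(kb$records, length, 1L) > 0]
    if (length(withrec) == 0) return(NULL)
    tn <- resample(withrec)
    list(table = tn, id = resample(as.integer(names(kb$records[[tn]]))))
  }
  for (op in sample(c("create", "add_field", "insert", "set_ref", "clear_ref",
                      "delete"), n_ops, replace = TRUE,
                    prob = c(0.10, 0.10, 0.35, 0.25, 0.05, 0.15))) {
    if (length(kb$tables) == 0) op <- "create"
    kb <- switch(op,
      create = new_table(kb),
      add_field = {
        tn <- sample(names(kb$tables), 1)
        kb_add_field(kb, tn, sim_field(
          sample(c("TEXT", "INTEGER", "DECIMAL", "BOOLEAN", "DATE", "ENUM"), 1),
          rand_ident("x")))
      },
      insert = {
        tn <- sample(names(kb$tables), 1)
        vals <- list()
        for (f in user_fields(kb$tables[[tn]])) {
          if (f$type != "REFERENCE" && stats::runif(1) < 0.7)
            vals[[f$name]] <- sim_value(f$type)
        }
        kb_insert(kb, tn, vals)
      },
      set_ref = {
        src <- pick_record(kb)
        reffields <- if (is.null(src)) character(0) else vapply(
          Filter(function(f) f$type == "REFERENCE", user_fields(kb$tables[[src$table]])),
          `[[`, "", "name")
        tgt <- pick_record(kb)
        if (is.null(src) || is.null(tgt) || length(reffields) == 0) kb
        else kb_set_ref(kb, src$table, src$id, sample(reffields, 1),
                        tgt$table, tgt$id)
      },
      clear_ref = {
        src <- pick_record(kb)
        reffields <- if (is.null(src)) character(0) else vapply(
          Filter(function(f) f$type == "REFERENCE", user_fields(kb$tables[[src$table]])),
          `[[`, "", "name")
        if (is.null(src) || length(reffields) == 0) kb
        else kb_clear_ref(kb, src$table, src$id, sample(reffields, 1))
      },
      delete = {
        r <- pick_record(kb)
        if (is.null(r)) kb else kb_delete(kb, r$table, r$id, "nullify")
      }
    )
  }
  kb
}
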