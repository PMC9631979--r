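#' Parameter databases: a shared table of simulation jobs
#'
#' A parameter database is a spreadsheet-like table. The header row names the
#' attributes; every other row is one *job*: a unique `id`, a `status`, optional
#' metadata (`start-time`, `end-time`, `comment`) and one parameter set. Workers
#' coordinate solely through this table — there is no job-distribution server.
#'
#' The status lifecycle is encoded in the `status` cell: the empty string means
#' the job is pending (never started), `"successful"` means complete, `"failed"`
#' means finished unsuccessfully, and any other non-empty value names the
#' pipeline task the job is currently completing (e.g. `"in progress"`,
#' `"running simulation"`).
#'
#' Two reference backends are provided: [delimited_db()], a delimited text file
#' suitable for a single machine (multiple local processes serialize through an
#' advisory lock), and [memory_db()], an in-memory stand-in for a remote
#' spreadsheet service used in tests and simulated-concurrency studies. Any
#' other backend (e.g. an online spreadsheet) can plug in by implementing the
#' five generics [db_get_table()], [db_get_attributes()], [db_update_row()],
#' [db_update_cell()] and [db_claim_if_pending()].
#'
#' All cell values are stored and round-tripped as strings.
#'
#' @name job-database
NULL

RESERVED_ATTRIBUTES <- c("id", "status", "start-time", "end-time", "comment")
STATUS_PENDING    <- ""
STATUS_SUCCESSFUL <- "successful"
STATUS_FAILED     <- "failed"
STATUS_IN_PROGRESS <- "in progress"

# -- table validation ---------------------------------------------------------

validate_table <- function(df, where = "table") {
  header <- names(df)
  if (!all(c("id", "status") %in% header)) {
    stop_sweepq("sweepq_schema_error",
                "%s: header must contain 'id' and 'status' (found: %s)",
                where, paste(header, collapse = ", "))
  }
  if (anyDuplicated(header)) {
    stop_sweepq("sweepq_schema_error", "%s: duplicated attribute names", where)
  }
  ids <- df[["id"]]
  if (any(!nzchar(ids))) {
    stop_sweepq("sweepq_schema_error", "%s: empty job id", where)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop_sweepq("sweepq_schema_error",
                "%s: duplicated job id(s): %s", where,
                paste(dup, collapse = ", "))
  }
  invisible(df)
}

as_character_df <- function(df) {
  df[] <- lapply(df, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })
  rownames(df) <- NULL
  df
}

# -- delimited-file backend ---------------------------------------------------

#' Open a delimited-file parameter database
#'
#' The file must exist and its header row must contain `id` and `status`.
#' Opening performs a schema check (duplicate ids are a hard error — silently
#' proceeding would corrupt claim semantics) but never modifies the file.
#'
#' @param path Path to the delimited text file (UTF-8, header row mandatory).
#' @param delimiter Field delimiter, comma by default.
#' @param lock_timeout Seconds to wait for the advisory file lock before
#'   signalling a retryable contention error.
#' @return A database handle usable with [db_get_table()] and friends.
#' @examples
#' db_file <- tempfile(fileext = ".csv")
#' sample_db(db_file)
#' db <- delimited_db(db_file)
#' db_get_attributes(db)
#' @export
delimited_db <- function(path, delimiter = ",", lock_timeout = 10) {
  if (!file.exists(path)) {
    stop_sweepq("sweepq_not_found_error", "database file '%s' not found", path)
  }
  handle <- new.env(parent = emptyenv())
  handle$path <- path
  handle$delimiter <- delimiter
  handle$lock_timeout <- lock_timeout
  class(handle) <- c("sweepq_delimited_db", "sweepq_db")
  validate_table(read_delimited(handle), where = path)
  handle
}

read_delimited <- function(db) {
  if (!file.exists(db$path)) {
    stop_sweepq("sweepq_io_error", "database file '%s' is unreachable", db$path)
  }
  df <- utils::read.table(db$path, header = TRUE, sep = db$delimiter,
                          quote = "\"", colClasses = "character",
                          check.names = FALSE, na.strings = character(),
                          fileEncoding = "UTF-8", comment.char = "",
                          stringsAsFactors = FALSE)
  as_character_df(df)
}

quote_field <- function(x, delim) {
  needs <- grepl(sprintf('[%s"\n\r]', delim), x, fixed = FALSE)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

format_delimited <- function(df, delim) {
  header <- paste(quote_field(names(df), delim), collapse = delim)
  if (nrow(df) == 0) return(header)
  cells <- vapply(seq_len(nrow(df)), function(i) {
    paste(quote_field(as.character(unlist(df[i, ], use.names = FALSE)), delim),
          collapse = delim)
  }, character(1))
  c(header, cells)
}

write_delimited <- function(db, df) {
  atomic_write_lines(format_delimited(df, db$delimiter), db$path)
}

lock_path_for <- function(db) paste0(db$path, ".lock")

# -- in-memory (remote-spreadsheet mock) backend ------------------------------

#' In-memory parameter database (remote-spreadsheet mock)
#'
#' Holds the table in process memory behind the same contract as
#' [delimited_db()]. Claims are a compare-and-swap: the status is re-read
#' immediately before the write, so a claim succeeds only if the job is still
#' pending at write time. The optional `before_cas` hook is invoked at the top
#' of every [db_claim_if_pending()] call and exists so tests can script
#' adversarial interleavings (e.g. a rival worker stealing the row between a
#' scan and the claim).
#'
#' @param table A data.frame whose columns include `id` and `status`; all
#'   values are coerced to strings.
#' @param before_cas Optional `function(db, job_id)` run before the
#'   compare-and-swap.
#' @return A database handle.
#' @examples
#' db <- memory_db(data.frame(id = c("a", "b"), status = c("", ""),
#'                            x = c("1", "2"), check.names = FALSE))
#' db_claim_if_pending(db, "a", "in progress")
#' @export
memory_db <- function(table, before_cas = NULL) {
  df <- validate_table(as_character_df(as.data.frame(table)), "memory table")
  handle <- new.env(parent = emptyenv())
  handle$table <- df
  handle$before_cas <- before_cas
  class(handle) <- c("sweepq_memory_db", "sweepq_db")
  handle
}

#' Open a parameter database from a backend descriptor
#'
#' Convenience dispatcher: a character path opens a [delimited_db()]; a list
#' with a `kind` field (`"delimited"` or `"memory"`) selects the backend
#' explicitly and passes the remaining fields as arguments.
#'
#' @param source A file path or a descriptor list.
#' @return A database handle.
#' @export
open_database <- function(source) {
  if (is.character(source) && length(source) == 1) {
    return(delimited_db(source))
  }
  if (is.list(source) && !is.null(source$kind)) {
    args <- source[setdiff(names(source), "kind")]
    return(switch(source$kind,
      delimited = do.call(delimited_db, args),
      memory = do.call(memory_db, args),
      stop_sweepq("sweepq_schema_error", "unknown backend kind '%s'",
                  source$kind)
    ))
  }
  stop_sweepq("sweepq_schema_error", "invalid database descriptor")
}

# -- adapter contract ---------------------------------------------------------

#' Retrieve the entire parameter table
#'
#' Returns a faithful snapshot of the table as a data.frame of strings, in
#' stored header and row order. Repeated calls with no intervening writes are
#' identical; re-reads observe external edits to the backing store.
#'
#' @param db A database handle.
#' @return A data.frame, all columns character.
#' @export
db_get_table <- function(db) UseMethod("db_get_table")

#' @export
db_get_table.sweepq_delimited_db <- function(db) read_delimited(db)

#' @export
db_get_table.sweepq_memory_db <- function(db) db$table

#' Attribute names of the database
#'
#' @param db A database handle.
#' @return Character vector of column headers, in stored order.
#' @export
db_get_attributes <- function(db) UseMethod("db_get_attributes")

#' @export
db_get_attributes.sweepq_db <- function(db) names(db_get_table(db))

#' Replace one job's row
#'
#' The row identified by `job_id` is fully replaced by `record`; every other
#' row is untouched. `record` must carry exactly the table's attributes (any
#' order); its `id` must equal `job_id`.
#'
#' @param db A database handle.
#' @param job_id Job identifier.
#' @param record Named list or character vector of attribute -> value.
#' @return `TRUE`, invisibly. Unknown ids raise a not-found condition;
#'   attribute mismatches raise a schema-violation condition.
#' @export
db_update_row <- function(db, job_id, record) UseMethod("db_update_row")

check_record <- function(record, header, job_id) {
  record <- as.list(record)
  if (!setequal(names(record), header)) {
    stop_sweepq("sweepq_schema_error",
                "record attributes do not match the table header")
  }
  record <- record[header]
  if (!identical(as.character(record$id), job_id)) {
    stop_sweepq("sweepq_schema_error",
                "record id '%s' does not match target job '%s'",
                record$id, job_id)
  }
  vapply(record, as.character, character(1))
}

row_index <- function(df, job_id) {
  i <- which(df$id == job_id)
  if (!length(i)) {
    stop_sweepq("sweepq_not_found_error", "no job with id '%s'", job_id)
  }
  i[[1]]
}

#' @export
db_update_row.sweepq_delimited_db <- function(db, job_id, record) {
  with_file_lock(lock_path_for(db), timeout = db$lock_timeout, {
    df <- read_delimited(db)
    i <- row_index(df, job_id)
    df[i, ] <- as.list(check_record(record, names(df), job_id))
    write_delimited(db, df)
  })
  invisible(TRUE)
}

#' @export
db_update_row.sweepq_memory_db <- function(db, job_id, record) {
  df <- db$table
  i <- row_index(df, job_id)
  df[i, ] <- as.list(check_record(record, names(df), job_id))
  db$table <- df
  invisible(TRUE)
}

#' Update a single cell
#'
#' Exactly one cell — row `job_id`, column `attribute` — is changed.
#'
#' @param db A database handle.
#' @param job_id Job identifier.
#' @param attribute Column name.
#' @param value New cell value (a string; other scalars are coerced).
#' @return `TRUE`, invisibly. Unknown id or attribute raises not-found.
#' @export
db_update_cell <- function(db, job_id, attribute, value) {
  UseMethod("db_update_cell")
}

check_attribute <- function(header, attribute) {
  if (!attribute %in% header) {
    stop_sweepq("sweepq_not_found_error", "no attribute '%s'", attribute)
  }
}

#' @export
db_update_cell.sweepq_delimited_db <- function(db, job_id, attribute, value) {
  with_file_lock(lock_path_for(db), timeout = db$lock_timeout, {
    df <- read_delimited(db)
    check_attribute(names(df), attribute)
    df[row_index(df, job_id), attribute] <- as.character(value)
    write_delimited(db, df)
  })
  invisible(TRUE)
}

#' @export
db_update_cell.sweepq_memory_db <- function(db, job_id, attribute, value) {
  df <- db$table
  check_attribute(names(df), attribute)
  df[row_index(df, job_id), attribute] <- as.character(value)
  db$table <- df
  invisible(TRUE)
}

#' Atomically claim a pending job
#'
#' If — and only if — the job's status is still the empty string at write
#' time, it becomes `claim_label` and the claim succeeds. Otherwise nothing
#' changes and the claim fails. This check-and-set is what guarantees a job is
#' never run twice: the delimited backend serializes claimants through an
#' exclusive advisory lock on the file, and the in-memory backend re-reads the
#' status immediately before writing (compare-and-swap).
#'
#' @param db A database handle.
#' @param job_id Job identifier (must exist).
#' @param claim_label Status value to install, conventionally `"in progress"`.
#' @return `TRUE` if this call claimed the job, `FALSE` if it was no longer
#'   pending. Lock-acquisition timeout raises a retryable
#'   `sweepq_contention_error`.
#' @export
db_claim_if_pending <- function(db, job_id, claim_label = STATUS_IN_PROGRESS) {
  UseMethod("db_claim_if_pending")
}

#' @export
db_claim_if_pending.sweepq_delimited_db <- function(db, job_id,
    claim_label = STATUS_IN_PROGRESS) {
  with_file_lock(lock_path_for(db), timeout = db$lock_timeout, {
    df <- read_delimited(db)
    i <- row_index(df, job_id)
    if (!identical(df$status[i], STATUS_PENDING)) return(FALSE)
    df$status[i] <- claim_label
    write_delimited(db, df)
    TRUE
  })
}

#' @export
db_claim_if_pending.sweepq_memory_db <- function(db, job_id,
    claim_label = STATUS_IN_PROGRESS) {
  if (is.function(db$before_cas)) db$before_cas(db, job_id)
  df <- db$table
  i <- row_index(df, job_id)
  if (!identical(df$status[i], STATUS_PENDING)) return(FALSE)
  df$status[i] <- claim_label
  db$table <- df
  TRUE
}

#' @export
print.sweepq_db <- function(x, ...) {
  df <- db_get_table(x)
  cat(sprintf("<%s> %d attribute(s), %d job(s)\n",
              class(x)[1], ncol(df), nrow(df)))
  invisible(x)
}

# Fetch one job as a named list of strings (internal; managers build on it).
db_get_record <- function(db, job_id) {
  df <- db_get_table(db)
  as.list(df[row_index(df, job_id), , drop = FALSE])
}
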