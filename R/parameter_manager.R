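#' Parameter manager: the claim/status job lifecycle
#'
#' A parameter manager drives one worker's walk through the shared table:
#' fetch the next pending job ([next_parameters()]), advance its status as the
#' pipeline progresses ([update_status()]), and record the outcome
#' ([successful()] / [failed()]). It also honors the session run limit
#' (`num-of-runs`) and crash-resume (`last-test`) read from a [load_config()]
#' store.
#'
#' A claimed job's status becomes `"in progress"` and, if the table has a
#' `start-time` attribute, the claim moment is stamped in local time as
#' `"YYYY-MM-DD HH:MM:SS"`. Completion stamps `end-time` the same way.
#'
#' @name parameter-manager
NULL

#' Create a parameter manager
#'
#' @param db A database handle (see [delimited_db()], [memory_db()]).
#' @param config Optional [load_config()] store. Supplies `num-of-runs` (how
#'   many jobs this session may start; `-1` = unlimited) and persists
#'   `last-test` (the current job id) so an interrupted session resumes the
#'   same job. Without a config, runs are unlimited and resume is disabled.
#' @param claim_predicate Optional `function(record) -> logical` restricting
#'   which pending jobs this worker may claim (e.g. skip jobs needing more
#'   compute than this machine has). Default accepts every job.
#' @param claim_label Status installed on claim.
#' @param max_contention_retries How many retryable lock-contention failures
#'   to absorb before giving up.
#' @return A manager object.
#' @export
param_manager <- function(db, config = NULL, claim_predicate = NULL,
                          claim_label = STATUS_IN_PROGRESS,
                          max_contention_retries = 25) {
  stopifnot(inherits(db, "sweepq_db"))
  if (!is.null(config)) stopifnot(inherits(config, "sweepq_config"))
  pm <- new.env(parent = emptyenv())
  pm$db <- db
  pm$config <- config
  pm$predicate <- claim_predicate
  pm$claim_label <- claim_label
  pm$max_contention_retries <- max_contention_retries
  # The run limit is read once at session start and counted in memory; it is
  # not decremented in the config file.
  pm$num_of_runs <- if (is.null(config)) -1L else
    as.integer(get_value(config, CONFIG_NUM_OF_RUNS))
  pm$started <- 0L
  class(pm) <- "sweepq_param_manager"
  pm
}

is_terminal_status <- function(status) {
  status %in% c(STATUS_SUCCESSFUL, STATUS_FAILED)
}

# Resume candidate: the job named by `last-test`, provided it exists and is
# not finished. Takes precedence over scanning and does not consume the run
# limit anew.
resume_candidate <- function(pm) {
  if (is.null(pm$config)) return(NULL)
  last <- get_value(pm$config, CONFIG_LAST_TEST)
  if (is.null(last) || !nzchar(last)) return(NULL)
  df <- db_get_table(pm$db)
  i <- which(df$id == last)
  if (!length(i)) return(NULL)
  if (is_terminal_status(df$status[i[[1]]])) return(NULL)
  as.character(last)
}

stamp_if_present <- function(db, job_id, attribute, value) {
  if (attribute %in% db_get_attributes(db)) {
    db_update_cell(db, job_id, attribute, value)
  }
}

after_claim <- function(pm, job_id) {
  stamp_if_present(pm$db, job_id, "start-time", sweepq_timestamp())
  if (!is.null(pm$config)) {
    set_and_save(pm$config, CONFIG_LAST_TEST, job_id)
  }
}

#' Get the next pending job
#'
#' Resolution order:
#' 1. If the config's `last-test` names a job whose status is neither
#'    `"successful"` nor `"failed"`, that job is returned again — this is how
#'    a crashed or stopped run resumes — without consuming the run limit.
#' 2. Otherwise the first row in table order with an empty status (and passing
#'    the claim predicate) is claimed atomically: its status becomes the claim
#'    label, `start-time` is stamped, and `last-test` is persisted. If another
#'    worker steals the row between the scan and the claim, the scan restarts
#'    from a fresh snapshot.
#' 3. If no pending row remains, or the session run limit is exhausted, `NULL`
#'    (no more work) is returned.
#'
#' @param pm A [param_manager()].
#' @return The claimed job as a named list of strings, or `NULL`.
#' @export
next_parameters <- function(pm) {
  stopifnot(inherits(pm, "sweepq_param_manager"))

  resume <- resume_candidate(pm)
  if (!is.null(resume)) {
    rec <- db_get_record(pm$db, resume)
    if (identical(rec$status, STATUS_PENDING)) {
      # last-test points at a job that never got under way (e.g. the run died
      # between claim and config save the other way around): claim it now.
      if (db_claim_if_pending(pm$db, resume, pm$claim_label)) {
        after_claim(pm, resume)
      }
    }
    return(db_get_record(pm$db, resume))
  }

  if (pm$num_of_runs >= 0L && pm$started >= pm$num_of_runs) return(NULL)

  contention <- 0L
  repeat {
    df <- db_get_table(pm$db)
    pending <- which(df$status == STATUS_PENDING)
    if (!is.null(pm$predicate) && length(pending)) {
      keep <- vapply(pending, function(i) {
        isTRUE(pm$predicate(as.list(df[i, , drop = FALSE])))
      }, logical(1))
      pending <- pending[keep]
    }
    if (!length(pending)) return(NULL)
    job_id <- df$id[pending[[1]]]
    claimed <- tryCatch(
      db_claim_if_pending(pm$db, job_id, pm$claim_label),
      sweepq_contention_error = function(e) {
        contention <<- contention + 1L
        if (contention > pm$max_contention_retries) stop(e)
        NA
      }
    )
    if (isTRUE(claimed)) {
      after_claim(pm, job_id)
      pm$started <- pm$started + 1L
      return(db_get_record(pm$db, job_id))
    }
    # claim lost (stolen row) or contention: rescan a fresh snapshot
  }
}

#' Set a job's status
#'
#' May target any job, not just the one this worker claimed — the table is a
#' trust-based shared medium and cross-job edits are permitted.
#'
#' @param pm A [param_manager()].
#' @param job_id Job identifier.
#' @param status New status string (conventionally a task label such as
#'   `"running simulation"`).
#' @return The refreshed job record (named list of strings).
#' @export
update_status <- function(pm, job_id, status) {
  stopifnot(inherits(pm, "sweepq_param_manager"))
  db_update_cell(pm$db, job_id, "status", status)
  db_get_record(pm$db, job_id)
}

#' Mark a job complete
#'
#' Sets status `"successful"` and stamps `end-time` (when the attribute
#' exists).
#'
#' @inheritParams update_status
#' @return The refreshed job record.
#' @export
successful <- function(pm, job_id) {
  stopifnot(inherits(pm, "sweepq_param_manager"))
  db_update_cell(pm$db, job_id, "status", STATUS_SUCCESSFUL)
  stamp_if_present(pm$db, job_id, "end-time", sweepq_timestamp())
  db_get_record(pm$db, job_id)
}

#' Mark a job failed
#'
#' Sets status `"failed"`, stamps `end-time`, and appends `reason` (when
#' non-empty) to the job's comment.
#'
#' @inheritParams update_status
#' @param reason Free-text explanation; empty string leaves the comment
#'   untouched.
#' @return The refreshed job record.
#' @export
failed <- function(pm, job_id, reason = "") {
  stopifnot(inherits(pm, "sweepq_param_manager"))
  db_update_cell(pm$db, job_id, "status", STATUS_FAILED)
  stamp_if_present(pm$db, job_id, "end-time", sweepq_timestamp())
  if (nzchar(reason) && "comment" %in% db_get_attributes(pm$db)) {
    old <- db_get_record(pm$db, job_id)$comment
    new <- if (nzchar(old)) paste(old, reason, sep = "; ") else reason
    db_update_cell(pm$db, job_id, "comment", new)
  }
  db_get_record(pm$db, job_id)
}

#' @export
print.sweepq_param_manager <- function(x, ...) {
  lim <- if (x$num_of_runs < 0) "unlimited" else x$num_of_runs
  cat(sprintf("<sweepq_param_manager> started %d job(s) this session (limit %s)\n",
              x$started, lim))
  invisible(x)
}
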