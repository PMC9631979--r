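#' Run the model-exploration pipeline
#'
#' The end-to-end sweep loop: claim the next pending job, inject its
#' parameters into the XML settings file, advance its status to a task label,
#' execute the simulator, and mark the job `"successful"` (or `"failed"` on a
#' nonzero exit or error), repeating until no claimable work remains or the
#' session's `num-of-runs` limit is reached. The shared table is mutated in
#' place throughout, so anyone watching the database sees live progress.
#'
#' Executors:
#' * `"toy"` (default) — the bundled [run_toy_simulation()]; each job's
#'   settings are read back with [load_parameters_from_settings()].
#' * a command template string — `{settings}`, `{output}` and `{id}` are
#'   substituted, then the command is dispatched per the operating system's
#'   conventions (a shell on Unix, `cmd` on Windows); a nonzero exit marks
#'   the job failed.
#' * a function `function(record, settings_file, output_dir)` — any error it
#'   raises marks the job failed.
#'
#' Per job, parameters whose attribute name starts with `/` are injected into
#' a private copy of the settings file at `<output_root>/<id>/settings.xml`;
#' metadata attributes are passed through to the executor in `record`.
#'
#' @param db A database handle, or a path/descriptor accepted by
#'   [open_database()].
#' @param config A [load_config()] store, a path to a JSON config file, or
#'   `NULL` (unlimited runs, no resume).
#' @param settings Path to the base XML settings file; defaults to the
#'   bundled skeleton.
#' @param executor See above.
#' @param output_root Directory receiving one subfolder per job.
#' @param task_label Status written while a job executes.
#' @return A `sweepq_pipeline_report`: counts `jobs_attempted`,
#'   `jobs_successful`, `jobs_failed` and a per-job `timings` data.frame
#'   (id, outcome, seconds).
#' @examples
#' dir <- tempfile("sweep"); dir.create(dir)
#' db_file <- file.path(dir, "parameters.csv"); sample_db(db_file)
#' report <- run_pipeline(db_file, output_root = file.path(dir, "out"))
#' report$jobs_successful
#' @export
run_pipeline <- function(db, config = NULL, settings = NULL,
                         executor = "toy",
                         output_root = file.path(tempdir(), "sweepq_output"),
                         task_label = "running simulation") {
  if (!inherits(db, "sweepq_db")) db <- open_database(db)
  if (is.character(config)) config <- load_config(config)
  if (is.null(settings)) {
    settings <- system.file("extdata", "settings_skeleton.xml",
                            package = "sweepq", mustWork = TRUE)
  }
  if (!file.exists(settings)) {
    stop_sweepq("sweepq_not_found_error", "settings file '%s' not found",
                settings)
  }
  dir.create(output_root, recursive = TRUE, showWarnings = FALSE)

  pm <- param_manager(db, config)
  timings <- list()
  n_ok <- 0L
  n_fail <- 0L

  record <- next_parameters(pm)
  while (!is.null(record)) {
    job_id <- record$id
    t0 <- Sys.time()
    job_dir <- file.path(output_root, job_id)
    dir.create(job_dir, recursive = TRUE, showWarnings = FALSE)
    job_settings <- file.path(job_dir, "settings.xml")

    outcome <- tryCatch({
      keys <- names(record)
      injectable <- record[startsWith(keys, "/")]
      apply_parameters(injectable, settings, job_settings)
      update_status(pm, job_id, task_label)
      execute_job(executor, record, job_settings, job_dir)
      successful(pm, job_id)
      "successful"
    }, error = function(e) {
      failed(pm, job_id, conditionMessage(e))
      "failed"
    })

    if (outcome == "successful") n_ok <- n_ok + 1L else n_fail <- n_fail + 1L
    timings[[length(timings) + 1L]] <- data.frame(
      id = job_id, outcome = outcome,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      stringsAsFactors = FALSE
    )
    message(sprintf("[sweepq] job '%s': %s", job_id, outcome))
    record <- next_parameters(pm)
  }

  structure(list(
    jobs_attempted = n_ok + n_fail,
    jobs_successful = n_ok,
    jobs_failed = n_fail,
    timings = if (length(timings)) do.call(rbind, timings) else
      data.frame(id = character(), outcome = character(),
                 seconds = numeric(), stringsAsFactors = FALSE)
  ), class = "sweepq_pipeline_report")
}

execute_job <- function(executor, record, settings_file, output_dir) {
  if (is.function(executor)) {
    executor(record, settings_file, output_dir)
    return(invisible(NULL))
  }
  if (identical(executor, "toy")) {
    params <- load_parameters_from_settings(settings_file)
    run_toy_simulation(params, output_dir)
    return(invisible(NULL))
  }
  if (is.character(executor) && length(executor) == 1) {
    cmd <- executor
    cmd <- gsub("{settings}", settings_file, cmd, fixed = TRUE)
    cmd <- gsub("{output}", output_dir, cmd, fixed = TRUE)
    cmd <- gsub("{id}", record$id, cmd, fixed = TRUE)
    status <- run_os_command(cmd)
    if (status != 0) {
      stop_sweepq("sweepq_executor_error",
                  "command exited with status %d: %s", status, cmd)
    }
    return(invisible(NULL))
  }
  stop_sweepq("sweepq_validation_error", "unrecognized executor")
}

# Dispatch a command line per operating-system convention.
run_os_command <- function(cmd) {
  if (.Platform$OS.type == "windows") {
    suppressWarnings(system2("cmd", c("/c", cmd), stdout = FALSE,
                             stderr = FALSE))
  } else {
    suppressWarnings(system2("sh", c("-c", shQuote(cmd)), stdout = FALSE,
                             stderr = FALSE))
  }
}

#' @export
print.sweepq_pipeline_report <- function(x, ...) {
  cat(sprintf("<sweepq_pipeline_report> attempted %d | successful %d | failed %d\n",
              x$jobs_attempted, x$jobs_successful, x$jobs_failed))
  if (nrow(x$timings)) {
    cat(sprintf("  %-12s %-10s %8s\n", "id", "outcome", "seconds"))
    for (i in seq_len(nrow(x$timings))) {
      cat(sprintf("  %-12s %-10s %8.2f\n", x$timings$id[i],
                  x$timings$outcome[i], x$timings$seconds[i]))
    }
  }
  invisible(x)
}
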