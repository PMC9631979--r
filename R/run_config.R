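#' Persistent run configuration
#'
#' Run settings live in a JSON file: reserved run-state keys, backend
#' descriptors, credentials for optional remote adapters (stored under
#' namespaced keys the core never interprets), and arbitrary user values.
#' Two keys are reserved:
#'
#' * `last-test` — the id of the job most recently claimed by this
#'   configuration, or `null`. Persisted so an interrupted run can resume the
#'   same job.
#' * `num-of-runs` — how many jobs this session may start; `-1` means
#'   unlimited.
#'
#' When absent from the file these default to `null` and `-1` respectively.
#' Unknown keys are preserved verbatim across save cycles, and saves are
#' atomic (write-temp-then-rename), so no partial file is ever visible.
#'
#' @name run-config
NULL

CONFIG_LAST_TEST <- "last-test"
CONFIG_NUM_OF_RUNS <- "num-of-runs"

config_defaults <- function() {
  stats::setNames(list(NULL, -1L), c(CONFIG_LAST_TEST, CONFIG_NUM_OF_RUNS))
}

#' Load a configuration store from a JSON file
#'
#' @param path Path to a JSON file holding a single object.
#' @return A config store (environment) for [get_value()], [set_value()],
#'   [save_config()] and [set_and_save()].
#' @examples
#' cfg_file <- tempfile(fileext = ".json")
#' writeLines('{"last-test":null, "num-of-runs":-1}', cfg_file)
#' config <- load_config(cfg_file)
#' get_value(config, "num-of-runs")
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_sweepq("sweepq_not_found_error", "config file '%s' not found", path)
  }
  values <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop_sweepq("sweepq_parse_error", "config file '%s' is not valid JSON: %s",
                  path, conditionMessage(e))
    }
  )
  if (length(values) && is.null(names(values))) {
    stop_sweepq("sweepq_parse_error",
                "config file '%s' must hold a JSON object, not an array", path)
  }
  store <- new.env(parent = emptyenv())
  store$path <- path
  store$values <- as.list(values)
  class(store) <- "sweepq_config"
  store
}

#' Read a configuration value
#'
#' Top-level lookup only. Missing keys yield `default` (`NULL` unless given);
#' the reserved keys fall back to their documented defaults (`last-test` ->
#' `NULL`, `num-of-runs` -> `-1`).
#'
#' @param store A config store from [load_config()].
#' @param key Top-level key name.
#' @param default Value returned when the key is absent.
#' @export
get_value <- function(store, key, default = NULL) {
  stopifnot(inherits(store, "sweepq_config"))
  if (key %in% names(store$values)) {
    return(store$values[[key]])
  }
  defaults <- config_defaults()
  if (key %in% names(defaults)) defaults[[key]] else default
}

#' Set a configuration value in memory
#'
#' @inheritParams get_value
#' @param value New value; `NULL` stores JSON `null`.
#' @return The store, invisibly.
#' @export
set_value <- function(store, key, value) {
  stopifnot(inherits(store, "sweepq_config"))
  store$values[key] <- list(value)
  invisible(store)
}

#' Persist the store to its JSON file
#'
#' All keys — known and unknown — are written back; the write is atomic.
#'
#' @inheritParams get_value
#' @return The store, invisibly.
#' @export
save_config <- function(store) {
  stopifnot(inherits(store, "sweepq_config"))
  json <- if (length(store$values)) {
    jsonlite::toJSON(store$values, auto_unbox = TRUE, null = "null",
                     digits = NA, pretty = TRUE)
  } else {
    "{}"
  }
  atomic_write_lines(as.character(json), store$path)
  invisible(store)
}

#' Set a value and persist immediately
#'
#' @inheritParams set_value
#' @return The store, invisibly.
#' @export
set_and_save <- function(store, key, value) {
  set_value(store, key, value)
  save_config(store)
}

#' @export
print.sweepq_config <- function(x, ...) {
  cat(sprintf("<sweepq_config> %s (%d key(s))\n", x$path, length(x$values)))
  invisible(x)
}
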