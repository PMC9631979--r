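# Internal helpers: classed conditions, timestamps, atomic file replacement,
# and an advisory inter-process lock built on the atomicity of mkdir().

stop_sweepq <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "sweepq_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' @noRd
sweepq_timestamp <- function(time = Sys.time()) {
  format(time, "%Y-%m-%d %H:%M:%S")
}

# Write `lines` to `path` atomically: write a sibling temp file, then rename.
# Readers never observe a partially written file.
atomic_write_lines <- function(lines, path) {
  tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wb", encoding = "UTF-8")
  writeLines(lines, con, useBytes = TRUE)
  close(con)
  if (!file.rename(tmp, path)) {
    stop_sweepq("sweepq_io_error", "could not replace '%s'", path)
  }
  invisible(path)
}

# Exclusive advisory lock: dir.create() either creates the lock directory or
# fails, atomically, so concurrent processes serialize on it. `timeout` is in
# seconds; acquisition failure raises a retryable contention condition.
acquire_lock <- function(lock_path, timeout = 10, poll = 0.01) {
  deadline <- Sys.time() + timeout
  repeat {
    if (suppressWarnings(dir.create(lock_path, showWarnings = FALSE))) {
      return(invisible(lock_path))
    }
    if (Sys.time() > deadline) {
      stop_sweepq("sweepq_contention_error",
                  "could not acquire lock '%s' within %s s", lock_path, timeout)
    }
    Sys.sleep(stats::runif(1, 0, poll))
  }
}

release_lock <- function(lock_path) {
  unlink(lock_path, recursive = TRUE)
  invisible(NULL)
}

with_file_lock <- function(lock_path, expr, timeout = 10) {
  acquire_lock(lock_path, timeout = timeout)
  on.exit(release_lock(lock_path), add = TRUE)
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
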