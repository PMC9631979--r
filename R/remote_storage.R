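#' Storage adapters: uniform file/folder transfer
#'
#' Simulation outputs are shared through a storage service behind a uniform
#' contract: [storage_connect()], [upload_file()], [download_file()],
#' [delete_file()], [rename_file()], and the recursive folder counterparts.
#' The reference backend, [local_storage()], is a sandboxed local folder so
#' every pipeline (and the whole test suite) runs offline; a cloud service
#' (Box-style, Drive-style, ...) plugs in by implementing the same generics.
#' Credentials for such adapters live under namespaced keys of the run config
#' and are never interpreted by the core.
#'
#' Remote paths are slash-separated and relative to the storage root; the
#' local backend rejects paths that escape the root. Uploads overwrite an
#' existing object of the same name. Transfers are byte-faithful.
#'
#' @name remote-storage
NULL

#' Local-folder storage backend
#'
#' @param root Folder that acts as the remote root; created on
#'   [storage_connect()] if absent.
#' @return An unconnected storage handle.
#' @examples
#' store <- storage_connect(local_storage(tempfile("store")))
#' f <- tempfile(); writeLines("hello", f)
#' upload_file(store, f, "results/hello.txt")
#' @export
local_storage <- function(root) {
  handle <- new.env(parent = emptyenv())
  handle$root <- root
  handle$connected <- FALSE
  class(handle) <- c("sweepq_local_storage", "sweepq_storage")
  handle
}

#' Connect a storage handle
#'
#' Idempotent; transfer operations require a connected handle.
#'
#' @param storage A storage handle.
#' @return The handle, now ready.
#' @export
storage_connect <- function(storage) UseMethod("storage_connect")

#' @export
storage_connect.sweepq_local_storage <- function(storage) {
  if (!dir.exists(storage$root)) {
    ok <- suppressWarnings(dir.create(storage$root, recursive = TRUE))
    if (!ok || !dir.exists(storage$root)) {
      stop_sweepq("sweepq_connection_error",
                  "cannot create storage root '%s'", storage$root)
    }
  }
  storage$connected <- TRUE
  storage
}

require_connected <- function(storage) {
  if (!isTRUE(storage$connected)) {
    stop_sweepq("sweepq_connection_error",
                "storage handle is not connected; call storage_connect() first")
  }
}

# Resolve a remote path inside the root, refusing parent-directory escapes.
resolve_remote <- function(storage, remote_path) {
  segs <- strsplit(remote_path, "/", fixed = TRUE)[[1]]
  segs <- segs[nzchar(segs) & segs != "."]
  if (any(segs == "..")) {
    stop_sweepq("sweepq_path_error",
                "remote path '%s' escapes the storage root", remote_path)
  }
  file.path(storage$root, paste(segs, collapse = "/"))
}

#' @rdname storage-transfers
#' @export
upload_file <- function(storage, local_path, remote_path) {
  UseMethod("upload_file")
}

#' Transfer operations of the storage contract
#'
#' `upload_file()`/`download_file()` copy one file byte-faithfully between the
#' local filesystem and the storage backend; `delete_file()` removes exactly
#' one stored object; `rename_file()` renames an object within its folder,
#' preserving content; `upload_folder()`/`download_folder()` are the recursive
#' counterparts, reproducing the whole tree (names and bytes). Missing sources
#' raise a not-found condition; renaming onto an existing name raises a
#' conflict.
#'
#' @param storage A connected storage handle.
#' @param local_path File or folder on the local filesystem.
#' @param remote_path Slash-separated location relative to the storage root.
#' @param new_name Replacement base name (no slashes) for `rename_file()`.
#' @return `TRUE`, invisibly.
#' @name storage-transfers
NULL

#' @export
upload_file.sweepq_local_storage <- function(storage, local_path, remote_path) {
  require_connected(storage)
  if (!file.exists(local_path)) {
    stop_sweepq("sweepq_not_found_error", "local file '%s' not found",
                local_path)
  }
  dest <- resolve_remote(storage, remote_path)
  dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
  if (!file.copy(local_path, dest, overwrite = TRUE)) {
    stop_sweepq("sweepq_io_error", "upload to '%s' failed", remote_path)
  }
  invisible(TRUE)
}

#' @rdname storage-transfers
#' @export
download_file <- function(storage, remote_path, local_path) {
  UseMethod("download_file")
}

#' @export
download_file.sweepq_local_storage <- function(storage, remote_path,
                                               local_path) {
  require_connected(storage)
  src <- resolve_remote(storage, remote_path)
  if (!file.exists(src)) {
    stop_sweepq("sweepq_not_found_error", "remote file '%s' not found",
                remote_path)
  }
  dir.create(dirname(local_path), recursive = TRUE, showWarnings = FALSE)
  if (!file.copy(src, local_path, overwrite = TRUE)) {
    stop_sweepq("sweepq_io_error", "download of '%s' failed", remote_path)
  }
  invisible(TRUE)
}

#' @rdname storage-transfers
#' @export
delete_file <- function(storage, remote_path) UseMethod("delete_file")

#' @export
delete_file.sweepq_local_storage <- function(storage, remote_path) {
  require_connected(storage)
  target <- resolve_remote(storage, remote_path)
  if (!file.exists(target)) {
    stop_sweepq("sweepq_not_found_error", "remote file '%s' not found",
                remote_path)
  }
  unlink(target)
  invisible(TRUE)
}

#' @rdname storage-transfers
#' @export
rename_file <- function(storage, remote_path, new_name) {
  UseMethod("rename_file")
}

#' @export
rename_file.sweepq_local_storage <- function(storage, remote_path, new_name) {
  require_connected(storage)
  if (grepl("/", new_name, fixed = TRUE)) {
    stop_sweepq("sweepq_path_error", "new name '%s' must not contain '/'",
                new_name)
  }
  src <- resolve_remote(storage, remote_path)
  if (!file.exists(src)) {
    stop_sweepq("sweepq_not_found_error", "remote file '%s' not found",
                remote_path)
  }
  dest <- file.path(dirname(src), new_name)
  if (file.exists(dest)) {
    stop_sweepq("sweepq_conflict_error", "'%s' already exists", new_name)
  }
  if (!file.rename(src, dest)) {
    stop_sweepq("sweepq_io_error", "rename of '%s' failed", remote_path)
  }
  invisible(TRUE)
}

#' @rdname storage-transfers
#' @export
upload_folder <- function(storage, local_path, remote_path) {
  UseMethod("upload_folder")
}

#' @export
upload_folder.sweepq_local_storage <- function(storage, local_path,
                                               remote_path) {
  require_connected(storage)
  if (!dir.exists(local_path)) {
    stop_sweepq("sweepq_not_found_error", "local folder '%s' not found",
                local_path)
  }
  files <- list.files(local_path, recursive = TRUE, all.files = TRUE,
                      no.. = TRUE)
  for (f in files) {
    upload_file(storage, file.path(local_path, f),
                paste(remote_path, f, sep = "/"))
  }
  invisible(TRUE)
}

#' @rdname storage-transfers
#' @export
download_folder <- function(storage, remote_path, local_path) {
  UseMethod("download_folder")
}

#' @export
download_folder.sweepq_local_storage <- function(storage, remote_path,
                                                 local_path) {
  require_connected(storage)
  src <- resolve_remote(storage, remote_path)
  if (!dir.exists(src)) {
    stop_sweepq("sweepq_not_found_error", "remote folder '%s' not found",
                remote_path)
  }
  files <- list.files(src, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  for (f in files) {
    download_file(storage, paste(remote_path, f, sep = "/"),
                  file.path(local_path, f))
  }
  invisible(TRUE)
}

#' @export
print.sweepq_storage <- function(x, ...) {
  state <- if (isTRUE(x$connected)) "ready" else "unconnected"
  cat(sprintf("<%s> root '%s' (%s)\n", class(x)[1], x$root, state))
  invisible(x)
}
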