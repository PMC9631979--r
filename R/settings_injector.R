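#' Inject job parameters into an XML settings file
#'
#' Simulation frameworks such as PhysiCell read their run configuration from
#' an XML settings file. A job's parameter columns name the elements to edit
#' as slash-separated *element paths* from the document root — e.g.
#' `/user_parameters/attached_worker_migration_bias` addresses the
#' `<attached_worker_migration_bias>` tag inside `<user_parameters>`. The
#' leading `/` is what distinguishes an injectable path from a plain metadata
#' attribute (`id`, `status`, timestamps, ...), which are skipped.
#'
#' For every path key the *first* element (in document order) matching the
#' segment sequence has its text replaced by the value string, verbatim — no
#' numeric reformatting. Everything else (elements, attributes, structure) is
#' preserved; serializer whitespace may be normalized, so comparisons should
#' be made on canonicalized trees (see [xml2::as_list()]). Indexed path
#' segments for repeated sibling tags are not supported: the first match wins.
#' A path that matches nothing is an error — elements are never created
#' silently.
#'
#' @param params Named character vector or list mapping attribute names to
#'   value strings. Keys with a leading `/` are injected; others are skipped
#'   and reported.
#' @param settings_in Path to a well-formed XML file.
#' @param settings_out Output path; may equal `settings_in` for in-place
#'   editing. Defaults to in-place.
#' @return Invisibly, a list with `written` (the paths injected) and
#'   `skipped` (the non-path keys ignored).
#' @examples
#' skel <- system.file("extdata", "settings_skeleton.xml", package = "sweepq")
#' out <- tempfile(fileext = ".xml")
#' apply_parameters(
#'   c("/user_parameters/attached_worker_migration_bias" = "0.1"),
#'   skel, out
#' )
#' @export
apply_parameters <- function(params, settings_in, settings_out = settings_in) {
  params <- as.list(params)
  doc <- tryCatch(
    xml2::read_xml(settings_in),
    error = function(e) {
      stop_sweepq("sweepq_parse_error", "cannot parse XML '%s': %s",
                  settings_in, conditionMessage(e))
    }
  )
  keys <- names(params) %||% character(0)
  is_path <- startsWith(keys, "/")
  for (key in keys[is_path]) {
    node <- resolve_element_path(doc, key)
    xml2::xml_text(node) <- as.character(params[[key]])
  }
  xml2::write_xml(doc, settings_out)
  invisible(list(written = keys[is_path], skipped = keys[!is_path]))
}

# An element path /a/b/c addresses root/a/b/c, where "root" is the document's
# root element; the first match in document order wins.
resolve_element_path <- function(doc, path) {
  segs <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  if (!length(segs) || any(!nzchar(segs))) {
    stop_sweepq("sweepq_path_error", "malformed element path '%s'", path)
  }
  xpath <- paste0("./", paste(segs, collapse = "/"))
  node <- xml2::xml_find_first(xml2::xml_root(doc), xpath)
  if (inherits(node, "xml_missing") || length(node) == 0) {
    stop_sweepq("sweepq_path_error", "no element matches path '%s'", path)
  }
  node
}

#' Write the bundled example parameter database
#'
#' Creates a small, valid delimited database of three biorobots jobs —
#' `default`, `attached`, `unattached` — all pending, with the two worker
#' migration biases as parameter columns (named as element paths so the
#' pipeline can inject them straight into a settings file). Useful as a
#' starting point for a new sweep and as the desk-scale demonstration input.
#'
#' @param path Where to write the CSV.
#' @param delimiter Field delimiter.
#' @return The path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' sample_db(f)
#' db_get_table(delimited_db(f))
#' @export
sample_db <- function(path, delimiter = ",") {
  df <- sample_table()
  atomic_write_lines(format_delimited(df, delimiter), path)
  invisible(path)
}

sample_table <- function() {
  data.frame(
    id = c("default", "attached", "unattached"),
    status = c("", "", ""),
    `start-time` = c("", "", ""),
    `end-time` = c("", "", ""),
    comment = c("", "", ""),
    `/user_parameters/attached_worker_migration_bias` = c("1.0", "0.1", "1.0"),
    `/user_parameters/unattached_worker_migration_bias` = c("0.5", "1.0", "0.1"),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Write the bundled example XML settings skeleton
#'
#' Copies the package's PhysiCell-style settings skeleton (a synthetic,
#' minimal stand-in for a real settings file) to `path`. Its
#' `<user_parameters>` block carries the worker migration biases targeted by
#' [sample_db()] plus the knobs read by [run_toy_simulation()].
#'
#' @param path Destination file.
#' @return The path, invisibly.
#' @export
sample_settings <- function(path) {
  src <- system.file("extdata", "settings_skeleton.xml", package = "sweepq",
                     mustWork = TRUE)
  if (!file.copy(src, path, overwrite = TRUE)) {
    stop_sweepq("sweepq_io_error", "could not write '%s'", path)
  }
  invisible(path)
}
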