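# Fixtures are built in code. The three-job example database is written
# literally (independent of sample_db) so it can serve as an oracle for the
# generator and the file backend.

ATTACHED_BIAS_PATH <- "/user_parameters/attached_worker_migration_bias"
UNATTACHED_BIAS_PATH <- "/user_parameters/unattached_worker_migration_bias"

example_db_lines <- function() {
  c(paste0("id,status,start-time,end-time,comment,",
           ATTACHED_BIAS_PATH, ",", UNATTACHED_BIAS_PATH),
    "default,,,,,1.0,0.5",
    "attached,,,,,0.1,1.0",
    "unattached,,,,,1.0,0.1")
}

write_example_db <- function(path = tempfile(fileext = ".csv")) {
  writeLines(example_db_lines(), path)
  path
}

write_example_config <- function(text = '{"last-test":null, "num-of-runs":-1}',
                                 path = tempfile(fileext = ".json")) {
  writeLines(text, path)
  path
}

skeleton_path <- function() {
  system.file("extdata", "settings_skeleton.xml", package = "sweepq",
              mustWork = TRUE)
}

# A settings file dialed down so a pipeline job runs in milliseconds.
write_tiny_settings <- function(path = tempfile(fileext = ".xml")) {
  sample_settings(path)
  apply_parameters(c("/user_parameters/number_of_steps" = "60",
                     "/user_parameters/number_of_workers" = "2",
                     "/user_parameters/number_of_cargo" = "3",
                     "/user_parameters/arena_size" = "40"),
                   path)
  path
}

TS_PATTERN <- "^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}:\\d{2}$"

canonical_tree <- function(path) xml2::as_list(xml2::read_xml(path))

# n pending jobs for the in-memory backend.
pending_table <- function(n, extra_status = character(0)) {
  status <- rep("", n)
  if (length(extra_status)) status[seq_along(extra_status)] <- extra_status
  data.frame(id = sprintf("job%03d", seq_len(n)), status = status,
             x = as.character(seq_len(n)), check.names = FALSE,
             stringsAsFactors = FALSE)
}

# Brute-force oracle: the claim order a sequential worker should see.
oracle_claim_order <- function(df) {
  order_ids <- character(0)
  repeat {
    i <- which(df$status == "")
    if (!length(i)) break
    order_ids <- c(order_ids, df$id[i[[1]]])
    df$status[i[[1]]] <- "in progress"
  }
  order_ids
}
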