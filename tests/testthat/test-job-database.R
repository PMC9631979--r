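test_that("opening a delimited database validates the schema without touching the file", {
  path <- write_example_db()
  before <- tools::md5sum(path)
  db <- delimited_db(path)
  tbl <- db_get_table(db)
  expect_identical(ncol(tbl), 7L)
  expect_identical(nrow(tbl), 3L)
  expect_identical(tbl$id, c("default", "attached", "unattached"))
  expect_true(all(tbl$status == ""))
  expect_identical(db_get_attributes(db)[1:2], c("id", "status"))
  expect_identical(db_get_attributes(db), names(tbl))
  expect_identical(tools::md5sum(path), before)

  # header-only file: a valid, empty table
  empty <- tempfile(fileext = ".csv")
  writeLines("id,status,x", empty)
  expect_identical(nrow(db_get_table(delimited_db(empty))), 0L)

  expect_error(delimited_db(tempfile()), class = "sweepq_not_found_error")
  noid <- tempfile(fileext = ".csv")
  writeLines(c("name,status", "a,"), noid)
  expect_error(delimited_db(noid), class = "sweepq_schema_error")
})

test_that("duplicate ids are a hard error at open time", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(example_db_lines(), "default,,,,,0.3,0.3"), path)
  # oracle: a plain uniqueness scan over the raw id column
  ids <- vapply(strsplit(readLines(path)[-1], ","), `[[`, character(1), 1)
  expect_true(anyDuplicated(ids) > 0)
  expect_error(delimited_db(path), class = "sweepq_schema_error")
})

test_that("get_table is a faithful snapshot and re-reads observe external edits", {
  path <- write_example_db()
  db <- delimited_db(path)
  expect_identical(db_get_table(db), db_get_table(db))
  cat("extra,,,,,0.2,0.2\n", file = path, append = TRUE)
  tbl <- db_get_table(db)
  # oracle: independent raw-file parse
  raw_ids <- vapply(strsplit(readLines(path)[-1], ","), `[[`, character(1), 1)
  expect_identical(tbl$id, raw_ids)
  expect_identical(nrow(tbl), 4L)
  unlink(path)
  expect_error(db_get_table(db), class = "sweepq_io_error")
})

test_that("update_row replaces exactly one row and rejects bad input", {
  path <- write_example_db()
  db <- delimited_db(path)
  before <- db_get_table(db)
  completed <- list(
    id = "default", status = "successful",
    "start-time" = "2021-02-28 19:36:30", "end-time" = "2021-02-28 19:38:20",
    comment = "")
  completed[[ATTACHED_BIAS_PATH]] <- "1.0"
  completed[[UNATTACHED_BIAS_PATH]] <- "0.5"
  expect_true(db_update_row(db, "default", completed))
  after <- db_get_table(db)
  expect_identical(after$status, c("successful", "", ""))
  expect_identical(after[["start-time"]][1], "2021-02-28 19:36:30")
  # full-table diff: rows 2..3 untouched
  expect_identical(after[-1, ], before[-1, ])

  # identity update leaves the table semantically unchanged
  db_update_row(db, "attached", as.list(after[2, ]))
  expect_identical(db_get_table(db), after)

  # unknown id: not-found, table untouched (full-file diff)
  snapshot <- readLines(path)
  expect_error(db_update_row(db, "missing", completed),
               class = "sweepq_not_found_error")
  expect_identical(readLines(path), snapshot)
  bad <- completed; bad$extra <- "x"
  expect_error(db_update_row(db, "default", bad),
               class = "sweepq_schema_error")
  expect_error(db_update_row(db, "attached", completed),
               class = "sweepq_schema_error") # id mismatch
})

test_that("update_cell changes exactly one cell", {
  path <- write_example_db()
  db <- delimited_db(path)
  before <- db_get_table(db)
  expect_true(db_update_cell(db, "default", "status", "successful"))
  after <- db_get_table(db)
  # exhaustive cell-by-cell comparison
  for (i in seq_len(nrow(before))) {
    for (j in names(before)) {
      expected <- if (before$id[i] == "default" && j == "status")
        "successful" else before[i, j]
      expect_identical(after[i, j], expected)
    }
  }
  # writing the current value is observationally a no-op
  db_update_cell(db, "attached", "status", "")
  expect_identical(db_get_table(db), after)
  expect_error(db_update_cell(db, "default", "nope", "x"),
               class = "sweepq_not_found_error")
  expect_error(db_update_cell(db, "nope", "status", "x"),
               class = "sweepq_not_found_error")
})

test_that("tables round-trip through the file backend, including delimiter-hostile values", {
  path <- write_example_db()
  db <- delimited_db(path)
  tricky <- 'crashed, with "quotes" and, commas'
  db_update_cell(db, "default", "comment", tricky)
  expect_identical(db_get_table(db)[1, "comment"], tricky)
  # a second write/read cycle is byte-stable
  once <- readLines(path)
  db_update_cell(db, "default", "comment", tricky)
  expect_identical(readLines(path), once)
  # header and row order are preserved
  expect_identical(db_get_attributes(db), strsplit(example_db_lines()[1], ",")[[1]])
  expect_identical(db_get_table(db)$id, c("default", "attached", "unattached"))
})

test_that("claim_if_pending succeeds once and only once per job", {
  path <- write_example_db()
  db <- delimited_db(path)
  expect_true(db_claim_if_pending(db, "default", "in progress"))
  expect_identical(db_get_table(db)$status[1], "in progress")
  expect_false(db_claim_if_pending(db, "default", "in progress"))
  expect_identical(db_get_table(db)$status[1], "in progress")
  expect_error(db_claim_if_pending(db, "missing"),
               class = "sweepq_not_found_error")
})

test_that("simulated workers racing over the in-memory backend claim each job exactly once", {
  set.seed(42)
  n_jobs <- 100L
  claims <- character(0)          # successful claims, in order
  stealing <- FALSE
  db <- memory_db(pending_table(n_jobs), before_cas = function(db, job_id) {
    # adversary: with some probability a rival claims the same row between
    # the caller's scan and its compare-and-swap
    if (stealing) return(invisible(NULL))
    if (stats::runif(1) < 0.25) {
      stealing <<- TRUE
      if (db_claim_if_pending(db, job_id, "in progress")) {
        claims <<- c(claims, job_id)
        db_update_cell(db, job_id, "status",
                       sample(c("successful", "failed"), 1))
      }
      stealing <<- FALSE
    }
    invisible(NULL)
  })
  workers <- lapply(1:8, function(i) param_manager(db))
  repeat {
    progressed <- FALSE
    for (w in sample(workers)) {
      rec <- next_parameters(w)
      if (!is.null(rec)) {
        claims <- c(claims, rec$id)
        if (stats::runif(1) < 0.9) successful(w, rec$id)
        else failed(w, rec$id, "injected")
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  # the multiset of successful claims is exactly the job-id set
  expect_identical(sort(claims), sort(sprintf("job%03d", 1:n_jobs)))
  expect_identical(anyDuplicated(claims), 0L)
  expect_true(all(db_get_table(db)$status %in% c("successful", "failed")))
})
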