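Package: sweepq
Title: Serverless Distributed Parameter Sweeps over a Shared Job Table
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A database-centric job queue for model exploration of
    agent-based and other simulation models. Parameter sets are stored as
    rows of a shared table (a delimited text file, or any spreadsheet-like
    backend implementing the adapter contract), claimed exclusively by
    workers, executed, and marked complete, so a team can pool ad hoc
    computing resources without a job-distribution server. Includes
    persistent JSON run configuration with crash-resume, injection of
    parameters into XML simulation-settings files via element paths, a
    local-folder reference implementation of a cloud-storage transfer
    contract, a deterministic toy biased-migration ("biorobots") simulator
    so the full pipeline runs at desk scale, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
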