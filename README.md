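# sweepq

Serverless, database-centric parameter sweeps for simulation models.

## The problem

Evaluating a computational model — an agent-based multicellular simulation,
an ODE system, anything driven by a settings file — means running it over
many parameter sets (*model exploration*). Doing that across a small team is
usually bottlenecked on one person's machine, and the classic remedies
(HPC schedulers, client–server job farms) carry setup costs that small
groups rarely want to pay.

`sweepq` takes the lightweight alternative: **the job queue is just a shared
table**. Each row is a *job* — a unique `id`, a `status`, optional metadata
(`start-time`, `end-time`, `comment`) and one parameter set. Workers
coordinate exclusively through that table:

```
pending ("")  →  "in progress"  →  task labels…  →  "successful" | "failed"
```

A worker *claims* the first pending row with an atomic check-and-set (the
file backend serializes claimants through an advisory lock; a
spreadsheet-style backend uses compare-and-swap), so no job is ever run
twice even with several workers pulling from the same table. There is no
server to operate: anyone with the script and access to the table can
contribute compute, which makes ad hoc crowdsourcing of a sweep practical.

Around that core the package provides:

* **`delimited_db()` / `memory_db()`** — the table backends, behind a
  five-generic adapter contract (`db_get_table`, `db_get_attributes`,
  `db_update_row`, `db_update_cell`, `db_claim_if_pending`) that any remote
  spreadsheet service can implement.
* **`param_manager()`** — the job lifecycle: `next_parameters()`,
  `update_status()`, `successful()`, `failed()`, with session run limits
  (`num-of-runs`) and crash-resume (`last-test`) persisted in a JSON config
  (`load_config()`, `get_value()`, `set_and_save()`).
* **`apply_parameters()`** — injects parameter columns into an XML
  simulation-settings file. A column named with a leading slash, e.g.
  `/user_parameters/attached_worker_migration_bias`, addresses the element
  at that path from the document root; metadata columns are skipped.
* **`local_storage()`** — a sandboxed local-folder reference implementation
  of the storage contract (`upload_file`, `download_file`, `delete_file`,
  `rename_file`, folder variants) for sharing outputs; cloud adapters plug
  into the same generics.
* **`run_toy_simulation()`** — a deterministic toy "biorobots" agent-based
  model (workers drag cargo to a director under a migration bias
  `b ∈ [0, 1]`; step direction `normalize(b·û + (1−b)·r̂)`), so the whole
  pipeline runs end to end in seconds with analytically checkable limits:
  pure diffusion at `b = 0`, straight-line motion at `b = 1`.
* **`run_pipeline()` and a CLI** (`inst/exec/sweepq`: `init` / `run` /
  `status`) — the claim → inject → execute → mark-complete loop, with any
  executor: the toy simulator, an R function, or an external command
  template such as `"./mysim {settings} {output}"`.

## Worked example

```r
library(sweepq)

dir.create(ws <- tempfile("sweep"))
sample_db(file.path(ws, "parameters.csv"))        # the three-job example DB
writeLines('{"last-test":null, "num-of-runs":-1}',
           file.path(ws, "config.json"))

report <- run_pipeline(file.path(ws, "parameters.csv"),
                       config = file.path(ws, "config.json"),
                       output_root = file.path(ws, "output"))
#> [sweepq] job 'default': successful
#> [sweepq] job 'attached': successful
#> [sweepq] job 'unattached': successful
print(report)
#> <sweepq_pipeline_report> attempted 3 | successful 3 | failed 0
#>   id           outcome     seconds
#>   default      successful     0.18
#>   attached     successful     0.04
#>   unattached   successful     0.10
db_get_table(delimited_db(file.path(ws, "parameters.csv")))[, 1:4]
#>           id     status          start-time            end-time
#> 1    default successful 2026-09-23 18:33:52 2026-09-23 18:33:52
#> 2   attached successful 2026-09-23 18:33:52 2026-09-23 18:33:52
#> 3 unattached successful 2026-09-23 18:33:52 2026-09-23 18:33:53
```

The three jobs sweep the attached/unattached worker migration biases
(1.0/0.5, 0.1/1.0, 1.0/0.1). For each job the pipeline claimed the row,
wrote its biases into a private copy of the XML settings skeleton, ran the
toy simulator into `output/<id>/` (three position snapshots plus a
`summary.json`), and marked the row `successful` with start/end timestamps.
The CSV is updated in place as jobs run, so `sweepq status --db
parameters.csv` (or just opening the file) shows live progress. A single
simulation summary looks like:

```r
run_toy_simulation(sim_params(attached_bias = 0.1, unattached_bias = 1.0,
                              seed = 42), tempfile("sim"))
#> <sweepq_sim_summary> delivered 3 cargo (fraction 0.300), mean final distance 28.733
```

— with a weak attached bias (0.1), workers wander while dragging, so only
3 of 10 cargo reach the director within the default 500 steps; at
`attached_bias = 1` deliveries are fast and deterministic.

To spread the same sweep across machines, host the table on a shared
spreadsheet-style backend implementing the adapter contract and give every
participant the same script; claims guarantee disjoint work.

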