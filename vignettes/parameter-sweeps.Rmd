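---
title: "Distributed parameter sweeps over a shared job table"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed parameter sweeps over a shared job table}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepq)
```

## The model of coordination

`sweepq` implements a *database-centric* architecture for model exploration:
workers coordinate through a shared table and nothing else. Compared with a
client–server job farm this trades central control for radical simplicity —
the only thing a team has to manage is the table itself, which can be a CSV
file on a shared disk or any spreadsheet-like service wrapped in the
five-generic adapter contract.

The correctness core is a single primitive, `db_claim_if_pending()`: *iff*
a job's status is still the empty string at write time, install the claim
label and report success. Everything else in the lifecycle (`"in progress"`,
free-form task labels, `"successful"`, `"failed"`) is ordinary cell writing.
Two backends realize the primitive differently:

* the **delimited file** backend serializes every mutation through an
  exclusive advisory lock (a lock *directory*, because `mkdir` is atomic on
  POSIX filesystems) and replaces the file by write-temp-then-rename, so
  concurrent local processes either see the old table or the new one, never
  a torn write;
* the **in-memory** backend re-reads the status immediately before the
  write (compare-and-swap). It mocks a remote spreadsheet; its `before_cas`
  hook lets tests script adversarial interleavings — a rival claiming the
  row between a worker's scan and its claim — which is the race the
  primitive must win.

Assumptions worth stating plainly: the table is a *trust-based* medium.
Any participant can edit any row (that is a feature — stuck jobs can be
cleared by teammates), there is no authentication, and a remote spreadsheet
backend is only as atomic as its service's check-and-set lets it be. The
package targets cooperating colleagues, not adversaries.

## The job lifecycle and its parameters

`param_manager()` drives one worker's session. `next_parameters()` resolves
in a fixed order: **resume** (if the config's `last-test` names a job that
is neither `"successful"` nor `"failed"`, return it again), then the **run
limit**, then a **scan** for the first pending row in table order, claimed
atomically with rescan-on-steal. Resume takes precedence because its whole
purpose is to survive a crash between claiming and finishing; it does not
re-consume the run limit, since that job's start was already paid for.

Tunables, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `num-of-runs` (config) | `-1` | jobs this session may start; `-1` = unlimited. Read once at session start and counted in memory — it is a per-session budget, not persisted state. |
| `last-test` (config) | `null` | id of the job currently in flight; persisted on every claim. |
| claim label | `"in progress"` | installed by the claim; pipelines overwrite it with task labels afterwards. |
| `lock_timeout` | 10 s | how long a file-backend mutation waits for the advisory lock before raising a retryable contention error. |
| `delimiter` | `,` | field separator of the file backend; all values are strings, the empty string is the pending status. |

Re-running a parameter set is done by adding a new row with a fresh id;
there is deliberately no in-place reset, because a reset row would be
indistinguishable from a never-run one in the audit trail. Failed jobs are
never retried automatically — transient-failure policy belongs to the
operator, and an automatic retry would blur the meaning of `"failed"`.

Timestamps are written in local time as `YYYY-MM-DD HH:MM:SS`. With
second resolution, a fast job can legitimately show `start-time ==
end-time`.

## XML parameter injection

A parameter column named with a leading `/` is an *element path*:
`/user_parameters/attached_worker_migration_bias` addresses the first
element (in document order) reached by following those child names from the
document root. The leading slash is also what separates injectable columns
from metadata (`id`, `status`, …), so one header row can carry both.
Choices made where behaviour was genuinely open:

* **Unresolved paths are errors**, never silently created elements — a typo
  in a column header should stop the sweep, not add a tag the simulator
  ignores.
* **Repeated sibling tags:** the first match wins; indexed segments are not
  supported. This keeps paths readable and covers settings files whose
  parameter blocks use unique tag names, which is the norm.
* Values are written **verbatim as strings** (no numeric reformatting), and
  everything untargeted is preserved. The serializer may normalize
  whitespace, so equality checks compare canonicalized trees rather than
  bytes.

## The toy simulator

The bundled "biorobots" model exists so the *pipeline* can be exercised and
tested at desk scale; its dynamics are intentionally minimal. Workers,
cargo and a director live in a square arena. Each step, a worker moves
`step_length` along

$$d = \mathrm{normalize}\!\left(b\,\hat u + (1-b)\,\hat r\right),$$

where $\hat u$ points at the target (nearest free cargo when unattached,
the director when attached), $\hat r$ is a uniform random unit vector, and
$b$ is the relevant migration bias. A worker attaches when within
`delivery_radius` of free cargo and delivers when, attached, it comes
within `delivery_radius` of the director. With no reachable cargo the walk
is purely random. All randomness flows from one integer seed through a
private RNG stream (the caller's `.Random.seed` is saved and restored), so
runs are bit-reproducible; snapshot files are written with fixed `%.6f`
formatting and relative paths for the same reason.

Two closed forms anchor the tests:

* **$b = 1$:** motion is deterministic and straight. A worker at distance
  10 from cargo that is 20 from the director, with `step_length = 1` and
  `delivery_radius = 0.5`, delivers after exactly 30 steps — attachment and
  delivery checks run after each move, and the small radius makes "arrival"
  coincide with the exact step counts.
* **$b = 0$:** displacement is a sum of $T$ i.i.d. unit steps, so
  $\mathbb{E}\lvert X_T\rvert^2 = T\cdot\mathrm{step}^2$. The test compares
  the Monte-Carlo mean over 1000 seeds against this value with a tolerance
  of four standard errors *of that same sample* — the tolerance is derived
  from the oracle's variance, not tuned.

Defaults (5 workers, 10 cargo, 500 steps, unit step, delivery radius 2,
arena 100) give runs of a few hundred milliseconds in which the default
bias pair delivers most cargo — a plausible miniature of a directed-
migration experiment. What the toy model *emulates* is the shape of a real
sweep: a settings file in, stochastic agent dynamics governed by a bias in
$[0,1]$ interpolating random walk → directed motion, snapshots and a
summary out. What it does **not** emulate: diffusion fields, cell
mechanics, volume exclusion, or anything quantitative about a real
multicellular simulator. Green tests therefore certify the *workflow
machinery* and the toy model's own invariants, not any biological claim.

## Degenerate inputs and numerical corners

* A header-only table is valid and yields a clean zero-job run.
* Duplicate ids are a hard error at open time; proceeding would make
  "claimed exactly once" unenforceable.
* Empty cells and the empty status are the same thing: strings. `NA` never
  enters a table.
* The claim scan tie-break is table row order (first pending wins), which
  makes the sequential claim order exactly reproducible by a brute-force
  scan — a property the suite checks on randomized tables.
* A normalized direction with a near-zero norm (opposed bias and noise
  vectors) falls back to the random unit vector.
* `successful()` on an already-successful job refreshes `end-time` only;
  cross-job status edits are allowed by design.

## Problem sizes in the test suite

The suite runs at deliberately small scale: the three-job example database
for end-to-end runs (simulator dialed to 60 steps, 2 workers, 3 cargo),
100 jobs × 8 simulated workers for claim exclusivity, 100 randomized tables
for the claim-order oracle, 1000 seeds × 50 steps for the diffusive limit,
250 seeds × 150 steps for bias monotonicity, and two real OS processes
hammering one CSV for the file-lock test. These sizes give the statistical
checks comfortable margins while keeping the whole suite around ten
seconds.

## Known limitations

* The file backend's advisory lock assumes a filesystem with atomic
  `mkdir`/`rename` (any local POSIX filesystem; NFS setups vary).
* No scheduling priorities, job dependencies, retry policies, or
  notifications; no web dashboard. The CLI (`sweepq init|run|status`) plus
  the table itself are the operational surface.
* XML injection edits element *text* only, not attributes, and performs no
  schema validation of the settings file.
* Remote spreadsheet and cloud-storage services are adapter seams, not
  bundled integrations; the in-repo backends are the local file, the
  in-memory mock, and the local-folder store.
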