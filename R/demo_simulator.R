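#' Toy biorobots simulator
#'
#' A deterministic, desk-scale agent-based model in the spirit of the
#' PhysiCell "biorobots" sample project: *worker* agents seek *cargo* agents,
#' attach on contact, and drag them to a *director* at the arena centre. It
#' exists so the full parameter-sweep pipeline can be exercised end to end in
#' seconds, with analytically checkable behaviour; it makes no claim of
#' quantitative agreement with PhysiCell.
#'
#' Movement follows a biased random walk. At every step a worker's direction
#' is
#' \deqn{d = \mathrm{normalize}\big(b\,\hat u + (1-b)\,\hat r\big),}
#' where \eqn{\hat u} is the unit vector toward the current target (the
#' nearest free cargo when unattached, the director when attached), \eqn{\hat
#' r} is a uniformly random unit vector, and \eqn{b \in [0,1]} is the
#' migration bias — `unattached_bias` or `attached_bias` according to the
#' worker's state. At \eqn{b = 0} the walk is a pure random walk (mean
#' squared displacement \eqn{T \cdot \mathrm{step}^2} after \eqn{T} steps);
#' at \eqn{b = 1} motion is straight-line deterministic. A worker attaches
#' when it comes within `delivery_radius` of a free cargo and delivers when,
#' carrying cargo, it comes within `delivery_radius` of the director.
#'
#' @name demo-simulator
NULL

#' Simulation parameters for the toy biorobots model
#'
#' @param attached_bias Migration bias of a worker dragging cargo toward the
#'   director, in `[0, 1]` (dimensionless).
#' @param unattached_bias Migration bias of a worker seeking cargo, in
#'   `[0, 1]`.
#' @param n_workers Number of worker agents (>= 1).
#' @param n_cargo Number of cargo agents (>= 0).
#' @param n_steps Number of time steps (>= 1).
#' @param step_length Distance moved per step, in arena units.
#' @param delivery_radius Contact distance for attaching and delivering, in
#'   arena units.
#' @param arena_size Side length of the square arena centred on the director,
#'   in arena units.
#' @param seed Integer; fixes all randomness (placement and walk).
#' @param worker_positions,cargo_positions Optional n x 2 matrices of initial
#'   positions overriding random placement.
#' @param director_position Length-2 numeric, default the origin.
#' @return A validated `sweepq_sim_params` object.
#' @export
sim_params <- function(attached_bias = 1.0, unattached_bias = 0.5,
                       n_workers = 5L, n_cargo = 10L, n_steps = 500L,
                       step_length = 1.0, delivery_radius = 2.0,
                       arena_size = 100.0, seed = 0L,
                       worker_positions = NULL, cargo_positions = NULL,
                       director_position = c(0, 0)) {
  check_bias <- function(b, what) {
    if (!is.numeric(b) || length(b) != 1 || is.na(b) || b < 0 || b > 1) {
      stop_sweepq("sweepq_validation_error",
                  "%s must be a single number in [0, 1] (got %s)",
                  what, format(b))
    }
  }
  check_bias(attached_bias, "attached_bias")
  check_bias(unattached_bias, "unattached_bias")
  check_count <- function(n, what, min) {
    if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < min ||
        n != as.integer(n)) {
      stop_sweepq("sweepq_validation_error", "%s must be an integer >= %d",
                  what, min)
    }
  }
  check_count(n_workers, "n_workers", 1L)
  check_count(n_cargo, "n_cargo", 0L)
  check_count(n_steps, "n_steps", 1L)
  if (step_length <= 0 || delivery_radius <= 0 || arena_size <= 0) {
    stop_sweepq("sweepq_validation_error",
                "step_length, delivery_radius and arena_size must be positive")
  }
  check_positions <- function(p, n, what) {
    if (is.null(p)) return(NULL)
    p <- as.matrix(p)
    if (nrow(p) != n || ncol(p) != 2 || any(!is.finite(p))) {
      stop_sweepq("sweepq_validation_error",
                  "%s must be a finite %d x 2 matrix", what, n)
    }
    unname(p)
  }
  structure(list(
    attached_bias = as.numeric(attached_bias),
    unattached_bias = as.numeric(unattached_bias),
    n_workers = as.integer(n_workers),
    n_cargo = as.integer(n_cargo),
    n_steps = as.integer(n_steps),
    step_length = as.numeric(step_length),
    delivery_radius = as.numeric(delivery_radius),
    arena_size = as.numeric(arena_size),
    seed = as.integer(seed),
    worker_positions = check_positions(worker_positions, n_workers,
                                       "worker_positions"),
    cargo_positions = check_positions(cargo_positions, n_cargo,
                                      "cargo_positions"),
    director_position = as.numeric(director_position)
  ), class = "sweepq_sim_params")
}

# Run `expr` under the simulation's private RNG stream, restoring the
# caller's stream afterwards.
with_sim_rng <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

random_unit <- function() {
  theta <- stats::runif(1, 0, 2 * pi)
  c(cos(theta), sin(theta))
}

#' Run the toy biorobots simulation
#'
#' Deterministic for fixed parameters and seed (bit-identical outputs). Writes
#' three agent-position snapshots — initial (step 0), middle (step
#' `n_steps %/% 2`) and final (step `n_steps`) — as delimited text plus a
#' JSON summary into `output_dir`.
#'
#' @param params A [sim_params()] object.
#' @param output_dir Directory for snapshots and summary; created if needed.
#'   `NULL` skips all file output.
#' @return A `sweepq_sim_summary` list: `delivered_count`,
#'   `delivered_fraction` (of `n_cargo`), `mean_final_distance` (mean cargo
#'   distance to the director; delivered cargo count as 0), and
#'   `snapshot_paths`.
#' @examples
#' p <- sim_params(n_workers = 2, n_cargo = 3, n_steps = 50, seed = 1)
#' run_toy_simulation(p, output_dir = NULL)$delivered_count
#' @export
run_toy_simulation <- function(params, output_dir = NULL) {
  stopifnot(inherits(params, "sweepq_sim_params"))
  with_sim_rng(params$seed, run_sim_impl(params, output_dir))
}

run_sim_impl <- function(params, output_dir) {
  half <- params$arena_size / 2
  director <- params$director_position

  workers <- params$worker_positions
  if (is.null(workers)) {
    workers <- matrix(stats::runif(2 * params$n_workers, -half, half),
                      ncol = 2)
  }
  cargo <- params$cargo_positions
  if (is.null(cargo)) {
    cargo <- matrix(stats::runif(2 * max(params$n_cargo, 1), -half, half),
                    ncol = 2)[seq_len(params$n_cargo), , drop = FALSE]
    # keep randomly placed cargo from starting inside the delivery zone
    if (params$n_cargo > 0) {
      too_close <- sqrt(colSums((t(cargo) - director)^2)) <
        2 * params$delivery_radius
      cargo[too_close, ] <- cargo[too_close, , drop = FALSE] +
        2 * params$delivery_radius
    }
  }

  delivered <- rep(FALSE, params$n_cargo)   # cargo placed at the director
  carried_by <- rep(NA_integer_, params$n_cargo)
  carrying <- rep(NA_integer_, params$n_workers)

  snapshots <- list()
  snap_steps <- c(initial = 0L, middle = params$n_steps %/% 2L,
                  final = params$n_steps)
  take_snapshot <- function(step) {
    agent_frame(workers, cargo, director, carrying, delivered, step)
  }
  snapshots[["initial"]] <- take_snapshot(0L)

  for (step in seq_len(params$n_steps)) {
    for (w in seq_len(params$n_workers)) {
      rnd <- random_unit()
      if (is.na(carrying[w])) {
        free <- which(!delivered & is.na(carried_by))
        if (length(free)) {
          d2 <- colSums((t(cargo[free, , drop = FALSE]) - workers[w, ])^2)
          target <- cargo[free[which.min(d2)], ]
          bias <- params$unattached_bias
        } else {
          target <- NULL
        }
      } else {
        target <- director
        bias <- params$attached_bias
      }
      if (is.null(target)) {
        dir_vec <- rnd
      } else {
        to_target <- target - workers[w, ]
        nt <- sqrt(sum(to_target^2))
        u <- if (nt > 1e-12) to_target / nt else c(0, 0)
        v <- bias * u + (1 - bias) * rnd
        nv <- sqrt(sum(v^2))
        dir_vec <- if (nv > 1e-12) v / nv else rnd
      }
      workers[w, ] <- workers[w, ] + params$step_length * dir_vec
      if (!is.na(carrying[w])) cargo[carrying[w], ] <- workers[w, ]

      if (is.na(carrying[w])) {
        free <- which(!delivered & is.na(carried_by))
        if (length(free)) {
          d <- sqrt(colSums((t(cargo[free, , drop = FALSE]) - workers[w, ])^2))
          hit <- free[d < params$delivery_radius]
          if (length(hit)) {
            carrying[w] <- hit[[1]]
            carried_by[hit[[1]]] <- w
            cargo[hit[[1]], ] <- workers[w, ]
          }
        }
      } else if (sqrt(sum((workers[w, ] - director)^2)) <
                 params$delivery_radius) {
        c_idx <- carrying[w]
        delivered[c_idx] <- TRUE
        carried_by[c_idx] <- NA_integer_
        cargo[c_idx, ] <- director
        carrying[w] <- NA_integer_
      }
    }
    if (step == snap_steps[["middle"]]) {
      snapshots[["middle"]] <- take_snapshot(step)
    }
    if (step == snap_steps[["final"]]) {
      snapshots[["final"]] <- take_snapshot(step)
    }
  }
  if (is.null(snapshots[["middle"]])) {     # n_steps == 1
    snapshots[["middle"]] <- snapshots[["initial"]]
  }

  cargo_dist <- if (params$n_cargo > 0) {
    sqrt(colSums((t(cargo) - director)^2))
  } else {
    numeric(0)
  }

  snapshot_paths <- stats::setNames(character(3), names(snap_steps))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(snap_steps)) {
      p <- file.path(output_dir, sprintf("snapshot_%s.csv", nm))
      atomic_write_lines(format_snapshot(snapshots[[nm]]), p)
      snapshot_paths[[nm]] <- p
    }
  } else {
    snapshot_paths[] <- NA_character_
  }

  summary <- structure(list(
    delivered_count = sum(delivered),
    delivered_fraction = if (params$n_cargo > 0) {
      sum(delivered) / params$n_cargo
    } else {
      0
    },
    mean_final_distance = if (length(cargo_dist)) mean(cargo_dist) else NA_real_,
    final_worker_positions = workers,
    snapshot_paths = as.list(snapshot_paths)
  ), class = "sweepq_sim_summary")

  if (!is.null(output_dir)) {
    # snapshot locations are recorded relative to output_dir so the summary
    # file is byte-identical across runs in different directories
    on_disk <- summary[c("delivered_count", "delivered_fraction",
                         "mean_final_distance", "snapshot_paths")]
    on_disk$snapshot_paths <- lapply(on_disk$snapshot_paths, basename)
    json <- jsonlite::toJSON(on_disk, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, na = "null")
    atomic_write_lines(as.character(json),
                       file.path(output_dir, "summary.json"))
  }
  summary
}

agent_frame <- function(workers, cargo, director, carrying, delivered, step) {
  n_w <- nrow(workers)
  n_c <- nrow(cargo)
  data.frame(
    step = step,
    type = c(rep("worker", n_w), rep("cargo", n_c), "director"),
    agent = c(seq_len(n_w), seq_len(n_c), 1L),
    x = c(workers[, 1], cargo[, 1], director[1]),
    y = c(workers[, 2], cargo[, 2], director[2]),
    state = c(ifelse(is.na(carrying), "unattached", "attached"),
              ifelse(delivered, "delivered", "undelivered"), "fixed"),
    stringsAsFactors = FALSE
  )
}

format_snapshot <- function(df) {
  c("step,type,agent,x,y,state",
    sprintf("%d,%s,%d,%.6f,%.6f,%s",
            df$step, df$type, df$agent, df$x, df$y, df$state))
}

#' @export
print.sweepq_sim_summary <- function(x, ...) {
  cat(sprintf(
    "<sweepq_sim_summary> delivered %d cargo (fraction %.3f), mean final distance %.3f\n",
    x$delivered_count, x$delivered_fraction, x$mean_final_distance))
  invisible(x)
}

#' Build simulation parameters from an XML settings file
#'
#' Reads the `<user_parameters>` block of a settings file (see
#' [sample_settings()]): the two migration biases are required; the remaining
#' knobs (`number_of_workers`, `number_of_cargo`, `number_of_steps`,
#' `step_length`, `delivery_radius`, `arena_size`, `random_seed`) fall back to
#' the [sim_params()] defaults when absent.
#'
#' @param settings_file Path to a well-formed XML settings file.
#' @return A validated [sim_params()] object.
#' @export
load_parameters_from_settings <- function(settings_file) {
  doc <- tryCatch(
    xml2::read_xml(settings_file),
    error = function(e) {
      stop_sweepq("sweepq_parse_error", "cannot parse XML '%s': %s",
                  settings_file, conditionMessage(e))
    }
  )
  get_text <- function(path) {
    node <- xml2::xml_find_first(xml2::xml_root(doc), paste0(".", path))
    if (inherits(node, "xml_missing")) return(NULL)
    xml2::xml_text(node)
  }
  get_num <- function(path, required = FALSE) {
    txt <- get_text(path)
    if (is.null(txt)) {
      if (required) {
        stop_sweepq("sweepq_path_error",
                    "settings file is missing element %s", path)
      }
      return(NULL)
    }
    val <- suppressWarnings(as.numeric(txt))
    if (is.na(val)) {
      stop_sweepq("sweepq_validation_error",
                  "element %s holds non-numeric text '%s'", path, txt)
    }
    val
  }
  base <- "/user_parameters/"
  defaults <- formals(sim_params)
  pick <- function(name, default) get_num(paste0(base, name)) %||% default
  sim_params(
    attached_bias = get_num(paste0(base, "attached_worker_migration_bias"),
                            required = TRUE),
    unattached_bias = get_num(paste0(base, "unattached_worker_migration_bias"),
                              required = TRUE),
    n_workers = pick("number_of_workers", eval(defaults$n_workers)),
    n_cargo = pick("number_of_cargo", eval(defaults$n_cargo)),
    n_steps = pick("number_of_steps", eval(defaults$n_steps)),
    step_length = pick("step_length", eval(defaults$step_length)),
    delivery_radius = pick("delivery_radius", eval(defaults$delivery_radius)),
    arena_size = pick("arena_size", eval(defaults$arena_size)),
    seed = pick("random_seed", eval(defaults$seed))
  )
}
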