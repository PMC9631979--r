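# Collinear fixture: worker at the origin, cargo 10 units away, director 30
# units away. With both biases at 1 motion is fully directed, so delivery
# takes exactly 10 steps (reach cargo) + 20 steps (drag to director).
collinear_params <- function(n_steps, seed = 1) {
  sim_params(attached_bias = 1, unattached_bias = 1,
             n_workers = 1, n_cargo = 1, n_steps = n_steps,
             step_length = 1, delivery_radius = 0.5, seed = seed,
             worker_positions = matrix(c(0, 0), 1),
             cargo_positions = matrix(c(10, 0), 1),
             director_position = c(30, 0))
}

test_that("bias 1 gives straight-line delivery in the exact predicted step count", {
  expect_identical(run_toy_simulation(collinear_params(30))$delivered_count, 1L)
  expect_identical(run_toy_simulation(collinear_params(29))$delivered_count, 0L)
  # the step count is seed-independent: motion is deterministic at bias 1
  expect_identical(run_toy_simulation(collinear_params(30, seed = 99))$delivered_count, 1L)
  done <- run_toy_simulation(collinear_params(30))
  expect_identical(done$delivered_fraction, 1)
  expect_identical(done$mean_final_distance, 0)
})

test_that("bias 0 reproduces diffusive mean squared displacement", {
  T_steps <- 50L
  n_seeds <- 1000L
  msd <- vapply(seq_len(n_seeds), function(s) {
    p <- sim_params(attached_bias = 0, unattached_bias = 0,
                    n_workers = 1, n_cargo = 0, n_steps = T_steps,
                    step_length = 1, seed = s,
                    worker_positions = matrix(c(0, 0), 1))
    sum(run_toy_simulation(p)$final_worker_positions[1, ]^2)
  }, numeric(1))
  # closed form: E|X_T|^2 = T * step^2 for a sum of T iid unit steps;
  # tolerance is 4 Monte-Carlo standard errors of this very sample
  se <- stats::sd(msd) / sqrt(n_seeds)
  expect_lt(abs(mean(msd) - T_steps), 4 * se)
})

test_that("identical parameters and seed give bit-identical outputs", {
  p <- sim_params(n_workers = 3, n_cargo = 4, n_steps = 80, seed = 123,
                  arena_size = 50)
  d1 <- tempfile("sim"); d2 <- tempfile("sim")
  s1 <- run_toy_simulation(p, d1)
  s2 <- run_toy_simulation(p, d2)
  expect_identical(s1$delivered_count, s2$delivered_count)
  expect_identical(s1$final_worker_positions, s2$final_worker_positions)
  for (nm in c("snapshot_initial.csv", "snapshot_middle.csv",
               "snapshot_final.csv", "summary.json")) {
    expect_identical(readLines(file.path(d1, nm)),
                     readLines(file.path(d2, nm)))
  }
  # a different seed changes the walk
  p2 <- sim_params(n_workers = 3, n_cargo = 4, n_steps = 80, seed = 124,
                   arena_size = 50)
  s3 <- run_toy_simulation(p2)
  expect_false(identical(s1$final_worker_positions,
                         s3$final_worker_positions))
  # and the simulation does not disturb the caller's RNG stream
  set.seed(5); before <- stats::runif(3)
  set.seed(5); run_toy_simulation(p); after <- stats::runif(3)
  expect_identical(before, after)
})

test_that("exactly three snapshots are taken, at steps 0, n/2 and n", {
  p <- sim_params(n_workers = 2, n_cargo = 2, n_steps = 40, seed = 3,
                  arena_size = 30)
  dir <- tempfile("snaps")
  summary <- run_toy_simulation(p, dir)
  expect_identical(sort(basename(unlist(summary$snapshot_paths))),
                   sort(list.files(dir, pattern = "^snapshot_")))
  steps <- vapply(summary$snapshot_paths, function(f) {
    unique(utils::read.csv(f)$step)
  }, numeric(1))
  expect_identical(unname(steps), c(0, 20, 40))
  expect_identical(summary$delivered_fraction, summary$delivered_count / 2)
})

test_that("directedness is monotone in the attached bias", {
  biases <- c(0, 0.5, 1)
  n_seeds <- 250L
  mean_dist <- vapply(biases, function(b) {
    mean(vapply(seq_len(n_seeds), function(s) {
      p <- sim_params(attached_bias = b, unattached_bias = 1,
                      n_workers = 1, n_cargo = 2, n_steps = 150,
                      arena_size = 60, seed = s)
      run_toy_simulation(p)$mean_final_distance
    }, numeric(1)))
  }, numeric(1))
  # non-increasing, with slack of one Monte-Carlo standard error scale
  expect_true(all(diff(mean_dist) < 1))
  expect_gt(mean_dist[1], mean_dist[3])
})

test_that("invalid parameters are rejected", {
  expect_error(sim_params(attached_bias = 1.5),
               class = "sweepq_validation_error")
  expect_error(sim_params(unattached_bias = -0.1),
               class = "sweepq_validation_error")
  expect_error(sim_params(n_workers = 0), class = "sweepq_validation_error")
  expect_error(sim_params(step_length = 0), class = "sweepq_validation_error")
  expect_error(sim_params(worker_positions = matrix(0, 3, 2), n_workers = 2),
               class = "sweepq_validation_error")
})

test_that("simulation parameters load from a settings file", {
  f <- tempfile(fileext = ".xml")
  sample_settings(f)
  apply_parameters(stats::setNames(c("0.1", "1.0"),
                                   c(ATTACHED_BIAS_PATH, UNATTACHED_BIAS_PATH)),
                   f)
  p <- load_parameters_from_settings(f)
  expect_identical(p$attached_bias, 0.1)
  expect_identical(p$unattached_bias, 1.0)
  # knobs fall back to defaults from the skeleton or sim_params
  expect_identical(p$n_workers, 5L)
  # the bundled defaults file carries 1.0 / 0.5
  defaults <- load_parameters_from_settings(skeleton_path())
  expect_identical(defaults$attached_bias, 1.0)
  expect_identical(defaults$unattached_bias, 0.5)
  # out-of-range bias text is a validation error
  apply_parameters(stats::setNames("1.5", ATTACHED_BIAS_PATH), f)
  expect_error(load_parameters_from_settings(f),
               class = "sweepq_validation_error")
  # non-numeric bias text
  apply_parameters(stats::setNames("fast", ATTACHED_BIAS_PATH), f)
  expect_error(load_parameters_from_settings(f),
               class = "sweepq_validation_error")
  # missing bias elements
  bare <- tempfile(fileext = ".xml")
  writeLines("<settings><user_parameters/></settings>", bare)
  expect_error(load_parameters_from_settings(bare),
               class = "sweepq_path_error")
})
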