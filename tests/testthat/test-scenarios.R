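make_traj <- function(y, times = seq(0, 1, length.out = nrow(y))) {
  n <- ncol(y)
  states <- cbind(matrix(0, nrow(y), n), y, 2e6)
  colnames(states) <- c(paste0("x_", 1:n), paste0("y_", 1:n), "z")
  structure(list(times = times, states = states,
                 labels = colnames(states), model = "model2",
                 n_classes = n),
            class = "ab_trajectory")
}

test_that("presets carry the published parameter sets", {
  cd <- scenario_preset("clonal_deletion")
  expect_equal(cd$params$strong$k2, 1e-8)
  expect_equal(cd$params$weak$k2, 1e-9)
  expect_equal(cd$params$strong$k4, 0.1)
  expect_equal(unname(cd$initial_state), c(0, 1e5, 3e7))

  ps <- scenario_preset("pathogen_selection")
  expect_equal(ps$params$k2, c(1e-5, 9e-6, 8e-6, 7e-6, 6e-6))
  expect_equal(ps$params$k4, 2)

  st <- scenario_preset("shm_self_tolerance")
  expect_equal(st$params$k4, 0.6)
  expect_equal(st$p_values, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(st$initial_state$y[9], 1e5)

  sf <- scenario_preset("shm_foreign")
  expect_equal(sf$params$k4, 1.1)
  expect_equal(sf$initial_state$y[1], 1e5)   # seeded in the weakest class
  expect_equal(sf$p_values, c(0, 0.5))

  ag <- scenario_preset("aging_sweep")
  expect_equal(ag$params$k4, 0.7)
  expect_equal(ag$initial_state$y,
               initial_composition(affinity_grid(), 1e6))
  expect_equal(ag$initial_state$z, 2e6)

  expect_error(scenario_preset("nope"), "clonal_deletion")
})

test_that("repertoire metrics summarize composition and dominance", {
  ## uniform repertoire: equal composition, ties go to the lowest index
  tr <- make_traj(matrix(3, nrow = 4, ncol = 9))
  m <- trajectory_metrics(tr)
  expect_equal(m$composition[1, ], rep(1 / 9, 9), ignore_attr = TRUE)
  expect_equal(m$dominant_class, rep(1L, 4))
  expect_equal(m$mean_class_index, rep(5, 4))
  expect_equal(rowSums(m$composition), rep(1, 4), tolerance = 1e-12)

  ## mass concentrated in class 7
  y <- matrix(0, 3, 9); y[, 7] <- 5e4
  m7 <- trajectory_metrics(make_traj(y))
  expect_equal(m7$dominant_class, rep(7L, 3))
  expect_equal(m7$mean_class_index, rep(7, 3))
  expect_equal(m7$total_antibody, rep(5e4, 3))

  ## metrics require per-class antibody columns
  p <- model1_params(k2 = 1e-8)
  tr1 <- integrate_model1(c(0, 1e5, 3e7), p, 5, model = "self")
  expect_error(trajectory_metrics(tr1), "model 2")
})

test_that("time_to_fraction finds the first crossing time", {
  y <- matrix(0, 5, 9)
  y[, 9] <- c(100, 80, 50, 30, 10)
  tr <- make_traj(y, times = 0:4)
  expect_equal(time_to_fraction(tr, 9, 0.5), 2)
  expect_equal(time_to_fraction(tr, 9, 0.05), NA_real_)
  expect_error(time_to_fraction(tr, 10, 0.5), "out of range")
})

test_that("hypermutation accelerates the decay of the seeded self-binder", {
  ## the seeded class is mostly eliminated in the fast binding transient,
  ## so resolve the early window finely
  spec <- scenario_preset("shm_self_tolerance")
  spec$t_end <- 2
  spec$n_points <- 4001
  res <- run_scenario(spec)
  t_half <- vapply(res$members, function(m)
    time_to_fraction(m$trajectory, 9, 0.5), numeric(1))
  expect_true(all(diff(t_half) <= 0))  # larger p never delays halving
  t_05 <- vapply(res$members, function(m)
    time_to_fraction(m$trajectory, 9, 0.05), numeric(1))
  expect_true(all(diff(t_05) < 0))     # and strictly accelerates elimination
})

test_that("scenario runs are deterministic and export cleanly", {
  spec <- scenario_preset("clonal_deletion")
  r1 <- run_scenario(spec)
  r2 <- run_scenario(spec)
  expect_identical(r1$members$strong$trajectory$states,
                   r2$members$strong$trajectory$states)

  out <- withr::local_tempdir()
  run_scenario(scenario_preset("aging_sweep"), out_dir = out)
  csvs <- list.files(out, pattern = "\\.csv$")
  expect_length(csvs, 3)              # one per SHM rate
  meta <- jsonlite::read_json(file.path(out, "aging_sweep_metrics.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$scenario, "aging_sweep")
  expect_equal(meta$parameters$k4, 0.7)
  expect_equal(meta$members[["p=0.2"]]$report_times, c(0, 25, 50, 75, 100))
  comp <- meta$members[["p=0.2"]]$composition_at_report_times
  expect_equal(rowSums(comp), rep(1, 5), tolerance = 1e-10)
})

test_that("trajectory CSVs round-trip at full double precision", {
  spec <- scenario_preset("clonal_deletion")
  tr <- run_scenario(spec)$members$strong$trajectory
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read_trajectory_csv(f, model = tr$model)
  expect_equal(back$states, tr$states, ignore_attr = TRUE)
  expect_equal(back$times, tr$times)
})
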