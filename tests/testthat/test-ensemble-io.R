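test_that("ensemble seeds derive from the base seed, one per run", {
  m <- birth_death_model()
  ens <- run_ensemble(m, 2, base_seed = 40, grid_step = 0.5)
  solo1 <- simulate_trajectory(m, 40, 0.5)
  solo2 <- simulate_trajectory(m, 41, 0.5)
  expect_identical(ens$trajectories[[1]]$counts, solo1$counts)
  expect_identical(ens$trajectories[[2]]$counts, solo2$counts)
  expect_equal(ens$manifest$seeds, c(40L, 41L))
  # full determinism of the ensemble path
  ens2 <- run_ensemble(m, 2, base_seed = 40, grid_step = 0.5)
  expect_identical(lapply(ens$trajectories, `[[`, "counts"),
                   lapply(ens2$trajectories, `[[`, "counts"))
  expect_identical(ens$manifest$model_hash, ens2$manifest$model_hash)
})

test_that("summaries compute exact sample moments and censored medians", {
  s1 <- summarize_ensemble(list(simulate_trajectory(frozen_model(c(A = 4)), 1, 0.5)))
  expect_true(all(s1$sd_series == 0))          # n = 1 convention
  expect_equal(unname(s1$mean_series["A", ]), rep(4, length(s1$grid)))

  t4 <- simulate_trajectory(frozen_model(c(A = 4)), 1, 0.5)
  t6 <- simulate_trajectory(frozen_model(c(A = 6)), 2, 0.5)
  s <- summarize_ensemble(list(t4, t6))
  expect_equal(unname(s$mean_series["A", 1]), 5)       # two-point mean
  expect_equal(unname(s$sd_series["A", 1]), sqrt(2))   # n-1 denominator
  # recompute the mean by an independent brute-force pass
  brute <- (t4$series$A + t6$series$A) / 2
  expect_equal(unname(s$mean_series["A", ]), brute)

  mism <- simulate_trajectory(frozen_model(c(A = 4)), 1, 0.25)
  expect_error(summarize_ensemble(list(t4, mism)), "grid")
  expect_error(summarize_ensemble(list()), "empty")

  # all runs censored -> censored median, zero fractions
  calm <- build_default_network(list(k_ros_basal = 0, k_ab_basal = 0))
  trs <- run_ensemble(calm, 3, 1)$trajectories
  sc <- summarize_ensemble(trs)
  expect_true(is.na(sc$median_first_plaque))
  expect_true(is.na(sc$median_first_tangle))
  expect_equal(sc$fraction_with_plaque_by_end, 0)
})

test_that("outputs round-trip exactly and are byte-deterministic", {
  m <- birth_death_model(horizon = 2)
  ens <- run_ensemble(m, 3, base_seed = 9, grid_step = 0.5)
  s <- summarize_ensemble(ens$trajectories)
  s$trajectories <- ens$trajectories
  s$manifest <- ens$manifest
  d1 <- file.path(tempdir(), "out_a")
  d2 <- file.path(tempdir(), "out_b")
  unlink(c(d1, d2), recursive = TRUE)
  write_outputs(s, out_dir = d1)
  write_outputs(s, out_dir = d2)
  for (f in c("summary.csv", "trajectories.csv", "first_passage.csv",
              "manifest.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  back <- read_summary_table(file.path(d1, "summary.csv"))
  expect_equal(back$mean_series, s$mean_series, ignore_attr = FALSE)
  expect_equal(back$sd_series, s$sd_series)
  expect_equal(back$grid, s$grid)
  # trajectories reader reproduces every series
  trs2 <- read_trajectories_table(file.path(d1, "trajectories.csv"))
  expect_length(trs2, 3)
  expect_equal(trs2[[1]]$series$A, ens$trajectories[[1]]$series$A)
  expect_equal(trs2[[2]]$seed, 10)
  # refusal to clobber a non-empty directory without the flag
  expect_error(write_outputs(s, out_dir = d1), "overwrite")
  expect_silent(write_outputs(s, out_dir = d1, overwrite = TRUE))
})

test_that("models round-trip losslessly through YAML", {
  m <- apply_intervention(build_default_network(),
                          intervention_spec("clearance_boost", 6))
  p <- file.path(tempdir(), "model.yaml")
  write_model_yaml(m, p)
  m2 <- read_model_yaml(p)
  expect_equal(m2, m)
  # and the round-tripped model simulates identically
  a <- simulate_trajectory(m, 3, 0.5)
  b <- simulate_trajectory(m2, 3, 0.5)
  expect_identical(a$counts, b$counts)
})

test_that("experiment conditions are independent of execution order", {
  m <- build_default_network(list(k_ros_basal = 0.1))  # light model
  m$horizon <- 4
  sw1 <- run_clearance_sweep(days = c(0, 2, NA), n_runs = 3, base_seed = 5,
                             grid_step = 0.5, model = m)
  sw2 <- run_clearance_sweep(days = c(NA, 2, 0), n_runs = 3, base_seed = 5,
                             grid_step = 0.5, model = m)
  for (nm in c("day_0", "day_2", "none")) {
    expect_identical(sw1[[nm]]$mean_series, sw2[[nm]]$mean_series)
    expect_identical(sw1[[nm]]$manifest$seeds, sw2[[nm]]$manifest$seeds)
  }
})

test_that("run_baseline with one run reproduces that run's series", {
  m <- build_default_network()
  m$horizon <- 2
  s <- run_baseline(n_runs = 1, base_seed = 123, grid_step = 0.5, model = m)
  tr <- s$trajectories[[1]]
  for (o in rownames(s$mean_series)) {
    expect_equal(unname(s$mean_series[o, ]), unname(tr$series[[o]]))
  }
  expect_true(all(s$sd_series == 0))
})
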