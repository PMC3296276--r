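test_that("propensities follow the combinatoric mass-action convention", {
  m <- model_definition(
    "props",
    species = list(ad_species("A", initial_count = 5),
                   ad_species("B", initial_count = 0),
                   ad_species("M", initial_count = 3)),
    reactions = list(
      ad_reaction("source", products = c(A = 1), rate_parameter = "k4"),
      ad_reaction("uni", reactants = c(B = 1), rate_parameter = "k2"),
      ad_reaction("dimer", reactants = c(A = 2), products = c(B = 1),
                  rate_parameter = "k1"),
      ad_reaction("cat", products = c(B = 1), modifiers = "M",
                  rate_parameter = "k4")),
    parameters = list(ad_parameter("k4", 4), ad_parameter("k2", 2),
                      ad_parameter("k1", 1)),
    horizon = 1)
  st <- sim_state(m)
  expect_equal(propensity(m$reactions[[1]], st), 4)       # constant source
  expect_equal(propensity(m$reactions[[2]], st), 0)       # empty pool
  # dimerisation: number of unordered pairs of 5 molecules, counted
  # directly as the independent oracle
  pairs <- 0
  for (i in 1:4) for (j in (i + 1):5) pairs <- pairs + 1
  expect_equal(propensity(m$reactions[[3]], st), 1 * pairs)  # 10
  expect_equal(propensity(m$reactions[[4]], st), 4 * 3)      # modifier scales
})

test_that("pair-catalysed reactions have zero propensity with a single catalyst", {
  m <- build_default_network()
  rx <- m$reactions[[which(vapply(m$reactions, `[[`, "", "id") ==
                             "tau_phosphorylation")]]
  st <- sim_state(m)
  sp <- attr(st, "species")
  st$counts[match("GSK3b_p53", sp)] <- 1
  expect_equal(propensity(rx, st), 0)
  st$counts[match("GSK3b_p53", sp)] <- 2
  expect_gt(propensity(rx, st), 0)
})

test_that("a pending event interrupts and applies exactly, discarding the waiting time", {
  m <- birth_death_model(k = 0, g = 1, horizon = 10, init = 0)  # a0 = 0
  m$events <- list(timed_event(8, "k", "multiply", 100))
  st <- sim_state(m)
  set.seed(1)
  step <- ssa_advance(st, m)
  expect_equal(step$state$time, 8)
  expect_equal(step$fired, "event:k@8")
  expect_equal(step$state$param_values[["k"]], 0)  # 0 * 100
  expect_equal(step$state$counts, st$counts)
  expect_length(step$state$pending_events, 0)

  # multiply semantics on a nonzero value: parameter is exactly x100
  m2 <- birth_death_model(k = 10, g = 1, horizon = 10)
  m2$events <- list(timed_event(8, "k", "multiply", 100))
  m2 <- model_definition(m2$name, m2$species, m2$reactions, m2$parameters,
                         m2$events, m2$horizon)
  tr <- simulate_trajectory(m2, seed = 7, grid_step = 0.5)
  expect_identical(attr(tr, "final_params")[["k"]], 1000)
})

test_that("waiting times are exponential with mean 1/a0", {
  m <- birth_death_model(k = 1, g = 0, horizon = 1e6)
  set.seed(42)
  st <- sim_state(m)
  taus <- replicate(4000, {
    st$time <- 0
    ssa_advance(st, m)$state$time
  })
  # closed form: mean 1/a0 = 1, sd 1; 3 standard errors of the mean
  expect_lt(abs(mean(taus) - 1), 3 / sqrt(4000))
})

test_that("birth-death time average matches the Poisson stationary mean", {
  k <- 50; g <- 5
  m <- birth_death_model(k = k, g = g, horizon = 60, init = 10)
  tr <- simulate_trajectory(m, seed = 11, grid_step = 0.05)
  burn <- tr$grid > 5   # discard transient
  x <- tr$series$A[burn]
  # stationary law is Poisson(k/g): mean 10, var 10; correct the MC
  # error for autocorrelation (relaxation time 1/g) of the sampled chain
  n_eff <- sum(burn) * 0.05 * g
  expect_lt(abs(mean(x) - k / g), 3 * sqrt((k / g) / n_eff))
})

test_that("ensemble moments of a linear chain match the CME solution", {
  k <- 20; cc <- 2; g <- 1
  m <- chain_model(k = k, c = cc, g = g, horizon = 2)
  ens <- run_ensemble(m, n_runs = 2000, base_seed = 500, grid_step = 1)
  # product-Poisson CME solution for the open linear chain:
  # mA(t) = k/c (1 - exp(-c t));  dmB/dt = c mA - g mB
  mA <- function(t) k / cc * (1 - exp(-cc * t))
  # mB(t) = int_0^t c mA(s) exp(-g (t-s)) ds, evaluated by quadrature
  # as the independent oracle
  mB <- function(t) {
    f <- function(s) cc * mA(s) * exp(-g * (t - s))
    integrate(f, 0, t)$value
  }
  for (ti in c(2, 3)) {   # grid indices: t = 1, 2
    t <- (ti - 1) * 1
    A <- vapply(ens$trajectories, function(tr) tr$series$A[ti], 0)
    B <- vapply(ens$trajectories, function(tr) tr$series$B[ti], 0)
    for (obs in list(list(x = A, mu = mA(t)), list(x = B, mu = mB(t)))) {
      se <- sqrt(obs$mu / 2000)        # Poisson variance = mean
      expect_lt(abs(mean(obs$x) - obs$mu), 3 * se)
      # variance check: SE(var) ~ sqrt(2/(n-1)) * var for near-normal;
      # Poisson at these means is close enough for a 4-sigma band
      expect_lt(abs(var(obs$x) - obs$mu),
                4 * sqrt(2 / 1999) * obs$mu + 0.05 * obs$mu)
    }
  }
})

test_that("the compiled engine and the pure-R stepper are bit-identical", {
  m <- birth_death_model(k = 10, g = 1, horizon = 5)
  m$events <- list(timed_event(2, "k", "multiply", 3),
                   timed_event(4, "g", "set_value", 0.5))
  m <- model_definition(m$name, m$species, m$reactions, m$parameters,
                        m$events, m$horizon)
  for (seed in c(1, 99, 12345)) {
    a <- simulate_trajectory(m, seed, grid_step = 0.1)
    b <- adcycle:::simulate_trajectory_r(m, seed, grid_step = 0.1)
    expect_identical(a$counts, b$counts)
    expect_identical(a$first_passage, b$first_passage)
    expect_equal(attr(a, "final_params"), attr(b, "final_params"))
  }
  # and on the full default network with an intervention event
  md <- apply_intervention(build_default_network(list(k_syn_p53 = 10)),
                          intervention_spec("clearance_boost", 8))
  md$horizon <- 3
  a <- simulate_trajectory(md, 5, grid_step = 0.5)
  b <- adcycle:::simulate_trajectory_r(md, 5, grid_step = 0.5)
  expect_identical(a$counts, b$counts)
})

test_that("identical seeds give identical trajectories; counts never go negative", {
  m <- build_default_network()
  a <- simulate_trajectory(m, 123)
  b <- simulate_trajectory(m, 123)
  expect_identical(a$counts, b$counts)
  expect_identical(a$first_passage, b$first_passage)
  expect_true(all(a$counts >= 0))
  c2 <- simulate_trajectory(m, 124)
  expect_false(identical(a$counts, c2$counts))
  expect_true(all(c2$counts >= 0))
})

test_that("piecewise-constant recording holds the last state at each grid point", {
  m <- birth_death_model(k = 5, g = 0, horizon = 2, init = 0)
  tr <- simulate_trajectory(m, 9, grid_step = 0.01)
  x <- tr$series$A
  expect_true(all(diff(x) >= 0))           # pure birth never decreases
  expect_equal(x[1], 0)                    # grid point 0 = initial state
  expect_true(all(x == floor(x)))
})
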