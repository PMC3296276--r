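test_that("constructors enforce type invariants", {
  expect_error(ad_species("x", initial_count = -1), "non-negative integer")
  expect_error(ad_species("x", initial_count = 2.5), "non-negative integer")
  expect_error(ad_species("x", tags = "nonsense"), "unknown species tag")
  expect_error(ad_reaction("r", reactants = c(A = 0), rate_parameter = "k"),
               "positive integers")
  expect_error(ad_reaction("r", reactants = setNames(1L, ""),
                           rate_parameter = "k"), "named")
  expect_error(ad_parameter("k", -0.1), "non-negative")
  expect_silent(ad_parameter("k", 0))  # zero encodes the blockades
  expect_error(timed_event(-1, "k", "multiply", 100), ">= 0")
})

test_that("the default network is valid, with a 12-day horizon and no initial stress", {
  m <- build_default_network()
  expect_s3_class(m, "ad_model")
  expect_equal(m$horizon, 12)
  expect_equal(nrow(validate_network(m)), 0L)
  init <- initial_counts(m)
  expect_equal(unname(init[c("abeta_plaque", "tau_tangles", "damDNA",
                             "abeta_monomer", "abeta_oligomer")]),
               rep(0L, 5))
  # all blockade/intervention targets exist
  expect_true(all(c("k_ab_clear", "k_abeta_ros", "k_gsk_p53_bind") %in%
                    names(parameter_values(m))))
})

test_that("parameter overrides replace exactly the named values", {
  m <- build_default_network(list(k_abeta_ros = 0))
  expect_equal(parameter_values(m)[["k_abeta_ros"]], 0)
  base <- parameter_values(build_default_network())
  changed <- parameter_values(m)
  expect_equal(changed[names(changed) != "k_abeta_ros"],
               base[names(base) != "k_abeta_ros"])
  expect_error(build_default_network(list(no_such_param = 1)),
               "no_such_param")
})

test_that("validate_network reports broken cross-references as diagnostics", {
  m <- build_default_network()
  bad <- m
  bad$reactions[[1]]$products <- c(ghost = 1L)
  d <- validate_network(bad)
  expect_true(any(d$severity == "error" & grepl("ghost", d$message)))
  bad2 <- m
  bad2$parameters[[1]]$value <- -1
  d2 <- validate_network(bad2)
  expect_true(any(d2$severity == "error" &
                    grepl("non-negative", d2$message)))
  bad3 <- m
  bad3$species[[1]]$id <- m$species[[2]]$id
  expect_true(any(validate_network(bad3)$severity == "error"))
})

test_that("observable_total sums the tagged p53 pool and resolves identities", {
  m <- build_default_network()
  state <- setNames(rep(0, length(species_ids(m))), species_ids(m))
  state[c("p53", "p53_Mdm2", "p53_Ub")] <- c(5, 3, 2)
  expect_equal(observable_total(state, "total_p53", m), 10)
  expect_equal(observable_total(setNames(rep(0, length(state)),
                                         names(state)), "total_p53", m), 0)
  state["abeta_plaque"] <- 7
  expect_equal(observable_total(state, "abeta_plaque", m), 7)
  expect_error(observable_total(state, "no_such", m), "valid observables")
})

test_that("apply_intervention is pure and encodes each protocol", {
  m <- build_default_network()
  snapshot <- rlang::hash(m)
  d0 <- apply_intervention(m, intervention_spec("clearance_boost", 0))
  expect_identical(rlang::hash(m), snapshot)  # input untouched
  expect_length(d0$events, 0)
  expect_equal(parameter_values(d0)[["k_ab_clear"]],
               100 * parameter_values(m)[["k_ab_clear"]])
  d8 <- apply_intervention(m, intervention_spec("clearance_boost", 8))
  expect_length(d8$events, 1)
  ev <- d8$events[[1]]
  expect_equal(ev$fire_time, 8)
  expect_equal(ev$parameter_id, "k_ab_clear")
  expect_equal(ev$action, "multiply")
  expect_equal(ev$operand, 100)
  expect_identical(apply_intervention(m, intervention_spec("none")), m)
  # repeat application yields an equal model
  expect_identical(apply_intervention(m, intervention_spec("clearance_boost", 8)),
                   d8)
  rb <- apply_intervention(m, intervention_spec("ros_block"))
  expect_equal(parameter_values(rb)[["k_abeta_ros"]], 0)
  expect_equal(rb$events[[1]]$fire_time, 8)
  bb <- apply_intervention(m, intervention_spec("binding_block"))
  expect_equal(parameter_values(bb)[["k_gsk_p53_bind"]], 0)
  expect_error(apply_intervention(m, intervention_spec("clearance_boost", 13)),
               "\\[0, 12\\]")
  # oligomer clearance boost is off by default, available as a switch
  d0o <- apply_intervention(m, intervention_spec("clearance_boost", 0),
                            boost_oligomer_clearance = TRUE)
  expect_equal(parameter_values(d0)[["k_ab2_clear"]],
               parameter_values(m)[["k_ab2_clear"]])
  expect_equal(parameter_values(d0o)[["k_ab2_clear"]],
               100 * parameter_values(m)[["k_ab2_clear"]])
})

test_that("a reactionless model is valid and simulates to a constant trajectory", {
  m <- frozen_model()
  expect_equal(nrow(validate_network(m)), 0L)
  tr <- simulate_trajectory(m, seed = 3, grid_step = 0.5)
  expect_true(all(tr$series$A == 7))
})
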