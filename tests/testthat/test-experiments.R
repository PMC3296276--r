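# ensemble-level behaviour of the in-silico experiments; the heavy
# 100-run sweep is computed once (helper cache) and shared

test_that("baseline ensembles reproduce the calibrated disease course", {
  s <- cached_none()
  # the majority of simulated cells accumulate both aggregates ...
  expect_gt(s$fraction_with_plaque_by_end, 0.5)
  expect_gt(s$fraction_with_tangle_by_end, 0.5)
  # ... while a small minority escape at least one aggregate type
  expect_gt((1 - s$fraction_with_plaque_by_end) +
              (1 - s$fraction_with_tangle_by_end), 0)
  # tangles precede plaques among runs forming both
  fp <- vapply(s$trajectories, function(tr) tr$first_passage[["first_plaque"]], 0)
  ft <- vapply(s$trajectories, function(tr) tr$first_passage[["first_tangle"]], 0)
  both <- !is.na(fp) & !is.na(ft)
  expect_gt(sum(both), 50)
  expect_lt(median(ft[both]), median(fp[both]))
})

test_that("a day-2 clearance boost leaves traces: no plaques, a few tangles, residual ROS", {
  d2 <- cached_sweep()$day_2
  expect_lt(end_mean_of(d2, "abeta_plaque"), 0.5)
  expect_gt(end_mean_of(d2, "tau_tangles"), 0)
  expect_gt(end_mean_of(d2, "ROS"), 0)
  # and tangles stay far below the uncontrolled burden
  expect_lt(end_mean_of(d2, "tau_tangles"),
            0.2 * end_mean_of(cached_none(), "tau_tangles"))
})

test_that("late clearance boosts no longer reduce the tangle burden, only plaques", {
  sw <- cached_sweep()
  none_tgl <- end_mean_of(sw$none, "tau_tangles")
  none_plq <- end_mean_of(sw$none, "abeta_plaque")
  for (d in c("day_6", "day_8")) {
    expect_gt(end_mean_of(sw[[d]], "tau_tangles"), 0.75 * none_tgl)
    expect_lt(end_mean_of(sw[[d]], "abeta_plaque"), 0.2 * none_plq)
  }
})

test_that("the ROS-production blockade reproduces the day-0 clearance condition", {
  s <- cached("ros_block", run_ros_block(n_runs = 100, base_seed = 1))
  none <- cached_none()
  d0 <- cached_day0()
  # near-zero rule: below one count and below 2% of the uncontrolled mean
  for (o in c("abeta_plaque", "tau_tangles", "damDNA", "GSK3b_p53")) {
    expect_lt(end_mean_of(s, o), 1)
    expect_lt(end_mean_of(s, o), 0.02 * max(end_mean_of(none, o), 50))
  }
  # within Monte-Carlo error of the day-0 condition on the reported
  # observables (total p53 carries the only appreciable variance)
  for (o in c("total_p53", "GSK3b_p53", "abeta_plaque", "tau_tangles",
              "damDNA")) {
    n <- ncol(s$mean_series)
    se <- sqrt(s$sd_series[o, n]^2 / s$n_runs +
                 d0$sd_series[o, n]^2 / d0$n_runs)
    expect_lt(abs(end_mean_of(s, o) - end_mean_of(d0, o)), 3 * se + 0.5)
  }
})

test_that("with no entry into the cycle there is never any damage or aggregation", {
  quiet <- build_default_network(list(k_abeta_ros = 0, k_ros_basal = 0,
                                      k_ab_basal = 0))
  trs <- run_ensemble(quiet, 10, base_seed = 31)$trajectories
  for (tr in trs) {
    expect_true(all(tr$series$damDNA == 0))
    expect_true(all(tr$series$abeta_plaque == 0))
    expect_true(all(tr$series$tau_tangles == 0))
  }
})

test_that("the binding blockade abolishes complexes and aggregates while p53 still rises", {
  s <- cached("binding_block", run_binding_block(n_runs = 100, base_seed = 1))
  none <- cached_none()
  expect_true(all(s$mean_series["GSK3b_p53", ] == 0))  # complex never forms
  expect_lt(end_mean_of(s, "abeta_plaque"), 1)
  expect_lt(end_mean_of(s, "abeta_plaque"),
            0.02 * end_mean_of(none, "abeta_plaque"))
  expect_lt(end_mean_of(s, "tau_tangles"), 1)
  expect_gt(end_mean_of(s, "total_p53"), s$mean_series["total_p53", 1])
})

test_that("viability falls the later the clearance boost is applied", {
  sw <- cached_sweep()
  v <- viability_analysis(lapply(sw, `[[`, "trajectories"),
                          threshold_model(), seed = 11)
  endv <- vapply(v, function(x)
    x$viable_curve$percent_viable[nrow(x$viable_curve)], 0)
  ord <- c("day_0", "day_2", "day_4", "day_6", "day_8", "none")
  expect_equal(names(endv), ord)
  expect_true(all(diff(endv[ord]) <= 0))
  expect_equal(unname(endv[["day_0"]]), 100)
  # a day-8 boost buys little viability compared with no intervention,
  # in contrast to the early interventions
  expect_lt(endv[["day_8"]] - endv[["none"]], 20)
  expect_gt(endv[["day_0"]] - endv[["none"]], 60)
})
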