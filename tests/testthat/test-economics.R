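test_that("discounting convention: cycle 1 undiscounted", {
  expect_equal(discount_factor(0.04, 1), 1)
  expect_equal(discount_factor(0.04, 2), 1 / 1.04)
  expect_equal(discount_factor(0.04, 2), 0.96154, tolerance = 1e-5)
  expect_equal(discount_factor(0, 1:50), rep(1, 50))
  expect_error(discount_factor(-0.01, 1))
})

test_that("half-cycle correction averages cycle boundaries", {
  expect_equal(half_cycle_value(1, 0), 0.5)
  expect_equal(half_cycle_value(0.37, 0.37), 0.37)

  # a 3-cycle declining occupancy accumulates like the trapezoid rule
  p <- toy_params(q = 0.2, utility = 1, horizon = 3)
  tr <- suppressWarnings(run_cohort(p))
  out <- accumulate(tr, p)
  occ <- 0.8^(0:3)
  trapezoid <- sum((occ[-4] + occ[-1]) / 2)
  expect_equal(out$total_ly, trapezoid)
})

test_that("trastuzumab acquisition arithmetic", {
  expect_equal(trastuzumab_acquisition_cost(list(
    vials_per_cycle = 3, n_administrations = 15,
    vial_price = 605, admin_price = 257, her2_testing = 0)), 31080)
  expect_equal(trastuzumab_acquisition_cost(list(
    vials_per_cycle = 3, n_administrations = 0,
    vial_price = 605, admin_price = 257)), 0)
  expect_equal(trastuzumab_acquisition_cost(list(
    vials_per_cycle = 1, n_administrations = 1,
    vial_price = 1, admin_price = 1)), 2)
  expect_error(trastuzumab_acquisition_cost(list(
    vials_per_cycle = -1, n_administrations = 1,
    vial_price = 1, admin_price = 1)))
})

test_that("accumulate: first-year utility weighting and degenerate traces", {
  # one full person-year disease free in year 1 at utility 0.728
  uc <- function(f, s) c(first = f, subsequent = s)
  p <- model_parameters(
    arm = "control", p_os = uc(0, 0), p_dfs = uc(0, 0), p_dm = uc(0, 0),
    state_costs = list(dfs = uc(12776, 1237), lr = uc(0, 0), dm = uc(0, 0)),
    utilities = list(dfs = uc(0.728, 0.8), lr = uc(0.71, 0.71),
                     dm = uc(0.6, 0.6)),
    life_table = flat_life_table(0), discount_costs = 0,
    discount_effects = 0, horizon = 1)
  tr <- suppressWarnings(run_cohort(p))
  out <- accumulate(tr, p)
  expect_equal(out$qaly[["dfs"]], 0.728)
  expect_equal(out$costs[["dfs"]], 12776)
  expect_equal(out$total_ly, 1)

  # an empty trace (cycle 0 only) yields an all-zero outcome
  empty <- tr[1, , drop = FALSE]
  out0 <- accumulate(empty, p)
  expect_equal(out0$total_cost, 0)
  expect_equal(out0$total_qaly, 0)
  expect_equal(out0$total_ly, 0)
})

test_that("first-year state costs attach to the year of entry (tunnel accounting)", {
  # everyone moves DFS -> DM in cycle 1 (p = 1 - exp(-30) ~ 1); DM costs
  # differ sharply between entry year and later years
  uc <- function(f, s) c(first = f, subsequent = s)
  p_dm_in <- 1 - exp(-30)
  p <- model_parameters(
    arm = "control", p_os = uc(0, 0),
    p_dfs = uc(p_dm_in, p_dm_in), p_dm = uc(p_dm_in, p_dm_in),
    state_costs = list(dfs = uc(0, 0), lr = uc(0, 0),
                       dm = uc(30165, 47959)),
    utilities = list(dfs = uc(1, 1), lr = uc(1, 1), dm = uc(0.6, 0.6)),
    life_table = flat_life_table(0), discount_costs = 0,
    discount_effects = 0, horizon = 3)
  tr <- suppressWarnings(run_cohort(p))
  out <- accumulate(tr, p)
  # entrants arrive mid-cycle 1 and leave the entry-year tunnel at the
  # cycle-2 boundary, so half-cycle correction credits them half a year at
  # the first-year rate in each of cycles 1 and 2 (one full entry year in
  # total), then the subsequent rate: 0.5 y in cycle 2 plus 1 y in cycle 3
  expect_equal(out$costs[["dm"]], 30165 * 1 + 47959 * 1.5, tolerance = 1e-6)
})

test_that("category decomposition is exact and utilities bound QALYs by LYs", {
  cfg <- her2cea_example_config("real_world")
  for (arm in c("trastuzumab", "control")) {
    prm <- build_scenario_parameters(cfg, arm)
    out <- accumulate(run_cohort(prm), prm)
    expect_identical(out$total_cost, sum(out$costs))
    expect_identical(out$total_qaly, sum(out$qaly))
    expect_lte(out$total_qaly, out$total_ly)
    expect_true(all(out$costs >= 0))
  }

  # all utilities 1 and no disutility: QALYs equal LYs
  p <- toy_params(q = 0.1, utility = 1, horizon = 40)
  out1 <- accumulate(suppressWarnings(run_cohort(p)), p)
  expect_equal(out1$total_qaly, out1$total_ly, tolerance = 1e-12)
})

test_that("discounted totals are non-increasing in the discount rate", {
  totals <- vapply(c(0, 0.015, 0.04, 0.08), function(r) {
    p <- toy_params(q = 0.05, cost = 1000, discount_costs = r, horizon = 50)
    out <- accumulate(suppressWarnings(run_cohort(p)), p)
    out$total_cost
  }, numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("two-state toy model matches the closed-form discounted sojourn cost", {
  # DFS -> dead at q; cost c per year; discount r; half-cycle corrected
  q <- 0.2; cost <- 1000; r <- 0.04
  p <- toy_params(q = q, cost = cost, discount_costs = r, horizon = 500)
  out <- accumulate(run_cohort(p), p)
  t <- 1:500
  occ <- (1 - q)^(t - 1)
  hcc <- (occ + occ * (1 - q)) / 2
  oracle <- sum(cost * hcc * (1 + r)^(-(t - 1)))
  expect_equal(out$costs[["dfs"]], oracle, tolerance = 1e-6)
})

test_that("cardiac monitoring and disutility follow the configured scope", {
  cfg <- her2cea_example_config("real_world")
  prm_tr <- build_scenario_parameters(cfg, "trastuzumab")
  prm_ct <- build_scenario_parameters(cfg, "control")
  out_tr <- accumulate(run_cohort(prm_tr), prm_tr)
  out_ct <- accumulate(run_cohort(prm_ct), prm_ct)
  # whole-arm monitoring: the full cost in the trastuzumab arm, none in control
  expect_equal(out_tr$costs[["cardiac"]], 467)
  expect_equal(out_ct$costs[["cardiac"]], 0)
  # disutility applies to the cardiac-event fraction of each arm
  expect_equal(out_tr$qaly[["cardiac"]], -0.128 * 0.125)
  expect_equal(out_ct$qaly[["cardiac"]], -0.128 * 0.125 / 5.33)

  # event-scope switches the monitoring cost to the affected fraction
  cfg_ev <- apply_overrides(cfg, list("cardiac_monitoring_scope" = "events"))
  prm_ev <- build_scenario_parameters(cfg_ev, "trastuzumab")
  out_ev <- accumulate(run_cohort(prm_ev), prm_ev)
  expect_equal(out_ev$costs[["cardiac"]], 467 * 0.125)
})
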