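test_that("the generator respects edge cases, ordering and reproducibility", {
  # zero death rate: nobody dies, every death time is censored
  g0 <- generate_cohort(true_probs = list(
    p_os = c(first = 0, subsequent = 0),
    p_dfs = c(first = 0.02, subsequent = 0.05),
    p_dm = c(first = 0.01, subsequent = 0.04),
    p_cardiac = 0.1), n = 500, seed = 2)
  expect_true(all(!g0$event_death))
  expect_equal(g0$time_death, g0$censor_time)

  # same seed, same cohort; different seed, different cohort
  g1 <- generate_cohort(n = 400, seed = 31)
  g2 <- generate_cohort(n = 400, seed = 31)
  g3 <- generate_cohort(n = 400, seed = 32)
  expect_identical(g1, g2)
  expect_false(identical(g1$time_dfs_event, g3$time_dfs_event))

  # observed event times are ordered: DFS event <= DM <= death when observed
  g <- generate_cohort(true_probs = list(
    p_os = c(first = 0.05, subsequent = 0.1),
    p_dfs = c(first = 0.1, subsequent = 0.2),
    p_dm = c(first = 0.05, subsequent = 0.15),
    p_cardiac = 0.1), n = 2000, seed = 8)
  both_dm <- g$event_dfs & g$event_dm
  expect_true(all(g$time_dfs_event[both_dm] <= g$time_dm[both_dm] + 1e-12))
  dm_death <- g$event_dm & g$event_death
  expect_true(all(g$time_dm[dm_death] <= g$time_death[dm_death] + 1e-12))

  # censoring window is respected
  expect_true(all(g$censor_time >= 3.8 & g$censor_time <= 6.8))

  # control arm derived by dividing hazards by the HR: more events
  gc <- generate_cohort(n = 5000, arm = "control",
                        hr = c(dfs = 0.76, os = 0.76, dm = 0.75),
                        rr_cardiac = 5.33, seed = 12)
  gt <- generate_cohort(n = 5000, arm = "trastuzumab", seed = 12)
  expect_gt(sum(gc$event_death), sum(gt$event_death))
  expect_lt(mean(gc$cardiac_event_year1), mean(gt$cardiac_event_year1))
})

test_that("uncensored exponential means match 1/rate within CLT tolerance", {
  p <- 0.2
  rate <- rate_from_prob(p)
  g <- generate_cohort(true_probs = list(
    p_os = c(first = p, subsequent = p),
    p_dfs = c(first = 0.3, subsequent = 0.3),
    p_dm = c(first = 0.25, subsequent = 0.25),
    p_cardiac = 0), n = 1e5, censor_range = c(1e6, 1e6), seed = 21)
  expect_true(all(g$event_death))
  expect_lt(abs(mean(g$time_death) - 1 / rate), 3 * (1 / rate) / sqrt(1e5))
})

test_that("the exponential rate estimator handles hand-checkable strata", {
  # one patient, death at exactly one year: 1 event / 1 person-year
  one <- data.frame(time_death = 1, event_death = TRUE,
                    time_dfs_event = 1, event_dfs = FALSE,
                    time_dm = 1, event_dm = FALSE,
                    cardiac_event_year1 = FALSE)
  w <- testthat::capture_warnings(est <- estimate_inputs(one))
  expect_equal(unname(est$rates$os[["first"]]), 1)
  expect_true(is.na(est$rates$os[["subsequent"]]))  # no person-time there
  expect_true(any(grepl("subsequent", w)))  # flagged missing stratum

  # all censored at 0.5 with no events: rate and probability are zero
  cens <- data.frame(time_death = rep(0.5, 4), event_death = FALSE,
                     time_dfs_event = 0.5, event_dfs = FALSE,
                     time_dm = 0.5, event_dm = FALSE,
                     cardiac_event_year1 = FALSE)
  est2 <- suppressWarnings(estimate_inputs(cens))
  expect_equal(unname(est2$rates$os[["first"]]), 0)
  expect_equal(unname(est2$transitions$p_os[["first"]]), 0)
})

test_that("annual probabilities are recovered at cohort scale (n = 5000)", {
  truth <- list(p_os = c(first = 0.000, subsequent = 0.026),
                p_dfs = c(first = 0.016, subsequent = 0.054),
                p_dm = c(first = 0.003, subsequent = 0.041),
                p_cardiac = 0.125)
  g <- generate_cohort(true_probs = truth, n = 5000, seed = 404)
  est <- estimate_inputs(g)
  # the key subsequent-year distant-metastasis probability within +/- 0.006
  expect_lt(abs(est$transitions$p_dm[["subsequent"]] - 0.041), 0.006)
  expect_lt(abs(est$transitions$p_dfs[["subsequent"]] - 0.054), 0.008)
  expect_lt(abs(est$transitions$p_os[["subsequent"]] - 0.026), 0.006)
  expect_lt(abs(est$transitions$p_cardiac - 0.125), 3 *
              sqrt(0.125 * 0.875 / 5000))
  # cost table recovered: means within 3 standard errors at this n
  for (state in c("dfs", "lr", "dm")) {
    for (period in c("first", "subsequent")) {
      true_mean <- her2cea:::default_cost_model()[[state]][[period]]$mean
      est_c <- est$state_costs[[state]][[period]]
      expect_lt(abs(est_c$mean - true_mean), 3.5 * est_c$se)
    }
  }
})

test_that("generated event times scale exactly with the hazard time unit", {
  # flat hazards: with the same seed, dividing every rate by c multiplies
  # every latent event time by c, so probabilities per rescaled year match
  p <- list(p_os = c(first = 0.05, subsequent = 0.05),
            p_dfs = c(first = 0.1, subsequent = 0.1),
            p_dm = c(first = 0.08, subsequent = 0.08),
            p_cardiac = 0)
  r <- lapply(p[1:3], function(x) rate_from_prob(x[["first"]]))
  c_fac <- 2
  p_slow <- lapply(p[1:3], function(x) {
    v <- prob_from_rate(rate_from_prob(x) / c_fac)
    names(v) <- names(x); v
  })
  p_slow$p_cardiac <- 0
  g_fast <- generate_cohort(true_probs = p, n = 300,
                            censor_range = c(1e9, 1e9), seed = 55)
  g_slow <- generate_cohort(true_probs = p_slow, n = 300,
                            censor_range = c(1e9, 1e9), seed = 55)
  expect_equal(g_slow$time_death, g_fast$time_death * c_fac,
               tolerance = 1e-10)
  expect_equal(g_slow$time_dm, g_fast$time_dm * c_fac, tolerance = 1e-10)
})

test_that("full loop: generate -> estimate -> model converges to the direct-parameter CEA", {
  cfg <- her2cea_example_config("real_world")
  direct <- run_experiment(config = cfg)
  # a single cohort draw can be lucky at small n, so compare the mean
  # absolute error over replicates at each cohort size
  mean_err <- vapply(c(500, 5000, 50000), function(n) {
    errs <- vapply(1:4, function(r) {
      g <- generate_cohort(n = n, seed = 1000 * r + n)
      est <- estimate_inputs(g)
      cfg_hat <- estimates_to_config(est, base_config = cfg)
      ex <- run_experiment(config = cfg_hat)
      abs(ex$cea$delta_qaly - direct$cea$delta_qaly)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(mean_err[3], mean_err[1])  # Monte Carlo error shrinks with n
  expect_lt(mean_err[3], 0.05)         # and is small at n = 50,000
})
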