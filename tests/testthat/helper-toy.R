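# Shared builders for small, fully controlled parameter sets.

flat_life_table <- function(q = 0, ages = 0:109) {
  data.frame(age = ages, q = q)
}

# Uniform cost/utility model with flat background mortality; every argument
# overridable. Defaults: nothing happens (all probabilities zero).
toy_params <- function(arm = "trastuzumab",
                       p_os = c(first = 0, subsequent = 0),
                       p_dfs = c(first = 0, subsequent = 0),
                       p_dm = c(first = 0, subsequent = 0),
                       q = 0,
                       cost = 0, utility = 1,
                       discount_costs = 0, discount_effects = 0,
                       dm_mortality = "derived",
                       horizon = "lifetime", ...) {
  uc <- function(v) c(first = v, subsequent = v)
  model_parameters(
    arm = arm, p_os = p_os, p_dfs = p_dfs, p_dm = p_dm,
    state_costs = list(dfs = uc(cost), lr = uc(cost), dm = uc(cost)),
    utilities = list(dfs = uc(utility), lr = uc(utility), dm = uc(utility)),
    life_table = flat_life_table(q),
    discount_costs = discount_costs, discount_effects = discount_effects,
    dm_mortality = dm_mortality, horizon = horizon, ...)
}

# Economic outcomes assembled from bare totals, for quadrant tests.
outcome_of <- function(cost, qaly, ly = qaly) {
  economic_outcome(
    costs = c(trastuzumab = 0, cardiac = 0, dfs = cost, lr = 0, dm = 0),
    ly = c(dfs = ly, lr = 0, dm = 0),
    qaly = c(cardiac = 0, dfs = qaly, lr = 0, dm = 0))
}

# Independent 6x6 one-step matrix for toy chains whose states have at most
# one exit cause each (so no competing-risk overlap): hand-built, not via
# the engine.
toy_matrix <- function(p_dfs_to_dm, p_dm_death) {
  states <- c("dfs", "lr1", "lr2", "dm1", "dm2", "dead")
  P <- matrix(0, 6, 6, dimnames = list(states, states))
  P["dfs", "dfs"] <- 1 - p_dfs_to_dm
  P["dfs", "dm1"] <- p_dfs_to_dm
  P["dm1", "dm2"] <- 1 - p_dm_death
  P["dm1", "dead"] <- p_dm_death
  P["dm2", "dm2"] <- 1 - p_dm_death
  P["dm2", "dead"] <- p_dm_death
  P["lr1", "lr2"] <- 1
  P["lr2", "lr2"] <- 1
  P["dead", "dead"] <- 1
  P
}
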