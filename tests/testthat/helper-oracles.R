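# Independent oracles and shared fixtures for the test suite.

baseline <- hk2022_parameters()

# Brute-force frontier oracle: a strategy is off the frontier iff some other
# single strategy, or a convex mixture of two other strategies, is at least
# as effective and at least as cheap with one inequality strict.
brute_force_frontier <- function(cost, eff) {
  n <- length(cost)
  on <- rep(TRUE, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    # single-strategy (strong) dominance
    for (j in others) {
      if ((cost[j] < cost[i] && eff[j] >= eff[i]) ||
          (cost[j] <= cost[i] && eff[j] > eff[i])) { on[i] <- FALSE; break }
    }
    if (!on[i]) next
    # two-strategy mixtures (extended dominance)
    for (j in others) for (k in others) {
      if (j >= k || eff[j] == eff[k]) next
      lo <- min(eff[j], eff[k]); hi <- max(eff[j], eff[k])
      if (eff[i] < lo || eff[i] > hi) next
      w <- (eff[i] - eff[j]) / (eff[k] - eff[j])
      mix_cost <- cost[j] + w * (cost[k] - cost[j])
      if (mix_cost <= cost[i]) { on[i] <- FALSE; break }
    }
  }
  on
}

# Per-individual Monte Carlo oracle for the cohort engine: n children walk
# the severity ladder independently; returns occupancy fractions per cycle.
simulate_individuals <- function(spec, P, n = 10000) {
  n_states <- nrow(P)
  cycles <- spec$accrual_events
  state <- sample.int(n_states, n, replace = TRUE, prob = spec$start_distribution)
  occ <- matrix(0, cycles, n_states)
  occ[1, ] <- tabulate(state, n_states) / n
  for (t in 2:cycles) {
    u <- stats::runif(n)
    cum <- t(apply(P, 1, cumsum))
    state <- vapply(seq_len(n), function(i)
      which(u[i] <= cum[state[i], ])[1], 0L)
    occ[t, ] <- tabulate(state, n_states) / n
  }
  occ
}

# Tiny two/three-strategy parameter sets for engine tests.
make_strategy <- function(name, cost, effect, modality = "spectacle",
                          cost_range = c(cost * 0.5, cost * 1.5),
                          ser_ci = c(effect - 0.3, effect + 0.3),
                          lens_cost = 0, adverse_events = list(),
                          cost_distribution = "gamma",
                          effect_distribution = "normal") {
  strategy_parameters(
    name = name, annual_cost = cost, cost_range = cost_range,
    cost_distribution = cost_distribution,
    ser_effect = effect, ser_ci = ser_ci,
    al_effect_raw = -effect / 2,
    al_ci_raw = sort(c(-effect / 2 - 0.15, -effect / 2 + 0.15)),
    effect_distribution = effect_distribution,
    adverse_events = adverse_events,
    modality = modality, lens_cost = lens_cost
  )
}

make_pair <- function(ref_cost = 6000, trt_cost = 9000, trt_effect = 0.5) {
  strategies <- list(
    REF = make_strategy("REF", ref_cost, -0.81),
    TRT = make_strategy("TRT", trt_cost, trt_effect)
  )
  list(spec = model_spec(reference_strategy = "REF"), strategies = strategies)
}
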