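# Synthetic parameter tables with known ground truth ----------------------
#
# The generator emulates the statistical shape of the baseline parameter
# table - Gamma-distributed annual costs in the thousands-of-HK$ range,
# Normal annual effects of a fraction of a diopter, a reference strategy
# that progresses rather than benefits - so every pipeline stage can be
# tested against planted, verifiable structure.

#' Describe a synthetic parameter-table scenario
#'
#' @param seed integer seed; generation is deterministic given the scenario.
#' @param n_strategies number of strategies including the reference (>= 2).
#' @param cost_law list with `mean_range` (HK$/yr, bounds for strategy mean
#'   costs) and `cv` (coefficient of variation turned into a 95% range).
#' @param effect_law list with `mean_range` (D/yr, bounds for annual benefit
#'   means) and `sd` (half-width/1.96 of the 95% CI).
#' @param planted_structure `"random"`, `"planted_dominated"` (one strategy
#'   strictly costlier and less effective than another) or
#'   `"planted_frontier_chain"` (all strategies on the frontier with
#'   increasing sequential ICERs).
#' @return Object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1, n_strategies = 13,
                               cost_law = list(mean_range = c(5000, 20000), cv = 0.2),
                               effect_law = list(mean_range = c(-0.1, 0.6), sd = 0.15),
                               planted_structure = c("random", "planted_dominated",
                                                     "planted_frontier_chain")) {
  planted_structure <- match.arg(planted_structure)
  if (n_strategies < 2) validation_error("n_strategies", "need at least 2")
  if (any(cost_law$mean_range <= 0))
    validation_error("cost_law", "cost means must be positive")
  structure(list(seed = seed, n_strategies = n_strategies,
                 cost_law = cost_law, effect_law = effect_law,
                 planted_structure = planted_structure),
            class = "synthetic_scenario")
}

synth_strategy <- function(name, cost_mean, cv, eff_mean, eff_sd, modality = "spectacle") {
  half <- 1.96 * cv * cost_mean
  strategy_parameters(
    name = name, annual_cost = cost_mean,
    cost_range = c(max(0, cost_mean - half), cost_mean + half),
    cost_distribution = "gamma",
    ser_effect = eff_mean, ser_ci = c(eff_mean - 1.96 * eff_sd, eff_mean + 1.96 * eff_sd),
    al_effect_raw = -eff_mean / 2,
    al_ci_raw = sort(-c(eff_mean / 2 - 0.98 * eff_sd, eff_mean / 2 + 0.98 * eff_sd)),
    effect_distribution = "normal",
    modality = modality
  )
}

#' Generate a synthetic strategy set
#'
#' Produces a validated `(model_spec, strategies)` pair: strategy `"REF"` is
#' the reference with a negative annual effect (the untreated cohort's own
#' progression, mimicking the -0.81 D/yr comparator), the remaining
#' strategies draw cost and effect means from the scenario's laws, and the
#' planted structure is enforced by construction. AL effects are derived
#' from the SER effects at half magnitude so both outcomes are populated.
#'
#' @param scenario a [synthetic_scenario()].
#' @return As [load_parameters()]: list with `spec` and `strategies`.
#' @export
generate_strategy_set <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_strategies
  cl <- scenario$cost_law; el <- scenario$effect_law

  ref_eff <- -stats::runif(1, 0.6, 1.0)
  ref <- synth_strategy("REF",
                        cost_mean = stats::runif(1, cl$mean_range[1], cl$mean_range[2]),
                        cv = cl$cv, eff_mean = ref_eff, eff_sd = el$sd)

  k <- n - 1L
  cost_means <- stats::runif(k, cl$mean_range[1], cl$mean_range[2])
  eff_means <- stats::runif(k, el$mean_range[1], el$mean_range[2])

  if (scenario$planted_structure == "planted_dominated" && k >= 2L) {
    # strategy S2 strictly costlier and less effective than S1
    cost_means[2L] <- cost_means[1L] * 1.25
    eff_means[2L] <- eff_means[1L] - max(0.05, el$sd / 2)
  } else if (scenario$planted_structure == "planted_frontier_chain") {
    # strictly increasing effects; cost increments with strictly increasing
    # slopes, so every sequential ICER grows and no strategy leaves the hull
    gap <- max(0.05, diff(range(el$mean_range)) / k)
    eff_means <- el$mean_range[1] + cumsum(stats::runif(k, 0.02, gap))
    slopes <- cumsum(stats::runif(k - 1L, 2000, 8000))
    cost_means <- cl$mean_range[1] + c(0, cumsum(slopes * diff(eff_means)))
  }

  strategies <- c(list(ref), lapply(seq_len(k), function(i)
    synth_strategy(sprintf("S%02d", i), cost_means[i], cl$cv,
                   eff_means[i], el$sd,
                   modality = c("spectacle", "contact_lens", "drop")[1L + i %% 3L])))
  names(strategies) <- vapply(strategies, `[[`, "", "name")
  spec <- model_spec(reference_strategy = "REF",
                     reference_annual_change = abs(ref_eff))
  list(spec = spec, strategies = strategies)
}
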