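# Markov cohort engine ----------------------------------------------------
#
# Progression is driven by the SER axis: a cohort moves low -> moderate ->
# high and never back. The per-cycle probability of leaving a transient state
# is the net annual SER progression (D/yr) divided by the state's band width
# (D), optionally scaled by a per-category multiplier, capped at 1.

#' Net annual progression under treatment
#'
#' The untreated cohort progresses at `reference_annual_change` diopters per
#' year; treatment removes `treatment_effect` of that, floored at zero (a
#' treated cohort never progresses faster than the arithmetic allows, and
#' never regresses).
#'
#' @param reference_annual_change untreated annual SER change magnitude, D/yr.
#' @param treatment_effect annual benefit of the strategy, D/yr; may be
#'   negative (worse than the comparator).
#' @return Net progression rate in D/yr, >= 0. Vectorized.
#' @examples
#' net_progression_rate(0.81, 0.57) # 0.24
#' @export
net_progression_rate <- function(reference_annual_change, treatment_effect) {
  pmax(0, reference_annual_change - treatment_effect)
}

#' Transition-rule configuration
#'
#' The mapping from an annual progression rate to per-cycle transition
#' probabilities is configurable: each progression category can scale the
#' rate before it is divided by the state's band width. The default
#' multipliers of 1 make the rule purely geometric (rate / band width).
#' The rule is serialized into run manifests so alternative rules are
#' reproducible.
#'
#' @param slow,intermediate,rapid non-negative multipliers per category.
#' @return An object of class `transition_rule`.
#' @export
transition_rule <- function(slow = 1, intermediate = 1, rapid = 1) {
  m <- c(slow = slow, intermediate = intermediate, rapid = rapid)
  if (any(m < 0)) validation_error("transition_rule", "multipliers must be >= 0")
  structure(list(multipliers = m), class = "transition_rule")
}

#' Build the annual transition matrix for one progression rate
#'
#' Rows index the from-state, columns the to-state, ordered least to most
#' severe. Progression is irreversible (the lower triangle is zero) and only
#' single-step (a cohort cannot jump a band within one cycle under the
#' default rule). The last state is absorbing.
#'
#' @param rate net annual SER progression, D/yr, >= 0.
#' @param states ordered list of `state_definition`s.
#' @param rule a [transition_rule()].
#' @return A `transition_matrix`: square matrix with rows summing to 1.
#' @examples
#' build_transition_matrix(0.81)["low", "moderate"] # 0.324
#' @export
build_transition_matrix <- function(rate, states = default_states(),
                                    rule = transition_rule()) {
  if (rate < 0) stop("progression rate must be >= 0")
  n <- length(states)
  nm <- vapply(states, `[[`, "", "name")
  P <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) {
    st <- states[[i]]
    p <- min(1, rate * rule$multipliers[[st$progression_category]] / band_width(st))
    P[i, i + 1L] <- p
    P[i, i] <- 1 - p
  }
  P[n, n] <- 1
  validate_transition_matrix(P)
}

validate_transition_matrix <- function(P) {
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1")
  if (any(P[lower.tri(P)] != 0))
    stop("transition matrix must be upper-triangular (irreversible progression)")
  if (any(P < 0 | P > 1)) stop("transition probabilities must lie in [0, 1]")
  structure(P, class = c("transition_matrix", class(P)))
}

#' Expected annual adverse-event cost of a strategy
#'
#' Deterministic expectation: the sum over the profile of annual event
#' probability times unit cost. No sampling is involved.
#'
#' @param adverse_events list of lists with `probability` and `unit_cost`.
#' @return Expected HK$ per year.
#' @export
expected_adverse_event_cost <- function(adverse_events) {
  if (length(adverse_events) == 0L) return(0)
  sum(vapply(adverse_events, function(ae) ae$probability * ae$unit_cost, 0))
}

#' Total effect accrued over the horizon
#'
#' Effects accrue linearly and undiscounted: one annual effect per accrual
#' event (default 6 events, cycles 0 through 5 of the 5-year horizon).
#'
#' @param annual_effect benefit-positive annual effect.
#' @param accrual_events number of accrual events (>= 1).
#' @return `annual_effect * accrual_events`.
#' @examples
#' accrue_effect(0.57)  #  3.42
#' accrue_effect(-0.81) # -4.86
#' @export
accrue_effect <- function(annual_effect, accrual_events = 6) {
  if (any(accrual_events < 1)) stop("accrual_events must be >= 1")
  annual_effect * accrual_events
}

#' Effective treatment effect driving progression
#'
#' The reference strategy's stored SER value is the untreated annual change
#' itself (a benefit of -0.81 relative to no progression), not a reduction of
#' it, so for progression purposes the reference receives a treatment effect
#' of 0; every other strategy's SER benefit reduces the reference change.
#' @keywords internal
progression_effect <- function(strategy, spec, ser_override = NULL) {
  if (identical(strategy$name, spec$reference_strategy)) return(0)
  eff <- if (is.null(ser_override)) strategy$ser_effect else ser_override
  if (is.na(eff)) 0 else eff
}

#' Propagate one strategy's cohort through the model
#'
#' Starting from the configured state distribution, the cohort is pushed
#' through `horizon_years` annual transitions. Costs accrue at each of the
#' `accrual_events` cycles (0 through `horizon_years` by default): the annual
#' cost plus the expected adverse-event cost, discounted at the cost rate,
#' plus a lens-replacement surcharge (spectacle and contact-lens modalities
#' only) on the expected fraction newly entering the high-myopia state that
#' cycle. Effects accrue via [accrue_effect()] and are not discounted by
#' default.
#'
#' @param spec a `model_spec`.
#' @param strategy a `strategy_parameters`.
#' @param rule a [transition_rule()].
#' @param cost_override,ser_override,al_override optional replacements for
#'   the strategy's annual cost and annual effects, used by the sensitivity
#'   analyses. Overrides of the SER effect also drive progression (except for
#'   the reference strategy, which always progresses at the untreated rate).
#' @return An object of class `cohort_trace` with elements `occupancy`
#'   (matrix, one row per cycle), `accrued_cost` (discounted HK$),
#'   `accrued_effect_ser` and `accrued_effect_al` (benefit-positive),
#'   `lens_replacement_events` (expected per-capita count) and `strategy`.
#' @export
run_cohort <- function(spec, strategy, rule = transition_rule(),
                       cost_override = NULL, ser_override = NULL,
                       al_override = NULL) {
  ref <- spec$reference_strategy
  ref_change <- abs(spec$reference_annual_change %||% 0.81)
  annual_cost <- cost_override %||% strategy$annual_cost
  ser_eff <- ser_override %||% strategy$ser_effect
  al_raw <- al_override %||% strategy$al_effect_raw

  rate <- net_progression_rate(ref_change, progression_effect(strategy, spec, ser_override))
  P <- build_transition_matrix(rate, spec$states, rule)

  n_states <- length(spec$states)
  nm <- vapply(spec$states, `[[`, "", "name")
  n_cycles <- spec$accrual_events           # accrual cycles 0 .. accrual_events-1
  occ <- matrix(NA_real_, n_cycles, n_states,
                dimnames = list(cycle = seq_len(n_cycles) - 1L, state = nm))
  occ[1L, ] <- spec$start_distribution
  for (t in seq_len(n_cycles - 1L)) occ[t + 1L, ] <- occ[t, , drop = TRUE] %*% P

  cycles <- seq_len(n_cycles) - 1L
  df_cost <- discount_factor(spec$discount_rate_costs, cycles)
  ae_cost <- expected_adverse_event_cost(strategy$adverse_events)

  new_high <- c(0, pmax(0, diff(occ[, n_states])))
  surcharge <- if (strategy$modality %in% c("spectacle", "contact_lens"))
    strategy$lens_cost else 0

  accrued_cost <- sum((annual_cost + ae_cost) * df_cost) +
    sum(new_high * surcharge * df_cost)

  df_eff <- discount_factor(spec$discount_rate_effects, cycles)
  eff_ser <- if (is.na(ser_eff)) NA_real_ else sum(ser_eff * df_eff)
  eff_al <- if (is.na(al_raw)) NA_real_ else sum(-al_raw * df_eff)

  structure(list(
    occupancy = occ,
    accrued_cost = accrued_cost,
    accrued_effect_ser = eff_ser,
    accrued_effect_al = eff_al,
    lens_replacement_events = sum(new_high),
    strategy = strategy$name
  ), class = "cohort_trace")
}

#' Tidy per-cycle view of a cohort trace
#'
#' @param x a `cohort_trace`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return Long data frame with columns `strategy`, `cycle`, `state`,
#'   `occupancy`.
#' @export
as.data.frame.cohort_trace <- function(x, row.names = NULL, optional = FALSE, ...) {
  occ <- x$occupancy
  data.frame(
    strategy = x$strategy,
    cycle = rep(as.integer(rownames(occ)), times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    occupancy = as.vector(occ),
    stringsAsFactors = FALSE
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> %s: cost HK$%.0f, E_ser %.2f D, E_al %.2f mm\n",
              x$strategy, x$accrued_cost, x$accrued_effect_ser,
              x$accrued_effect_al))
  print(round(x$occupancy, 4))
  invisible(x)
}
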