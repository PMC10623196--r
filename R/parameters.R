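# Parameter schema, validation and I/O -----------------------------------
#
# All money is stored in Hong Kong dollars (HK$); US$ is a presentation-layer
# conversion.  Annual treatment effects follow a benefit-positive convention:
# spherical-equivalent (SER) effects are stored as printed (positive = less
# progression than the untreated comparator), axial-length (AL) effects are
# stored raw (negative = slowed elongation) and negated by annual_benefit().

#' Signal a parameter-validation failure
#'
#' All schema violations raise a condition of class
#' `myopiacea_validation_error` whose message names the offending field, so
#' callers (and the command-line wrapper) can distinguish bad input from
#' runtime failures.
#'
#' @param field name of the offending field.
#' @param msg human-readable description of the violation.
#' @keywords internal
validation_error <- function(field, msg) {
  stop(structure(
    class = c("myopiacea_validation_error", "error", "condition"),
    list(message = sprintf("invalid parameter `%s`: %s", field, msg),
         call = sys.call(-1), field = field)
  ))
}

#' Define one myopia severity state
#'
#' States partition the spherical-equivalent (SER) axis.  The conventional
#' bands are low myopia (-0.50 to -3.00 D, width 2.5 D), moderate myopia
#' (-3.00 to -6.00 D, width 3.0 D) and high myopia (-6.00 D and beyond).
#' Each state carries the progression category observed for children in that
#' band: slow (< 0.5 D/yr), intermediate (0.5-0.99 D/yr) or rapid
#' (>= 1.0 D/yr).
#'
#' @param name one of `"low"`, `"moderate"`, `"high"`.
#' @param ser_lower,ser_upper SER band boundaries in diopters
#'   (`ser_lower < ser_upper`; more negative = more myopic). The high state is
#'   open below (`ser_lower = -Inf`).
#' @param progression_category one of `"slow"`, `"intermediate"`, `"rapid"`.
#' @return An object of class `state_definition`.
#' @export
state_definition <- function(name, ser_lower, ser_upper, progression_category) {
  name <- match.arg(name, c("low", "moderate", "high"))
  progression_category <- match.arg(progression_category,
                                    c("slow", "intermediate", "rapid"))
  if (!is.numeric(ser_lower) || !is.numeric(ser_upper) || ser_lower >= ser_upper)
    validation_error("ser_lower/ser_upper", "band must satisfy lower < upper")
  structure(list(name = name, ser_lower = ser_lower, ser_upper = ser_upper,
                 progression_category = progression_category),
            class = "state_definition")
}

#' Default three-state severity ladder
#'
#' @return List of three `state_definition` objects (low, moderate, high),
#'   with band widths 2.5 D and 3.0 D for the two transient states.
#' @export
default_states <- function() {
  list(
    state_definition("low",      -3.00, -0.50, "slow"),
    state_definition("moderate", -6.00, -3.00, "intermediate"),
    state_definition("high",     -Inf,  -6.00, "rapid")
  )
}

#' Width of a state's SER band in diopters
#' @keywords internal
band_width <- function(state) state$ser_upper - state$ser_lower

#' Construct one intervention strategy's parameter set
#'
#' Mirrors one row block of the published Hong Kong 2022 parameter table:
#' total annual cost with its sensitivity range and sampling distribution,
#' annual SER effect (D/yr, benefit-positive) with 95% CI, annual AL effect
#' (mm/yr, raw sign: negative = slowed elongation) with 95% CI, and an
#' adverse-event profile of (label, annual probability, unit cost) triples.
#'
#' @param name unique strategy label.
#' @param annual_cost total annual cost, HK$/yr (direct plus indirect).
#' @param cost_range length-2 numeric `(min, max)` HK$/yr used for
#'   sensitivity analysis.
#' @param cost_distribution `"gamma"` or `"fixed"`.
#' @param ser_effect annual SER effect, D/yr, benefit-positive; `NA` when the
#'   strategy has no SER evidence (e.g. orthokeratology).
#' @param ser_ci length-2 `(low, high)` 95% CI for `ser_effect`.
#' @param al_effect_raw annual AL effect, mm/yr, as conventionally reported
#'   (negative = slowed elongation = benefit).
#' @param al_ci_raw length-2 `(low, high)` 95% CI for `al_effect_raw`.
#' @param effect_distribution `"normal"` or `"fixed"`.
#' @param adverse_events list of lists with fields `event`, `probability`
#'   (annual), `unit_cost` (HK$). May be empty.
#' @param modality delivery modality, one of `"spectacle"`, `"contact_lens"`,
#'   `"drop"`, `"behavior"`, `"light_therapy"`. Drives the lens-replacement
#'   surcharge on progression to high myopia.
#' @param lens_cost HK$ cost of the spectacle/lens component, charged once
#'   (per expected entrant) when a wearer progresses to high myopia and the
#'   lenses must be replaced. Only used for spectacle and contact-lens
#'   modalities; defaults to 0 when the published total already bundles
#'   replacement.
#' @return An object of class `strategy_parameters`.
#' @export
strategy_parameters <- function(name, annual_cost, cost_range,
                                cost_distribution = c("gamma", "fixed"),
                                ser_effect = NA_real_, ser_ci = c(NA_real_, NA_real_),
                                al_effect_raw = NA_real_, al_ci_raw = c(NA_real_, NA_real_),
                                effect_distribution = c("normal", "fixed"),
                                adverse_events = list(),
                                modality = c("spectacle", "contact_lens", "drop",
                                             "behavior", "light_therapy"),
                                lens_cost = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    validation_error("name", "must be a non-empty string")
  if (length(cost_distribution) == 1L &&
      !cost_distribution %in% c("gamma", "fixed"))
    validation_error("cost_distribution",
                     sprintf("unknown distribution family '%s'", cost_distribution))
  if (length(effect_distribution) == 1L &&
      !effect_distribution %in% c("normal", "fixed"))
    validation_error("effect_distribution",
                     sprintf("unknown distribution family '%s'", effect_distribution))
  cost_distribution <- match.arg(cost_distribution)
  effect_distribution <- match.arg(effect_distribution)
  modality <- match.arg(modality)

  if (!is.numeric(annual_cost) || length(annual_cost) != 1L || annual_cost < 0)
    validation_error("annual_cost", "must be a single non-negative number")
  if (length(cost_range) != 2L || anyNA(cost_range) || cost_range[1] > cost_range[2])
    validation_error("cost_range", "must be an ordered (min, max) pair")
  if (annual_cost < cost_range[1] || annual_cost > cost_range[2])
    validation_error("annual_cost",
                     sprintf("%.6g outside cost_range [%.6g, %.6g]",
                             annual_cost, cost_range[1], cost_range[2]))
  check_ci <- function(point, ci, field) {
    if (is.na(point)) return(invisible())
    if (length(ci) != 2L || anyNA(ci) || ci[1] > ci[2])
      validation_error(field, "CI must be an ordered (low, high) pair")
    if (point < ci[1] || point > ci[2])
      validation_error(field, sprintf("point %.6g outside CI [%.6g, %.6g]",
                                      point, ci[1], ci[2]))
  }
  check_ci(ser_effect, ser_ci, "ser_ci")
  check_ci(al_effect_raw, al_ci_raw, "al_ci_raw")
  for (ae in adverse_events) {
    if (!all(c("event", "probability", "unit_cost") %in% names(ae)))
      validation_error("adverse_events",
                       "each entry needs event, probability, unit_cost")
    if (ae$probability < 0 || ae$probability > 1)
      validation_error("adverse_events",
                       sprintf("probability %.6g of '%s' outside [0, 1]",
                               ae$probability, ae$event))
    if (ae$unit_cost < 0)
      validation_error("adverse_events", "unit costs must be non-negative")
  }
  if (!is.numeric(lens_cost) || lens_cost < 0)
    validation_error("lens_cost", "must be non-negative")

  structure(list(
    name = name, annual_cost = annual_cost,
    cost_range = as.numeric(cost_range), cost_distribution = cost_distribution,
    ser_effect = as.numeric(ser_effect), ser_ci = as.numeric(ser_ci),
    al_effect_raw = as.numeric(al_effect_raw), al_ci_raw = as.numeric(al_ci_raw),
    effect_distribution = effect_distribution,
    adverse_events = adverse_events, modality = modality,
    lens_cost = as.numeric(lens_cost)
  ), class = "strategy_parameters")
}

#' Construct the model settings
#'
#' @param states ordered list of `state_definition`s (least to most severe).
#' @param start_distribution named numeric vector of starting state
#'   occupancies; must sum to 1.
#' @param horizon_years model horizon in years (default 5).
#' @param accrual_events number of annual cost/effect accrual events over the
#'   horizon; default 6, i.e. cycles 0 through `horizon_years` inclusive.
#' @param discount_rate_costs annual discount rate applied to costs
#'   (default 0.03).
#' @param discount_rate_effects annual discount rate applied to effects
#'   (default 0: effects are accrued undiscounted).
#' @param exchange_rate HK$ per US$ (default 7.85, the 2022 peg).
#' @param reference_strategy label of the comparator (default `"SVLs"`,
#'   single-vision lenses).
#' @param reference_annual_change untreated annual SER progression magnitude
#'   in D/yr (default 0.81, the placebo-arm estimate); treatment effects are
#'   subtracted from this to obtain each strategy's net progression rate.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(states = default_states(),
                       start_distribution = c(low = 0.70, moderate = 0.25, high = 0.05),
                       horizon_years = 5, accrual_events = 6,
                       discount_rate_costs = 0.03, discount_rate_effects = 0.0,
                       exchange_rate = 7.85, reference_strategy = "SVLs",
                       reference_annual_change = 0.81) {
  if (!is.list(states) || !all(vapply(states, inherits, TRUE, "state_definition")))
    validation_error("states", "must be a list of state_definition objects")
  nm <- vapply(states, `[[`, "", "name")
  if (anyDuplicated(nm)) validation_error("states", "duplicate state names")
  for (i in seq_len(length(states) - 1L)) {
    if (abs(states[[i + 1L]]$ser_upper - states[[i]]$ser_lower) > 1e-9)
      validation_error("states", "bands must be contiguous and non-overlapping")
  }
  sd <- start_distribution[nm]
  if (anyNA(sd))
    validation_error("start_distribution", "must name every state")
  if (any(sd < 0) || abs(sum(sd) - 1) > 1e-9)
    validation_error("start_distribution",
                     sprintf("must be non-negative and sum to 1 (got %.10g)", sum(sd)))
  for (r in c(discount_rate_costs, discount_rate_effects))
    if (r < 0 || r >= 1)
      validation_error("discount_rate", "rates must lie in [0, 1)")
  if (exchange_rate <= 0)
    validation_error("exchange_rate", "must be positive")
  if (accrual_events < 1)
    validation_error("accrual_events", "need at least one accrual event")
  if (reference_annual_change < 0)
    validation_error("reference_annual_change", "must be >= 0")
  structure(list(
    states = states, start_distribution = sd,
    horizon_years = horizon_years, accrual_events = accrual_events,
    discount_rate_costs = discount_rate_costs,
    discount_rate_effects = discount_rate_effects,
    exchange_rate = exchange_rate, reference_strategy = reference_strategy,
    reference_annual_change = reference_annual_change
  ), class = "model_spec")
}

#' Benefit-positive annual effect of a strategy
#'
#' SER effects are benefit-positive as stored. AL effects are reported raw
#' (negative = slowed elongation), so the benefit is the negated raw value:
#' a raw AL effect of -0.30 mm/yr is a benefit of +0.30 mm/yr of avoided
#' elongation, while the untreated comparator's raw +0.41 mm/yr elongation is
#' a benefit of -0.41. This single accessor is the only place the sign flip
#' happens.
#'
#' @param strategy a `strategy_parameters` object.
#' @param outcome `"ser"` or `"al"`.
#' @return Annual benefit (D/yr or mm/yr); `NA` if the strategy has no
#'   evidence for the outcome.
#' @export
annual_benefit <- function(strategy, outcome = c("ser", "al")) {
  outcome <- match.arg(outcome)
  if (outcome == "ser") strategy$ser_effect else -strategy$al_effect_raw
}

#' 95% CI of the benefit-positive annual effect
#' @inheritParams annual_benefit
#' @return Ordered `(low, high)` CI on the benefit scale.
#' @export
annual_benefit_ci <- function(strategy, outcome = c("ser", "al")) {
  outcome <- match.arg(outcome)
  if (outcome == "ser") strategy$ser_ci else sort(-strategy$al_ci_raw)
}

#' Strategies with evidence for an outcome
#'
#' Drops strategies whose annual effect for `outcome` is `NA` (orthokeratology
#' has no SER estimate, so SER analyses run on 12 of the 13 strategies).
#'
#' @param strategies list of `strategy_parameters`.
#' @param outcome `"ser"` or `"al"`.
#' @return Filtered list.
#' @export
strategies_for_outcome <- function(strategies, outcome = c("ser", "al")) {
  outcome <- match.arg(outcome)
  keep <- !vapply(strategies, function(s) is.na(annual_benefit(s, outcome)), TRUE)
  strategies[keep]
}

# I/O ---------------------------------------------------------------------

strategy_to_list <- function(s) {
  list(name = s$name, modality = s$modality,
       annual_cost = s$annual_cost, cost_range = s$cost_range,
       cost_distribution = s$cost_distribution,
       ser_effect = s$ser_effect, ser_ci = s$ser_ci,
       al_effect_raw = s$al_effect_raw, al_ci_raw = s$al_ci_raw,
       effect_distribution = s$effect_distribution,
       lens_cost = s$lens_cost,
       adverse_events = s$adverse_events)
}

#' Load a model configuration from a YAML document
#'
#' The document has a `model` block (states, start distribution, horizon,
#' discount rates, exchange rate, reference strategy) and a `strategies`
#' list, one block per intervention. Every invariant of
#' [strategy_parameters()] and [model_spec()] is enforced on load; a missing
#' reference strategy, an out-of-range baseline cost, a reversed CI or an
#' unknown distribution family each raise a `myopiacea_validation_error`
#' naming the offending field.
#'
#' @param path path to the YAML configuration.
#' @return A list with elements `spec` (a `model_spec`) and `strategies`
#'   (named list of `strategy_parameters`).
#' @seealso [write_parameters()] for the inverse, [hk2022_parameters()] for
#'   the packaged baseline configuration.
#' @export
load_parameters <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$strategies) || length(doc$strategies) < 2L)
    validation_error("strategies", "need at least two strategies")
  m <- doc$model %||% list()
  states <- if (is.null(m$states)) default_states() else
    lapply(m$states, function(st)
      state_definition(st$name,
                       if (is.character(st$ser_lower)) -Inf else st$ser_lower,
                       st$ser_upper, st$progression_category))
  spec <- model_spec(
    states = states,
    start_distribution = unlist(m$start_distribution %||%
                                  c(low = 0.70, moderate = 0.25, high = 0.05)),
    horizon_years = m$horizon_years %||% 5,
    accrual_events = m$accrual_events %||% 6,
    discount_rate_costs = m$discount_rate_costs %||% 0.03,
    discount_rate_effects = m$discount_rate_effects %||% 0.0,
    exchange_rate = m$exchange_rate %||% 7.85,
    reference_strategy = m$reference_strategy %||% "SVLs",
    reference_annual_change = m$reference_annual_change %||% 0.81
  )
  strategies <- lapply(doc$strategies, function(b) {
    strategy_parameters(
      name = b$name, annual_cost = b$annual_cost,
      cost_range = unlist(b$cost_range),
      cost_distribution = b$cost_distribution %||% "gamma",
      ser_effect = b$ser_effect %||% NA_real_,
      ser_ci = unlist(b$ser_ci %||% c(NA_real_, NA_real_)),
      al_effect_raw = b$al_effect_raw %||% NA_real_,
      al_ci_raw = unlist(b$al_ci_raw %||% c(NA_real_, NA_real_)),
      effect_distribution = b$effect_distribution %||% "normal",
      adverse_events = b$adverse_events %||% list(),
      modality = b$modality %||% "spectacle",
      lens_cost = b$lens_cost %||% 0
    )
  })
  names(strategies) <- vapply(strategies, `[[`, "", "name")
  if (anyDuplicated(names(strategies)))
    validation_error("strategies", "strategy names must be unique")
  if (!spec$reference_strategy %in% names(strategies))
    validation_error("reference_strategy",
                     sprintf("reference strategy '%s' not found among strategies",
                             spec$reference_strategy))
  list(spec = spec, strategies = strategies)
}

#' Write a model configuration back to YAML
#'
#' Inverse of [load_parameters()]: reloading the written file yields
#' identical objects.
#'
#' @param params list with `spec` and `strategies` as returned by
#'   [load_parameters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  spec <- params$spec
  doc <- list(
    model = list(
      states = lapply(spec$states, function(st)
        list(name = st$name,
             ser_lower = if (is.infinite(st$ser_lower)) "-Inf" else st$ser_lower,
             ser_upper = st$ser_upper,
             progression_category = st$progression_category)),
      start_distribution = as.list(spec$start_distribution),
      horizon_years = spec$horizon_years,
      accrual_events = spec$accrual_events,
      discount_rate_costs = spec$discount_rate_costs,
      discount_rate_effects = spec$discount_rate_effects,
      exchange_rate = spec$exchange_rate,
      reference_strategy = spec$reference_strategy,
      reference_annual_change = spec$reference_annual_change
    ),
    strategies = unname(lapply(params$strategies, strategy_to_list))
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Convert Hong Kong dollars to US dollars
#'
#' Linear conversion at the configured peg; rounding is left to the caller's
#' presentation layer.
#'
#' @param amount amount(s) in HK$.
#' @param exchange_rate HK$ per US$ (default 7.85).
#' @return Amount(s) in US$.
#' @examples
#' hkd_to_usd(7850) # 1000
#' @export
hkd_to_usd <- function(amount, exchange_rate = 7.85) {
  if (exchange_rate <= 0) validation_error("exchange_rate", "must be positive")
  amount / exchange_rate
}

#' Per-cycle discount factor
#'
#' `(1 + rate)^-cycle`: cycle 0 is undiscounted, and with rate 0 every cycle
#' weighs 1.
#'
#' @param rate annual discount rate (>= 0).
#' @param cycle integer cycle index (vectorized, each >= 0).
#' @return Discount factor(s) in (0, 1].
#' @examples
#' discount_factor(0.03, 0:5)
#' @export
discount_factor <- function(rate, cycle) {
  if (any(rate < 0)) validation_error("rate", "discount rate must be >= 0")
  if (any(cycle < 0)) stop("cycle index must be >= 0")
  (1 + rate)^(-cycle)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.strategy_parameters <- function(x, ...) {
  cat(sprintf("<strategy> %s [%s]\n", x$name, x$modality))
  cat(sprintf("  annual cost HK$%.0f (range %.0f-%.0f, %s)\n",
              x$annual_cost, x$cost_range[1], x$cost_range[2],
              x$cost_distribution))
  cat(sprintf("  SER effect %.2f D/yr (CI %.2f, %.2f); AL raw %.2f mm/yr (CI %.2f, %.2f)\n",
              x$ser_effect, x$ser_ci[1], x$ser_ci[2],
              x$al_effect_raw, x$al_ci_raw[1], x$al_ci_raw[2]))
  invisible(x)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %d states, horizon %d y, %d accrual events\n",
              length(x$states), x$horizon_years, x$accrual_events))
  cat(sprintf("  discount: costs %.1f%%, effects %.1f%%; HK$%.2f/US$; reference '%s'\n",
              100 * x$discount_rate_costs, 100 * x$discount_rate_effects,
              x$exchange_rate, x$reference_strategy))
  invisible(x)
}
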