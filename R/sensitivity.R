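# Deterministic and probabilistic sensitivity analysis --------------------

#' Fit a Gamma distribution to a mean and sensitivity range
#'
#' The published cost ranges carry no explicit uncertainty statement; they
#' are interpreted as central 95% intervals, so the standard deviation is
#' `(max - min) / 3.92` and the Gamma is moment-matched: shape = mean^2/SD^2,
#' scale = SD^2/mean. The fitted distribution reproduces the input mean
#' exactly. A degenerate range collapses to a point mass at the mean.
#'
#' @param mean mean cost (> 0).
#' @param range length-2 `(min, max)`, `max >= min >= 0`, mean inside.
#' @return List with `family` (`"gamma"` or `"fixed"`), `shape`, `scale`,
#'   `mean`, `sd`.
#' @examples
#' fit_gamma_from_range(8415, c(5055, 13376))
#' @export
fit_gamma_from_range <- function(mean, range) {
  if (mean <= 0) validation_error("mean", "must be positive")
  if (length(range) != 2L || range[1] > range[2] || range[1] < 0)
    validation_error("range", "must be an ordered non-negative (min, max) pair")
  if (mean < range[1] || mean > range[2])
    validation_error("mean", "must lie inside the range")
  sd <- (range[2] - range[1]) / 3.92
  if (sd == 0)
    return(list(family = "fixed", shape = NA_real_, scale = NA_real_,
                mean = mean, sd = 0))
  list(family = "gamma", shape = mean^2 / sd^2, scale = sd^2 / mean,
       mean = mean, sd = sd)
}

#' Fit a Normal distribution to a mean and 95% CI
#'
#' SD = `(high - low) / 3.92`. Draws are deliberately not truncated: several
#' published effect CIs cross zero and a negative drawn benefit (treatment
#' worse than the comparator) is meaningful.
#'
#' @param mean point estimate.
#' @param ci length-2 `(low, high)` 95% CI containing the mean.
#' @return List with `family` (`"normal"` or `"fixed"`), `mean`, `sd`.
#' @examples
#' fit_normal_from_ci(0.57, c(0.28, 0.86)) # sd 0.1479592
#' @export
fit_normal_from_ci <- function(mean, ci) {
  if (length(ci) != 2L || anyNA(ci) || ci[1] > ci[2])
    validation_error("ci", "must be an ordered (low, high) pair")
  if (mean < ci[1] || mean > ci[2])
    validation_error("mean", "must lie inside the CI")
  sd <- (ci[2] - ci[1]) / 3.92
  list(family = if (sd == 0) "fixed" else "normal", mean = mean, sd = sd)
}

draw_cost <- function(strategy, n) {
  if (strategy$cost_distribution == "fixed" ||
      diff(strategy$cost_range) == 0)
    return(rep(strategy$annual_cost, n))
  fit <- fit_gamma_from_range(strategy$annual_cost, strategy$cost_range)
  if (fit$family == "fixed") rep(fit$mean, n)
  else stats::rgamma(n, shape = fit$shape, scale = fit$scale)
}

draw_effect <- function(strategy, outcome, n) {
  mean <- annual_benefit(strategy, outcome)
  ci <- annual_benefit_ci(strategy, outcome)
  if (strategy$effect_distribution == "fixed") return(rep(mean, n))
  fit <- fit_normal_from_ci(mean, ci)
  if (fit$family == "fixed") rep(fit$mean, n)
  else stats::rnorm(n, mean = fit$mean, sd = fit$sd)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over the parameter distributions: per iteration, every
#' strategy's annual cost (Gamma, moment-matched to its range) and annual
#' effect (Normal from its CI) are drawn independently, the cohort engine is
#' run with the drawn values, and the total cost and accrued effectiveness
#' are recorded. For the SER outcome the drawn effect also drives the
#' progression rate; for the AL outcome progression keeps the base-case SER
#' rates (the axial effect has no band structure of its own). The reference
#' strategy always progresses at the untreated rate. Fully reproducible given
#' the seed.
#'
#' @param spec a `model_spec`.
#' @param strategies named list of `strategy_parameters`.
#' @param outcome `"ser"` or `"al"`; strategies without evidence for the
#'   outcome are dropped.
#' @param iterations number of Monte Carlo iterations (default 1000).
#' @param seed integer RNG seed.
#' @param rule a [transition_rule()].
#' @return Object of class `psa_result`: list with `samples` (data frame
#'   `iteration`, `strategy`, `drawn_cost`, `drawn_effect`, `total_cost`,
#'   `effectiveness`), `outcome`, `iterations`, `seed`.
#' @export
run_psa <- function(spec, strategies, outcome = c("ser", "al"),
                    iterations = 1000, seed = 1, rule = transition_rule()) {
  outcome <- match.arg(outcome)
  if (iterations < 1) stop("iterations must be >= 1")
  strategies <- strategies_for_outcome(strategies, outcome)
  set.seed(seed)

  blocks <- lapply(strategies, function(s) {
    costs <- draw_cost(s, iterations)
    effects <- draw_effect(s, outcome, iterations)
    tc <- numeric(iterations); ef <- numeric(iterations)
    for (i in seq_len(iterations)) {
      tr <- if (outcome == "ser")
        run_cohort(spec, s, rule, cost_override = costs[i],
                   ser_override = effects[i])
      else
        run_cohort(spec, s, rule, cost_override = costs[i],
                   al_override = -effects[i])
      tc[i] <- tr$accrued_cost
      ef[i] <- if (outcome == "ser") tr$accrued_effect_ser else tr$accrued_effect_al
    }
    data.frame(iteration = seq_len(iterations), strategy = s$name,
               drawn_cost = costs, drawn_effect = effects,
               total_cost = tc, effectiveness = ef,
               stringsAsFactors = FALSE)
  })
  structure(list(samples = do.call(rbind, c(blocks, make.row.names = FALSE)),
                 outcome = outcome, iterations = iterations, seed = seed),
            class = "psa_result")
}

#' Default willingness-to-pay grid
#'
#' HK$0 to HK$78,500 per unit of benefit in steps of HK$3,925 - i.e. US$0 to
#' US$10,000 in US$500 steps at the HK$7.85 peg.
#'
#' @param wtp_max,wtp_step grid limit and step in HK$.
#' @return Numeric vector of thresholds.
#' @export
default_wtp_grid <- function(wtp_max = 78500, wtp_step = 3925) {
  seq(0, wtp_max, by = wtp_step)
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay threshold, each strategy's acceptability is the
#' fraction of PSA iterations in which it attains the maximal net monetary
#' benefit. Ties are broken deterministically: lower total cost first, then
#' lexicographic label. Probabilities across strategies sum to 1 at every
#' threshold by construction.
#'
#' @param psa a `psa_result`.
#' @param wtp_grid vector of thresholds (>= 0), default [default_wtp_grid()].
#' @return Data frame of class `ceac` with columns `lambda`, `strategy`,
#'   `probability`.
#' @export
ceac <- function(psa, wtp_grid = default_wtp_grid()) {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) == 0L || any(wtp_grid < 0))
    validation_error("wtp_grid", "thresholds must be a non-empty set of values >= 0")
  s <- psa$samples
  labs <- sort(unique(s$strategy))
  ord <- order(s$iteration, s$strategy)
  s <- s[ord, ]
  tc <- matrix(s$total_cost, nrow = psa$iterations, byrow = TRUE,
               dimnames = list(NULL, labs))
  ef <- matrix(s$effectiveness, nrow = psa$iterations, byrow = TRUE,
               dimnames = list(NULL, labs))
  res <- lapply(wtp_grid, function(lambda) {
    nmb <- lambda * ef - tc
    win <- vapply(seq_len(nrow(nmb)), function(i) {
      v <- nmb[i, ]
      best <- which(v == max(v))
      if (length(best) > 1L) best <- best[order(tc[i, best], labs[best])][1L]
      best
    }, 0L)
    p <- tabulate(win, nbins = length(labs)) / psa$iterations
    data.frame(lambda = lambda, strategy = labs, probability = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  class(out) <- c("ceac", class(out))
  out
}

#' Modal (optimal) strategy at each willingness-to-pay threshold
#'
#' @param curves a `ceac` data frame.
#' @return Data frame `lambda`, `strategy` (highest acceptability; ties by
#'   label).
#' @export
optimal_strategy <- function(curves) {
  do.call(rbind, lapply(split(curves, curves$lambda), function(d) {
    d <- d[order(-d$probability, d$strategy), ]
    data.frame(lambda = d$lambda[1L], strategy = d$strategy[1L],
               probability = d$probability[1L], stringsAsFactors = FALSE)
  }))
}

# -- deterministic (one-way) sensitivity analysis -------------------------

apply_param <- function(spec, strategies, param, value) {
  if (param == "discount_rate") {
    spec$discount_rate_costs <- value
    return(list(spec = spec, strategies = strategies))
  }
  parts <- strsplit(param, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !parts[1L] %in% c("cost", "ser", "al"))
    validation_error("param",
                     sprintf("unknown parameter identifier '%s'", param))
  who <- parts[2L]
  if (!who %in% names(strategies))
    validation_error("param", sprintf("unknown strategy '%s'", who))
  s <- strategies[[who]]
  if (parts[1L] == "cost") {
    s$annual_cost <- value
    s$cost_range <- range(c(s$cost_range, value))
  } else if (parts[1L] == "ser") {
    s$ser_effect <- value
    s$ser_ci <- range(c(s$ser_ci, value))
  } else {
    s$al_effect_raw <- value
    s$al_ci_raw <- range(c(s$al_ci_raw, value))
  }
  strategies[[who]] <- s
  list(spec = spec, strategies = strategies)
}

#' One-way deterministic sensitivity analysis
#'
#' Reruns the base case with a single parameter pinned to each end of its
#' sensitivity range, all else fixed, and reports both incremental tables
#' and the per-strategy ICER spread `|ICER_high - ICER_low|`.
#'
#' Parameter identifiers: `"cost:<strategy>"` (annual cost, HK$),
#' `"ser:<strategy>"` / `"al:<strategy>"` (annual effect, stored sign) and
#' `"discount_rate"`.
#'
#' @param spec a `model_spec`.
#' @param strategies named list of `strategy_parameters`.
#' @param param parameter identifier.
#' @param range length-2 `(low, high)` bounds for the parameter.
#' @param outcome `"ser"` or `"al"`.
#' @param rule a [transition_rule()].
#' @return List with `param`, `range`, `low`/`high` (incremental tables) and
#'   `spread` (data frame `strategy`, `icer_low`, `icer_high`, `spread`,
#'   sorted descending by spread).
#' @export
one_way_dsa <- function(spec, strategies, param, range,
                        outcome = c("ser", "al"), rule = transition_rule()) {
  outcome <- match.arg(outcome)
  if (length(range) != 2L || range[1] > range[2])
    validation_error("range", "must be an ordered (low, high) pair")
  run_at <- function(value) {
    mod <- apply_param(spec, strategies, param, value)
    base_case_table(mod$spec, mod$strategies, outcome = outcome, rule = rule)
  }
  lo <- run_at(range[1]); hi <- run_at(range[2])
  spread <- data.frame(strategy = lo$strategy,
                       icer_low = lo$icer, icer_high = hi$icer,
                       stringsAsFactors = FALSE)
  spread$spread <- abs(spread$icer_high - spread$icer_low)
  spread <- spread[order(-spread$spread, spread$strategy), ]
  rownames(spread) <- NULL
  list(param = param, range = range, low = lo, high = hi, spread = spread)
}

#' Tornado analysis for one target strategy
#'
#' Runs [one_way_dsa()] for every strategy cost range, every effect CI of the
#' chosen outcome, and the discount rate, recording the target strategy's
#' ICER at both ends. Output is sorted descending by spread, ready for a
#' tornado plot.
#'
#' @param spec,strategies,outcome,rule as in [one_way_dsa()].
#' @param target strategy whose ICER is tracked.
#' @param discount_range bounds for the discount-rate scenario
#'   (default `c(0, 0.06)`).
#' @return Data frame `param`, `low`, `high`, `icer_low`, `icer_high`,
#'   `spread`.
#' @export
tornado <- function(spec, strategies, target, outcome = c("ser", "al"),
                    rule = transition_rule(), discount_range = c(0, 0.06)) {
  outcome <- match.arg(outcome)
  strategies <- strategies_for_outcome(strategies, outcome)
  if (!target %in% names(strategies))
    validation_error("target", sprintf("unknown strategy '%s'", target))
  params <- c(
    paste0("cost:", names(strategies)),
    paste0(outcome, ":", names(strategies)),
    "discount_rate"
  )
  rows <- lapply(params, function(p) {
    rng <- if (p == "discount_rate") discount_range
    else {
      parts <- strsplit(p, ":", fixed = TRUE)[[1L]]
      s <- strategies[[parts[2L]]]
      switch(parts[1L], cost = s$cost_range, ser = s$ser_ci, al = s$al_ci_raw)
    }
    d <- one_way_dsa(spec, strategies, p, rng, outcome, rule)
    i <- match(target, d$low$strategy)
    data.frame(param = p, low = rng[1], high = rng[2],
               icer_low = d$low$icer[i], icer_high = d$high$icer[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$spread <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$spread, out$param), ]
  rownames(out) <- NULL
  out
}
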