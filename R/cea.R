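# Incremental cost-effectiveness arithmetic and dominance analysis --------

#' Incremental cost-effectiveness ratio
#'
#' `(TCa - TCb) / (Ea - Eb)`: the additional cost per additional unit of
#' benefit of strategy a over comparator b. A negative value with positive
#' incremental effectiveness is a cost saving per unit of benefit and is
#' reported as a negative number, never reclassified. When the incremental
#' effectiveness is zero the ratio is undefined and `NA` is returned:
#' strategies tied on effectiveness are compared by cost alone.
#'
#' @param delta_cost incremental cost (money).
#' @param delta_effect incremental effectiveness (benefit units).
#' @return Money per unit benefit; `NA_real_` when `delta_effect == 0`.
#'   Vectorized.
#' @examples
#' compute_icer(14303, 8.28) # 1727.4
#' @export
compute_icer <- function(delta_cost, delta_effect) {
  out <- delta_cost / delta_effect
  out[delta_effect == 0] <- NA_real_
  out
}

#' Incremental comparison table against a common reference
#'
#' Computes incremental cost, incremental effectiveness and the ICER of every
#' strategy against one common comparator (not chained along the frontier),
#' and attaches dominance labels from [find_frontier()].
#'
#' @param results data frame with columns `strategy`, `total_cost`,
#'   `effectiveness` (one row per strategy, unique labels).
#' @param reference label of the comparator strategy.
#' @return The input with columns `incr_cost`, `incr_effect`, `icer`,
#'   `dominance` added. The reference row has zero incrementals, `NA` ICER
#'   and dominance `"reference"`.
#' @export
incremental_table <- function(results, reference) {
  stopifnot(all(c("strategy", "total_cost", "effectiveness") %in% names(results)))
  if (anyDuplicated(results$strategy))
    validation_error("strategy", "duplicate strategy labels")
  i_ref <- match(reference, results$strategy)
  if (is.na(i_ref))
    validation_error("reference", sprintf("reference '%s' not present", reference))
  out <- results
  out$incr_cost <- out$total_cost - out$total_cost[i_ref]
  out$incr_effect <- out$effectiveness - out$effectiveness[i_ref]
  out$icer <- compute_icer(out$incr_cost, out$incr_effect)
  out$icer[i_ref] <- NA_real_
  out$dominance <- find_frontier(results)$dominance
  out$dominance[i_ref] <- if (out$dominance[i_ref] == "on_frontier")
    "reference" else paste0("reference_", out$dominance[i_ref])
  out
}

#' Dominance analysis and cost-effectiveness frontier
#'
#' A strategy is strongly dominated when some other strategy costs less and
#' is more effective (or costs strictly less at equal effectiveness).
#' Among the survivors - whose costs and effectiveness are then co-monotone -
#' extended dominance is removed by the standard convex-hull sweep: sorted by
#' effectiveness, sequential ICERs along the frontier must be strictly
#' increasing; any strategy breaking that lies above the segment joining its
#' neighbours and is beaten by a mixture of them. The frontier is what
#' remains, ordered by increasing effectiveness. The result does not depend
#' on which strategy is later designated the reference.
#'
#' @param results data frame with columns `strategy`, `total_cost`,
#'   `effectiveness`.
#' @return The input with a `dominance` column (`"on_frontier"`,
#'   `"strongly_dominated"` or `"extended_dominated"`) and attribute
#'   `frontier`: the frontier labels ordered by effectiveness.
#' @export
find_frontier <- function(results) {
  stopifnot(all(c("strategy", "total_cost", "effectiveness") %in% names(results)))
  n <- nrow(results)
  if (n == 0L) stop("need at least one strategy")
  cost <- results$total_cost
  eff <- results$effectiveness
  dominance <- rep("on_frontier", n)

  for (i in seq_len(n)) {
    better <- (cost < cost[i] & eff > eff[i]) |
      (cost < cost[i] & eff == eff[i]) |
      (cost == cost[i] & eff > eff[i])
    if (any(better)) dominance[i] <- "strongly_dominated"
  }

  cand <- which(dominance == "on_frontier")
  # equal-(cost, effectiveness) duplicates: keep the first label only
  if (length(cand) > 1L) {
    key <- paste(cost[cand], eff[cand])
    dup <- duplicated(key)
    dominance[cand[dup]] <- "strongly_dominated"
    cand <- cand[!dup]
  }
  cand <- cand[order(eff[cand], cost[cand])]
  # lower convex hull in the (effectiveness, cost) plane
  if (length(cand) > 2L) {
    hull <- cand[1:2]
    for (i in cand[-(1:2)]) {
      repeat {
        k <- length(hull)
        if (k < 2L) break
        a <- hull[k - 1L]; b <- hull[k]
        cross <- (eff[b] - eff[a]) * (cost[i] - cost[a]) -
          (cost[b] - cost[a]) * (eff[i] - eff[a])
        if (cross <= 0) {               # b on/above segment a-i: extended dominated
          dominance[b] <- "extended_dominated"
          hull <- hull[-k]
        } else break
      }
      hull <- c(hull, i)
    }
  }
  out <- results
  out$dominance <- dominance
  frontier <- which(dominance == "on_frontier")
  attr(out, "frontier") <- results$strategy[frontier[order(eff[frontier])]]
  out
}

#' Sequential ICERs along the frontier
#'
#' ICER of each frontier strategy against its immediate (next-less-effective)
#' frontier neighbour. These are the switch points of the optimal strategy as
#' the willingness-to-pay grows, distinct from the common-reference ICERs of
#' [incremental_table()].
#'
#' @param results data frame as for [find_frontier()].
#' @return Data frame `strategy`, `total_cost`, `effectiveness`,
#'   `icer_sequential` (NA for the cheapest frontier strategy), frontier
#'   order.
#' @export
sequential_icers <- function(results) {
  fr <- find_frontier(results)
  labs <- attr(fr, "frontier")
  idx <- match(labs, results$strategy)
  out <- results[idx, c("strategy", "total_cost", "effectiveness")]
  out$icer_sequential <- c(NA_real_,
                           compute_icer(diff(out$total_cost), diff(out$effectiveness)))
  rownames(out) <- NULL
  out
}

#' Net monetary benefit
#'
#' `lambda * E - TC`: the monetized value of a strategy at willingness-to-pay
#' `lambda` per unit of benefit. The strategy maximizing NMB at a given
#' `lambda` is the optimal one; at `lambda = 0` that is simply the cheapest.
#'
#' @param lambda willingness-to-pay, money per unit benefit (>= 0).
#' @param total_cost total cost (money).
#' @param effectiveness total benefit.
#' @return Money. Vectorized.
#' @export
net_monetary_benefit <- function(lambda, total_cost, effectiveness) {
  if (any(lambda < 0)) validation_error("lambda", "willingness-to-pay must be >= 0")
  lambda * effectiveness - total_cost
}

#' WHO GDP-threshold classification of an ICER
#'
#' An intervention is highly cost-effective when its ICER is below the
#' per-capita gross domestic product, cost-effective below three times the
#' per-capita GDP, and not cost-effective otherwise (strict inequalities).
#' The default GDP is Hong Kong's 2022 per-capita GDP of HK$382,377
#' (US$48,710).
#'
#' @param icer money per unit benefit (vectorized); `NA` propagates.
#' @param gdp_per_capita per-capita GDP in the same currency (> 0).
#' @return Character vector in `{"highly_cost_effective", "cost_effective",
#'   "not_cost_effective"}`.
#' @export
who_classify <- function(icer, gdp_per_capita = 382377) {
  if (gdp_per_capita <= 0) validation_error("gdp_per_capita", "must be positive")
  ifelse(is.na(icer), NA_character_,
         ifelse(icer < gdp_per_capita, "highly_cost_effective",
                ifelse(icer < 3 * gdp_per_capita, "cost_effective",
                       "not_cost_effective")))
}
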