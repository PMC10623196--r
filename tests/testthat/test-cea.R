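published_pairs <- function(outcome) {
  tab <- hk2022_base_case()
  tab <- tab[tab$outcome == outcome, ]
  data.frame(strategy = tab$strategy, total_cost = tab$cost_hkd,
             effectiveness = tab$effectiveness, stringsAsFactors = FALSE)
}

test_that("ICERs are exact quotients, with zero incremental effect undefined", {
  expect_equal(compute_icer(14303, 8.28), 1727.4, tolerance = 1e-4)
  expect_equal(compute_icer(55782, 8.40), 6640.7, tolerance = 1e-4)
  expect_equal(compute_icer(0, 5), 0)
  expect_true(is.na(compute_icer(100, 0)))
  # cost-saving ICERs stay negative, never reclassified
  expect_lt(compute_icer(-204, 5.82), 0)
})

test_that("incremental table compares every strategy to the one common reference", {
  res <- published_pairs("ser")
  tab <- incremental_table(res, "SVLs")
  svl <- tab[tab$strategy == "SVLs", ]
  expect_equal(svl$incr_cost, 0)
  expect_equal(svl$incr_effect, 0)
  expect_true(is.na(svl$icer))
  atr <- tab[tab$strategy == "Atropine eye drops, 0.05%", ]
  expect_equal(atr$incr_effect, 8.28)
  expect_equal(atr$icer, (43615 - 34320) / 8.28)
  out <- tab[tab$strategy == "Outdoor", ]
  expect_equal(out$incr_cost, -212)  # model-exact; published -204 reflects input rounding
  expect_error(incremental_table(rbind(res, res[2, ]), "SVLs"),
               class = "myopiacea_validation_error")
})

test_that("frontier on the published pairs matches the published dominance flags", {
  for (oc in c("ser", "al")) {
    res <- published_pairs(oc)
    fr <- find_frontier(res)
    tab <- hk2022_base_case(); tab <- tab[tab$outcome == oc, ]
    expect_setequal(attr(fr, "frontier"),
                    tab$strategy[tab$dominant])
    expect_setequal(res$strategy[brute_force_frontier(res$total_cost, res$effectiveness)],
                    attr(fr, "frontier"))
  }
  # red light therapy (AL) is strongly dominated by atropine 0.05%
  fr_al <- find_frontier(published_pairs("al"))
  expect_equal(fr_al$dominance[fr_al$strategy == "Red light therapy"],
               "strongly_dominated")
})

test_that("frontier agrees with exhaustive enumeration on random small instances", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    cost <- runif(n, 1e3, 1e5)
    eff <- runif(n, -5, 5)
    res <- data.frame(strategy = sprintf("s%d", seq_len(n)),
                      total_cost = cost, effectiveness = eff,
                      stringsAsFactors = FALSE)
    fr <- find_frontier(res)
    expect_setequal(attr(fr, "frontier"),
                    res$strategy[brute_force_frontier(cost, eff)])
    # labels partition correctly
    expect_true(all(fr$dominance %in%
      c("on_frontier", "strongly_dominated", "extended_dominated")))
  }
  single <- data.frame(strategy = "only", total_cost = 10, effectiveness = 1)
  expect_equal(find_frontier(single)$dominance, "on_frontier")
})

test_that("frontier is invariant to scaling, shifts and the reference choice", {
  res <- published_pairs("ser")
  fr0 <- attr(find_frontier(res), "frontier")
  scaled <- res; scaled$total_cost <- scaled$total_cost * 3.7
  expect_equal(attr(find_frontier(scaled), "frontier"), fr0)
  shifted <- res; shifted$effectiveness <- shifted$effectiveness + 11
  expect_equal(attr(find_frontier(shifted), "frontier"), fr0)
  # scaling costs by k scales every ICER by k
  t1 <- incremental_table(res, "SVLs")
  t2 <- incremental_table(scaled, "SVLs")
  expect_equal(t2$icer, t1$icer * 3.7)
  # dominance labels do not depend on which strategy is the reference
  tA <- incremental_table(res, "SVLs")
  tB <- incremental_table(res, "Outdoor")
  keep <- !(res$strategy %in% c("SVLs", "Outdoor"))
  expect_equal(tA$dominance[keep], tB$dominance[keep])
})

test_that("NMB is lambda * E - TC and consistent with the frontier intervals", {
  expect_equal(net_monetary_benefit(0, 43615, 8.28), -43615)
  expect_equal(net_monetary_benefit(7850, 43615, 8.28), 21383)
  res <- published_pairs("ser")
  seq_ic <- sequential_icers(res)
  # between consecutive sequential ICERs, the NMB argmax is that frontier strategy
  brk <- c(0, seq_ic$icer_sequential[-1], max(seq_ic$icer_sequential, na.rm = TRUE) * 2)
  for (i in seq_len(nrow(seq_ic))) {
    lam <- (max(0, brk[i]) + brk[i + 1]) / 2
    nmb <- net_monetary_benefit(lam, res$total_cost, res$effectiveness)
    expect_equal(res$strategy[which.max(nmb)], seq_ic$strategy[i])
  }
  # at lambda = 0 the cheapest strategy maximizes NMB
  nmb0 <- net_monetary_benefit(0, res$total_cost, res$effectiveness)
  expect_equal(which.max(nmb0), which.min(res$total_cost))
})

test_that("WHO GDP classification uses strict thresholds", {
  expect_equal(who_classify(5770), "highly_cost_effective")
  expect_equal(who_classify(382377, 382377), "cost_effective")
  expect_equal(who_classify(1.2e6, 382377), "not_cost_effective")
  expect_equal(who_classify(3 * 382377, 382377), "not_cost_effective")
  expect_equal(who_classify(-39), "highly_cost_effective")
  expect_true(is.na(who_classify(NA_real_)))
})
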