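test_that("Gamma fits treat the range as a central 95% interval and keep the mean", {
  fit <- fit_gamma_from_range(8415, c(5055, 13376))
  expect_equal(fit$sd, (13376 - 5055) / 3.92)
  expect_equal(fit$sd, 2122.7, tolerance = 1e-4)
  expect_equal(fit$shape, 8415^2 / fit$sd^2)
  expect_equal(fit$shape * fit$scale, 8415, tolerance = 1e-9)  # mean identity
  deg <- fit_gamma_from_range(100, c(100, 100))
  expect_equal(deg$family, "fixed")
  expect_error(fit_gamma_from_range(50, c(100, 200)),
               class = "myopiacea_validation_error")
})

test_that("Normal fits use SD = CI width / 3.92 and allow sign-crossing draws", {
  fit <- fit_normal_from_ci(0.57, c(0.28, 0.86))
  expect_equal(fit$sd, 0.58 / 3.92)
  expect_equal(fit$sd, 0.14796, tolerance = 1e-4)
  expect_equal(fit_normal_from_ci(0.5, c(0.2, 0.8))$mean, 0.5) # symmetric CI midpoint
  deg <- fit_normal_from_ci(0.3, c(0.3, 0.3))
  expect_equal(deg$family, "fixed")
  expect_equal(deg$sd, 0)
  expect_error(fit_normal_from_ci(0.57, c(0.86, 0.28)),
               class = "myopiacea_validation_error")
})

test_that("drawn parameters recover their configured moments at n = 10000", {
  pair <- make_pair()
  spec <- pair$spec
  s <- pair$strategies$TRT
  psa <- run_psa(spec, pair$strategies, "ser", iterations = 10000, seed = 11)
  d <- psa$samples[psa$samples$strategy == "TRT", ]
  cfit <- fit_gamma_from_range(s$annual_cost, s$cost_range)
  efit <- fit_normal_from_ci(s$ser_effect, s$ser_ci)
  n <- nrow(d)
  expect_lt(abs(mean(d$drawn_cost) - cfit$mean), 3 * cfit$sd / sqrt(n))
  expect_lt(abs(mean(d$drawn_effect) - efit$mean), 3 * efit$sd / sqrt(n))
  expect_lt(abs(sd(d$drawn_cost) - cfit$sd), 3 * cfit$sd / sqrt(n))
  expect_true(all(d$drawn_cost >= 0))
})

test_that("the PSA is reproducible given the seed and degenerates to the base case", {
  p1 <- run_psa(baseline$spec, baseline$strategies, "ser", 50, seed = 3)
  p2 <- run_psa(baseline$spec, baseline$strategies, "ser", 50, seed = 3)
  expect_identical(p1$samples, p2$samples)
  p3 <- run_psa(baseline$spec, baseline$strategies, "ser", 50, seed = 4)
  expect_false(identical(p1$samples, p3$samples))

  fixed <- lapply(baseline$strategies, function(s) {
    s$cost_distribution <- "fixed"; s$effect_distribution <- "fixed"; s
  })
  pf <- run_psa(baseline$spec, fixed, "ser", 5, seed = 1)
  bc <- base_case_table(baseline$spec, baseline$strategies, "ser", "model")
  for (nm in bc$strategy) {
    d <- pf$samples[pf$samples$strategy == nm, ]
    expect_equal(unique(d$total_cost), bc$total_cost[bc$strategy == nm])
    expect_equal(unique(d$effectiveness), bc$effectiveness[bc$strategy == nm])
  }
})

test_that("CEAC probabilities sum to 1 at every threshold and behave at the limits", {
  psa <- run_psa(baseline$spec, baseline$strategies, "ser", 200, seed = 5)
  curves <- ceac(psa)
  sums <- tapply(curves$probability, curves$lambda, sum)
  expect_equal(as.vector(sums), rep(1, length(unique(curves$lambda))))
  expect_true(all(curves$probability >= 0 & curves$probability <= 1))

  # lambda = 0: the strategy with the lowest drawn total cost wins each iteration
  at0 <- curves[curves$lambda == 0, ]
  s <- psa$samples
  wins0 <- tapply(seq_len(nrow(s)), s$iteration, function(idx)
    s$strategy[idx][which.min(s$total_cost[idx])])
  counts0 <- table(factor(unlist(wins0), levels = at0$strategy))
  expect_equal(unname(at0$probability), as.vector(counts0) / 200)

  # very large lambda: the most effective draw wins
  big <- ceac(psa, wtp_grid = 1e9)
  winsb <- tapply(seq_len(nrow(s)), s$iteration, function(idx)
    s$strategy[idx][which.max(s$effectiveness[idx])])
  top <- names(which.max(table(winsb)))
  expect_equal(big$strategy[which.max(big$probability)], top)
})

test_that("with degenerate distributions the CEAC steps exactly at the frontier ICERs", {
  pair <- make_pair()
  fixed <- lapply(pair$strategies, function(s) {
    s$cost_distribution <- "fixed"; s$effect_distribution <- "fixed"; s
  })
  psa <- run_psa(pair$spec, fixed, "ser", 3, seed = 1)
  bc <- base_case_table(pair$spec, pair$strategies, "ser", "model")
  icer <- bc$icer[bc$strategy == "TRT"]
  below <- ceac(psa, wtp_grid = icer * 0.9)
  above <- ceac(psa, wtp_grid = icer * 1.1)
  expect_equal(below$probability[below$strategy == "REF"], 1)
  expect_equal(above$probability[above$strategy == "TRT"], 1)
})

test_that("one-way DSA brackets the base case and respects monotonicity", {
  atr <- "Atropine eye drops, 0.05%"
  d <- one_way_dsa(baseline$spec, baseline$strategies,
                   paste0("cost:", atr), c(5055, 13376), "ser")
  bc <- base_case_table(baseline$spec, baseline$strategies, "ser", "model")
  i <- match(atr, bc$strategy)
  expect_lt(d$low$icer[i], bc$icer[i])
  expect_gt(d$high$icer[i], bc$icer[i])
  # varying one strategy's cost leaves the other strategies' ICERs untouched
  j <- match("HALs", bc$strategy)
  expect_equal(d$low$icer[j], bc$icer[j])
  expect_equal(d$high$icer[j], bc$icer[j])
  # total costs decrease strictly in the discount rate
  dd <- one_way_dsa(baseline$spec, baseline$strategies,
                    "discount_rate", c(0, 0.06), "ser")
  expect_true(all(dd$high$total_cost < dd$low$total_cost))
  expect_error(one_way_dsa(baseline$spec, baseline$strategies,
                           "nonsense:SVLs", c(0, 1), "ser"),
               class = "myopiacea_validation_error")
})

test_that("the tornado ranks parameters by ICER spread for the target", {
  atr <- "Atropine eye drops, 0.05%"
  tor <- tornado(baseline$spec, baseline$strategies, atr, "ser")
  expect_true(all(diff(tor$spread) <= 1e-9))
  # the target's own cost and effect are influential; unrelated costs are not
  expect_gt(tor$spread[tor$param == paste0("cost:", atr)], 0)
  expect_equal(tor$spread[tor$param == "cost:DIMS"], 0)
})
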