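test_that("net progression rate subtracts the treatment effect and floors at zero", {
  expect_equal(net_progression_rate(0.81, 0.57), 0.24)
  expect_equal(net_progression_rate(0.81, 0), 0.81)
  expect_equal(net_progression_rate(0.81, 1.2), 0)
  # a negative benefit (worse than untreated) speeds progression
  expect_equal(net_progression_rate(0.81, -0.07), 0.88)
})

test_that("transition matrices follow the rate/band-width rule", {
  P0 <- build_transition_matrix(0)
  expect_equal(unclass(P0), diag(3), ignore_attr = TRUE)

  P <- build_transition_matrix(0.81)
  expect_equal(P["low", "moderate"], 0.81 / 2.5)
  expect_equal(P["moderate", "high"], 0.81 / 3.0)
  expect_equal(P["high", "high"], 1)
  expect_equal(rowSums(P), c(low = 1, moderate = 1, high = 1))
  expect_true(all(P[lower.tri(P)] == 0))

  # probabilities cap at 1 for absurd rates
  Pbig <- build_transition_matrix(50)
  expect_equal(Pbig["low", "moderate"], 1)

  # category multipliers scale the exit probability
  P2 <- build_transition_matrix(0.81, rule = transition_rule(slow = 0.5))
  expect_equal(P2["low", "moderate"], 0.5 * 0.81 / 2.5)
  expect_error(build_transition_matrix(-0.1))
})

test_that("cohort occupancy is conserved and high myopia only grows", {
  for (s in baseline$strategies) {
    tr <- run_cohort(baseline$spec, s)
    expect_equal(rowSums(tr$occupancy), rep(1, nrow(tr$occupancy)),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_true(all(diff(tr$occupancy[, "high"]) >= -1e-12))
  }
})

test_that("a zero-rate cohort stays put and costs annual_cost times the discount sum", {
  pair <- make_pair(trt_effect = 0.81)           # exactly cancels progression
  spec <- pair$spec
  spec$start_distribution <- c(low = 1, moderate = 0, high = 0)
  tr <- run_cohort(spec, pair$strategies$TRT)
  expect_equal(tr$occupancy[, "low"], rep(1, 6), ignore_attr = TRUE)
  expect_identical(tr$lens_replacement_events, 0)
  expect_equal(tr$accrued_cost,
               9000 * sum(discount_factor(0.03, 0:5)), tolerance = 1e-12)
})

test_that("effect accrual is annual value times the number of events, undiscounted", {
  expect_equal(accrue_effect(0.57), 3.42)
  expect_equal(accrue_effect(-0.81), -4.86)
  expect_equal(accrue_effect(0), 0)
  expect_equal(accrue_effect(0.2, 10), 2)
  svl <- run_cohort(baseline$spec, baseline$strategies[["SVLs"]])
  expect_equal(svl$accrued_effect_ser, -4.86)
  expect_equal(svl$accrued_effect_al, -2.46)
})

test_that("expected adverse-event cost is the probability-weighted sum", {
  expect_equal(expected_adverse_event_cost(list()), 0)
  expect_equal(expected_adverse_event_cost(
    list(list(event = "photophobia", probability = 0.08, unit_cost = 1000))), 80)
  cc <- 500
  profile <- list(
    list(event = "keratitis", probability = 0.0003, unit_cost = cc),
    list(event = "infiltrate", probability = 0.004, unit_cost = cc)
  )
  expect_equal(expected_adverse_event_cost(profile), 0.0043 * cc)
  # and it enters the discounted cost accrual linearly
  pair <- make_pair()
  with_ae <- pair$strategies$TRT
  with_ae$adverse_events <- profile
  base <- run_cohort(pair$spec, pair$strategies$TRT)$accrued_cost
  plus <- run_cohort(pair$spec, with_ae)$accrued_cost
  expect_equal(plus - base, 0.0043 * cc * sum(discount_factor(0.03, 0:5)))
})

test_that("lens replacement surcharge is charged on expected entries to high myopia", {
  pair <- make_pair(trt_effect = 0)
  s_free <- pair$strategies$TRT
  s_paid <- s_free; s_paid$lens_cost <- 2000
  spec <- pair$spec
  tr_free <- run_cohort(spec, s_free)
  tr_paid <- run_cohort(spec, s_paid)
  expect_true(tr_paid$lens_replacement_events > 0)
  new_high <- c(0, pmax(0, diff(tr_free$occupancy[, "high"])))
  expected_surcharge <- sum(new_high * 2000 * discount_factor(0.03, 0:5))
  expect_equal(tr_paid$accrued_cost - tr_free$accrued_cost, expected_surcharge)
  # drops never pay the surcharge
  s_drop <- s_paid; s_drop$modality <- "drop"
  expect_equal(run_cohort(spec, s_drop)$accrued_cost, tr_free$accrued_cost)
})

test_that("stronger treatment effects never increase final high-state occupancy", {
  pair <- make_pair()
  finals <- vapply(seq(-0.2, 1.0, by = 0.1), function(e) {
    s <- pair$strategies$TRT; s$ser_effect <- e
    s$ser_ci <- c(e - 0.3, e + 0.3)
    tr <- run_cohort(pair$spec, s)
    tr$occupancy[nrow(tr$occupancy), "high"]
  }, 0)
  expect_true(all(diff(finals) <= 1e-12))
})

test_that("cohort propagation agrees with a per-individual Monte Carlo oracle", {
  set.seed(42)
  n <- 10000
  for (nm in c("SVLs", "Atropine eye drops, 0.05%")) {
    s <- baseline$strategies[[nm]]
    tr <- run_cohort(baseline$spec, s)
    rate <- net_progression_rate(
      baseline$spec$reference_annual_change,
      if (nm == "SVLs") 0 else s$ser_effect)
    P <- build_transition_matrix(rate, baseline$spec$states)
    occ_mc <- simulate_individuals(baseline$spec, P, n)
    se <- sqrt(pmax(tr$occupancy * (1 - tr$occupancy), 1e-12) / n)
    expect_true(all(abs(occ_mc - tr$occupancy) <= 3 * se + 1e-9))
  }
})

test_that("cohort traces export tidily", {
  tr <- run_cohort(baseline$spec, baseline$strategies[["SVLs"]])
  df <- as.data.frame(tr)
  expect_named(df, c("strategy", "cycle", "state", "occupancy"))
  expect_equal(nrow(df), 6 * 3)
  expect_equal(sum(df$occupancy), 6)
})
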