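test_that("stage capture probability has the right limits and matches simulation", {
  expect_lt(stage_capture_prob(1e-9, 1), 1e-8)
  expect_gt(stage_capture_prob(1e9, 1), 1 - 1e-8)
  expect_error(stage_capture_prob(0, 1), "must be > 0")
  expect_error(stage_capture_prob(1, -2), "must be > 0")
  # monotone in dwell time
  d <- c(0.1, 0.5, 1, 2, 10)
  expect_true(all(diff(stage_capture_prob(d, 1)) > 0))

  # d = T: individual-level oracle (exponential sojourn, uniform phase)
  set.seed(101)
  n <- 1e6
  caught <- stats::rexp(n, 1) > stats::runif(n, 0, 1)
  p_hat <- mean(caught)
  se <- sqrt(p_hat * (1 - p_hat) / n)
  expect_lt(abs(stage_capture_prob(1, 1) - p_hat), 3 * se)
})

test_that("trajectory decomposition matches the monotone-envelope arithmetic", {
  w0 <- shedding_trajectory_weights(c(0, 0, 0, 0))
  expect_equal(unname(w0["never"]), 1)
  w1 <- shedding_trajectory_weights(c(1, 1, 1, 1))
  expect_equal(unname(w1["I"]), 1)
  # non-monotone input: envelope (0.2, 0.2, 0.6, 0.6)
  w <- shedding_trajectory_weights(c(0.2, 0.1, 0.6, 0.6))
  expect_equal(unname(w), c(0.2, 0, 0.4, 0, 0.4))
  # property: valid distribution for random sensitivity vectors
  set.seed(5)
  for (i in 1:50) {
    wi <- shedding_trajectory_weights(stats::runif(4))
    expect_true(all(wi >= 0))
    expect_equal(sum(wi), 1)
  }
})

test_that("incidence-round interception reproduces the two-stage enumeration", {
  reg <- cancer_registry("alpha", "A")
  d_half <- dwell_for_capture(0.5)
  rates <- matrix(0, 1, 5, dimnames = list("alpha", STAGES))
  rates[1, "II"] <- 100
  perf <- test_performance(matrix(1, 1, 4, dimnames = list("alpha", NULL)), 0)
  dwell <- dwell_scenario(matrix(d_half, 1, 4, dimnames = list("alpha", NULL)))
  res <- incidence_round_interception(rates, perf, dwell,
                                      screening_config(1, 1e5))
  expect_equal(res$detected["alpha", "I", "II"], 50, tolerance = 1e-9)
  expect_equal(res$detected["alpha", "II", "II"], 25, tolerance = 1e-9)
  expect_equal(res$not_detected["alpha", "II"], 25, tolerance = 1e-9)
})

test_that("interception limits: zero sensitivity, certain capture, infinite dwell", {
  reg <- toy_registry()
  rates <- stratum_incidence(toy_incidence(), "female", 65)
  dwell <- toy_dwell()
  cfg <- screening_config()
  zero <- test_performance(toy_perf()$sens * 0, 0.01)
  res0 <- incidence_round_interception(rates, zero, dwell, cfg)
  expect_equal(sum(res0$detected), 0)
  expect_equal(res0$not_detected[, STAGES], rates[, STAGES])

  # q ~ 1 and onset I: everything found at stage I regardless of s_clin
  ones <- test_performance(toy_perf()$sens * 0 + 1, 0)
  huge <- dwell_scenario(dwell$d * 0 + 1e12, "huge")
  res1 <- incidence_round_interception(rates, ones, huge, cfg)
  staged <- rates[, SHIFT_STAGES]
  expect_equal(apply(res1$detected[, "I", SHIFT_STAGES], 1, sum),
               rowSums(staged), tolerance = 1e-9)

  # infinite dwell with partial shedding: episode sensitivity hits the
  # envelope ceiling per clinical stage
  perf <- toy_perf(0)
  resc <- incidence_round_interception(rates, perf, huge, cfg)
  for (cl in reg$class) {
    env <- cummax(perf$sens[cl, ])
    expect_equal(apply(resc$detected[cl, , SHIFT_STAGES], 2, sum),
                 unname(rates[cl, SHIFT_STAGES] * env), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("case conservation and stage-shift direction hold for both rounds", {
  fit <- toy_fit()
  res <- fit$interception
  per_class <- apply(res$detected, 1, sum) + rowSums(res$not_detected)
  expect_equal(per_class, rowSums(res$incident), tolerance = 1e-9)
  # no downward shift: s_det > s_clin always empty
  for (i in seq_len(4)) {
    for (j in seq_len(4)) {
      if (i > j) expect_equal(sum(res$detected[, i, j]), 0)
    }
  }
  expect_gte(res$fp_total, 0)
  expect_equal(res$fp_total,
               0.005 * (res$cohort_size - sum(res$detected)))

  prev <- prevalence_round_interception(stratum_incidence(toy_incidence(),
                                                          "female", 65),
                                        toy_perf(), toy_dwell(),
                                        screening_config(round = "prevalence"))
  per_class_p <- apply(prev$detected, 1, sum) + rowSums(prev$not_detected)
  expect_equal(per_class_p, rowSums(prev$incident), tolerance = 1e-9)
})

test_that("prevalence round follows the length-biased pool arithmetic", {
  reg <- cancer_registry("alpha", "A")
  rates <- matrix(0, 1, 5, dimnames = list("alpha", STAGES))
  rates[1, "I"] <- 100
  sens <- matrix(0.5, 1, 4, dimnames = list("alpha", NULL))
  perf <- test_performance(sens, 0)
  dwell2 <- dwell_scenario(matrix(2, 1, 4, dimnames = list("alpha", NULL)))
  res <- prevalence_round_interception(rates, perf, dwell2,
                                       screening_config(round = "prevalence"))
  expect_equal(sum(res$detected), 100) # pool 200 x shedding 0.5
  # doubling dwell doubles the standing pool and detections
  dwell4 <- dwell_scenario(dwell2$d * 2)
  res2 <- prevalence_round_interception(rates, perf, dwell4,
                                        screening_config(round = "prevalence"))
  expect_equal(sum(res2$detected), 2 * sum(res$detected))
})

test_that("shrinking dwell times never increases detections", {
  rates <- stratum_incidence(toy_incidence(), "female", 65)
  cfg <- screening_config()
  slow <- incidence_round_interception(rates, toy_perf(), toy_dwell(), cfg)
  fast <- incidence_round_interception(rates, toy_perf(), toy_dwell(0.5), cfg)
  expect_true(all(apply(fast$detected, 1, sum) <=
                    apply(slow$detected, 1, sum) + 1e-12))
  prev_s <- prevalence_round_interception(rates, toy_perf(), toy_dwell(),
                                          screening_config(round = "prevalence"))
  prev_f <- prevalence_round_interception(rates, toy_perf(), toy_dwell(0.5),
                                          screening_config(round = "prevalence"))
  expect_true(all(apply(prev_f$detected, 1, sum) <=
                    apply(prev_s$detected, 1, sum) + 1e-12))
})
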