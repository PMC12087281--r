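test_that("posterior draws are seeded, conjugate, and concentrate with data", {
  syn <- generate_synthetic_inputs(seed = 3)
  spec <- posterior_spec_from_truth(syn)
  d1 <- posterior_draws(spec, R = 5, seed = 42)
  d2 <- posterior_draws(spec, R = 5, seed = 42)
  expect_identical(d1, d2)
  d3 <- posterior_draws(spec, R = 5, seed = 43)
  expect_false(identical(d1, d3))

  # FP-rate draws follow Beta(fp + 1/2, tn + 1/2): Monte-Carlo mean vs
  # closed form within 3 SE
  R <- 4000
  dr <- posterior_draws(spec, R = R, seed = 7, blocks = "fp")
  fps <- vapply(dr, function(d) d$perf$fp_rate, numeric(1))
  a <- spec$fp + 0.5
  b <- spec$n_noncancer - spec$fp + 0.5
  mu <- a / (a + b)
  se <- sqrt(a * b / ((a + b)^2 * (a + b + 1))) / sqrt(R)
  expect_lt(abs(mean(fps) - mu), 3 * se)

  # large counts at a fixed ratio: draws concentrate at the point estimate
  big <- posterior_spec(spec$sens_detected * 1000, spec$sens_total * 1000,
                        spec$fp * 1000, spec$n_noncancer * 1000, spec$counts)
  drb <- posterior_draws(big, R = 50, seed = 8, blocks = c("sens", "fp"))
  s_pt <- big$sens_detected / big$sens_total
  spread <- vapply(drb, function(d)
    max(abs(d$perf$sens - s_pt), na.rm = TRUE), numeric(1))
  expect_lt(max(spread), 0.01)
})

test_that("uncertainty propagation brackets the point estimate and widens with FP noise", {
  syn <- generate_synthetic_inputs(seed = 3)
  fit <- syn$fit
  spec <- posterior_spec_from_truth(syn)
  us <- propagate_uncertainty(fit, spec, R = 120, seed = 5,
                              attribute = FALSE)
  expect_equal(us$n_failed, 0)
  ok <- is.finite(us$ppv$est)
  # quantile ordering: lower <= central (draw median) <= upper, always
  expect_true(all(us$ppv$lo[ok] <= us$ppv$central[ok] + 1e-12))
  expect_true(all(us$ppv$central[ok] <= us$ppv$hi[ok] + 1e-12))
  # most intervals cover the point estimate (draws center on the data)
  cover <- us$ppv$est[ok] >= us$ppv$lo[ok] - 1e-9 &
    us$ppv$est[ok] <= us$ppv$hi[ok] + 1e-9
  expect_gt(mean(cover), 0.7)

  # a sparser FP study (same rate, fewer participants) widens PPV intervals
  tight <- posterior_spec(spec$sens_detected, spec$sens_total,
                          fp = spec$fp * 50,
                          n_noncancer = spec$n_noncancer * 50, spec$counts)
  wide <- posterior_spec(spec$sens_detected, spec$sens_total,
                         fp = max(1, round(spec$fp / 5)),
                         n_noncancer = round(spec$n_noncancer / 5),
                         spec$counts)
  ut <- propagate_uncertainty(fit, tight, R = 120, seed = 5,
                              attribute = FALSE)
  uw <- propagate_uncertainty(fit, wide, R = 120, seed = 5,
                              attribute = FALSE)
  expect_gt(mean(uw$ppv$hi - uw$ppv$lo, na.rm = TRUE),
            mean(ut$ppv$hi - ut$ppv$lo, na.rm = TRUE))
})

test_that("variance attribution assigns shares that sum to one", {
  syn <- generate_synthetic_inputs(seed = 3)
  spec <- posterior_spec_from_truth(syn)
  us <- propagate_uncertainty(syn$fit, spec, R = 80, seed = 2,
                              attribute = TRUE)
  expect_equal(sum(us$attribution$share), 1, tolerance = 1e-12)
  expect_true(all(us$attribution$variance >= 0))
  expect_setequal(us$attribution$block, c("sens", "fp", "confusion"))
})

test_that("dwell-scenario comparison reports deltas with the right direction", {
  syn <- generate_synthetic_inputs(seed = 3)
  fit <- syn$fit
  same <- dwell_scenario_compare(fit, list(a = syn$dwell$default,
                                           b = syn$dwell$default))
  expect_equal(max(abs(same$metrics$d_ppv_any)), 0)
  expect_equal(max(abs(same$metrics$d_lives), na.rm = TRUE), 0)

  cmpr <- dwell_scenario_compare(fit, syn$dwell) # default vs fast_aggressive
  expect_true(all(cmpr$monotone_vs_reference))
  expect_true(all(cmpr$detected[, "fast_aggressive"] <=
                    cmpr$detected[, "default"] + 1e-9))
  expect_error(
    refit <- dwell_scenario_compare(fit, syn$dwell["default"]), "length")
})

test_that("posterior 95% intervals cover truth-parameter output at a sane rate", {
  syn <- generate_synthetic_inputs(seed = 13)
  fit <- syn$fit
  truth_med <- stats::median(fit$chain$ppv_any, na.rm = TRUE)
  n_rep <- 12
  covered <- logical(n_rep)
  set.seed(99)
  for (r in seq_len(n_rep)) {
    # replicate validation study drawn from the truth parameters
    tot <- syn$perf$sens * 0 + 60
    det <- matrix(stats::rbinom(length(tot), 60, as.vector(syn$perf$sens)),
                  nrow(tot), dimnames = dimnames(tot))
    n_nc <- 2000
    fp <- stats::rbinom(1, n_nc, syn$fp_rate)
    spec <- posterior_spec(det, tot, fp, n_nc, syn$counts)
    dr <- posterior_draws(spec, R = 80)
    meds <- vapply(dr, function(d) {
      f <- mcedcso:::refit_mced(fit, perf = d$perf, model = d$model)
      stats::median(f$chain$ppv_any, na.rm = TRUE)
    }, numeric(1))
    qs <- stats::quantile(meds, c(0.025, 0.975))
    covered[r] <- truth_med >= qs[1] && truth_med <= qs[2]
  }
  # binomial slack at 12 replicates: allow down to 8/12
  expect_gte(sum(covered), 8)
})
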