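# build a minimal stratified object with explicit stage-shift detail:
# 10 alpha cancers intercepted at I that would have presented at IV,
# with a perfectly matched CSO prediction
shift_fixture <- function(s5_alpha = c(0.9, 0.6, 0.4, 0.2),
                          p_match = 1, n_shift = 10) {
  reg <- cancer_registry(c("alpha", "beta"), c("A", "B"))
  labs <- c("A", "B")
  detected <- array(0, dim = c(2, 5, 5),
                    dimnames = list(c("alpha", "beta"), STAGES, STAGES))
  detected["alpha", "I", "IV"] <- n_shift
  interception <- structure(
    list(detected = detected,
         not_detected = matrix(0, 2, 5,
                               dimnames = list(c("alpha", "beta"), STAGES)),
         fp_total = 0,
         incident = matrix(0, 2, 5,
                           dimnames = list(c("alpha", "beta"), STAGES)),
         cohort_size = 1e5, round = "incidence", screen_interval = 1),
    class = "interception_result")
  tp <- rbind(alpha = c(A = n_shift * p_match, B = n_shift * (1 - p_match)),
              beta = c(A = 0, B = 0))
  strat <- structure(list(tp_by_class = tp, fp = c(A = 0, B = 0),
                          interception = interception, labels = labs),
                     class = "cso_stratified")
  s5 <- rbind(alpha = s5_alpha, beta = c(0.8, 0.6, 0.4, 0.2))
  colnames(s5) <- SHIFT_STAGES
  list(reg = reg, strat = strat,
       surv = survival_table(s5, os = data.frame(
         sex = "female", age_lo = 65, age_hi = 70, os5 = 0.8)))
}

test_that("stage-shift lives saved follow the 5-year survival increments", {
  fx <- shift_fixture()
  lv <- stage_shift_lives_saved(fx$strat, fx$surv, fx$reg)
  expect_equal(unname(lv$lives_first["A"]), 10 * (0.9 - 0.2))
  expect_equal(unname(lv$lives_post["A"]), 0)
  # stage-flat survival: no benefit
  flat <- shift_fixture(s5_alpha = rep(0.5, 4))
  expect_equal(sum(stage_shift_lives_saved(flat$strat, flat$surv,
                                           flat$reg)$lives_first), 0)
  # cross-talk prediction routes the benefit to the post-directed step
  half <- shift_fixture(p_match = 0.6)
  lv2 <- stage_shift_lives_saved(half$strat, half$surv, half$reg)
  expect_equal(unname(lv2$lives_first["A"]), 0.6 * 7)
  expect_equal(unname(lv2$lives_post["B"]), 0.4 * 7)
})

test_that("no stage shift means no lives saved", {
  fit <- toy_fit()
  det <- fit$interception$detected
  same <- det * 0
  for (s in STAGES) same[, s, s] <- apply(det[, , s], 1, sum)
  # rebuild with only the diagonal (same-stage) detections
  strat <- fit$stratified
  strat$interception$detected <- same
  lv <- stage_shift_lives_saved(strat, toy_surv(), toy_registry())
  expect_equal(sum(lv$lives_first) + sum(lv$lives_post), 0)
})

test_that("missing survival excludes a class with a flag, never silently", {
  fx <- shift_fixture()
  s5 <- fx$surv$s5
  s5["alpha", ] <- NA
  surv_na <- suppressWarnings(survival_table(s5))
  lv <- stage_shift_lives_saved(fx$strat, surv_na, fx$reg)
  expect_identical(lv$excluded_classes, "alpha")
  expect_true(is.na(lv$class_lives["alpha"]))
})

test_that("tests per life saved divide pools by lives, flagged when undefined", {
  fx <- shift_fixture()
  lv <- stage_shift_lives_saved(fx$strat, fx$surv, fx$reg)
  ch <- chain_ppvs(fx$strat, fx$reg)
  oc <- tests_per_life(lv, ch, benchmark = 240)
  a <- oc[oc$predicted_cso == "A", ]
  expect_equal(a$tests_per_life_first, 10 / 7)
  # worked division: pool 30, lives 2 -> 15 tests per life
  lv2 <- lv
  lv2$lives_first["A"] <- 2
  ch2 <- ch
  ch2$n_pool[ch2$predicted_cso == "A"] <- 30
  oc2 <- tests_per_life(lv2, ch2)
  expect_equal(oc2$tests_per_life_first[oc2$predicted_cso == "A"], 15)
  # zero lives: flagged undefined, not infinite
  lv0 <- lv
  lv0$lives_first["A"] <- 0
  oc0 <- tests_per_life(lv0, ch)
  expect_true(is.na(oc0$tests_per_life_first[oc0$predicted_cso == "A"]))
  # halving every survival gap doubles the ratio exactly
  sq <- shift_fixture(s5_alpha = c(0.55, 0.4, 0.3, 0.2)) # gap 0.35 = 0.7/2
  lvh <- stage_shift_lives_saved(sq$strat, sq$surv, sq$reg)
  och <- tests_per_life(lvh, ch)
  expect_equal(och$tests_per_life_first[och$predicted_cso == "A"],
               2 * a$tests_per_life_first)
})

test_that("competing-risk adjustment scales lives by all-cause survival", {
  fx <- shift_fixture()
  base <- stage_shift_lives_saved(fx$strat, fx$surv, fx$reg)
  os <- os_adjusted_lives(fx$strat, fx$surv, fx$reg, "female", 65)
  expect_equal(os$lives_first, 0.8 * base$lives_first)
  expect_equal(os$lives_post, 0.8 * base$lives_post)
  expect_error(os_adjusted_lives(fx$strat, fx$surv, fx$reg, "male", 75),
               "no all-cause survival")
  surv_noos <- survival_table(fx$surv$s5)
  expect_error(os_adjusted_lives(fx$strat, surv_noos, fx$reg, "female", 65),
               "no all-cause")
})

test_that("the proportional-hazards split preserves the mixture and its limits", {
  sp <- hr_split_survival(0.6, 0.5, 2)
  # independent oracle: with h = 2 the constraint is quadratic in u = s^k
  u <- (-(1 - 0.5) + sqrt((1 - 0.5)^2 + 4 * 0.5 * 0.6)) / (2 * 0.5)
  expect_equal(unname(sp$s5_nondetectable), u, tolerance = 1e-8)
  expect_equal(unname(sp$s5_detectable), u^2, tolerance = 1e-8)
  expect_equal(0.5 * sp$s5_detectable + 0.5 * sp$s5_nondetectable, 0.6,
               tolerance = 1e-10, ignore_attr = TRUE)
  # h = 1: no split
  sp1 <- hr_split_survival(c(0.3, 0.8), 0.4, 1)
  expect_equal(unname(sp1$s5_detectable), c(0.3, 0.8))
  # detectable fraction -> 1: detectable survival -> mixture
  spf <- hr_split_survival(0.6, 1 - 1e-9, 2)
  expect_equal(unname(spf$s5_detectable), 0.6, tolerance = 1e-6)
  # mixture constraint across random inputs
  set.seed(11)
  for (i in 1:25) {
    s <- stats::runif(1, 0.05, 0.95)
    f <- stats::runif(1, 0.05, 0.95)
    h <- stats::runif(1, 1, 5)
    spi <- hr_split_survival(s, f, h)
    expect_equal(f * spi$s5_detectable + (1 - f) * spi$s5_nondetectable,
                 s, tolerance = 1e-8, ignore_attr = TRUE)
    expect_lte(spi$s5_detectable, s + 1e-10)
    expect_gte(spi$s5_nondetectable, s - 1e-10)
  }
})

test_that("OS and HR variants never increase lives saved", {
  fit <- toy_fit()
  base <- fit$lives
  os <- os_adjusted_lives(fit$stratified, toy_surv(), toy_registry(),
                          "female", 65)
  hr <- hr_adjusted_lives(fit$stratified, toy_surv(), toy_registry(),
                          toy_perf(), h = 2)
  expect_true(all(os$lives_first <= base$lives_first + 1e-12))
  expect_true(all(os$lives_post <= base$lives_post + 1e-12))
  expect_true(all(hr$lives_first <= base$lives_first + 1e-12))
  expect_true(all(hr$lives_post <= base$lives_post + 1e-12))
  # h = 1 leaves the baseline untouched
  hr1 <- hr_adjusted_lives(fit$stratified, toy_surv(), toy_registry(),
                           toy_perf(), h = 1)
  expect_equal(hr1$lives_first, base$lives_first, tolerance = 1e-12)
})
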