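test_that("the three PPV tiers follow the pool arithmetic", {
  reg <- toy_registry()
  # pool A: matched 6 (alpha), cross-talk 3 (beta), FP 1
  tp <- rbind(alpha = c(A = 6, B = 1), beta = c(A = 3, B = 5),
              gamma = c(A = 0, B = 0), other = c(A = 0, B = 0))
  strat <- manual_strat(tp, fp = c(A = 1, B = 0))
  ch <- chain_ppvs(strat, reg)
  a <- ch[ch$predicted_cso == "A", ]
  expect_equal(a$ppv_any, 0.9)
  expect_equal(a$ppv_first, 0.6)
  expect_equal(a$ppv_remaining, 3 / 4)
  # F = 0 pool: ppv_any = 1
  b <- ch[ch$predicted_cso == "B", ]
  expect_equal(b$ppv_any, 1)
  # tier ordering is structural
  expect_true(all(ch$ppv_first <= ch$ppv_any + 1e-12))
  # matched-only removal: cross-talk TPs stay in the remaining pool
  expect_equal(b$n_any - b$n_match, 1)
})

test_that("empty and degenerate pools are flagged, not zeroed", {
  reg <- cancer_registry(c("x", "y"), c("X", "Y"))
  tp <- rbind(x = c(X = 5, Y = 0), y = c(X = 0, Y = 0))
  strat <- manual_strat(tp, fp = c(X = 0, Y = 0))
  ch <- chain_ppvs(strat, reg)
  y <- ch[ch$predicted_cso == "Y", ]
  expect_false(y$defined)
  expect_true(is.na(y$ppv_any))
  # identity confusion with FPs: remaining pool holds only FPs
  tp2 <- rbind(x = c(X = 5, Y = 0), y = c(X = 0, Y = 3))
  ch2 <- chain_ppvs(manual_strat(tp2, fp = c(X = 1, Y = 1)), reg)
  expect_equal(ch2$ppv_remaining, c(0, 0))
})

test_that("cross-CSO summaries use the median/range conventions", {
  m <- data.frame(predicted_cso = c("a", "b", "c"),
                  ppv_any = c(0.2, 0.4, 0.6))
  sm <- summarize_across_csos(m)
  expect_equal(sm$median, 0.4)
  expect_equal(c(sm$min, sm$max), c(0.2, 0.6))
  expect_equal(c(sm$argmin, sm$argmax), c("a", "c"))
  expect_equal(summarize_across_csos(
    data.frame(predicted_cso = "z", ppv_any = 0.33))$median, 0.33)
  expect_equal(summarize_across_csos(
    data.frame(predicted_cso = letters[1:4],
               ppv_any = c(0.1, 0.2, 0.3, 0.4)))$median, 0.25)
  expect_error(summarize_across_csos(
    data.frame(predicted_cso = "z", ppv_any = NA_real_)), "no defined")
})

test_that("workup-threshold comparison is inclusive at the boundary", {
  m <- data.frame(predicted_cso = c("a", "b", "c", "d"),
                  ppv_any = c(0.07, 0, 0.5, 0.069),
                  ppv_first = c(0, 0, 0, 0),
                  ppv_remaining = c(0.1, 0, 0.02, NA))
  rep <- threshold_report(m, 0.07)
  expect_identical(rep$pass_any, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(rep$pass_first, rep(FALSE, 4))
  expect_equal(sum(rep$pass_any), 2)
  expect_true(is.na(rep$pass_remaining[4]))
})

test_that("modelability flags mirror the exclusion rules", {
  reg <- cancer_registry(c("thy", "mye", "lun"), c("THY", "MYE", "LUN"))
  sens <- rbind(thy = rep(0, 4), mye = c(0.2, 0.3, 0.4, 0.5),
                lun = c(0.3, 0.5, 0.7, 0.9))
  colnames(sens) <- SHIFT_STAGES
  perf <- test_performance(sens, 0.005)
  labs <- c("THY", "MYE", "LUN")
  n <- diag(10, 3); dimnames(n) <- list(labs, labs)
  n["MYE", "MYE"] <- 0; n["MYE", "LUN"] <- 7 # never predicted correctly
  counts <- confusion_counts(n, stats::setNames(rep(0, 3), labs),
                             stats::setNames(rep(1 / 3, 3), labs))
  s5 <- rbind(thy = c(0.95, 0.9, 0.8, 0.6), mye = c(0.8, 0.7, 0.5, 0.3),
              lun = c(NA, NA, NA, NA))
  colnames(s5) <- SHIFT_STAGES
  surv <- survival_table(s5)
  fl <- modelable_cso_flags(perf, counts, surv, reg)
  expect_false(fl$detectable[fl$predicted_cso == "THY"])
  expect_false(fl$cso_predictable[fl$predicted_cso == "MYE"])
  expect_false(fl$survival_available[fl$predicted_cso == "LUN"])
  expect_true(fl$detectable[fl$predicted_cso == "MYE"])
  expect_false(any(fl$modelable))
  # with everything present all flags pass
  fl2 <- modelable_cso_flags(perf, counts, NULL, reg)
  expect_true(fl2$modelable[fl2$predicted_cso == "LUN"])
})

test_that("raising incidence at fixed FP count strictly raises PPV-any", {
  reg <- toy_registry()
  tp <- rbind(alpha = c(A = 6, B = 1), beta = c(A = 3, B = 5),
              gamma = c(A = 0, B = 2), other = c(A = 0.5, B = 0.5))
  fp <- c(A = 2, B = 1.5)
  ch1 <- chain_ppvs(manual_strat(tp, fp), reg)
  for (f in c(1.5, 2, 4)) {
    ch2 <- chain_ppvs(manual_strat(tp * f, fp), reg)
    expect_true(all(ch2$ppv_any > ch1$ppv_any))
  }
})
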