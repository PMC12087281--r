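# Small deterministic fixtures shared across test files. Everything is
# built in code; no stored data.

toy_registry <- function() {
  cancer_registry(c("alpha", "beta", "gamma", "other"),
                  cso = c("A", "B", "B", "none"),
                  sex = c("both", "both", "female", "both"))
}

# stage-complete incidence for one stratum; per-class totals spread over
# stages I..IV plus a small unstaged share
toy_incidence <- function(totals = c(alpha = 100, beta = 40, gamma = 10,
                                     other = 5),
                          sex = "female", age_lo = 65, smoking = "any",
                          registry = toy_registry()) {
  mix <- c(I = 0.4, II = 0.3, III = 0.2, IV = 0.08, unstaged = 0.02)
  rows <- do.call(rbind, lapply(names(totals), function(cl) {
    data.frame(sex = sex, age_lo = age_lo, age_hi = age_lo + 5,
               smoking = smoking, cancer_class = cl, stage = names(mix),
               rate_per_100k = unname(totals[cl] * mix),
               stringsAsFactors = FALSE)
  }))
  validate_incidence(rows, registry, source = "toy incidence")
}

toy_perf <- function(fp_rate = 0.005, registry = toy_registry()) {
  sens <- rbind(alpha = c(0.3, 0.5, 0.7, 0.9),
                beta = c(0.2, 0.4, 0.6, 0.8),
                gamma = c(0.1, 0.3, 0.5, 0.7),
                other = c(0.2, 0.3, 0.4, 0.5))
  colnames(sens) <- SHIFT_STAGES
  test_performance(sens, fp_rate)
}

toy_dwell <- function(mult = 1, registry = toy_registry()) {
  d <- matrix(rep(c(2, 1, 1, 0.5) * mult, each = 4), 4, 4,
              dimnames = list(registry$class, SHIFT_STAGES))
  dwell_scenario(d, if (mult == 1) "default" else "scaled")
}

toy_counts <- function(diag_n = 20, off = 1) {
  labs <- c("A", "B")
  n <- matrix(off, 2, 2, dimnames = list(labs, labs))
  diag(n) <- diag_n
  confusion_counts(n, fp_counts = c(A = 1, B = 0),
                   prior_freq = c(A = 0.6, B = 0.4))
}

toy_surv <- function(registry = toy_registry()) {
  s5 <- rbind(alpha = c(0.9, 0.7, 0.5, 0.2),
              beta = c(0.85, 0.6, 0.4, 0.15),
              gamma = c(0.8, 0.6, 0.35, 0.1),
              other = c(0.7, 0.5, 0.3, 0.1))
  colnames(s5) <- SHIFT_STAGES
  os <- data.frame(sex = c("female", "male"), age_lo = 65, age_hi = 70,
                   os5 = c(0.95, 0.93))
  survival_table(s5, os)
}

toy_fit <- function(fp_rate = 0.005, ...) {
  mced_screen(toy_incidence(), toy_perf(fp_rate), toy_counts(), toy_dwell(),
              toy_surv(), toy_registry(), sex = "female", age_lo = 65, ...)
}

# dwell time whose single-stage capture probability is exactly q (T = 1)
dwell_for_capture <- function(q) {
  stats::uniroot(function(d) d * (1 - exp(-1 / d)) - q,
                 c(1e-6, 1e6), tol = 1e-14)$root
}

rdirich_test <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}

# hand-built CSO-stratified object for closed-form chain arithmetic
manual_strat <- function(tp_by_class, fp, labels = colnames(tp_by_class)) {
  structure(list(tp_by_class = tp_by_class, fp = fp, labels = labels),
            class = "cso_stratified")
}
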