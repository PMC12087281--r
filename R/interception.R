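#' MCED test performance
#'
#' @param sens numeric matrix of per-class, per-stage (I--IV) sensitivities
#'   in \[0,1\]: the fraction of cancers of that class shedding a detectable
#'   signal while in that stage.
#' @param fp_rate single aggregate false-positive rate (1 - specificity),
#'   applied once per screened person regardless of the number of CSO
#'   categories.
#' @return a `test_performance` list.
#' @export
test_performance <- function(sens, fp_rate) {
  sens <- as.matrix(sens)
  if (is.null(colnames(sens))) colnames(sens) <- SHIFT_STAGES
  stopifnot(identical(colnames(sens), SHIFT_STAGES),
            all(sens >= 0 & sens <= 1),
            length(fp_rate) == 1, fp_rate >= 0, fp_rate <= 1)
  structure(list(sens = sens, fp_rate = fp_rate), class = "test_performance")
}

#' A dwell-time scenario
#'
#' @param d numeric matrix of per-class, per-stage (I--IV) mean sojourn
#'   times in years, all > 0.
#' @param label scenario label, e.g. `"default"` or `"fast_aggressive"`.
#' @return a `dwell_scenario` list.
#' @export
dwell_scenario <- function(d, label = "default") {
  d <- as.matrix(d)
  if (is.null(colnames(d))) colnames(d) <- SHIFT_STAGES
  stopifnot(identical(colnames(d), SHIFT_STAGES), all(d > 0))
  structure(list(label = label, d = d), class = "dwell_scenario")
}

#' Screening configuration
#'
#' @param screen_interval years between screens (default 1).
#' @param cohort_size persons per stratum (default 100,000).
#' @param round `"incidence"` (steady-state repeat screening) or
#'   `"prevalence"` (first screen of an unscreened population).
#' @return a `screening_config` list.
#' @export
screening_config <- function(screen_interval = 1, cohort_size = 1e5,
                             round = c("incidence", "prevalence")) {
  round <- match.arg(round)
  stopifnot(screen_interval > 0, cohort_size > 0)
  structure(list(screen_interval = screen_interval,
                 cohort_size = cohort_size, round = round),
            class = "screening_config")
}

#' Probability that screening catches a stage
#'
#' Probability that at least one screen (interval `T`, uniform random phase)
#' falls within a stage whose sojourn is exponential with mean `d`:
#' `(d/T) * (1 - exp(-T/d))`, capped at 1. This is exact for a single stage:
#' the stage is missed iff its duration is shorter than the (uniform) time to
#' the next screen.
#'
#' @param d mean stage sojourn in years (> 0); vectorized.
#' @param T screening interval in years (> 0).
#' @return capture probability in \[0, 1\].
#' @export
stage_capture_prob <- function(d, T) {
  if (any(d <= 0) || T <= 0) stop("dwell time and screen interval must be > 0")
  pmin(1, (d / T) * (-expm1(-T / d)))
}

#' Decompose a sensitivity vector into shedding-onset trajectory weights
#'
#' Detectability is assumed monotone: once a cancer sheds signal it keeps
#' shedding in later stages, so the observed per-stage sensitivities are the
#' cumulative fractions of cancers whose shedding onset lies at or before
#' each stage. Raw sensitivity estimates can dip by sampling noise; they are
#' first made monotone by the running-maximum envelope. The weight on onset
#' stage j is the envelope increment, and the residual mass is the
#' never-detectable trajectory.
#'
#' @param sens numeric vector of per-stage (I--IV) sensitivities in \[0,1\].
#' @return named numeric vector of weights over onset
#'   `c("I","II","III","IV","never")`, nonnegative and summing to 1.
#' @export
shedding_trajectory_weights <- function(sens) {
  stopifnot(length(sens) == 4, all(sens >= 0 & sens <= 1))
  env <- cummax(sens)
  w <- c(diff(c(0, env)), 1 - env[4])
  names(w) <- c(SHIFT_STAGES, "never")
  w
}

#' Interception in an incidence (steady-state) screening round
#'
#' Distributes each class's incident cancers over (detected stage,
#' counterfactual clinical stage). A cancer destined for clinical diagnosis
#' at stage `s_clin` that begins shedding at onset stage `b <= s_clin` is
#' intercepted at the first stage `j >= b` at which a screen captures it,
#' with per-stage capture probabilities [stage_capture_prob()] treated as
#' independent across stages; mass still uncaptured when the clinical stage
#' ends is an interval/usual-care diagnosis. Same-stage detection
#' (`s_det == s_clin`) counts as screen-detected with zero stage shift.
#' Unstaged incidence is detected at "unstaged" with probability
#' `sens_IV * capture(d_IV)` and never stage-shifted.
#'
#' @param rates class x stage matrix of rates per 100,000 person-years
#'   (columns `STAGES`), e.g. from [stratum_incidence()].
#' @param perf a [test_performance()].
#' @param dwell a [dwell_scenario()].
#' @param cfg a [screening_config()].
#' @return An `interception_result`: list with `detected` (class x s_det x
#'   s_clin array of expected screen-detected counts per cohort),
#'   `not_detected` (class x s_clin matrix), `fp_total`, `incident`
#'   (class x s_clin matrix of cohort-scale case counts), `cohort_size`,
#'   `round`.
#' @export
incidence_round_interception <- function(rates, perf, dwell, cfg) {
  stopifnot(inherits(perf, "test_performance"),
            inherits(dwell, "dwell_scenario"),
            inherits(cfg, "screening_config"))
  cls <- rownames(rates)
  need <- cls[rowSums(rates) > 0]
  miss <- setdiff(need, intersect(rownames(perf$sens), rownames(dwell$d)))
  if (length(miss)) {
    stop("missing sensitivity or dwell for class(es) with nonzero incidence: ",
         paste(miss, collapse = ", "))
  }
  scale <- cfg$cohort_size / 1e5
  T <- cfg$screen_interval
  detected <- array(0, dim = c(length(cls), 5, 5),
                    dimnames = list(cls, STAGES, STAGES))
  not_detected <- matrix(0, length(cls), 5, dimnames = list(cls, STAGES))
  incident <- rates * scale
  for (cl in cls) {
    q <- stage_capture_prob(dwell$d[cl, ], T)
    w <- shedding_trajectory_weights(perf$sens[cl, ])
    env <- cummax(perf$sens[cl, ])
    for (j0 in 1:4) { # clinical stage index
      n <- incident[cl, j0]
      if (n == 0) next
      undet <- 0
      for (b in 1:4) { # shedding onset stage
        if (w[b] == 0) next
        if (b > j0) { undet <- undet + w[b]; next }
        surv <- 1 # prob not yet captured
        for (j in b:j0) {
          detected[cl, j, j0] <- detected[cl, j, j0] + n * w[b] * surv * q[j]
          surv <- surv * (1 - q[j])
        }
        undet <- undet + w[b] * surv
      }
      undet <- undet + w["never"]
      not_detected[cl, j0] <- not_detected[cl, j0] + n * undet
    }
    # unstaged: detectable with the stage-IV envelope, captured at d_IV pace
    n_u <- incident[cl, "unstaged"]
    if (n_u > 0) {
      p_u <- env[4] * q[4]
      detected[cl, "unstaged", "unstaged"] <- n_u * p_u
      not_detected[cl, "unstaged"] <- n_u * (1 - p_u)
    }
  }
  total_det <- sum(detected)
  fp_total <- perf$fp_rate * (cfg$cohort_size - total_det)
  structure(list(detected = detected, not_detected = not_detected,
                 fp_total = fp_total, incident = incident,
                 cohort_size = cfg$cohort_size, round = "incidence",
                 screen_interval = T),
            class = "interception_result")
}

#' Interception in a prevalence (first-screen) round
#'
#' The standing preclinical pool in stage `s` from cancers destined for
#' clinical diagnosis at `s_clin >= s` is length-biased: pool size equals
#' incidence flow times mean stage sojourn. The first screen detects a pool
#' member at its current stage with probability equal to the monotone
#' sensitivity envelope at that stage (the fraction already shedding); the
#' counterfactual clinical stage follows the forward progression the cancer
#' was on.
#'
#' @inheritParams incidence_round_interception
#' @return An `interception_result`; `incident` holds the preclinical pool
#'   (class x s_clin), the denominator conserved by
#'   `detected + not_detected`.
#' @export
prevalence_round_interception <- function(rates, perf, dwell, cfg) {
  stopifnot(inherits(perf, "test_performance"),
            inherits(dwell, "dwell_scenario"),
            inherits(cfg, "screening_config"))
  cls <- rownames(rates)
  scale <- cfg$cohort_size / 1e5
  detected <- array(0, dim = c(length(cls), 5, 5),
                    dimnames = list(cls, STAGES, STAGES))
  not_detected <- matrix(0, length(cls), 5, dimnames = list(cls, STAGES))
  pool_by_clin <- matrix(0, length(cls), 5, dimnames = list(cls, STAGES))
  for (cl in cls) {
    env <- cummax(perf$sens[cl, ])
    for (j0 in 1:4) {
      flow <- rates[cl, j0] * scale
      if (flow == 0) next
      for (s in 1:j0) {
        pool <- flow * dwell$d[cl, s]
        pool_by_clin[cl, j0] <- pool_by_clin[cl, j0] + pool
        detected[cl, s, j0] <- detected[cl, s, j0] + pool * env[s]
        not_detected[cl, j0] <- not_detected[cl, j0] + pool * (1 - env[s])
      }
    }
    flow_u <- rates[cl, "unstaged"] * scale
    if (flow_u > 0) {
      pool <- flow_u * dwell$d[cl, 4]
      pool_by_clin[cl, "unstaged"] <- pool
      detected[cl, "unstaged", "unstaged"] <- pool * env[4]
      not_detected[cl, "unstaged"] <- pool * (1 - env[4])
    }
  }
  total_det <- sum(detected)
  fp_total <- perf$fp_rate * (cfg$cohort_size - total_det)
  structure(list(detected = detected, not_detected = not_detected,
                 fp_total = fp_total, incident = pool_by_clin,
                 cohort_size = cfg$cohort_size, round = "prevalence",
                 screen_interval = cfg$screen_interval),
            class = "interception_result")
}

#' Per-class screen-detected totals
#' @param x an `interception_result`.
#' @return named numeric vector of expected detections per class.
#' @export
detected_by_class <- function(x) {
  stopifnot(inherits(x, "interception_result"))
  apply(x$detected, 1, sum)
}

#' @export
print.interception_result <- function(x, ...) {
  cat("MCED interception (", x$round, " round), cohort ",
      format(x$cohort_size, big.mark = ","), "\n", sep = "")
  cat("  screen-detected cancers:", format(sum(x$detected), digits = 5), "\n")
  cat("  not screen-detected:    ", format(sum(x$not_detected), digits = 5), "\n")
  cat("  expected false positives:", format(x$fp_total, digits = 5), "\n")
  invisible(x)
}
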