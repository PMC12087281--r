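#' Stage-resolved 5-year survival table
#'
#' @param s5 numeric matrix, class x stage (columns `STAGES`; the
#'   `"unstaged"` column may be `NA`), of 5-year cancer-specific survival
#'   probabilities. Survival should be non-increasing in stage within each
#'   class; violations are kept but reported with a warning (they arise from
#'   registry noise and are handled downstream by clamping negative
#'   survival gaps to zero).
#' @param os optional data frame `sex,age_lo,age_hi,os5` of 5-year all-cause
#'   survival by age band, used to account for competing risks.
#' @return a `survival_table` list.
#' @export
survival_table <- function(s5, os = NULL) {
  s5 <- as.matrix(s5)
  if (is.null(colnames(s5))) colnames(s5) <- STAGES
  if (!all(SHIFT_STAGES %in% colnames(s5))) {
    stop("s5 must have columns for stages I-IV")
  }
  if (!"unstaged" %in% colnames(s5)) {
    s5 <- cbind(s5, unstaged = NA_real_)
  }
  s5 <- s5[, STAGES, drop = FALSE]
  vals <- s5[is.finite(s5)]
  if (any(vals < 0 | vals > 1)) stop("survival probabilities must be in [0,1]")
  inc <- apply(s5[, SHIFT_STAGES, drop = FALSE], 1, function(r) {
    r <- r[is.finite(r)]
    length(r) > 1 && any(diff(r) > 1e-12)
  })
  if (any(inc)) {
    warning("5-year survival increases with stage for class(es): ",
            paste(rownames(s5)[inc], collapse = ", "),
            " (negative stage-shift gaps will be clamped to zero)")
  }
  if (!is.null(os)) {
    stopifnot(all(c("sex", "age_lo", "age_hi", "os5") %in% names(os)),
              all(os$os5 >= 0 & os$os5 <= 1))
  }
  structure(list(s5 = s5, os = os), class = "survival_table")
}

#' Read a survival table from delimited files
#' @param s5_path file with header `cancer_class,stage,s5`.
#' @param os_path optional file with header `sex,age_lo,age_hi,os5`.
#' @return a [survival_table()].
#' @export
load_survival <- function(s5_path, os_path = NULL) {
  d <- utils::read.csv(s5_path, stringsAsFactors = FALSE)
  cls <- unique(d$cancer_class)
  s5 <- matrix(NA_real_, length(cls), length(STAGES),
               dimnames = list(cls, STAGES))
  s5[cbind(d$cancer_class, d$stage)] <- d$s5
  os <- if (!is.null(os_path)) utils::read.csv(os_path,
                                               stringsAsFactors = FALSE)
  suppressWarnings(survival_table(s5, os))
}

# internal: per-class expected lives saved from stage shift, using a
# (possibly adjusted) survival matrix for the detected arm and the observed
# matrix for the counterfactual clinical arm. Negative gaps clamp to zero.
# Returns list(lives = named vector, excluded = classes lacking survival).
class_lives <- function(interception, s5_det_arm, s5_clin_arm) {
  cls <- dimnames(interception$detected)[[1]]
  lives <- stats::setNames(numeric(length(cls)), cls)
  excluded <- character(0)
  for (cl in cls) {
    det <- interception$detected[cl, SHIFT_STAGES, SHIFT_STAGES]
    if (sum(det) == 0) next
    if (!cl %in% rownames(s5_clin_arm) ||
        anyNA(s5_clin_arm[cl, SHIFT_STAGES]) ||
        anyNA(s5_det_arm[cl, SHIFT_STAGES])) {
      excluded <- c(excluded, cl)
      lives[cl] <- NA_real_
      next
    }
    gap <- outer(s5_det_arm[cl, SHIFT_STAGES],
                 s5_clin_arm[cl, SHIFT_STAGES], `-`)
    gap[gap < 0] <- 0
    lives[cl] <- sum(det * gap)
  }
  list(lives = lives, excluded = excluded)
}

# internal: spread per-class lives over predicted CSOs with the confusion
# weights already embedded in tp_by_class, splitting matched vs cross-talk.
spread_lives <- function(strat, registry, lives) {
  labs <- strat$labels
  det <- detected_by_class(strat$interception)
  map <- cso_map(registry)[names(det)]
  frac <- strat$tp_by_class / ifelse(det > 0, det, 1) # class share per CSO
  lives_first <- stats::setNames(numeric(length(labs)), labs)
  lives_post <- lives_first
  for (o in labs) {
    match_cls <- names(map)[map == o]
    cross_cls <- names(map)[map != o]
    lf <- lives[match_cls] * frac[match_cls, o]
    lp <- lives[cross_cls] * frac[cross_cls, o]
    lives_first[o] <- sum(lf, na.rm = TRUE)
    lives_post[o] <- sum(lp, na.rm = TRUE)
  }
  list(first = lives_first, post = lives_post)
}

#' Lives saved by stage shift, per predicted CSO
#'
#' Each intercepted cancer contributes the increment in 5-year
#' cancer-specific survival between its detected stage and its
#' counterfactual clinical stage (negative increments, arising from noisy
#' stage-specific survival, clamp to zero). `lives_first` accrues the
#' matched cancers found by the CSO-directed step; `lives_post` accrues
#' cross-talk cancers found by the later general step. Classes without
#' stage-resolved survival are excluded and flagged, never silently zeroed.
#'
#' @param strat a `cso_stratified`.
#' @param surv a [survival_table()].
#' @param registry the `cso_registry`.
#' @return an `outcome_lives` list: `lives_first`, `lives_post` (per CSO),
#'   `class_lives` (per class, NA where excluded), `excluded_classes`,
#'   `variant`.
#' @export
stage_shift_lives_saved <- function(strat, surv, registry) {
  stopifnot(inherits(strat, "cso_stratified"),
            inherits(surv, "survival_table"))
  cl <- class_lives(strat$interception, surv$s5, surv$s5)
  sp <- spread_lives(strat, registry, cl$lives)
  structure(list(lives_first = sp$first, lives_post = sp$post,
                 class_lives = cl$lives, excluded_classes = cl$excluded,
                 variant = "baseline"),
            class = "outcome_lives")
}

#' Competing-risk (overall survival) adjusted lives saved
#'
#' Each cancer's survival increment is multiplied by the stratum age band's
#' 5-year all-cause survival, discounting benefit by the chance of dying of
#' other causes. Always less than or equal to the unadjusted value.
#'
#' @inheritParams stage_shift_lives_saved
#' @param sex,age_lo stratum identifiers used to look up all-cause survival.
#' @return an `outcome_lives` list, `variant = "os"`.
#' @export
os_adjusted_lives <- function(strat, surv, registry, sex, age_lo) {
  if (is.null(surv$os)) stop("survival table carries no all-cause (OS) data")
  hit <- surv$os$sex == sex & surv$os$age_lo == age_lo
  if (!any(hit)) {
    stop("no all-cause survival for stratum (", sex, ", ", age_lo, ")")
  }
  os5 <- surv$os$os5[which(hit)[1]]
  base <- stage_shift_lives_saved(strat, surv, registry)
  base$lives_first <- base$lives_first * os5
  base$lives_post <- base$lives_post * os5
  base$class_lives <- base$class_lives * os5
  base$variant <- "os"
  base$os5 <- os5
  base
}

#' Split mixture survival into detectable / non-detectable subgroups
#'
#' Postulates a proportional-hazards penalty `h > 1` for ctDNA-detectable
#' cancers relative to non-detectable ones while preserving the observed
#' mixture survival: on the 5-year scale, `s_det = s^(h*k)` and
#' `s_non = s^k` with `k > 0` solving
#' `f * s^(h*k) + (1 - f) * s^k = s` for detectable fraction `f`.
#'
#' @param s5_mix observed (mixture) 5-year survival in (0, 1); vectorized.
#' @param detectable_fraction fraction of cases that are ctDNA-detectable,
#'   in (0, 1).
#' @param h hazard ratio for detectable vs non-detectable cases, >= 1.
#' @return list with numeric vectors `s5_detectable`, `s5_nondetectable`
#'   (elementwise; equal to `s5_mix` where `h == 1` or survival is 0/1).
#' @export
hr_split_survival <- function(s5_mix, detectable_fraction, h) {
  stopifnot(detectable_fraction > 0, detectable_fraction < 1, h >= 1)
  f <- detectable_fraction
  solve1 <- function(s) {
    if (!is.finite(s)) return(c(NA_real_, NA_real_))
    if (h == 1 || s <= 0 || s >= 1) return(c(s, s))
    g <- function(k) f * s^(h * k) + (1 - f) * s^k - s
    # g(0) = 1 - s > 0; g decreasing in k; bracket upward from k = 1
    hi <- 1
    while (g(hi) > 0 && hi < 1e6) hi <- hi * 2
    if (g(hi) > 0) stop("no root for hr_split_survival at s5 = ", s)
    k <- stats::uniroot(g, c(0, hi), tol = 1e-12)$root
    c(s^(h * k), s^k)
  }
  res <- vapply(s5_mix, solve1, numeric(2))
  list(s5_detectable = stats::setNames(res[1, ], names(s5_mix)),
       s5_nondetectable = stats::setNames(res[2, ], names(s5_mix)))
}

#' Hazard-ratio-adjusted lives saved
#'
#' Sensitivity variant in which screen-detected (hence ctDNA-shedding)
#' cancers carry the worse detectable-subgroup survival at their detected
#' stage, while the counterfactual clinical arm keeps the observed
#' stage-specific survival. Because the detectable subgroup's survival never
#' exceeds the mixture, this variant never increases lives saved.
#'
#' @inheritParams stage_shift_lives_saved
#' @param perf the [test_performance()] used upstream; the per-stage
#'   detectable fraction is the monotone sensitivity envelope.
#' @param h hazard ratio >= 1 for detectable cancers.
#' @return an `outcome_lives` list, `variant = "hr"`.
#' @export
hr_adjusted_lives <- function(strat, surv, registry, perf, h) {
  stopifnot(h >= 1)
  s5_det_arm <- surv$s5
  for (cl in rownames(s5_det_arm)) {
    if (!cl %in% rownames(perf$sens)) next
    env <- cummax(perf$sens[cl, ])
    for (j in seq_along(SHIFT_STAGES)) {
      f <- env[j]
      s <- surv$s5[cl, j]
      if (!is.finite(s) || f <= 0 || h == 1) next
      if (f >= 1) { s5_det_arm[cl, j] <- s; next }
      s5_det_arm[cl, j] <- hr_split_survival(s, f, h)$s5_detectable
    }
  }
  cl <- class_lives(strat$interception, s5_det_arm, surv$s5)
  sp <- spread_lives(strat, registry, cl$lives)
  structure(list(lives_first = sp$first, lives_post = sp$post,
                 class_lives = cl$lives, excluded_classes = cl$excluded,
                 variant = "hr", h = h),
            class = "outcome_lives")
}

#' Diagnostic tests per life saved
#'
#' Every individual entering a predicted-CSO pool consumes one CSO-directed
#' test; everyone not resolved by it (all but the matched true positives)
#' consumes one general test. The ratios tests/lives are reported per tier
#' and compared with a benchmark of diagnostic procedures per life saved
#' (default 240, the modeled figure for diagnostic mammography). Zero lives
#' saved yields a flagged undefined ratio (NA), not infinity.
#'
#' @param lives an `outcome_lives` from [stage_shift_lives_saved()] or a
#'   variant.
#' @param chain a `chain_metrics` from [chain_ppvs()].
#' @param benchmark reference tests-per-life value (> 0), default 240.
#' @return an `outcome_metrics` data frame per CSO: `lives_first`,
#'   `lives_post`, `tests_first`, `tests_post`, `tests_per_life_first`,
#'   `tests_per_life_post`, `beats_benchmark_first/_post`.
#' @export
tests_per_life <- function(lives, chain, benchmark = 240) {
  stopifnot(inherits(lives, "outcome_lives"), benchmark > 0)
  labs <- chain$predicted_cso
  lf <- lives$lives_first[labs]
  lp <- lives$lives_post[labs]
  tf <- chain$n_pool
  tp <- chain$n_pool - chain$n_match
  ratio <- function(tests, l) ifelse(is.finite(l) & l > 0, tests / l, NA_real_)
  out <- data.frame(
    predicted_cso = labs,
    lives_first = lf, lives_post = lp,
    tests_first = tf, tests_post = tp,
    tests_per_life_first = ratio(tf, lf),
    tests_per_life_post = ratio(tp, lp),
    stringsAsFactors = FALSE)
  out$beats_benchmark_first <- out$tests_per_life_first <= benchmark
  out$beats_benchmark_post <- out$tests_per_life_post <= benchmark
  attr(out, "benchmark") <- benchmark
  attr(out, "variant") <- lives$variant
  class(out) <- c("outcome_metrics", "data.frame")
  out
}
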