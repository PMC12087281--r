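#' Three-tier PPV of the CSO-directed diagnostic chain
#'
#' For each predicted CSO pool the chain applies first a CSO-directed test
#' (assumed 100% sensitive for cancers of the matching type and 0% for
#' others), then a general non-site-specific test. With `A` the expected
#' true positives of any type in the pool, `M` those whose clinical CSO
#' matches the prediction, and `F` the false positives:
#' `ppv_any = A/(A+F)` (entering the chain), `ppv_first = M/(A+F)` (yield of
#' the directed step), and `ppv_remaining = (A-M)/((A-M)+F)` (cancer risk
#' among individuals left after the matched cancer is ruled out; false
#' positives stay in the pool until a general test resolves them).
#'
#' @param strat a `cso_stratified` from [stratify_positives()].
#' @param registry the `cso_registry` used upstream.
#' @return a `chain_metrics` data frame, one row per predicted CSO, columns
#'   `predicted_cso`, `n_pool`, `n_any` (A), `n_match` (M), `n_fp` (F),
#'   `ppv_any`, `ppv_first`, `ppv_remaining` (NA with `defined = FALSE` for
#'   an empty pool, never a silent zero).
#' @export
chain_ppvs <- function(strat, registry) {
  stopifnot(inherits(strat, "cso_stratified"))
  labs <- strat$labels
  map <- cso_map(registry)[rownames(strat$tp_by_class)]
  A <- colSums(strat$tp_by_class)
  M <- vapply(labs, function(o) {
    sum(strat$tp_by_class[names(map)[map == o], o])
  }, numeric(1))
  F <- strat$fp[labs]
  pool <- A + F
  defined <- pool > 0
  rem <- A - M
  out <- data.frame(
    predicted_cso = labs,
    n_pool = pool,
    n_any = A,
    n_match = M,
    n_fp = F,
    ppv_any = ifelse(defined, A / pool, NA_real_),
    ppv_first = ifelse(defined, M / pool, NA_real_),
    ppv_remaining = ifelse(rem + F > 0, rem / (rem + F), NA_real_),
    defined = defined,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("chain_metrics", "data.frame")
  out
}

#' Modelability flags per predicted CSO
#'
#' A CSO is excluded from summaries when the validation evidence cannot
#' support it: no evidence of detectable signal for any class mapping to it
#' (all sensitivities zero), no successful CSO prediction (zero diagonal
#' confusion count), or no stage-resolved survival for its classes.
#'
#' @param perf a [test_performance()].
#' @param counts a [confusion_counts()].
#' @param survival a [survival_table()] or `NULL`.
#' @param registry the `cso_registry`.
#' @return data frame per CSO with logical columns `detectable`,
#'   `cso_predictable`, `survival_available`, and `modelable` (their
#'   conjunction; `survival_available` is ignored when no survival table is
#'   supplied).
#' @export
modelable_cso_flags <- function(perf, counts, survival = NULL, registry) {
  labs <- counts$labels
  map <- cso_map(registry)
  flags <- data.frame(predicted_cso = labs, stringsAsFactors = FALSE)
  flags$detectable <- vapply(labs, function(o) {
    cls <- names(map)[map == o]
    cls <- intersect(cls, rownames(perf$sens))
    length(cls) > 0 && any(perf$sens[cls, , drop = FALSE] > 0)
  }, logical(1))
  flags$cso_predictable <- diag(counts$n)[labs] > 0
  if (is.null(survival)) {
    flags$survival_available <- NA
    flags$modelable <- flags$detectable & flags$cso_predictable
  } else {
    flags$survival_available <- vapply(labs, function(o) {
      cls <- names(map)[map == o]
      cls <- intersect(cls, rownames(survival$s5))
      length(cls) > 0 &&
        all(is.finite(survival$s5[cls, SHIFT_STAGES]))
    }, logical(1))
    flags$modelable <- flags$detectable & flags$cso_predictable &
      flags$survival_available
  }
  rownames(flags) <- NULL
  flags
}

#' Median and range of a per-CSO metric
#'
#' @param metrics a `chain_metrics` (or any per-CSO data frame).
#' @param statistic column name to summarize (default `"ppv_any"`).
#' @param include optional logical vector / CSO label subset restricting the
#'   summary to modelable CSOs, as in the headline summaries.
#' @return list with `median`, `min`, `max`, `argmin`, `argmax`, `n`,
#'   `included` (labels used). Even-count medians are the mean of the
#'   central pair.
#' @export
summarize_across_csos <- function(metrics, statistic = "ppv_any",
                                  include = NULL) {
  stopifnot(statistic %in% names(metrics))
  keep <- rep(TRUE, nrow(metrics))
  if (!is.null(include)) {
    keep <- if (is.logical(include)) include
    else metrics$predicted_cso %in% include
  }
  v <- metrics[[statistic]][keep]
  labs <- metrics$predicted_cso[keep]
  ok <- is.finite(v)
  v <- v[ok]; labs <- labs[ok]
  if (!length(v)) stop("no defined values to summarize for ", statistic)
  list(median = stats::median(v),
       min = min(v), max = max(v),
       argmin = labs[which.min(v)], argmax = labs[which.max(v)],
       n = length(v), included = labs)
}

#' Per-CSO pass/fail against a PPV workup threshold
#'
#' The threshold (default 7%, a minimal reasonable cancer risk justifying
#' diagnostic workup) is compared inclusively: a PPV exactly at the line
#' passes.
#'
#' @param metrics a `chain_metrics`.
#' @param threshold PPV threshold in (0, 1), default 0.07.
#' @return data frame per CSO with logical `pass_any`, `pass_first`,
#'   `pass_remaining` (NA where the PPV is undefined).
#' @export
threshold_report <- function(metrics, threshold = 0.07) {
  stopifnot(threshold > 0, threshold < 1)
  data.frame(predicted_cso = metrics$predicted_cso,
             pass_any = metrics$ppv_any >= threshold,
             pass_first = metrics$ppv_first >= threshold,
             pass_remaining = metrics$ppv_remaining >= threshold,
             stringsAsFactors = FALSE)
}
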