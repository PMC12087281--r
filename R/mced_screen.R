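#' Fit the MCED screening benefit model for one population stratum
#'
#' Runs the full interception pipeline for a (sex, age band, smoking status)
#' slice: stratified incidence -> screen interception by stage ->
#' CSO stratification of all positives -> diagnostic-chain PPVs ->
#' stage-shift lives saved and tests per life saved -> workup strategy
#' comparison. The returned object is queried with `print()`, `summary()`,
#' `plot()` and `simulate()` (the individual-level Monte-Carlo oracle).
#'
#' @param incidence an `incidence_table` (see [load_incidence()]) with
#'   `smoking = "any"` rows (and/or pre-adjusted rows for the requested
#'   status).
#' @param perf a [test_performance()].
#' @param counts a [confusion_counts()].
#' @param dwell a [dwell_scenario()].
#' @param surv a [survival_table()] or `NULL` (PPVs only).
#' @param registry a [cancer_registry()]; defaults to [default_registry()].
#' @param sex,age_lo,smoking stratum selector. If `smoking` is not `"any"`
#'   and the table has no rows for it, `smoking_risk` must be supplied and
#'   the adjustment is applied on the fly.
#' @param smoking_risk optional [smoking_risk()] object.
#' @param alpha pseudo-count weight for confusion smoothing (default 1).
#' @param round `"incidence"` or `"prevalence"` screening round.
#' @param screen_interval years between screens (default 1).
#' @param cohort_size persons in the stratum cohort (default 100,000).
#' @param threshold PPV workup threshold (default 0.07).
#' @param benchmark tests-per-life reference (default 240, diagnostic
#'   mammography).
#' @return an object of class `mced_screen` with components
#'   `interception`, `stratified`, `chain` (per-CSO PPV table), `flags`,
#'   `lives`, `outcomes` (per-CSO tests-per-life table), `strategy`,
#'   `breakeven`, plus the inputs under `$inputs` for refitting.
#' @examples
#' syn <- generate_synthetic_inputs(seed = 7)
#' fit <- mced_screen(syn$incidence, syn$perf, syn$counts, syn$dwell$default,
#'                    syn$surv, syn$registry, sex = "female", age_lo = 65)
#' summary(fit)
#' @export
mced_screen <- function(incidence, perf, counts, dwell, surv = NULL,
                        registry = default_registry(),
                        sex = "female", age_lo = 65, smoking = "any",
                        smoking_risk = NULL, alpha = 1,
                        round = c("incidence", "prevalence"),
                        screen_interval = 1, cohort_size = 1e5,
                        threshold = 0.07, benchmark = 240) {
  round <- match.arg(round)
  inc <- incidence
  has_status <- any(inc$sex == sex & inc$age_lo == age_lo &
                      inc$smoking == smoking)
  if (!has_status && smoking != "any") {
    if (is.null(smoking_risk)) {
      stop("stratum smoking status '", smoking,
           "' absent from table and no smoking_risk supplied")
    }
    inc <- apply_smoking_adjustment(incidence, smoking_risk, smoking)
  }
  rates <- stratum_incidence(inc, sex, age_lo, smoking)
  cfg <- screening_config(screen_interval, cohort_size, round)
  interception <- if (round == "incidence") {
    incidence_round_interception(rates, perf, dwell, cfg)
  } else {
    prevalence_round_interception(rates, perf, dwell, cfg)
  }
  model <- cso_model(counts, alpha)
  stratified <- stratify_positives(interception, model, registry)
  chain <- chain_ppvs(stratified, registry)
  flags <- modelable_cso_flags(perf, counts, surv, registry)
  lives <- NULL; outcomes <- NULL; strategy <- NULL; breakeven <- NULL
  if (!is.null(surv)) {
    lives <- stage_shift_lives_saved(stratified, surv, registry)
    outcomes <- tests_per_life(lives, chain, benchmark)
    strategy <- strategy_compare(chain, lives)
    breakeven <- expense_breakeven_ratio(strategy)
  }
  structure(list(
    stratum = list(sex = sex, age_lo = age_lo, age_hi = age_lo + 5,
                   smoking = smoking),
    interception = interception,
    model = model,
    stratified = stratified,
    chain = chain,
    flags = flags,
    lives = lives,
    outcomes = outcomes,
    strategy = strategy,
    breakeven = breakeven,
    threshold = threshold,
    benchmark = benchmark,
    inputs = list(rates = rates, perf = perf, counts = counts, dwell = dwell,
                  surv = surv, registry = registry, alpha = alpha, cfg = cfg),
    call = match.call()),
    class = "mced_screen")
}

# internal: refit with selected inputs replaced (used by uncertainty and
# dwell-scenario machinery; cheap because stratification is already done)
refit_mced <- function(object, perf = NULL, dwell = NULL, model = NULL) {
  inp <- object$inputs
  perf <- perf %||% inp$perf
  dwell <- dwell %||% inp$dwell
  interception <- if (object$interception$round == "incidence") {
    incidence_round_interception(inp$rates, perf, dwell, inp$cfg)
  } else {
    prevalence_round_interception(inp$rates, perf, dwell, inp$cfg)
  }
  model <- model %||% object$model
  stratified <- stratify_positives(interception, model, inp$registry)
  chain <- chain_ppvs(stratified, inp$registry)
  lives <- NULL; outcomes <- NULL
  if (!is.null(inp$surv)) {
    lives <- stage_shift_lives_saved(stratified, inp$surv, inp$registry)
    outcomes <- tests_per_life(lives, chain, object$benchmark)
  }
  list(interception = interception, stratified = stratified, chain = chain,
       lives = lives, outcomes = outcomes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mced_screen <- function(x, ...) {
  s <- x$stratum
  cat("MCED screening benefit model (", x$interception$round,
      " round)\n", sep = "")
  cat("  stratum: ", s$sex, ", ages ", s$age_lo, "-", s$age_hi - 1,
      ", smoking ", s$smoking, "\n", sep = "")
  cat("  cohort ", format(x$interception$cohort_size, big.mark = ","),
      ": ", format(sum(x$interception$detected), digits = 4),
      " screen-detected cancers, ",
      format(x$interception$fp_total, digits = 4),
      " false positives\n", sep = "")
  inc <- x$flags$modelable
  sm <- tryCatch(summarize_across_csos(x$chain, "ppv_any",
                                       include = x$flags$predicted_cso[inc]),
                 error = function(e) NULL)
  if (!is.null(sm)) {
    cat("  PPV (any cancer) across ", sm$n, " modelable CSOs: median ",
        sprintf("%.1f%%", 100 * sm$median), " (", sm$argmin, " ",
        sprintf("%.0f%%", 100 * sm$min), ", ", sm$argmax, " ",
        sprintf("%.0f%%", 100 * sm$max), ")\n", sep = "")
  }
  invisible(x)
}

#' Summarize a fitted MCED screening model
#'
#' Medians and ranges across modelable CSOs for the three PPV tiers and the
#' tests-per-life ratios, mirroring the headline reporting shape.
#'
#' @param object an `mced_screen`.
#' @param ... unused.
#' @return a `summary.mced_screen` list with the per-CSO table and the
#'   cross-CSO summaries.
#' @export
summary.mced_screen <- function(object, ...) {
  inc <- object$flags$modelable
  keep <- object$flags$predicted_cso[inc]
  tiers <- c("ppv_any", "ppv_first", "ppv_remaining")
  safe_sum <- function(metrics, st) {
    tryCatch(summarize_across_csos(metrics, st, include = keep),
             error = function(e) NULL)
  }
  ppv <- lapply(tiers, function(st) safe_sum(object$chain, st))
  names(ppv) <- tiers
  tpl <- NULL
  if (!is.null(object$outcomes)) {
    tpl <- lapply(c("tests_per_life_first", "tests_per_life_post"),
                  function(st) safe_sum(object$outcomes, st))
    names(tpl) <- c("tests_per_life_first", "tests_per_life_post")
  }
  tab <- merge(object$chain,
               object$outcomes %||%
                 data.frame(predicted_cso = object$chain$predicted_cso),
               by = "predicted_cso", sort = FALSE)
  tab <- merge(tab, object$flags, by = "predicted_cso", sort = FALSE)
  structure(list(stratum = object$stratum, table = tab, ppv = ppv,
                 tests_per_life = tpl, threshold = object$threshold,
                 benchmark = object$benchmark, strategy = object$strategy,
                 breakeven = object$breakeven,
                 n_modelable = sum(inc), n_cso = nrow(object$flags)),
            class = "summary.mced_screen")
}

#' @export
print.summary.mced_screen <- function(x, ...) {
  s <- x$stratum
  cat("MCED screening benefit, ", s$sex, " ", s$age_lo, "-", s$age_hi - 1,
      " (smoking ", s$smoking, "); ", x$n_modelable, "/", x$n_cso,
      " CSOs modelable\n\n", sep = "")
  fmt <- function(sm, pct = TRUE) {
    if (is.null(sm)) return("(no defined values)")
    f <- if (pct) function(v) sprintf("%.1f%%", 100 * v)
    else function(v) sprintf("%.1f", v)
    paste0("median ", f(sm$median), "  range ", f(sm$min), " (", sm$argmin,
           ") to ", f(sm$max), " (", sm$argmax, ")")
  }
  cat("PPV any cancer:   ", fmt(x$ppv$ppv_any), "\n")
  cat("PPV first (CSO):  ", fmt(x$ppv$ppv_first), "\n")
  cat("PPV remaining:    ", fmt(x$ppv$ppv_remaining), "\n")
  if (!is.null(x$tests_per_life)) {
    cat("Directed tests per life saved: ",
        fmt(x$tests_per_life$tests_per_life_first, pct = FALSE),
        "  [benchmark ", x$benchmark, "]\n", sep = "")
    cat("General tests per life saved:  ",
        fmt(x$tests_per_life$tests_per_life_post, pct = FALSE), "\n")
  }
  if (!is.null(x$strategy)) {
    cat("\nWorkup strategies (pooled over CSOs):\n")
    print(x$strategy, row.names = FALSE, digits = 4)
    if (is.finite(x$breakeven)) {
      cat("Expense break-even (general:directed cost ratio): ",
          sprintf("%.3g", x$breakeven), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Bar plot of chain PPVs or tests per life saved
#'
#' @param x an `mced_screen`.
#' @param what `"ppv"` (three tiers with the workup-threshold line) or
#'   `"tests_per_life"` (directed/general with the benchmark line; CSOs
#'   with undefined ratios have no bar).
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the matrix plotted.
#' @export
plot.mced_screen <- function(x, what = c("ppv", "tests_per_life"), ...) {
  what <- match.arg(what)
  op <- graphics::par(mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  if (what == "ppv") {
    m <- t(as.matrix(x$chain[, c("ppv_any", "ppv_first", "ppv_remaining")]))
    colnames(m) <- x$chain$predicted_cso
    graphics::barplot(m, beside = TRUE, las = 2,
                      col = c("grey25", "grey55", "grey85"),
                      ylab = "PPV", legend.text = c("any", "first", "remaining"),
                      ...)
    graphics::abline(h = x$threshold, lty = 2)
  } else {
    if (is.null(x$outcomes)) stop("no survival table: outcomes not fitted")
    m <- t(as.matrix(x$outcomes[, c("tests_per_life_first",
                                    "tests_per_life_post")]))
    colnames(m) <- x$outcomes$predicted_cso
    graphics::barplot(m, beside = TRUE, las = 2, col = c("grey25", "grey70"),
                      ylab = "diagnostic tests per life saved",
                      legend.text = c("directed", "general"), ...)
    graphics::abline(h = x$benchmark, lty = 2)
  }
  invisible(m)
}
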