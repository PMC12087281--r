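#' Compare diagnostic workup strategies
#'
#' Three strategies over the same positive pool:
#' \describe{
#'   \item{directed_then_general}{CSO-directed test first, then a general
#'     test for everyone unresolved; all true positives are found.}
#'   \item{directed_only}{workup stops after the CSO-directed step;
#'     cross-talk true positives stay undiagnosed, leaving residual risk.}
#'   \item{general_only}{CSO information ignored; everyone gets a general
#'     test, which finds every cancer.}
#' }
#' Lives follow the 100%-sensitivity assumption of the chain model, so
#' `lives(directed_only) <= lives(directed_then_general) =
#' lives(general_only)`.
#'
#' @param chain a `chain_metrics` from [chain_ppvs()].
#' @param lives an `outcome_lives`.
#' @return a `strategy_comparison` data frame, one row per strategy, columns
#'   `strategy`, `directed_tests`, `general_tests`, `lives_saved`,
#'   `residual_tp`, `residual_risk`.
#' @export
strategy_compare <- function(chain, lives) {
  stopifnot(inherits(chain, "chain_metrics"),
            inherits(lives, "outcome_lives"))
  labs <- chain$predicted_cso
  pool <- sum(chain$n_pool)
  M <- sum(chain$n_match)
  A <- sum(chain$n_any)
  F <- sum(chain$n_fp)
  lf <- sum(lives$lives_first[labs], na.rm = TRUE)
  lp <- sum(lives$lives_post[labs], na.rm = TRUE)
  crosstalk <- A - M
  out <- data.frame(
    strategy = c("directed_then_general", "directed_only", "general_only"),
    directed_tests = c(pool, pool, 0),
    general_tests = c(pool - M, 0, pool),
    lives_saved = c(lf + lp, lf, lf + lp),
    residual_tp = c(0, crosstalk, 0),
    residual_risk = c(0,
                      if (crosstalk + F > 0) crosstalk / (crosstalk + F) else 0,
                      0),
    stringsAsFactors = FALSE)
  class(out) <- c("strategy_comparison", "data.frame")
  out
}

#' Per-CSO residual risk when workup stops after the directed step
#'
#' Identical to `ppv_remaining` by construction; emitted separately because
#' the pooled residual risk of [strategy_compare()] hides CSO-level
#' variation.
#'
#' @param chain a `chain_metrics`.
#' @return named numeric vector per predicted CSO.
#' @export
directed_only_residual_risk <- function(chain) {
  stats::setNames(chain$ppv_remaining, chain$predicted_cso)
}

#' Expense break-even ratio between workup strategies
#'
#' The general:directed cost ratio `r*` at which the total expense of
#' directed-then-general equals that of general-only:
#' `directed_A + r * general_A = r * general_C`, i.e.
#' `r* = directed_A / (general_C - general_A)`. Above `r*` the CSO-directed
#' strategy is cheaper. Scale-invariant in the test counts; undefined
#' (flagged NA) when the two strategies use the same number of general
#' tests.
#'
#' @param comparison a `strategy_comparison` from [strategy_compare()].
#' @return single numeric `r*`, or `NA` with attribute `reason` when
#'   undefined.
#' @export
expense_breakeven_ratio <- function(comparison) {
  stopifnot(inherits(comparison, "strategy_comparison"))
  a <- comparison[comparison$strategy == "directed_then_general", ]
  c_ <- comparison[comparison$strategy == "general_only", ]
  denom <- c_$general_tests - a$general_tests
  if (denom <= 0) {
    return(structure(NA_real_, reason = "equal general-test counts"))
  }
  a$directed_tests / denom
}
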