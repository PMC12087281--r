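#' Posterior specification for input-parameter uncertainty
#'
#' Binomial-style counts behind the point estimates of the external
#' validation study: per-class per-stage detection counts behind the
#' sensitivities, false-positive counts among non-cancer participants
#' behind the FP rate, and the CSO confusion counts.
#'
#' @param sens_detected,sens_total class x stage (I--IV) integer matrices:
#'   cases detected / cases assayed.
#' @param fp,n_noncancer false-positive count and non-cancer total.
#' @param counts a [confusion_counts()].
#' @param alpha pseudo-count weight used for the Dirichlet prior on
#'   confusion rows (default 1).
#' @return a `posterior_spec` list.
#' @export
posterior_spec <- function(sens_detected, sens_total, fp, n_noncancer,
                           counts, alpha = 1) {
  sens_detected <- as.matrix(sens_detected)
  sens_total <- as.matrix(sens_total)
  stopifnot(identical(dim(sens_detected), dim(sens_total)),
            all(sens_detected >= 0), all(sens_total >= sens_detected),
            fp >= 0, n_noncancer >= fp,
            inherits(counts, "confusion_counts"), alpha > 0)
  structure(list(sens_detected = sens_detected, sens_total = sens_total,
                 fp = fp, n_noncancer = n_noncancer, counts = counts,
                 alpha = alpha),
            class = "posterior_spec")
}

#' Build a posterior spec for a synthetic truth
#'
#' Fabricates validation-study counts consistent with the truth's parameter
#' values at a chosen study size (detected counts are the rounded expected
#' values, so point estimates are recovered up to rounding).
#'
#' @param truth a `synthetic_truth`.
#' @param n_per_cell cases assayed per class-stage cell (default 60).
#' @param n_noncancer non-cancer participants (default 2000).
#' @return a `posterior_spec`.
#' @export
posterior_spec_from_truth <- function(truth, n_per_cell = 60,
                                      n_noncancer = 2000) {
  tot <- truth$perf$sens * 0 + n_per_cell
  det <- round(truth$perf$sens * tot)
  posterior_spec(det, tot, fp = round(truth$fp_rate * n_noncancer),
                 n_noncancer = n_noncancer, counts = truth$counts,
                 alpha = truth$alpha)
}

# internal: one Dirichlet draw via normalized gammas
rdirichlet1 <- function(a) {
  g <- stats::rgamma(length(a), shape = a)
  if (sum(g) == 0) { g[] <- 1 } # all-zero shapes cannot occur after smoothing
  g / sum(g)
}

#' Draws from the posterior of test-performance and CSO parameters
#'
#' Sensitivities are drawn per cell from conjugate
#' `Beta(detected + 1/2, misses + 1/2)` (Jeffreys prior), the FP rate from
#' `Beta(fp + 1/2, true negatives + 1/2)`, and each confusion row (and the
#' FP CSO distribution) from `Dirichlet(counts + alpha * prior_freq)`.
#' Reproducible under a fixed seed.
#'
#' @param spec a [posterior_spec()].
#' @param R number of draws (>= 1).
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @param blocks which input blocks to resample; the others stay at their
#'   point estimates. Any subset of `c("sens", "fp", "confusion")`.
#' @param point the point-estimate pair `list(perf=, model=)`; computed
#'   from the spec when omitted.
#' @return list of `R` draws, each `list(perf = test_performance,
#'   model = cso_model)`.
#' @export
posterior_draws <- function(spec, R = 500, seed = NULL,
                            blocks = c("sens", "fp", "confusion"),
                            point = NULL) {
  stopifnot(inherits(spec, "posterior_spec"), R >= 1)
  blocks <- match.arg(blocks, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(point)) point <- posterior_point(spec)
  labs <- spec$counts$labels
  prior <- spec$counts$prior_freq
  a_conf <- spec$counts$n + matrix(spec$alpha * prior, nrow(spec$counts$n),
                                   ncol(spec$counts$n), byrow = TRUE)
  a_fp <- spec$counts$fp_counts + spec$alpha * prior
  lapply(seq_len(R), function(r) {
    perf <- point$perf
    model <- point$model
    if ("sens" %in% blocks) {
      det <- spec$sens_detected
      mis <- spec$sens_total - det
      s <- matrix(stats::rbeta(length(det), det + 0.5, mis + 0.5),
                  nrow(det), ncol(det), dimnames = dimnames(det))
      s[spec$sens_total == 0] <- 0
      perf <- test_performance(s, perf$fp_rate)
    }
    if ("fp" %in% blocks) {
      fr <- stats::rbeta(1, spec$fp + 0.5, spec$n_noncancer - spec$fp + 0.5)
      perf <- test_performance(perf$sens, fr)
    }
    if ("confusion" %in% blocks) {
      p_tp <- t(apply(a_conf, 1, rdirichlet1))
      dimnames(p_tp) <- dimnames(spec$counts$n)
      p_fp <- stats::setNames(rdirichlet1(a_fp), labs)
      model <- structure(list(p_tp = p_tp, p_fp = p_fp, alpha = spec$alpha,
                              labels = labs, prior_freq = prior),
                         class = "cso_model")
    }
    list(perf = perf, model = model)
  })
}

# internal: point estimates implied by the spec
posterior_point <- function(spec) {
  s <- spec$sens_detected / pmax(spec$sens_total, 1)
  perf <- test_performance(s, spec$fp / spec$n_noncancer)
  model <- cso_model(spec$counts, spec$alpha)
  list(perf = perf, model = model)
}

#' Propagate posterior uncertainty through the fitted pipeline
#'
#' Re-runs the full pipeline for each posterior draw and summarizes the
#' variation: per-CSO 95% draw intervals for PPV (any cancer) and, when
#' survival is available, lives saved; plus a variance attribution obtained
#' by resampling one input block at a time with the others held at point
#' estimates.
#'
#' @param object a fitted [mced_screen()].
#' @param spec a [posterior_spec()].
#' @param R number of draws (default 500).
#' @param seed integer seed.
#' @param attribute logical; compute the one-block-at-a-time variance
#'   attribution (default TRUE; triples the draw cost).
#' @return an `uncertainty_summary`: `ppv` and `lives` per-CSO data frames
#'   with the point estimate `est`, draw median `central`, and 2.5%/97.5%
#'   draw quantiles `lo`/`hi` (so `lo <= central <= hi` always; the sparse
#'   FP CSO counts can skew draws away from `est`), `attribution` (variance
#'   share per resampled input block), `n_draws`, `n_failed`.
#' @export
propagate_uncertainty <- function(object, spec, R = 500, seed = 1,
                                  attribute = TRUE) {
  stopifnot(R >= 2)
  point <- posterior_point(spec)
  run_draws <- function(draws) {
    res <- lapply(draws, function(d) {
      tryCatch(refit_mced(object, perf = d$perf, model = d$model),
               error = function(e) e)
    })
    failed <- vapply(res, inherits, logical(1), "error")
    if (any(failed)) {
      message(sum(failed), " draw(s) failed: ",
              conditionMessage(res[[which(failed)[1]]]))
    }
    res[!failed]
  }
  set.seed(seed)
  main <- run_draws(posterior_draws(spec, R, seed = NULL, point = point))
  labs <- object$chain$predicted_cso
  ppv_mat <- vapply(main, function(f) f$chain$ppv_any, numeric(length(labs)))
  lives_mat <- if (!is.null(object$lives)) {
    vapply(main, function(f)
      f$lives$lives_first[labs] + f$lives$lives_post[labs],
      numeric(length(labs)))
  }
  q <- function(m) t(apply(m, 1, stats::quantile, c(0.025, 0.5, 0.975),
                           na.rm = TRUE))
  ppv_q <- q(ppv_mat)
  ppv <- data.frame(predicted_cso = labs, est = object$chain$ppv_any,
                    central = ppv_q[, 2], lo = ppv_q[, 1], hi = ppv_q[, 3],
                    row.names = NULL, stringsAsFactors = FALSE)
  lives <- NULL
  if (!is.null(lives_mat)) {
    lq <- q(lives_mat)
    lives <- data.frame(
      predicted_cso = labs,
      est = object$lives$lives_first[labs] + object$lives$lives_post[labs],
      central = lq[, 2], lo = lq[, 1], hi = lq[, 3],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  attribution <- NULL
  if (attribute) {
    blocks <- c("sens", "fp", "confusion")
    block_var <- vapply(blocks, function(b) {
      res <- run_draws(posterior_draws(spec, R, seed = NULL, blocks = b,
                                       point = point))
      med <- vapply(res, function(f)
        stats::median(f$chain$ppv_any, na.rm = TRUE), numeric(1))
      stats::var(med)
    }, numeric(1))
    attribution <- data.frame(block = blocks, variance = block_var,
                              share = block_var / sum(block_var),
                              row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(ppv = ppv, lives = lives, attribution = attribution,
                 n_draws = length(main), n_failed = R - length(main)),
            class = "uncertainty_summary")
}

#' @export
print.uncertainty_summary <- function(x, ...) {
  cat("Posterior uncertainty over", x$n_draws, "draws")
  if (x$n_failed) cat(" (", x$n_failed, " failed)", sep = "")
  cat("\nPPV (any cancer), 95% draw intervals:\n")
  print(transform(x$ppv, est = round(est, 3), central = round(central, 3),
                  lo = round(lo, 3), hi = round(hi, 3)), row.names = FALSE)
  if (!is.null(x$attribution)) {
    cat("\nVariance attribution (median PPV):\n")
    print(transform(x$attribution, share = round(share, 3)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Compare dwell-time scenarios
#'
#' Refits the pipeline under each scenario and reports per-CSO PPV and
#' lives-saved deltas against the first (reference) scenario, along with
#' per-class detected totals. Shorter dwell times shrink the window for
#' screen capture (more interval cancers), so a scenario elementwise faster
#' than the reference can only lower detections.
#'
#' @param object a fitted [mced_screen()].
#' @param scenarios named list of [dwell_scenario()] objects; the first is
#'   the reference.
#' @return a `dwell_comparison` list: `metrics` (long data frame scenario x
#'   CSO with `ppv_any`, `lives`, and deltas), `detected` (class x scenario
#'   matrix), `monotone_vs_reference` (logical per scenario).
#' @export
dwell_scenario_compare <- function(object, scenarios) {
  stopifnot(length(scenarios) >= 2)
  if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "label")
  }
  fits <- lapply(scenarios, function(sc) refit_mced(object, dwell = sc))
  labs <- object$chain$predicted_cso
  ref <- fits[[1]]
  metrics <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    lv <- if (!is.null(f$lives)) {
      f$lives$lives_first[labs] + f$lives$lives_post[labs]
    } else NA_real_
    lv_ref <- if (!is.null(ref$lives)) {
      ref$lives$lives_first[labs] + ref$lives$lives_post[labs]
    } else NA_real_
    data.frame(scenario = nm, predicted_cso = labs,
               ppv_any = f$chain$ppv_any, lives = lv,
               d_ppv_any = f$chain$ppv_any - ref$chain$ppv_any,
               d_lives = lv - lv_ref,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  detected <- vapply(fits, function(f) detected_by_class(f$interception),
                     detected_by_class(ref$interception))
  mono <- vapply(seq_along(fits), function(i) {
    faster <- all(scenarios[[i]]$d <= scenarios[[1]]$d)
    !faster || all(detected[, i] <= detected[, 1] + 1e-9)
  }, logical(1))
  names(mono) <- names(fits)
  structure(list(metrics = metrics, detected = detected,
                 monotone_vs_reference = mono),
            class = "dwell_comparison")
}
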