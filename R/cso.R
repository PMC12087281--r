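#' CSO confusion-matrix counts from a validation study
#'
#' @param n integer matrix of counts, clinical CSO (rows) x predicted CSO
#'   (columns); the label set must be identical on both axes.
#' @param fp_counts named integer vector of observed predicted CSOs among
#'   false positives (same label set).
#' @param prior_freq named probability vector over predicted CSOs summing
#'   to 1: the frequency of clinical CSOs among signal-detected individuals
#'   in the classifier training data, used as the reference prior.
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(n, fp_counts, prior_freq) {
  n <- as.matrix(n)
  labs <- colnames(n)
  if (is.null(labs) || length(labs) == 0) stop("empty CSO label set")
  stopifnot(identical(rownames(n), labs),
            all(n >= 0), all(fp_counts >= 0))
  fp_counts <- fp_counts[labs]
  prior_freq <- prior_freq[labs]
  if (anyNA(fp_counts) || anyNA(prior_freq)) {
    stop("fp_counts and prior_freq must cover the confusion label set")
  }
  if (abs(sum(prior_freq) - 1) > 1e-8) stop("prior_freq must sum to 1")
  structure(list(n = n, fp_counts = fp_counts, prior_freq = prior_freq,
                 labels = labs),
            class = "confusion_counts")
}

#' Read confusion counts from delimited files
#'
#' File headers: confusion `clinical_cso,predicted_cso,count`; false
#' positives `predicted_cso,count`; prior `predicted_cso,freq`.
#'
#' @param confusion_path,fp_path,prior_path file paths.
#' @return a [confusion_counts()] object.
#' @export
load_confusion <- function(confusion_path, fp_path, prior_path) {
  cm <- utils::read.csv(confusion_path, stringsAsFactors = FALSE)
  fp <- utils::read.csv(fp_path, stringsAsFactors = FALSE)
  pr <- utils::read.csv(prior_path, stringsAsFactors = FALSE)
  labs <- sort(unique(c(cm$clinical_cso, cm$predicted_cso,
                        fp$predicted_cso, pr$predicted_cso)))
  n <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  n[cbind(cm$clinical_cso, cm$predicted_cso)] <- cm$count
  fpv <- stats::setNames(rep(0, length(labs)), labs)
  fpv[fp$predicted_cso] <- fp$count
  prv <- stats::setNames(rep(0, length(labs)), labs)
  prv[pr$predicted_cso] <- pr$freq
  confusion_counts(n, fpv, prv)
}

#' Pseudo-count smoothing of the CSO confusion matrix
#'
#' The finite validation set cannot exclude low-probability
#' (clinical CSO, predicted CSO) events, so observed counts are augmented
#' with a reference prior: `p_tp(o | c) = (n(c, o) + alpha * prior(o)) /
#' (sum_o n(c, o) + alpha)`. Rows with no observations fall back to the
#' prior; every entry is strictly positive.
#'
#' @param counts a [confusion_counts()] object.
#' @param alpha total pseudo-count weight per row (> 0, default 1).
#' @return a `cso_model`: list with `p_tp` (row-stochastic matrix
#'   clinical x predicted), `p_fp` (probability vector over predicted CSOs),
#'   `alpha`, `labels`.
#' @export
augment_confusion <- function(counts, alpha = 1) {
  stopifnot(inherits(counts, "confusion_counts"), alpha > 0)
  add <- matrix(alpha * counts$prior_freq, nrow = nrow(counts$n),
                ncol = ncol(counts$n), byrow = TRUE)
  num <- counts$n + add
  p_tp <- num / rowSums(num)
  dimnames(p_tp) <- dimnames(counts$n)
  structure(list(p_tp = p_tp,
                 p_fp = fp_cso_distribution(counts, alpha),
                 alpha = alpha, labels = counts$labels),
            class = "cso_model")
}

#' Smoothed CSO distribution for false positives
#'
#' False positives are sparse (high test specificity), so the few observed
#' FP predictions are combined with the same reference prior:
#' `p_fp(o) = (fp(o) + alpha * prior(o)) / (sum fp + alpha)`.
#'
#' @inheritParams augment_confusion
#' @return named probability vector over predicted CSOs.
#' @export
fp_cso_distribution <- function(counts, alpha = 1) {
  stopifnot(inherits(counts, "confusion_counts"), alpha > 0)
  p <- (counts$fp_counts + alpha * counts$prior_freq) /
    (sum(counts$fp_counts) + alpha)
  stats::setNames(as.numeric(p), counts$labels)
}

#' Stratify all positives by predicted CSO
#'
#' True positives of each cancer class are spread over predicted CSOs by the
#' smoothed confusion row of the class's expected clinical CSO; false
#' positives are spread by the FP distribution. The map is linear and
#' mass-conserving: the single false-positive rate fixes the number of
#' individuals entering any diagnostic process, independent of the number of
#' CSO categories. Classes whose clinical CSO is `"none"` use their own
#' confusion row when one is supplied under the label `"none"`, otherwise
#' the reference prior.
#'
#' @param interception an `interception_result`.
#' @param model a `cso_model` from [augment_confusion()].
#' @param registry a `cso_registry` mapping classes to clinical CSOs.
#' @return a `cso_stratified` list: `tp_by_class` (class x predicted-CSO
#'   matrix of expected true positives), `fp` (vector over predicted CSOs),
#'   `interception` (detail retained for stage-shift payloads), `row_used`
#'   (confusion row per class).
#' @export
stratify_positives <- function(interception, model, registry) {
  stopifnot(inherits(interception, "interception_result"),
            inherits(model, "cso_model"),
            inherits(registry, "cso_registry"))
  det <- detected_by_class(interception)
  cls <- names(det)
  check_classes(cls, registry, "interception result")
  map <- cso_map(registry)[cls]
  labs <- model$labels
  tp <- matrix(0, length(cls), length(labs), dimnames = list(cls, labs))
  row_used <- stats::setNames(character(length(cls)), cls)
  for (cl in cls) {
    cso <- map[[cl]]
    if (cso %in% rownames(model$p_tp)) {
      p <- model$p_tp[cso, ]
      row_used[cl] <- cso
    } else if (cso == "none") {
      p <- model$p_fp * 0 + attr_prior(model)
      row_used[cl] <- "(prior)"
    } else {
      stop("class '", cl, "' maps to clinical CSO '", cso,
           "' with no confusion row and no fallback")
    }
    tp[cl, ] <- det[cl] * p
  }
  fp <- interception$fp_total * model$p_fp
  structure(list(tp_by_class = tp, fp = fp, interception = interception,
                 row_used = row_used, labels = labs),
            class = "cso_stratified")
}

# internal: reference prior recoverable from the smoothed model. The prior is
# stored alongside when the model is built from counts; fall back to p_fp's
# shape only if absent.
attr_prior <- function(model) {
  if (!is.null(model$prior_freq)) return(model$prior_freq)
  model$p_fp
}

#' Build the full CSO model (TP and FP parts) from counts
#'
#' Convenience wrapper keeping the reference prior attached for classes that
#' fall back to it.
#'
#' @inheritParams augment_confusion
#' @return a `cso_model` with `prior_freq` retained.
#' @export
cso_model <- function(counts, alpha = 1) {
  m <- augment_confusion(counts, alpha)
  m$prior_freq <- counts$prior_freq
  m
}

#' @export
print.cso_model <- function(x, ...) {
  cat("Smoothed CSO model:", length(x$labels), "CSO labels, alpha =",
      x$alpha, "\n")
  cat("  diagonal of P(predicted | clinical):\n")
  print(round(diag(x$p_tp), 3))
  invisible(x)
}
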