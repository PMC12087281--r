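#' Generate a complete synthetic input set with known ground truth
#'
#' Fabricates every input the pipeline consumes — stratified incidence,
#' smoking relative risks and population fractions, per-class per-stage
#' sensitivities with a single false-positive rate, dwell-time scenarios,
#' a CSO confusion matrix with observed FP predictions and a training-prior
#' frequency vector, stage-resolved 5-year survival, and all-cause survival
#' by age — with controlled structure: class-level incidence spans three
#' orders of magnitude, the confusion matrix is diagonal-dominant to a
#' configurable degree, and the set always contains one undetectable class
#' (no shedding at any stage) and one clinical CSO the classifier never
#' predicts correctly (zero diagonal count), exercising the modelability
#' flags. Ground-truth pipeline outputs for a reference stratum are computed
#' analytically from the same parameters and stored alongside.
#'
#' @param n_classes number of cancer classes including the trailing
#'   `"other"` class (>= 4; default 8).
#' @param n_csos number of CSO labels (>= 2, <= n_classes - 1; default 6).
#' @param seed integer seed; the same seed reproduces the same truth and
#'   files byte-for-byte.
#' @param difficulty `"easy"` (identity confusion, no false positives),
#'   `"realistic"` (diagonal-dominant confusion, fp_rate 0.5%), or
#'   `"adversarial"` (weak diagonal, fp_rate 1%, fast dwell).
#' @param dir optional directory; when given, the full delimited-text file
#'   set (plus `config.yaml`) is written there and paths are returned under
#'   `$files`.
#' @param cohort_size cohort scale for the stored ground truth (default
#'   100,000).
#' @return a `synthetic_truth` list: `registry`, `incidence`, `risks`,
#'   `perf`, `dwell` (list `default`, `fast_aggressive`), `counts`, `surv`,
#'   `alpha`, `config`, `stratum`, ground-truth `fit` (an [mced_screen()]
#'   on the reference stratum), and `files` when `dir` is given.
#' @export
generate_synthetic_inputs <- function(n_classes = 8, n_csos = 6, seed = 1,
                                      difficulty = c("realistic", "easy",
                                                     "adversarial"),
                                      dir = NULL, cohort_size = 1e5) {
  difficulty <- match.arg(difficulty)
  stopifnot(n_classes >= 4, n_csos >= 2, n_csos <= n_classes - 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  csos <- sprintf("cso%02d", seq_len(n_csos))
  cls <- c(sprintf("class%02d", seq_len(n_classes - 1)), "other")
  map <- c(csos[((seq_len(n_classes - 1) - 1) %% n_csos) + 1], "none")
  sex_r <- rep("both", n_classes)
  if (n_classes >= 6) {
    sex_r[1] <- "female"
    sex_r[2] <- "male"
  }
  registry <- cancer_registry(cls, map, sex_r)

  sexes <- c("female", "male")
  ages <- c(55, 65, 75)
  # class-level totals span 3 orders of magnitude (log-uniform), rescaled so
  # the all-site total is ~1,200/100k before age factors (screening-age scale)
  base_total <- 10^stats::runif(n_classes, 0, 3)
  base_total <- base_total * 1200 / sum(base_total)
  names(base_total) <- cls
  stage_mix <- t(vapply(cls, function(cl) {
    w <- stats::rgamma(4, shape = c(3, 2.5, 2, 1.5))
    u <- stats::runif(1, 0.02, 0.08) # unstaged fraction
    c(w / sum(w) * (1 - u), u)
  }, numeric(5)))
  colnames(stage_mix) <- STAGES
  rows <- list()
  for (sx in sexes) for (a in ages) {
    age_f <- 1.5^((a - 55) / 10)
    sex_f <- stats::setNames(exp(stats::rnorm(n_classes, 0, 0.15)), cls)
    for (cl in cls) {
      restricted <- registry$sex[registry$class == cl]
      tot <- if (restricted != "both" && restricted != sx) 0 else
        base_total[cl] * age_f * sex_f[cl]
      rows[[length(rows) + 1]] <- data.frame(
        sex = sx, age_lo = a, age_hi = a + 5, smoking = "any",
        cancer_class = cl, stage = STAGES,
        rate_per_100k = round(tot * stage_mix[cl, ], 6),
        stringsAsFactors = FALSE)
    }
  }
  incidence <- validate_incidence(do.call(rbind, rows), registry,
                                  source = "synthetic incidence")

  # smoking: one strongly smoking-driven class (lung-like), mild others
  rr <- do.call(rbind, lapply(seq_along(cls), function(i) {
    r <- if (i == 3) c(1, 4, 10) else exp(stats::rnorm(3, c(0, 0.1, 0.25), 0.05))
    r[1] <- 1
    data.frame(cancer_class = cls[i], smoking = c("never", "former", "current"),
               rr = round(r, 4), stringsAsFactors = FALSE)
  }))
  weights <- do.call(rbind, lapply(sexes, function(sx) {
    do.call(rbind, lapply(ages, function(a) {
      data.frame(sex = sx, age_lo = a, age_hi = a + 5,
                 smoking = c("never", "former", "current"),
                 weight = c(0.55, 0.30, 0.15), stringsAsFactors = FALSE)
    }))
  }))
  risks <- suppressMessages(smoking_risk(rr, weights, registry))

  # sensitivities: rising with stage; class n_classes-1 is undetectable
  lo <- switch(difficulty, easy = 0.5, realistic = 0.15, adversarial = 0.05)
  sens <- t(vapply(seq_along(cls), function(i) {
    s <- sort(stats::runif(4, lo, 0.95))
    round(s, 4)
  }, numeric(4)))
  dimnames(sens) <- list(cls, SHIFT_STAGES)
  undetectable <- cls[n_classes - 1]
  sens[undetectable, ] <- 0
  fp_rate <- switch(difficulty, easy = 0, realistic = 0.005,
                    adversarial = 0.01)
  perf <- test_performance(sens, fp_rate)

  d_default <- matrix(rep(c(2, 1, 1, 0.5), each = n_classes), n_classes, 4,
                      dimnames = list(cls, SHIFT_STAGES))
  if (difficulty == "adversarial") d_default <- d_default * 0.75
  dwell <- list(default = dwell_scenario(d_default, "default"),
                fast_aggressive = dwell_scenario(d_default / 2,
                                                 "fast_aggressive"))

  # confusion counts over CSO labels; zero-diagonal CSO = last label
  diag_n <- switch(difficulty, easy = 50, realistic = 30, adversarial = 12)
  n <- matrix(0, n_csos, n_csos, dimnames = list(csos, csos))
  for (i in seq_len(n_csos)) {
    off <- stats::rpois(n_csos, switch(difficulty, easy = 0, realistic = 1.5,
                                       adversarial = 4))
    n[i, ] <- off
    n[i, i] <- diag_n + stats::rpois(1, 5)
  }
  zero_diag <- csos[n_csos]
  n[zero_diag, zero_diag] <- 0
  if (difficulty == "easy") {
    # identity confusion, but keep the zero-diagonal CSO row observed
    n[zero_diag, 1] <- 5
  }
  fp_counts <- stats::setNames(integer(n_csos), csos)
  if (fp_rate > 0) {
    k <- stats::rmultinom(1, 4, rep(1 / n_csos, n_csos))[, 1]
    fp_counts[] <- k
  }
  prior <- rowSums(n) + 1
  prior <- prior / sum(prior)
  counts <- confusion_counts(n, fp_counts, prior)

  s5 <- t(vapply(seq_along(cls), function(i) {
    top <- stats::runif(1, 0.75, 0.95)
    drop <- sort(stats::runif(3, 0.1, 0.9), decreasing = FALSE)
    round(c(top, top * (1 - drop * stats::runif(1, 0.6, 1))), 4)
  }, numeric(4)))
  dimnames(s5) <- list(cls, SHIFT_STAGES)
  s5 <- cbind(s5, unstaged = NA_real_)
  if (difficulty != "easy") s5[n_classes - 2, ] <- NA_real_ # survival gap case
  os <- do.call(rbind, lapply(sexes, function(sx) {
    data.frame(sex = sx, age_lo = ages, age_hi = ages + 5,
               os5 = round(0.97 - 0.015 * (ages - 55) / 10 -
                             ifelse(sx == "male", 0.01, 0), 4),
               stringsAsFactors = FALSE)
  }))
  surv <- suppressWarnings(survival_table(s5, os))

  stratum <- list(sex = "female", age_lo = 65, smoking = "any")
  alpha <- 1
  config <- list(screen_interval_years = 1, cohort_size = cohort_size,
                 round = "incidence", dwell_scenario = "default",
                 alpha = alpha, fp_rate = fp_rate, threshold = 0.07,
                 benchmark = 240, seed = seed, difficulty = difficulty)

  fit <- mced_screen(incidence, perf, counts, dwell$default, surv, registry,
                     sex = stratum$sex, age_lo = stratum$age_lo,
                     smoking = stratum$smoking, alpha = alpha,
                     cohort_size = cohort_size)

  truth <- structure(list(registry = registry, incidence = incidence,
                          risks = risks, perf = perf, dwell = dwell,
                          counts = counts, surv = surv, alpha = alpha,
                          fp_rate = fp_rate, config = config,
                          stratum = stratum, fit = fit),
                     class = "synthetic_truth")
  if (!is.null(dir)) truth$files <- write_synthetic_inputs(truth, dir)
  truth
}

# Preserve the caller's RNG state: the generator must be deterministic in
# its own seed without disturbing outer simulations.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Write a synthetic truth's input file set
#'
#' Emits the delimited-text files in the production readers' formats plus a
#' `config.yaml`; [read_synthetic_inputs()] and [run_pipeline()] consume
#' them.
#'
#' @param truth a `synthetic_truth`.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly stored under
#'   `$files` by the generator.
#' @export
write_synthetic_inputs <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  files <- c(incidence = p("incidence.csv"), registry = p("registry.csv"),
             smoking_rr = p("smoking_rr.csv"),
             smoking_weights = p("smoking_weights.csv"),
             performance = p("performance.csv"), dwell = p("dwell.csv"),
             confusion = p("confusion.csv"), fp_cso = p("fp_cso.csv"),
             prior = p("prior.csv"), survival = p("survival.csv"),
             os = p("os.csv"), config = p("config.yaml"))
  write_incidence(truth$incidence, files["incidence"])
  utils::write.csv(data.frame(class = truth$registry$class,
                              cso = truth$registry$cso,
                              sex = truth$registry$sex),
                   files["registry"], row.names = FALSE, quote = FALSE)
  utils::write.csv(truth$risks$rr, files["smoking_rr"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(truth$risks$weights, files["smoking_weights"],
                   row.names = FALSE, quote = FALSE)
  sens <- truth$perf$sens
  utils::write.csv(data.frame(
    cancer_class = rep(rownames(sens), times = ncol(sens)),
    stage = rep(colnames(sens), each = nrow(sens)),
    sensitivity = as.vector(sens)),
    files["performance"], row.names = FALSE, quote = FALSE)
  dw <- do.call(rbind, lapply(truth$dwell, function(sc) {
    data.frame(scenario = sc$label,
               cancer_class = rep(rownames(sc$d), times = ncol(sc$d)),
               stage = rep(colnames(sc$d), each = nrow(sc$d)),
               dwell_years = as.vector(sc$d))
  }))
  utils::write.csv(dw, files["dwell"], row.names = FALSE, quote = FALSE)
  n <- truth$counts$n
  utils::write.csv(data.frame(
    clinical_cso = rep(rownames(n), times = ncol(n)),
    predicted_cso = rep(colnames(n), each = nrow(n)),
    count = as.vector(n)),
    files["confusion"], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(predicted_cso = names(truth$counts$fp_counts),
                              count = as.integer(truth$counts$fp_counts)),
                   files["fp_cso"], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(predicted_cso = names(truth$counts$prior_freq),
                              freq = as.numeric(truth$counts$prior_freq)),
                   files["prior"], row.names = FALSE, quote = FALSE)
  s5 <- truth$surv$s5
  sdf <- data.frame(cancer_class = rep(rownames(s5), times = ncol(s5)),
                    stage = rep(colnames(s5), each = nrow(s5)),
                    s5 = as.vector(s5))
  sdf <- sdf[is.finite(sdf$s5), ]
  utils::write.csv(sdf, files["survival"], row.names = FALSE, quote = FALSE)
  utils::write.csv(truth$surv$os, files["os"], row.names = FALSE,
                   quote = FALSE)
  cfg <- truth$config
  cfg$files <- as.list(stats::setNames(basename(files), names(files)))
  cfg$stratum <- truth$stratum
  yaml::write_yaml(cfg, files["config"])
  files
}

#' Read a registry file
#' @param path delimited text with header `class,cso,sex`.
#' @return a `cso_registry`.
#' @export
load_registry <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  cancer_registry(d$class, d$cso, d$sex)
}

#' Read MCED performance and dwell files
#' @param performance_path header `cancer_class,stage,sensitivity`.
#' @param fp_rate scalar false-positive rate (from the run configuration).
#' @return a [test_performance()].
#' @export
load_performance <- function(performance_path, fp_rate) {
  d <- utils::read.csv(performance_path, stringsAsFactors = FALSE)
  cls <- unique(d$cancer_class)
  sens <- matrix(0, length(cls), 4, dimnames = list(cls, SHIFT_STAGES))
  sens[cbind(d$cancer_class, d$stage)] <- d$sensitivity
  test_performance(sens, fp_rate)
}

#' Read dwell-time scenarios
#' @param path header `scenario,cancer_class,stage,dwell_years`.
#' @return named list of [dwell_scenario()] objects.
#' @export
load_dwell <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(d, d$scenario), function(s) {
    cls <- unique(s$cancer_class)
    m <- matrix(NA_real_, length(cls), 4, dimnames = list(cls, SHIFT_STAGES))
    m[cbind(s$cancer_class, s$stage)] <- s$dwell_years
    dwell_scenario(m, s$scenario[1])
  })
  out
}

#' Re-read an emitted synthetic input set
#'
#' Round-trips the files written by [write_synthetic_inputs()] through the
#' production readers.
#'
#' @param dir the directory holding the file set (with `config.yaml`).
#' @return list with the same input components as the generator.
#' @export
read_synthetic_inputs <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  p <- function(key) file.path(dir, cfg$files[[key]])
  registry <- load_registry(p("registry"))
  list(registry = registry,
       incidence = load_incidence(p("incidence"), registry),
       risks = suppressMessages(
         load_smoking_risk(p("smoking_rr"), p("smoking_weights"), registry)),
       perf = load_performance(p("performance"), cfg$fp_rate),
       dwell = load_dwell(p("dwell")),
       counts = load_confusion(p("confusion"), p("fp_cso"), p("prior")),
       surv = load_survival(p("survival"), p("os")),
       config = cfg)
}
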