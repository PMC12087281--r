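#' Run the full pipeline from a configuration file
#'
#' Orchestrates the whole analysis for each requested population stratum:
#' read and validate inputs, fit [mced_screen()], and write per-stratum
#' metric tables (long format keyed by stratum, predicted CSO and metric),
#' a cross-stratum summary of medians and ranges, and a machine-readable
#' run manifest (input file hashes, seed, package version). A failing
#' stratum is recorded with its cause while the others proceed.
#'
#' @param config path to a YAML configuration (as emitted by
#'   [write_synthetic_inputs()]) or an equivalent list. Recognized keys:
#'   `files` (named relative paths), `strata` (list of
#'   `sex`/`age_lo`/`smoking` entries; defaults to the single `stratum`),
#'   `round`, `dwell_scenario`, `alpha`, `fp_rate`, `threshold`,
#'   `benchmark`, `screen_interval_years`, `cohort_size`, `seed`.
#' @param input_dir directory the `files` entries are relative to; defaults
#'   to the configuration file's directory.
#' @param out_dir output directory for the result bundle.
#' @return an `mced_bundle` list: `fits` (per stratum, or a condition for a
#'   failed one), `summary` (cross-stratum data frame), `manifest`,
#'   `out_dir`, `n_failed`.
#' @export
run_pipeline <- function(config, input_dir = NULL, out_dir) {
  if (is.character(config)) {
    if (is.null(input_dir)) input_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(!is.null(input_dir))
  p <- function(key) file.path(input_dir, config$files[[key]])
  registry <- load_registry(p("registry"))
  incidence <- load_incidence(p("incidence"), registry)
  risks <- suppressMessages(
    load_smoking_risk(p("smoking_rr"), p("smoking_weights"), registry))
  perf <- load_performance(p("performance"), config$fp_rate)
  dwell_all <- load_dwell(p("dwell"))
  scen <- config$dwell_scenario %||% "default"
  if (!scen %in% names(dwell_all)) {
    stop("unknown dwell scenario '", scen, "'; available: ",
         paste(names(dwell_all), collapse = ", "))
  }
  counts <- load_confusion(p("confusion"), p("fp_cso"), p("prior"))
  surv <- if (!is.null(config$files$survival)) {
    load_survival(p("survival"),
                  if (!is.null(config$files$os)) p("os"))
  }
  strata <- config$strata %||% list(config$stratum)
  fits <- vector("list", length(strata))
  names(fits) <- vapply(strata, function(s)
    paste(s$sex, s$age_lo, s$smoking %||% "any", sep = "_"), character(1))
  for (i in seq_along(strata)) {
    s <- strata[[i]]
    fits[[i]] <- tryCatch(
      mced_screen(incidence, perf, counts, dwell_all[[scen]], surv,
                  registry, sex = s$sex, age_lo = s$age_lo,
                  smoking = s$smoking %||% "any", smoking_risk = risks,
                  alpha = config$alpha %||% 1,
                  round = config$round %||% "incidence",
                  screen_interval = config$screen_interval_years %||% 1,
                  cohort_size = config$cohort_size %||% 1e5,
                  threshold = config$threshold %||% 0.07,
                  benchmark = config$benchmark %||% 240),
      error = function(e) {
        message("stratum ", names(fits)[i], " failed: ",
                conditionMessage(e))
        e
      })
  }
  failed <- vapply(fits, inherits, logical(1), "condition")
  summary_tab <- cross_stratum_summary(fits[!failed])
  hashes <- tools::md5sum(vapply(names(config$files), p, character(1)))
  manifest <- list(
    package = "mcedcso",
    version = as.character(utils::packageVersion("mcedcso")),
    seed = config$seed %||% NA,
    config = config,
    input_md5 = as.list(hashes),
    strata_failed = names(fits)[failed])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(fits)[!failed]) {
    utils::write.csv(long_metrics(fits[[nm]], nm),
                     file.path(out_dir, paste0("metrics_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(fits = fits, summary = summary_tab, manifest = manifest,
                 out_dir = out_dir, n_failed = sum(failed)),
            class = "mced_bundle")
}

# internal: one fit -> long table (stratum, predicted_cso, metric, value)
long_metrics <- function(fit, stratum_label) {
  ch <- fit$chain
  cols <- c("n_pool", "n_any", "n_match", "n_fp",
            "ppv_any", "ppv_first", "ppv_remaining")
  out <- do.call(rbind, lapply(cols, function(m) {
    data.frame(stratum = stratum_label, predicted_cso = ch$predicted_cso,
               metric = m, value = ch[[m]], stringsAsFactors = FALSE)
  }))
  if (!is.null(fit$outcomes)) {
    oc <- fit$outcomes
    for (m in c("lives_first", "lives_post", "tests_per_life_first",
                "tests_per_life_post")) {
      out <- rbind(out, data.frame(stratum = stratum_label,
                                   predicted_cso = oc$predicted_cso,
                                   metric = m, value = oc[[m]],
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# internal: cross-stratum medians/ranges over modelable CSOs
cross_stratum_summary <- function(fits) {
  if (!length(fits)) {
    return(data.frame(stratum = character(), metric = character(),
                      median = numeric(), min = numeric(), max = numeric(),
                      argmin = character(), argmax = character(),
                      n_cso = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    keep <- fit$flags$predicted_cso[fit$flags$modelable]
    mets <- c(ppv_any = "chain", ppv_first = "chain",
              ppv_remaining = "chain")
    if (!is.null(fit$outcomes)) {
      mets <- c(mets, tests_per_life_first = "outcomes",
                tests_per_life_post = "outcomes")
    }
    do.call(rbind, lapply(names(mets), function(m) {
      sm <- summarize_across_csos(fit[[mets[[m]]]], m, include = keep)
      data.frame(stratum = nm, metric = m, median = sm$median,
                 min = sm$min, max = sm$max, argmin = sm$argmin,
                 argmax = sm$argmax, n_cso = sm$n,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Write a human-readable report for a result bundle
#'
#' A plain-text per-stratum account in the shape of an extrapolated
#' performance table, plus bar-chart figures (PPV tiers with the workup
#' threshold line; tests per life saved with the mammography benchmark
#' line, bars omitted where the ratio is undefined). Regeneration is
#' idempotent.
#'
#' @param bundle an `mced_bundle` from [run_pipeline()].
#' @param file report path; defaults to `report.txt` in the bundle
#'   directory.
#' @param figures logical; also write one PDF of figures per stratum.
#' @return the report path, invisibly.
#' @export
write_report <- function(bundle, file = file.path(bundle$out_dir,
                                                  "report.txt"),
                         figures = TRUE) {
  ok <- !vapply(bundle$fits, inherits, logical(1), "condition")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("MCED CSO-directed diagnostic chain: extrapolated performance",
             con)
  if (!any(ok)) {
    writeLines("(no successfully fitted strata)", con)
  }
  for (nm in names(bundle$fits)[ok]) {
    fit <- bundle$fits[[nm]]
    writeLines(c("", paste0("== stratum ", nm, " ==")), con)
    s <- summary(fit)
    writeLines(utils::capture.output(print(s)), con)
    if (figures) {
      grDevices::pdf(file.path(bundle$out_dir,
                               paste0("figures_", nm, ".pdf")),
                     width = 9, height = 5)
      plot(fit, "ppv", main = paste("PPV by predicted CSO,", nm))
      if (!is.null(fit$outcomes)) {
        plot(fit, "tests_per_life",
             main = paste("Tests per life saved,", nm))
      }
      grDevices::dev.off()
    }
  }
  if (length(bundle$manifest$strata_failed)) {
    writeLines(c("", paste("failed strata:",
                           paste(bundle$manifest$strata_failed,
                                 collapse = ", "))), con)
  }
  invisible(file)
}
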