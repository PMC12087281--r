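#' Read a stratified incidence table
#'
#' Expects delimited text with header
#' `sex,age_lo,age_hi,smoking,cancer_class,stage,rate_per_100k`; rates are
#' cases per 100,000 person-years for the stratum. Every (stratum, class)
#' present must carry a complete stage vector (I--IV plus unstaged) and
#' sex-restricted classes may only carry nonzero rates for their sex.
#'
#' @param path path to a delimited text file (comma-separated).
#' @param registry a [cancer_registry()] the class labels must belong to.
#' @return A validated `incidence_table` (data frame).
#' @export
load_incidence <- function(path, registry) {
  inc <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_incidence(inc, registry, source = path)
}

#' Validate an in-memory incidence table
#'
#' @param inc data frame with the incidence columns (see [load_incidence()]).
#' @param registry a `cso_registry`.
#' @param source label used in error messages.
#' @return the table, classed `incidence_table`.
#' @export
validate_incidence <- function(inc, registry, source = "incidence table") {
  needed <- c("sex", "age_lo", "age_hi", "smoking", "cancer_class",
              "stage", "rate_per_100k")
  missing_cols <- setdiff(needed, names(inc))
  if (length(missing_cols)) {
    stop(source, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  unknown <- !inc$cancer_class %in% registry$class
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop(source, ": unknown cancer class '", inc$cancer_class[i],
         "' at row ", i)
  }
  bad_stage <- !inc$stage %in% STAGES
  if (any(bad_stage)) {
    i <- which(bad_stage)[1]
    stop(source, ": unknown stage '", inc$stage[i], "' at row ", i)
  }
  neg <- inc$rate_per_100k < 0 | !is.finite(inc$rate_per_100k)
  if (any(neg)) {
    i <- which(neg)[1]
    stop(source, ": negative or non-finite rate at row ", i,
         " (", inc$cancer_class[i], ", stage ", inc$stage[i], ")")
  }
  bad_age <- inc$age_lo %% 5 != 0 | inc$age_hi - inc$age_lo != 5 |
    inc$age_lo < 40 | inc$age_hi > 85
  if (any(bad_age)) {
    i <- which(bad_age)[1]
    stop(source, ": age band must be a 5-year band within [40, 85); row ", i,
         " has [", inc$age_lo[i], ", ", inc$age_hi[i], ")")
  }
  # complete stage vectors per stratum x class
  key <- interaction(inc$sex, inc$age_lo, inc$smoking, inc$cancer_class,
                     drop = TRUE)
  n_stage <- tapply(inc$stage, key, function(s) length(unique(s)))
  if (any(n_stage != length(STAGES))) {
    bad <- names(n_stage)[n_stage != length(STAGES)][1]
    stop(source, ": incomplete stage vector for stratum/class ", bad)
  }
  # sex restriction: restricted classes must have zero rate in the other sex
  restr <- registry[registry$sex != "both", , drop = FALSE]
  if (nrow(restr)) {
    m <- match(inc$cancer_class, restr$class)
    viol <- !is.na(m) & inc$sex != restr$sex[m] & inc$rate_per_100k > 0
    if (any(viol)) {
      i <- which(viol)[1]
      stop(source, ": nonzero ", inc$sex[i], " rate for sex-restricted class '",
           inc$cancer_class[i], "' at row ", i)
    }
  }
  rownames(inc) <- NULL
  class(inc) <- c("incidence_table", "data.frame")
  inc
}

#' Write an incidence table
#' @param inc an `incidence_table`.
#' @param path output file path.
#' @export
write_incidence <- function(inc, path) {
  utils::write.csv(as.data.frame(inc), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read smoking relative risks and population fractions
#'
#' Relative-risk file header: `cancer_class,smoking,rr`; weights file header:
#' `sex,age_lo,age_hi,smoking,weight`, with weights summing to 1 within each
#' (sex, age band).
#'
#' @param rr_path path to the relative-risk file.
#' @param weights_path path to the population-fraction file.
#' @param registry a `cso_registry`; classes without an RR entry default to
#'   RR = 1 for every status (reported via message).
#' @return list with elements `rr` (data frame) and `weights` (data frame),
#'   classed `smoking_risk`.
#' @export
load_smoking_risk <- function(rr_path, weights_path, registry) {
  rr <- utils::read.csv(rr_path, stringsAsFactors = FALSE)
  w <- utils::read.csv(weights_path, stringsAsFactors = FALSE)
  smoking_risk(rr, w, registry)
}

#' Construct a smoking-risk object from data frames
#'
#' @param rr data frame `cancer_class,smoking,rr`.
#' @param weights data frame `sex,age_lo,age_hi,smoking,weight`.
#' @param registry a `cso_registry`.
#' @return a `smoking_risk` list.
#' @export
smoking_risk <- function(rr, weights, registry) {
  stopifnot(all(c("cancer_class", "smoking", "rr") %in% names(rr)),
            all(c("sex", "age_lo", "age_hi", "smoking", "weight") %in%
                  names(weights)))
  check_classes(rr$cancer_class, registry, "smoking RR table")
  if (any(rr$rr <= 0)) stop("relative risks must be > 0")
  statuses <- c("never", "former", "current")
  if (!all(rr$smoking %in% statuses) || !all(weights$smoking %in% statuses)) {
    stop("smoking status must be one of: ", paste(statuses, collapse = ", "))
  }
  key <- interaction(weights$sex, weights$age_lo, drop = TRUE)
  tot <- tapply(weights$weight, key, sum)
  if (any(abs(tot - 1) > 1e-8)) {
    stop("smoking population fractions must sum to 1 per (sex, age band)")
  }
  no_rr <- setdiff(registry$class, unique(rr$cancer_class))
  if (length(no_rr)) {
    message("classes without smoking RR (defaulting to RR = 1): ",
            paste(no_rr, collapse = ", "))
  }
  structure(list(rr = rr, weights = weights, statuses = statuses),
            class = "smoking_risk")
}

# internal: RR(class, status), defaulting to 1
lookup_rr <- function(risks, cls, status) {
  hit <- risks$rr$cancer_class == cls & risks$rr$smoking == status
  if (any(hit)) risks$rr$rr[which(hit)[1]] else 1
}

# internal: w(status | sex, age_lo)
lookup_weight <- function(risks, sex, age_lo, status) {
  w <- risks$weights
  hit <- w$sex == sex & w$age_lo == age_lo & w$smoking == status
  if (!any(hit)) stop("no smoking weight for (", sex, ", ", age_lo, ", ",
                      status, ")")
  w$weight[which(hit)[1]]
}

#' Smoking-status adjustment of incidence rates
#'
#' SEER-style rates carry no smoking stratification (`smoking = "any"`). For
#' a target status the class-specific baseline is recovered from the observed
#' mixture, `baseline = rate_any / sum_k w_k RR_k`, and the adjusted rate is
#' `baseline * RR(class, target)`. This is mixture-preserving: the
#' weight-averaged adjusted rates reconstitute the unadjusted rate exactly,
#' and `target_status = "any"` returns the input unchanged.
#'
#' @param inc an `incidence_table` with `smoking == "any"` rows.
#' @param risks a [smoking_risk()] object.
#' @param target_status one of `"never"`, `"former"`, `"current"`, `"any"`.
#' @return an `incidence_table` for the target status.
#' @export
apply_smoking_adjustment <- function(inc, risks, target_status) {
  target_status <- match.arg(target_status,
                             c("never", "former", "current", "any"))
  if (target_status == "any") return(inc)
  stopifnot(inherits(risks, "smoking_risk"))
  inc <- as.data.frame(inc)
  if (!all(inc$smoking == "any")) {
    stop("input incidence must be unstratified by smoking (smoking = 'any')")
  }
  out <- inc
  # denominator sum_k w_k RR_k varies by (sex, age band, class)
  for (i in seq_len(nrow(inc))) {
    cls <- inc$cancer_class[i]
    denom <- sum(vapply(risks$statuses, function(k) {
      lookup_weight(risks, inc$sex[i], inc$age_lo[i], k) *
        lookup_rr(risks, cls, k)
    }, numeric(1)))
    if (denom <= 0) stop("degenerate smoking mixture for class ", cls)
    out$rate_per_100k[i] <- inc$rate_per_100k[i] / denom *
      lookup_rr(risks, cls, target_status)
  }
  out$smoking <- target_status
  class(out) <- c("incidence_table", "data.frame")
  out
}

#' Per-class stage-resolved rates for one population stratum
#'
#' @param inc an `incidence_table`.
#' @param sex `"female"` or `"male"`.
#' @param age_lo lower bound of the 5-year age band.
#' @param smoking smoking status of the requested stratum.
#' @return matrix class x stage of rates per 100,000 person-years,
#'   with classes present in the table for that stratum.
#' @export
stratum_incidence <- function(inc, sex, age_lo, smoking = "any") {
  inc <- as.data.frame(inc)
  sel <- inc$sex == sex & inc$age_lo == age_lo & inc$smoking == smoking
  if (!any(sel)) {
    have <- unique(inc[c("sex", "age_lo", "smoking")])
    stop("stratum (", sex, ", ", age_lo, ", ", smoking,
         ") not present; available strata:\n",
         paste(apply(have, 1, paste, collapse = "/"), collapse = "\n"))
  }
  sub <- inc[sel, , drop = FALSE]
  cls <- unique(sub$cancer_class)
  rates <- matrix(0, nrow = length(cls), ncol = length(STAGES),
                  dimnames = list(cls, STAGES))
  rates[cbind(sub$cancer_class, sub$stage)] <- sub$rate_per_100k
  rates
}
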