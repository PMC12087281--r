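#' Stage labels used throughout the package
#'
#' AJCC-like stages I--IV plus `"unstaged"`. Unstaged disease is carried
#' through all computations but is never stage-shifted.
#'
#' @format Character vector of length 5.
#' @export
STAGES <- c("I", "II", "III", "IV", "unstaged")

#' Stages eligible for stage shift (I--IV)
#' @export
SHIFT_STAGES <- c("I", "II", "III", "IV")

#' Construct a cancer-class registry
#'
#' The registry fixes the cancer-class label set, the expected clinical CSO
#' (cancer signal origin) for each class, and the sex restriction of each
#' class. Classes that do not map to any CSO-directed workup (e.g. a residual
#' "other" group) use `cso = "none"`.
#'
#' @param classes character vector of unique cancer-class labels.
#' @param cso character vector, same length: expected clinical CSO label per
#'   class, or `"none"`.
#' @param sex one of `"both"`, `"female"`, `"male"` per class (recycled).
#' @return An object of class `cso_registry`: a data frame with columns
#'   `class`, `cso`, `sex`, plus an attribute `cso_levels` giving the ordered
#'   set of CSO labels (excluding `"none"`).
#' @examples
#' cancer_registry(c("lung", "ovary", "other"),
#'                 cso = c("lung", "ovary", "none"),
#'                 sex = c("both", "female", "both"))
#' @export
cancer_registry <- function(classes, cso, sex = "both") {
  classes <- as.character(classes)
  cso <- as.character(cso)
  sex <- rep_len(as.character(sex), length(classes))
  if (anyDuplicated(classes)) {
    stop("duplicate cancer-class labels: ",
         paste(unique(classes[duplicated(classes)]), collapse = ", "))
  }
  if (length(cso) != length(classes)) {
    stop("'cso' must have one entry per class")
  }
  bad <- !sex %in% c("both", "female", "male")
  if (any(bad)) stop("invalid sex restriction: ", paste(sex[bad], collapse = ", "))
  reg <- data.frame(class = classes, cso = cso, sex = sex,
                    stringsAsFactors = FALSE)
  attr(reg, "cso_levels") <- unique(cso[cso != "none"])
  class(reg) <- c("cso_registry", "data.frame")
  reg
}

#' CSO labels of a registry
#' @param registry a `cso_registry`.
#' @return character vector of CSO labels (excluding "none").
#' @export
cso_levels <- function(registry) attr(registry, "cso_levels")

#' Expected clinical CSO per class
#' @param registry a `cso_registry`.
#' @return named character vector mapping class -> clinical CSO (or "none").
#' @export
cso_map <- function(registry) {
  stats::setNames(registry$cso, registry$class)
}

#' Default 26-class registry
#'
#' Twenty-five cancer classes (with neuroendocrine tumors split out from
#' their host organs) plus a residual `"other"` class mapping to no CSO.
#' Sex-restricted organs are marked; breast is deliberately `"both"` (male
#' breast cancer occurs, and the CSO classifier may return any label for
#' either sex).
#'
#' @return A `cso_registry` with 26 classes.
#' @export
default_registry <- function() {
  cls <- c("anus", "bladder", "brain", "breast", "cervix", "colon_rectum",
           "esophagus", "gallbladder", "head_neck", "kidney",
           "liver_bile_duct", "lung", "lymphoid_neoplasm", "melanoma",
           "myeloid_neoplasm", "neuroendocrine", "ovary", "pancreas",
           "plasma_cell_neoplasm", "prostate", "sarcoma", "stomach",
           "testis", "thyroid", "uterus", "other")
  cso <- cls
  cso[cls == "other"] <- "none"
  sex <- rep("both", length(cls))
  sex[cls %in% c("cervix", "ovary", "uterus")] <- "female"
  sex[cls %in% c("prostate", "testis")] <- "male"
  cancer_registry(cls, cso, sex)
}

#' @export
print.cso_registry <- function(x, ...) {
  cat("Cancer-class registry:", nrow(x), "classes,",
      length(cso_levels(x)), "CSO labels\n")
  print.data.frame(x, ...)
  invisible(x)
}

# internal: validate a class label vector against the registry
check_classes <- function(labels, registry, where = "input") {
  unknown <- setdiff(unique(labels), registry$class)
  if (length(unknown)) {
    stop("unknown cancer class label(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
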