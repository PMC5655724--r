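# Canonical variable sets of the hospital cost system.  Order matters:
# matrices and vectors throughout the package are indexed by these names.

#' Canonical service (output), input and hedonic variable names
#'
#' The cost system distinguishes four hospital services, six inputs and six
#' hedonic case-mix characteristics interacted with admissions.
#'
#' @details
#' Services: inpatient admissions, outpatient visits, other (non-patient)
#' revenues as a volume proxy for research and ancillary activity, and
#' emergency-room visits.  Inputs: four labor categories (management and
#' administration, nursing, paramedical, auxiliary personnel), material
#' supplies and capital.  Hedonics: relative size of surgery and orthopedics,
#' psychiatric beds per 1000 admissions, IC beds per 1000 admissions,
#' expected length of stay, and the shares of neurosurgery and cardiothoracic
#' surgery.
#'
#' @return A character vector of variable names.
#' @export
#' @examples
#' hospital_outputs()
hospital_outputs <- function() {
  c("admissions", "outpatients", "other_revenues", "er_visits")
}

#' @rdname hospital_outputs
#' @export
hospital_inputs <- function() {
  c("man_adm", "nursing", "paramedical", "auxiliary", "material", "capital")
}

#' @rdname hospital_outputs
#' @export
hedonic_vars <- function() {
  c("surgery_ortho", "psych_beds", "ic_beds", "expected_los",
    "neurosurgery", "cardiothoracic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# named numeric coercion with order/name checks
.named_num <- function(x, names, what) {
  if (is.null(names(x))) {
    if (length(x) != length(names))
      stop(sprintf("`%s` must have length %d (got %d)", what,
                   length(names), length(x)), call. = FALSE)
    names(x) <- names
  }
  if (!all(names %in% names(x)))
    stop(sprintf("`%s` is missing entries: %s", what,
                 paste(setdiff(names, names(x)), collapse = ", ")),
         call. = FALSE)
  out <- as.numeric(x[names])
  names(out) <- names
  out
}

.named_mat <- function(x, rn, cn, what) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- rn
  if (is.null(colnames(x))) colnames(x) <- cn
  if (!all(rn %in% rownames(x)) || !all(cn %in% colnames(x)))
    stop(sprintf("`%s` must be a %d x %d matrix indexed by the canonical names",
                 what, length(rn), length(cn)), call. = FALSE)
  x[rn, cn, drop = FALSE]
}

.check_positive <- function(x, what) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad))
    stop(sprintf("non-positive or missing value in `%s`: %s", what,
                 paste(names(x)[bad], collapse = ", ")), call. = FALSE)
  invisible(x)
}
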