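#' Calibrated case table
#'
#' The central container of the configurational analysis: one row per case
#' (neighborhood), one integer column per calibrated factor, plus a
#' case-identifier column. Three-level factors take levels \{0, 1, 2\}; binary
#' meta-factors and the outcome take \{0, 1\}. Factor domains are stored so
#' literals can be validated and outcomes negated.
#'
#' @param data data.frame with a case-id column and integer factor columns.
#' @param outcome Name of the designated (binary) outcome factor.
#' @param case_id Name of the case-identifier column (default \code{"zcta"}).
#'   Identifiers are kept as character strings so ZCTA leading zeros survive.
#' @param domains Optional named list of integer vectors declaring each
#'   factor's domain; inferred as \code{0:max(level)} when omitted.
#' @param exclude Factor names carried in the table but excluded from
#'   configurational search (e.g. the monthly outcome components, which
#'   would trivially predict the outcome they define).
#' @return A \code{case_table}: the data.frame with attributes
#'   \code{outcome}, \code{case_id}, \code{domains}, \code{exclude}.
#' @export
case_table <- function(data, outcome, case_id = "zcta", domains = NULL,
                       exclude = character(0)) {
  stopifnot(is.data.frame(data))
  if (!case_id %in% names(data)) {
    stop("case-id column '", case_id, "' not found")
  }
  data[[case_id]] <- as.character(data[[case_id]])
  if (anyDuplicated(data[[case_id]])) {
    stop("duplicate case identifiers: ",
         paste(unique(data[[case_id]][duplicated(data[[case_id]])]),
               collapse = ", "))
  }
  fac_cols <- setdiff(names(data), case_id)
  if (length(fac_cols) < 2L) stop("need at least one factor plus the outcome")
  if (!outcome %in% fac_cols) stop("outcome '", outcome, "' not a column")
  for (f in fac_cols) {
    v <- data[[f]]
    if (anyNA(v)) stop("factor '", f, "' has missing levels")
    iv <- as.integer(v)
    if (any(iv != v) || any(iv < 0L)) {
      stop("factor '", f, "' has non-integer or negative levels")
    }
    data[[f]] <- iv
  }
  if (is.null(domains)) {
    domains <- lapply(fac_cols, function(f) 0:max(data[[f]]))
    names(domains) <- fac_cols
  } else {
    missing_dom <- setdiff(fac_cols, names(domains))
    if (length(missing_dom)) {
      stop("domains missing for: ", paste(missing_dom, collapse = ", "))
    }
    domains <- lapply(domains[fac_cols], function(d) sort(unique(as.integer(d))))
    for (f in fac_cols) {
      if (!all(data[[f]] %in% domains[[f]])) {
        stop("factor '", f, "' has levels outside its declared domain")
      }
    }
  }
  if (!setequal(domains[[outcome]], 0:1) || !all(data[[outcome]] %in% 0:1)) {
    stop("outcome '", outcome, "' must be binary with domain {0, 1}")
  }
  if (!all(exclude %in% fac_cols)) {
    stop("exclude names unknown factor(s): ",
         paste(setdiff(exclude, fac_cols), collapse = ", "))
  }
  structure(data,
            outcome = outcome, case_id = case_id, domains = domains,
            exclude = exclude,
            class = c("case_table", "data.frame"))
}

#' @export
print.case_table <- function(x, ...) {
  cat(sprintf("case_table: %d cases, %d factors, outcome '%s'\n",
              nrow(x), length(ct_factors(x)), attr(x, "outcome")))
  NextMethod()
}

# Accessors ------------------------------------------------------------

#' Factor names of a case table (excluding the case-id column)
#' @param ct A \code{case_table}.
#' @return Character vector of factor names (the outcome included).
#' @export
ct_factors <- function(ct) {
  setdiff(names(ct), attr(ct, "case_id"))
}

#' Case identifiers of a case table
#' @param ct A \code{case_table}.
#' @return Character vector of case ids.
#' @export
ct_case_ids <- function(ct) {
  as.character(ct[[attr(ct, "case_id")]])
}

#' The default positive-outcome literal of a case table
#' @param ct A \code{case_table}.
#' @param value Outcome level regarded as "present" (default 1).
#' @return A \code{geocna_literal} on the outcome factor.
#' @export
ct_outcome_literal <- function(ct, value = 1L) {
  out <- attr(ct, "outcome")
  literal(out, as.integer(value), domain = attr(ct, "domains")[[out]])
}

ct_domain <- function(ct, factor) {
  d <- attr(ct, "domains")[[factor]]
  if (is.null(d)) stop("unknown factor '", factor, "'")
  d
}
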