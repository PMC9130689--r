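# Set-theoretic evaluation of literals, conjunctions and disjunctions on a
# case table, and the two parameters of fit: consistency (sufficiency) and
# coverage (empirical importance).

cond_mask <- function(x, ct) {
  if (inherits(x, "geocna_literal")) {
    if (!x$factor %in% names(ct)) {
      stop("unknown factor '", x$factor, "' in condition")
    }
    dom <- ct_domain(ct, x$factor)
    if (!all(x$levels %in% dom)) {
      stop("literal ", format(x), ": levels outside domain of '",
           x$factor, "'")
    }
    if (length(setdiff(dom, x$levels)) == 0L) {
      stop("literal ", format(x), " is vacuous (accepts the full domain)")
    }
    return(ct[[x$factor]] %in% x$levels)
  }
  if (inherits(x, "geocna_conjunction")) {
    m <- rep(TRUE, nrow(ct))
    for (lit in x$literals) m <- m & cond_mask(lit, ct)
    return(m)
  }
  if (inherits(x, "geocna_solution")) {
    m <- rep(FALSE, nrow(ct))
    for (d in x$disjuncts) m <- m | cond_mask(d, ct)
    return(m)
  }
  if (is.character(x) && length(x) == 1L) {
    return(cond_mask(parse_condition(x), ct))
  }
  stop("cannot evaluate object of class ", paste(class(x), collapse = "/"))
}

#' Extension of a condition: the cases instantiating it
#'
#' @param x A \code{geocna_literal}, \code{geocna_conjunction},
#'   \code{geocna_solution}, or a canonical condition string.
#' @param ct A \code{case_table}.
#' @return Character vector of case ids whose levels satisfy the condition.
#' @export
#' @examples
#' ct <- build_paper_fixture()
#' length(extension("EDU=0*ICEBLACK=0|1", ct))
extension <- function(x, ct) {
  stopifnot(inherits(ct, "case_table"))
  ct_case_ids(ct)[cond_mask(x, ct)]
}

#' Consistency of a condition for an outcome
#'
#' Among cases instantiating the condition, the fraction also showing the
#' outcome: |ext(X) n ext(Y)| / |ext(X)|. Undefined (an error) when the
#' condition is instantiated by no case.
#'
#' @param x Condition (literal, conjunction, solution, or string).
#' @param outcome Outcome literal (or string); defaults to the table's
#'   positive outcome.
#' @param ct A \code{case_table}.
#' @return Fraction in \[0, 1\].
#' @export
consistency <- function(x, outcome = ct_outcome_literal(ct), ct) {
  stopifnot(inherits(ct, "case_table"))
  mx <- cond_mask(x, ct)
  if (!any(mx)) {
    stop("consistency undefined: condition '",
         if (is.character(x)) x else format(x),
         "' has an empty extension")
  }
  my <- cond_mask(outcome, ct)
  sum(mx & my) / sum(mx)
}

#' Coverage of a condition for an outcome
#'
#' Among cases showing the outcome, the fraction instantiating the condition:
#' |ext(X) n ext(Y)| / |ext(Y)|. Undefined when no case shows the outcome.
#'
#' @inheritParams consistency
#' @return Fraction in \[0, 1\].
#' @export
coverage <- function(x, outcome = ct_outcome_literal(ct), ct) {
  stopifnot(inherits(ct, "case_table"))
  my <- cond_mask(outcome, ct)
  if (!any(my)) {
    stop("coverage undefined: outcome '",
         if (is.character(outcome)) outcome else format(outcome),
         "' has an empty extension")
  }
  mx <- cond_mask(x, ct)
  sum(mx & my) / sum(my)
}

#' Consistency and coverage with their defining counts
#'
#' @inheritParams consistency
#' @return List with \code{consistency}, \code{coverage},
#'   \code{n_instantiating}, \code{n_overlap}, \code{n_outcome}.
#' @export
score_condition <- function(x, outcome = ct_outcome_literal(ct), ct) {
  stopifnot(inherits(ct, "case_table"))
  mx <- cond_mask(x, ct)
  my <- cond_mask(outcome, ct)
  if (!any(mx)) stop("score undefined: empty condition extension")
  if (!any(my)) stop("score undefined: empty outcome extension")
  ov <- sum(mx & my)
  list(consistency = ov / sum(mx), coverage = ov / sum(my),
       n_instantiating = sum(mx), n_overlap = ov, n_outcome = sum(my))
}
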