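#' Multi-value literal: a factor restricted to a set of levels
#'
#' A literal is the atomic building block of a configuration: it asserts that
#' a factor takes one of an accepted set of levels, e.g. \code{EDU = 0} or
#' \code{ICEBLACK = 0|1} ("low or medium concentrated racial privilege").
#' The accepted set must be a nonempty proper subset of the factor's domain;
#' a full-domain literal is vacuous and rejected.
#'
#' @param factor Factor name (single string).
#' @param levels Integer vector of accepted levels (nonempty, no duplicates).
#' @param domain Integer vector, the factor's full domain. Used to reject
#'   vacuous literals; if \code{NULL} the proper-subset check is deferred to
#'   evaluation time.
#' @return An object of class \code{geocna_literal}.
#' @export
#' @examples
#' literal("EDU", 0L)
#' literal("ICEBLACK", c(0L, 1L), domain = 0:2)
literal <- function(factor, levels, domain = NULL) {
  stopifnot(is.character(factor), length(factor) == 1L, nzchar(factor))
  levels <- sort(unique(as.integer(levels)))
  if (length(levels) == 0L) {
    stop("literal for '", factor, "': accepted level set must be nonempty")
  }
  if (!is.null(domain)) {
    domain <- sort(unique(as.integer(domain)))
    if (!all(levels %in% domain)) {
      stop("literal for '", factor, "': levels outside declared domain")
    }
    if (length(levels) == length(domain)) {
      stop("literal for '", factor,
           "': accepted set equals the full domain (vacuous literal)")
    }
  }
  structure(list(factor = factor, levels = levels), class = "geocna_literal")
}

#' Conjunction of literals (a configuration)
#'
#' A configuration asserts several literals jointly, at most one per factor.
#'
#' @param ... \code{geocna_literal} objects, or a single list of them.
#' @return An object of class \code{geocna_conjunction}. Literals are stored
#'   in canonical order (alphabetical by factor name).
#' @export
conjunction <- function(...) {
  lits <- list(...)
  if (length(lits) == 1L && !inherits(lits[[1L]], "geocna_literal")) {
    lits <- lits[[1L]]
  }
  if (length(lits) == 0L) stop("a conjunction requires at least one literal")
  ok <- vapply(lits, inherits, logical(1), "geocna_literal")
  if (!all(ok)) stop("all arguments must be geocna_literal objects")
  facs <- vapply(lits, `[[`, character(1), "factor")
  if (anyDuplicated(facs)) {
    stop("conjunction has two literals on factor '",
         facs[duplicated(facs)][1L], "'")
  }
  lits <- lits[order(facs)]
  structure(list(literals = lits), class = "geocna_conjunction")
}

#' Solution formula: a disjunction of configurations
#'
#' Represents equifinality: any of several pathways (configurations) suffices
#' for the outcome. Scores, when attached, are recomputable from the case
#' table.
#'
#' @param disjuncts List of \code{geocna_conjunction} objects (nonempty).
#' @param outcome Outcome literal (\code{geocna_literal}) or \code{NULL}.
#' @param consistency,coverage Optional scores in \[0, 1\].
#' @return Object of class \code{geocna_solution}.
#' @export
solution_formula <- function(disjuncts, outcome = NULL,
                             consistency = NA_real_, coverage = NA_real_) {
  if (inherits(disjuncts, "geocna_conjunction")) disjuncts <- list(disjuncts)
  if (length(disjuncts) == 0L) stop("a solution needs at least one disjunct")
  ok <- vapply(disjuncts, inherits, logical(1), "geocna_conjunction")
  if (!all(ok)) stop("disjuncts must be geocna_conjunction objects")
  keys <- vapply(disjuncts, format, character(1))
  if (anyDuplicated(keys)) stop("duplicate disjuncts in solution formula")
  disjuncts <- disjuncts[order(keys)]
  complexity <- sum(vapply(disjuncts, function(d) length(d$literals),
                           integer(1)))
  structure(list(disjuncts = disjuncts, outcome = outcome,
                 consistency = consistency, coverage = coverage,
                 complexity = complexity),
            class = "geocna_solution")
}

#' @export
format.geocna_literal <- function(x, ...) {
  paste0(x$factor, "=", paste(x$levels, collapse = "|"))
}

#' @export
format.geocna_conjunction <- function(x, ...) {
  paste(vapply(x$literals, format, character(1)), collapse = "*")
}

#' @export
format.geocna_solution <- function(x, ...) {
  paste(vapply(x$disjuncts, format, character(1)), collapse = " + ")
}

#' @export
print.geocna_literal <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' @export
print.geocna_conjunction <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' @export
print.geocna_solution <- function(x, ...) {
  cat(format(x))
  if (!is.na(x$consistency)) {
    cat(sprintf("  (consistency %.3f, coverage %.3f)",
                x$consistency, x$coverage))
  }
  cat("\n"); invisible(x)
}

#' Parse a canonical condition string
#'
#' Grammar: literals are \code{FACTOR=v} or \code{FACTOR=v1|v2}; literals are
#' joined by \code{*} into conjunctions; conjunctions joined by \code{+}
#' (surrounding whitespace ignored) into a disjunction. A string without
#' \code{+} parses to a \code{geocna_conjunction}; with \code{+} to a
#' \code{geocna_solution}.
#'
#' @param x Condition string, e.g. \code{"EDU=0*ICEBLACK=0|1"}.
#' @return A \code{geocna_conjunction} or \code{geocna_solution}.
#' @export
#' @examples
#' parse_condition("EDU=0*ICEBLACK=0|1")
#' parse_condition("EDU=1|2 + ICEBLACK=2")
parse_condition <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parse_conj <- function(s) {
    parts <- strsplit(trimws(s), "*", fixed = TRUE)[[1L]]
    lits <- lapply(parts, function(p) {
      kv <- strsplit(trimws(p), "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop("cannot parse literal '", p, "'")
      lv <- suppressWarnings(
        as.integer(strsplit(kv[2L], "|", fixed = TRUE)[[1L]]))
      if (anyNA(lv)) stop("non-integer level in literal '", p, "'")
      literal(kv[1L], lv)
    })
    conjunction(lits)
  }
  terms <- strsplit(x, "+", fixed = TRUE)[[1L]]
  if (length(terms) == 1L) return(parse_conj(terms))
  solution_formula(lapply(terms, parse_conj))
}

#' Complement (negation) of a literal
#'
#' Forms the literal accepting exactly the levels the input rejects, used to
#' negate a binary outcome for the causal-asymmetry analysis.
#'
#' @param lit A \code{geocna_literal}.
#' @param domain Integer vector, the factor's full domain.
#' @return A \code{geocna_literal} on the complementary value set.
#' @export
negate_literal <- function(lit, domain) {
  stopifnot(inherits(lit, "geocna_literal"))
  domain <- sort(unique(as.integer(domain)))
  comp <- setdiff(domain, lit$levels)
  if (length(comp) == 0L) stop("literal already covers the full domain")
  literal(lit$factor, comp, domain = domain)
}
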