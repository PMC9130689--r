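# Model building: disjunctions of minimally sufficient conditions, scored by
# model-level consistency and coverage, with ambiguity detection and the
# separate outcome-present / outcome-absent analyses (causal asymmetry).

#' Build candidate solution formulas from a condition table
#'
#' Exhaustively forms disjunctions of 1..\code{max_disjuncts} rows of the
#' msc condition table and retains those whose model-level consistency and
#' coverage meet the thresholds and that are redundancy-free: removing any
#' disjunct must drop coverage below \code{cov_threshold}, and no disjunct's
#' extension may be a subset of another disjunct's extension.
#'
#' @param msc_table A \code{condition_table} from \code{\link{enumerate_msc}}
#'   or \code{\link{threshold_search}}.
#' @param ct The \code{case_table} the condition table was computed on.
#' @param outcome Outcome literal (default: the condition table's).
#' @param con_threshold Model consistency threshold in (0, 1] (default: the
#'   condition table's msc threshold).
#' @param cov_threshold Model coverage threshold in (0, 1] (default 0.75).
#' @param max_disjuncts Maximum disjuncts per model (default 5).
#' @param node_budget Cap on search nodes explored (default 20000). On
#'   heavily noisy tables the space of irredundant covers grows
#'   exponentially; exceeding the budget raises an error of class
#'   \code{geocna_search_overflow} rather than enumerating indefinitely.
#' @return List of scored \code{geocna_solution} objects in canonical order
#'   (consistency desc, coverage desc, complexity asc, formula string).
#' @export
build_candidates <- function(msc_table, ct,
                             outcome = attr(msc_table, "outcome_literal"),
                             con_threshold = attr(msc_table, "threshold"),
                             cov_threshold = 0.75,
                             max_disjuncts = 5L,
                             node_budget = 2e4) {
  stopifnot(inherits(msc_table, "condition_table"), inherits(ct, "case_table"),
            con_threshold > 0, con_threshold <= 1,
            cov_threshold > 0, cov_threshold <= 1, max_disjuncts >= 1L)
  if (nrow(msc_table) == 0L) {
    stop("cannot build candidates from an empty condition table")
  }
  if (is.character(outcome)) outcome <- parse_condition(outcome)
  my <- cond_mask(outcome, ct)
  n_out <- sum(my)
  if (n_out == 0L) stop("outcome extension is empty")

  conjs <- lapply(msc_table$condition, parse_condition)
  masks <- vapply(conjs, cond_mask, logical(nrow(ct)), ct = ct)
  masks <- matrix(masks, nrow = nrow(ct))
  # rows with identical extensions are empirically indistinguishable
  # explanations: the search uses one representative each — the first in the
  # condition table's canonical order (lowest complexity, then
  # lexicographic). The alternatives stay visible in the condition table.
  ext_key <- apply(masks, 2L, paste, collapse = "")
  keep <- !duplicated(ext_key)
  conjs <- conjs[keep]
  masks <- masks[, keep, drop = FALSE]
  nr <- length(conjs)
  eps <- 1e-9

  # order rows by outcome overlap (descending) so the coverage upper bound
  # below is the sum of the next rows' overlaps
  row_ov <- colSums(masks & my)
  ord <- order(-row_ov)
  conjs <- conjs[ord]
  masks <- masks[, ord, drop = FALSE]
  row_ov <- row_ov[ord]

  # subset relations between disjunct extensions (structural redundancy)
  subset_of <- matrix(FALSE, nr, nr)
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    if (i != j) subset_of[i, j] <- !any(masks[, i] & !masks[, j])
  }

  need_ov <- cov_threshold * n_out - eps
  out <- list()

  # depth-first enumeration of disjunct sets with sound pruning: a branch is
  # cut when even the largest remaining overlaps cannot reach the coverage
  # threshold, and a row adding no new outcome case to the current union is
  # skipped (any model containing it fails the redundancy test)
  evaluate <- function(idx, m) {
    ninst <- sum(m)
    if (ninst == 0L) return()
    ov <- sum(m & my)
    cons <- ov / ninst
    cov <- ov / n_out
    if (cons + eps < con_threshold || cov + eps < cov_threshold) return()
    k <- length(idx)
    if (k > 1L) {
      for (drop_i in seq_len(k)) {
        m2 <- rowSums(masks[, idx[-drop_i], drop = FALSE]) > 0
        if (sum(m2 & my) + eps >= cov_threshold * n_out) return()
      }
    }
    out[[length(out) + 1L]] <<- solution_formula(conjs[idx],
                                                 outcome = outcome,
                                                 consistency = cons,
                                                 coverage = cov)
  }
  pos_masks <- masks & my
  nodes <- 0L
  recurse <- function(start, idx, union_m, union_ov) {
    nodes <<- nodes + 1L
    if (nodes > node_budget) {
      stop(structure(class = c("geocna_search_overflow", "error",
                               "condition"),
                     list(message = paste0(
                       "candidate search exceeded its node budget (",
                       format(node_budget, scientific = FALSE),
                       "); the table holds too many overlapping ",
                       "configurations - raise the consistency/coverage ",
                       "thresholds or lower max_disjuncts"),
                       call = NULL)))
    }
    depth <- length(idx)
    if (depth > 0L) evaluate(idx, union_m)
    if (depth == max_disjuncts || start > nr) return()
    slots <- max_disjuncts - depth
    for (i in start:nr) {
      ub <- union_ov + sum(row_ov[i:min(nr, i + slots - 1L)])
      if (ub < need_ov) break  # rows are overlap-sorted: no later row helps
      if (depth > 0L &&
          (any(subset_of[idx, i]) || any(subset_of[i, idx]))) next
      add <- sum(pos_masks[, i] & !union_m)
      if (depth > 0L && add == 0L) next
      idx2 <- c(idx, i)
      union2 <- union_m | masks[, i]
      ov2 <- union_ov + add
      # a disjunct whose unique contribution is already below the
      # redundancy margin can never survive the leave-one-out test (unique
      # contributions only shrink, the margin only grows)
      if (depth > 0L) {
        margin <- ov2 - need_ov
        dead <- FALSE
        for (d in seq_along(idx2)) {
          others <- rowSums(pos_masks[, idx2[-d], drop = FALSE]) > 0
          uniq <- sum(pos_masks[, idx2[d]] & !others)
          if (uniq == 0L || uniq <= margin) { dead <- TRUE; break }
        }
        if (dead) next
      }
      recurse(i + 1L, idx2, union2, ov2)
    }
  }
  recurse(1L, integer(0), rep(FALSE, nrow(ct)), 0L)
  if (length(out)) {
    key <- vapply(out, format, character(1))
    cons <- vapply(out, `[[`, numeric(1), "consistency")
    cov <- vapply(out, `[[`, numeric(1), "coverage")
    cmplx <- vapply(out, `[[`, numeric(1), "complexity")
    out <- out[order(-cons, -cov, cmplx, key)]
  }
  out
}

#' Select a final model, surfacing ambiguity
#'
#' Ranks candidates by (consistency desc, coverage desc, complexity asc). If
#' a unique best exists it becomes the final model; if two or more candidates
#' tie on all three keys the report flags model ambiguity, returns no final
#' model, and lists the tied set.
#'
#' @param candidates List of scored \code{geocna_solution} objects.
#' @return A \code{geocna_model_report}: list with \code{candidates},
#'   \code{final} (solution or \code{NULL}), \code{ambiguity} (logical),
#'   \code{tied} (list of solutions when ambiguous), \code{status}.
#' @export
select_final <- function(candidates) {
  if (length(candidates) == 0L) {
    return(structure(list(candidates = list(), final = NULL,
                          ambiguity = FALSE, tied = list(),
                          status = "no model met the thresholds"),
                     class = "geocna_model_report"))
  }
  cons <- vapply(candidates, `[[`, numeric(1), "consistency")
  cov <- vapply(candidates, `[[`, numeric(1), "coverage")
  cmplx <- vapply(candidates, `[[`, numeric(1), "complexity")
  o <- order(-cons, -cov, cmplx,
             vapply(candidates, format, character(1)))
  candidates <- candidates[o]
  cons <- cons[o]; cov <- cov[o]; cmplx <- cmplx[o]
  eps <- 1e-9
  tied <- abs(cons - cons[1L]) < eps & abs(cov - cov[1L]) < eps &
    cmplx == cmplx[1L]
  if (sum(tied) > 1L) {
    structure(list(candidates = candidates, final = NULL, ambiguity = TRUE,
                   tied = candidates[tied],
                   status = sprintf("ambiguous: %d models tie", sum(tied))),
              class = "geocna_model_report")
  } else {
    structure(list(candidates = candidates, final = candidates[[1L]],
                   ambiguity = FALSE, tied = list(), status = "ok"),
              class = "geocna_model_report")
  }
}

#' @export
print.geocna_model_report <- function(x, ...) {
  cat("geocna model report —", x$status, "\n")
  if (!is.null(x$final)) {
    cat("final:", format(x$final),
        sprintf("(consistency %.2f, coverage %.2f)\n",
                x$final$consistency, x$final$coverage))
  } else if (x$ambiguity) {
    for (m in x$tied) cat("  tied:", format(m), "\n")
  }
  cat(length(x$candidates), "candidate model(s)\n")
  invisible(x)
}

#' Separate analyses for an outcome and its negation
#'
#' Configurational models are causally asymmetric: the pathways to an
#' outcome's presence need not mirror the pathways to its absence, so each is
#' analyzed independently. Runs the full chain — threshold-lowering msc
#' search, candidate building, final-model selection — once for the outcome
#' literal and once for its complement, sharing no fitted state.
#'
#' After the msc search stops, model building at the stopping threshold may
#' yield no admissible candidate (every retained configuration can fall
#' short of the coverage threshold). Mirroring the iterative workflow, the
#' analysis then keeps lowering the consistency threshold — re-enumerating
#' msc and rebuilding candidates at each step — until a final model or an
#' ambiguous tie emerges, or the threshold floor is reached (reported as
#' no-model).
#'
#' @inheritParams threshold_search
#' @param con_threshold Model consistency threshold; \code{NULL} (default)
#'   uses each side's current msc threshold (and extends the search as
#'   described). A fixed numeric value disables the extension.
#' @param cov_threshold Model coverage threshold (default 0.75).
#' @param max_disjuncts Maximum disjuncts per model (default 5).
#' @return List with elements \code{positive} and \code{negative}, each a
#'   \code{geocna_model_report} augmented with \code{threshold},
#'   \code{cov_threshold} and the search \code{trail}.
#' @export
asymmetric_analysis <- function(ct, outcome = ct_outcome_literal(ct),
                                max_order = 3L, start = 1, step = 0.05,
                                min_rows = 2L, con_threshold = NULL,
                                cov_threshold = 0.75, max_disjuncts = 5L) {
  stopifnot(inherits(ct, "case_table"))
  if (is.character(outcome)) outcome <- parse_condition(outcome)
  dom <- ct_domain(ct, outcome$factor)
  if (length(dom) != 2L) stop("asymmetric analysis needs a binary outcome")
  sides <- list(positive = outcome,
                negative = negate_literal(outcome, dom))
  lapply(names(sides), function(side) {
    tryCatch(
      configurational_chain(ct, sides[[side]], max_order = max_order,
                            start = start, step = step, min_rows = min_rows,
                            con_threshold = con_threshold,
                            cov_threshold = cov_threshold,
                            max_disjuncts = max_disjuncts),
      error = function(e) {
        stop(side, "-side analysis failed: ", conditionMessage(e),
             call. = FALSE)
      })
  }) |> stats::setNames(names(sides))
}

#' Factor selection and model building for a single outcome literal
#'
#' The one-sided engine behind \code{\link{asymmetric_analysis}}: runs the
#' threshold-lowering msc search, then model building at the stopping
#' threshold, continuing to lower the threshold while no final model (or
#' ambiguous tie) emerges, and returns the model report with its full
#' threshold trail.
#'
#' @inheritParams asymmetric_analysis
#' @param outcome Outcome literal to model (not defaulted: pass the positive
#'   literal or its negation).
#' @return A \code{geocna_model_report}.
#' @export
configurational_chain <- function(ct, outcome, max_order = 3L, start = 1,
                                  step = 0.05, min_rows = 2L,
                                  con_threshold = NULL, cov_threshold = 0.75,
                                  max_disjuncts = 5L) {
  if (is.character(outcome)) outcome <- parse_condition(outcome)
  ts <- threshold_search(ct, outcome, max_order = max_order,
                         start = start, step = step, min_rows = min_rows)
  trail <- ts$trail
  th <- ts$threshold
  tab <- ts$table
  repeat {
    cth <- if (is.null(con_threshold)) th else con_threshold
    overflow <- FALSE
    rep <- if (nrow(tab) == 0L) select_final(list()) else {
      tryCatch(
        select_final(build_candidates(tab, ct, outcome = outcome,
                                      con_threshold = cth,
                                      cov_threshold = cov_threshold,
                                      max_disjuncts = max_disjuncts)),
        geocna_search_overflow = function(e) {
          overflow <<- TRUE
          r <- select_final(list())
          r$status <- conditionMessage(e)
          r
        })
    }
    if (overflow || !is.null(rep$final) || rep$ambiguity ||
        !is.null(con_threshold)) break
    th2 <- round(th - step, 10)
    if (th2 <= 1e-9) break
    th <- th2
    tab <- enumerate_msc(ct, outcome, max_order = max_order,
                         threshold = th)
    trail <- rbind(trail,
                   data.frame(threshold = th, n_rows = nrow(tab)))
  }
  rep$threshold <- cth
  rep$cov_threshold <- cov_threshold
  rep$trail <- trail
  rep$condition_table <- tab
  rep$outcome <- outcome
  rep
}
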