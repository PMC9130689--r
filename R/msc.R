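# Exhaustive enumeration of minimally sufficient conditions (msc) and the
# iterative threshold-lowering search over condition tables.

# All nonempty proper subsets of a factor's domain, as a list of integer
# vectors (e.g. domain 0:2 -> {0},{1},{2},{0,1},{0,2},{1,2}).
proper_subsets <- function(domain) {
  n <- length(domain)
  out <- vector("list", 2^n - 2L)
  k <- 0L
  for (m in seq_len(2^n - 2L)) {
    pick <- as.logical(bitwAnd(m, 2^(seq_len(n) - 1L)))
    k <- k + 1L
    out[[k]] <- domain[pick]
  }
  out
}

lit_key <- function(factor, levels) paste0(factor, "=", paste(levels, collapse = "|"))

# A conjunction D is a relaxation of C when D's factors are a subset of C's
# and, on each shared factor, D's accepted set contains C's: D then asserts
# strictly less, and its extension contains C's. C is minimal iff no other
# passing conjunction is a relaxation of it. The passing set is bucketed by
# factor set so each candidate only compares against conjunctions on a
# subset of its own factors.
minimal_flags <- function(pass_facs, pass_levs) {
  np <- length(pass_facs)
  fs_key <- vapply(pass_facs, paste, character(1), collapse = "|")
  buckets <- split(seq_len(np), fs_key)
  minimal <- logical(np)
  for (i in seq_len(np)) {
    facs_i <- pass_facs[[i]]
    levs_i <- pass_levs[[i]]
    k <- length(facs_i)
    is_min <- TRUE
    for (m in seq_len(2^k - 1L)) {
      keep <- as.logical(bitwAnd(m, 2^(seq_len(k) - 1L)))
      bk <- buckets[[paste(facs_i[keep], collapse = "|")]]
      if (is.null(bk)) next
      levs_s <- levs_i[keep]
      for (j in bk) {
        if (j == i) next
        dl <- pass_levs[[j]]
        ok <- TRUE
        for (t in seq_along(dl)) {
          if (!all(levs_s[[t]] %in% dl[[t]])) { ok <- FALSE; break }
        }
        if (ok) { is_min <- FALSE; break }
      }
      if (!is_min) break
    }
    minimal[i] <- is_min
  }
  minimal
}

#' Enumerate minimally sufficient conditions
#'
#' Exhaustively considers every conjunction of up to \code{max_order}
#' value-set literals over the non-outcome factors, retains those that are
#' instantiated in the data and meet the consistency threshold, and keeps
#' only the minimal ones: a conjunction is dropped when any relaxation of it
#' (a proper sub-conjunction, or the same conjunction with one or more
#' accepted sets enlarged) already meets the threshold. Rows carry
#' consistency, coverage and their defining counts.
#'
#' @param ct A \code{case_table}.
#' @param outcome Outcome literal (default: the table's positive outcome).
#' @param max_order Maximum number of literals per conjunction (default 3,
#'   mirroring a one-/two-/three-condition scan).
#' @param threshold Consistency threshold in (0, 1].
#' @return A \code{condition_table}: data.frame with columns
#'   \code{outcome}, \code{condition}, \code{consistency}, \code{coverage},
#'   \code{n_instantiating}, \code{n_overlap}, \code{order}, sorted by
#'   (consistency desc, coverage desc, order asc, condition), with
#'   attributes \code{threshold} and \code{outcome_literal}.
#' @export
enumerate_msc <- function(ct, outcome = ct_outcome_literal(ct),
                          max_order = 3L, threshold = 1) {
  stopifnot(inherits(ct, "case_table"))
  if (is.character(outcome)) outcome <- parse_condition(outcome)
  stopifnot(inherits(outcome, "geocna_literal"),
            max_order >= 1L, threshold > 0, threshold <= 1)
  my <- cond_mask(outcome, ct)
  if (all(my) || !any(my)) {
    stop("degenerate outcome: '", format(outcome),
         "' is constant across cases")
  }
  domains <- attr(ct, "domains")
  facs <- setdiff(ct_factors(ct), c(outcome$factor, attr(ct, "exclude")))
  facs <- facs[vapply(facs, function(f) length(domains[[f]]) > 1L, logical(1))]
  if (length(facs) == 0L) stop("no candidate factors besides the outcome")

  # masks for every candidate literal, grouped by factor
  lit_masks <- list()
  lit_keys <- list()
  lit_levs <- list()
  for (f in facs) {
    subs <- proper_subsets(domains[[f]])
    lit_levs[[f]] <- subs
    lit_keys[[f]] <- vapply(subs, function(s) lit_key(f, s), character(1))
    lit_masks[[f]] <- vapply(subs, function(s) ct[[f]] %in% s,
                             logical(nrow(ct)))
  }

  eps <- 1e-9
  pass_key <- character(0)
  pass_cons <- numeric(0)
  pass_cov <- numeric(0)
  pass_ninst <- integer(0)
  pass_nov <- integer(0)
  pass_order <- integer(0)
  pass_facs <- list()
  pass_levs <- list()
  n_out <- sum(my)

  max_order <- min(max_order, length(facs))
  for (ord in seq_len(max_order)) {
    fac_combos <- utils::combn(facs, ord, simplify = FALSE)
    for (fc in fac_combos) {
      idx <- as.matrix(do.call(expand.grid,
                               lapply(fc, function(f) {
                                 seq_along(lit_levs[[f]])
                               })))
      masks_fc <- lit_masks[fc]
      keys_fc <- lit_keys[fc]
      levs_fc <- lit_levs[fc]
      for (r in seq_len(nrow(idx))) {
        m <- masks_fc[[1L]][, idx[r, 1L]]
        if (ord > 1L) {
          for (j in 2:ord) m <- m & masks_fc[[j]][, idx[r, j]]
        }
        ninst <- sum(m)
        if (ninst == 0L) next
        nov <- sum(m & my)
        cons <- nov / ninst
        if (cons + eps < threshold) next
        n_pass <- length(pass_key) + 1L
        pass_key[n_pass] <- paste(vapply(seq_len(ord), function(j) {
          keys_fc[[j]][idx[r, j]]
        }, character(1)), collapse = "*")
        pass_cons[n_pass] <- cons
        pass_cov[n_pass] <- nov / n_out
        pass_ninst[n_pass] <- ninst
        pass_nov[n_pass] <- nov
        pass_order[n_pass] <- ord
        pass_facs[[n_pass]] <- fc
        pass_levs[[n_pass]] <- lapply(seq_len(ord), function(j) {
          levs_fc[[j]][[idx[r, j]]]
        })
      }
    }
  }

  minimal <- if (length(pass_key)) minimal_flags(pass_facs, pass_levs) else
    logical(0)

  tab <- data.frame(outcome = rep(format(outcome), sum(minimal)),
                    condition = pass_key[minimal],
                    consistency = pass_cons[minimal],
                    coverage = pass_cov[minimal],
                    n_instantiating = pass_ninst[minimal],
                    n_overlap = pass_nov[minimal],
                    order = pass_order[minimal],
                    stringsAsFactors = FALSE)
  o <- order(-tab$consistency, -tab$coverage, tab$order, tab$condition)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, threshold = threshold, outcome_literal = outcome,
            class = c("condition_table", "data.frame"))
}

#' @export
print.condition_table <- function(x, ...) {
  cat(sprintf("condition_table: %d configuration(s) at consistency >= %.2f for %s\n",
              nrow(x), attr(x, "threshold"),
              if (nrow(x)) x$outcome[1L] else format(attr(x, "outcome_literal"))))
  NextMethod()
}

#' Iterative consistency-threshold search
#'
#' Starts at a consistency threshold of \code{start} (default 1.00) and
#' lowers it by \code{step} (default 0.05: 1.00, 0.95, 0.90, ...) until the
#' condition table holds at least \code{min_rows} configurations, recording
#' the full trail of thresholds visited and the row count at each.
#'
#' @inheritParams enumerate_msc
#' @param start First threshold tried.
#' @param step Decrement per iteration.
#' @param min_rows Minimum number of configurations required to stop
#'   (default 2).
#' @return List with \code{threshold} (the stopping threshold),
#'   \code{table} (the \code{condition_table} at that threshold), and
#'   \code{trail} (data.frame of \code{threshold}, \code{n_rows}).
#' @export
threshold_search <- function(ct, outcome = ct_outcome_literal(ct),
                             max_order = 3L, start = 1, step = 0.05,
                             min_rows = 2L) {
  stopifnot(start > 0, start <= 1, step > 0, min_rows >= 1L)
  trail <- data.frame(threshold = numeric(0), n_rows = integer(0))
  k <- 0L
  repeat {
    th <- round(start - k * step, 10)
    if (th <= 1e-9) {
      stop("threshold search exhausted: fewer than ", min_rows,
           " configurations at every threshold down to ",
           format(round(start - (k - 1L) * step, 10)))
    }
    tab <- enumerate_msc(ct, outcome, max_order = max_order, threshold = th)
    trail <- rbind(trail, data.frame(threshold = th, n_rows = nrow(tab)))
    if (nrow(tab) >= min_rows) {
      return(list(threshold = th, table = tab, trail = trail))
    }
    k <- k + 1L
  }
}
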