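# Synthetic neighborhood-data generator: plants a Boolean configurational
# rule in a small multi-value dataset, back-fills raw continuous variables so
# that calibration reproduces the planted levels exactly, and emulates the
# shape of the study city (43 cases, 8 three-level social factors, a binary
# persistently-low outcome with prevalence 13/43).
#
# Social conditions are strongly collinear across neighborhoods, so factor
# levels are drawn from a shared latent advantage gradient with per-factor
# jitter rather than independently: each case's factors mostly sit in the
# same tertile. Independent draws would scatter cases over thousands of
# distinct level combinations, a regime real ACS-style data never shows.

#' Specification for the synthetic generator
#'
#' Defaults emulate the study conditions: 43 neighborhood cases, 8
#' three-level social factors named A..H (each carrying the cut-points and
#' raw range of one of the shipped calibration schemes), a planted rule
#' \code{"A=0*B=0|1"}, no outcome noise, and 13 outcome-positive cases.
#'
#' @param n_cases Number of cases (default 43).
#' @param planted_rule Canonical condition string (conjunction or
#'   disjunction) over the synthetic factors, or \code{NULL} for a
#'   pure-noise outcome independent of all factors.
#' @param noise Probability in \[0, 0.5) that a case's outcome is flipped
#'   from the rule's prediction (default 0).
#' @param n_positive Target number of rule-satisfying cases before noise
#'   (default 13), or \code{NULL} to leave prevalence to chance.
#' @param factor_names Names of the synthetic factors (default
#'   \code{LETTERS[1:8]}); each is assigned the cuts and raw range of one
#'   shipped social-condition scheme, in order.
#' @param jitter Probability that a factor level deviates by one step from
#'   the case's latent-gradient tertile (default 0.25); controls how
#'   collinear the social conditions are.
#' @param seed Integer PRNG seed or \code{NULL}.
#' @return Object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_cases = 43L, planted_rule = "A=0*B=0|1",
                           noise = 0, n_positive = 13L,
                           factor_names = LETTERS[1:8], jitter = 0.25,
                           seed = NULL) {
  stopifnot(n_cases >= 4L, noise >= 0, noise < 0.5,
            length(factor_names) >= 2L, jitter >= 0, jitter <= 0.5)
  if (!is.null(planted_rule)) {
    rule <- parse_condition(planted_rule)
    if (inherits(rule, "geocna_conjunction")) rule <- solution_formula(rule)
    rf <- unique(unlist(lapply(rule$disjuncts, function(d) {
      vapply(d$literals, `[[`, character(1), "factor")
    })))
    if (!all(rf %in% factor_names)) {
      stop("planted rule references undeclared factor(s): ",
           paste(setdiff(rf, factor_names), collapse = ", "))
    }
  }
  if (!is.null(n_positive)) {
    stopifnot(n_positive >= 1L, n_positive < n_cases)
  }
  structure(list(n_cases = as.integer(n_cases), planted_rule = planted_rule,
                 noise = noise, n_positive = n_positive,
                 factor_names = factor_names, jitter = jitter, seed = seed),
            class = "synthetic_spec")
}

# Schemes for the synthetic factors: the shipped social-condition cut-points
# and raw ranges, renamed to the synthetic factor names, plus the three
# vaccination-rate schemes (kept under their own names).
synthetic_schemes <- function(factor_names) {
  base <- default_schemes()
  social <- base[c("EDU", "ICEBLACK", "ICEINC", "UNINS",
                   "LEP", "TRANSIT", "SERVICE", "OVERCROWD")]
  if (length(factor_names) > length(social)) {
    stop("at most ", length(social), " synthetic factors are supported")
  }
  out <- list()
  for (i in seq_along(factor_names)) {
    s <- social[[i]]
    s$scheme$name <- factor_names[i]
    out[[factor_names[i]]] <- s
  }
  c(out, base[c("VAX_MAR", "VAX_APR", "VAX_MAY")])
}

# Uniform draw from the raw interval mapping to `level` under `entry`'s
# scheme: level 0 on [lo, c1], 1 on (c1, c2], 2 on (c2, hi]. Half-open
# intervals are sampled with a small inset so calibration round-trips.
backfill_raw <- function(level, entry) {
  c1 <- entry$scheme$cuts[1L]; c2 <- entry$scheme$cuts[2L]
  lo <- entry$raw_range[1L]; hi <- entry$raw_range[2L]
  n <- length(level)
  a <- ifelse(level == 0L, lo, ifelse(level == 1L, c1, c2))
  b <- ifelse(level == 0L, c1, ifelse(level == 1L, c2, hi))
  u <- stats::runif(n, min = ifelse(level == 0L, 0, 1e-6), max = 1)
  a + (b - a) * u
}

#' Generate a synthetic neighborhood dataset with a planted rule
#'
#' Draws factor levels so that every level of every factor is occupied,
#' assigns the outcome by the planted rule (with the target number of
#' rule-satisfying cases when requested), flips each case's outcome
#' independently with the noise probability, constructs three monthly
#' vaccination-rate levels consistent with the binary outcome (all-low
#' exactly when the outcome is present), and back-fills raw continuous
#' values uniformly within each level's raw interval so that calibrating
#' the raw table with the returned schemes reproduces the case table
#' exactly.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return List with \code{raw} (a \code{raw_table}), \code{case_table},
#'   \code{schemes} (for re-calibration), and \code{truth} (planted rule,
#'   flipped case ids, seed).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_cases
  facs <- spec$factor_names
  schemes <- synthetic_schemes(facs)

  rule <- NULL
  if (!is.null(spec$planted_rule)) {
    rule <- parse_condition(spec$planted_rule)
    if (inherits(rule, "geocna_conjunction")) rule <- solution_formula(rule)
  }

  rule_facs <- if (is.null(rule)) character(0) else {
    unique(unlist(lapply(rule$disjuncts, function(d) {
      vapply(d$literals, `[[`, character(1), "factor")
    })))
  }
  single_conj <- !is.null(rule) && length(rule$disjuncts) == 1L
  near <- function(x, set) set[which.min(abs(set - x))]
  sat_eval <- function(lv) {
    vapply(seq_len(nrow(lv)), function(i) {
      any(vapply(rule$disjuncts, function(d) {
        all(vapply(d$literals, function(l) {
          lv[i, l$factor] %in% l$levels
        }, logical(1)))
      }, logical(1)))
    }, logical(1))
  }
  sat_tuples <- NULL
  if (length(rule_facs) && !single_conj) {
    grid <- do.call(expand.grid, stats::setNames(
      rep(list(0:2), length(rule_facs)), rule_facs))
    sat <- vapply(seq_len(nrow(grid)), function(i) {
      any(vapply(rule$disjuncts, function(d) {
        all(vapply(d$literals, function(l) {
          grid[i, l$factor] %in% l$levels
        }, logical(1)))
      }, logical(1)))
    }, logical(1))
    if (!any(sat) || all(sat)) {
      stop("unsatisfiable or vacuous planted rule: ", spec$planted_rule)
    }
    sat_tuples <- list(yes = grid[sat, , drop = FALSE],
                       no = grid[!sat, , drop = FALSE])
  }

  for (attempt in 1:200) {
    # shared latent advantage gradient; factor levels are the case's latent
    # tertile, jittered one step per factor with probability spec$jitter
    u <- stats::runif(n)
    b <- pmin(2L, (rank(u, ties.method = "first") - 1L) %/%
                as.integer(ceiling(n / 3)))
    levels <- matrix(0L, nrow = n, ncol = length(facs),
                     dimnames = list(NULL, facs))
    for (f in facs) {
      lv <- b
      flip <- stats::runif(n) < spec$jitter
      dir <- sample(c(-1L, 1L), n, replace = TRUE)
      lv[flip] <- pmax(0L, pmin(2L, lv[flip] + dir[flip]))
      levels[, f] <- lv
    }

    if (!is.null(rule)) {
      if (!is.null(spec$n_positive)) {
        # the most deprived cases instantiate the rule
        sat_case <- logical(n)
        sat_case[order(u)[seq_len(spec$n_positive)]] <- TRUE
        if (single_conj) {
          lits <- rule$disjuncts[[1L]]$literals
          for (l in lits) {
            v <- levels[, l$factor]
            bad <- sat_case & !(v %in% l$levels)
            v[bad] <- vapply(v[bad], near, integer(1), set = l$levels)
            levels[, l$factor] <- v
          }
          # break the rule, minimally, for non-target cases satisfying it
          offenders <- which(!sat_case & sat_eval(levels))
          for (i in offenders) {
            dists <- vapply(lits, function(l) {
              min(abs(levels[i, l$factor] - setdiff(0:2, l$levels)))
            }, numeric(1))
            l <- lits[[which.min(dists)]]
            levels[i, l$factor] <- near(levels[i, l$factor],
                                        setdiff(0:2, l$levels))
          }
          # identifiability of the planted rule. (1) Each accepted level of
          # every literal is occupied among the rule cases, and the most
          # deprived rule case keeps a fully deprived profile, so no
          # narrower or factor-swapped condition covers all positives.
          sat_order <- intersect(order(u), which(sat_case))
          i0 <- sat_order[1L]
          levels[i0, ] <- vapply(facs, function(f) {
            l <- Filter(function(x) x$factor == f, lits)
            if (length(l)) near(0L, l[[1L]]$levels) else 0L
          }, integer(1))
          pos <- 1L
          for (l in lits) {
            for (v in setdiff(l$levels, levels[i0, l$factor])) {
              pos <- pos + 1L
              if (pos <= length(sat_order)) {
                levels[sat_order[pos], l$factor] <- v
              }
            }
          }
          # (2) Minimal-pair contrast cases: for every level outside each
          # literal's accepted set, one negative case deviating from the
          # deprived rule profile in that literal only, so every
          # enlargement or simplification of the rule catches a negative.
          ns <- setdiff(order(u), which(sat_case))
          j <- 0L
          for (k in seq_along(lits)) {
            for (v in setdiff(0:2, lits[[k]]$levels)) {
              j <- j + 1L
              i <- ns[j]
              levels[i, ] <- levels[i0, ]
              levels[i, lits[[k]]$factor] <- v
            }
          }
        } else {
          yes_pick <- sample(nrow(sat_tuples$yes), sum(sat_case),
                             replace = TRUE)
          no_pick <- sample(nrow(sat_tuples$no), sum(!sat_case),
                            replace = TRUE)
          levels[sat_case, rule_facs] <-
            as.matrix(sat_tuples$yes[yes_pick, , drop = FALSE])
          levels[!sat_case, rule_facs] <-
            as.matrix(sat_tuples$no[no_pick, , drop = FALSE])
        }
        if (!identical(sat_eval(levels), sat_case)) next
        y_rule <- as.integer(sat_case)
      } else {
        y_rule <- as.integer(sat_eval(levels))
        if (sum(y_rule) == 0L || sum(y_rule) == n) next
      }
    } else {
      np <- if (is.null(spec$n_positive)) stats::rbinom(1L, n, 13 / 43) else
        spec$n_positive
      y_rule <- integer(n)
      y_rule[sample.int(n, np)] <- 1L
    }
    if (all(apply(levels, 2L, function(v) length(unique(v)) == 3L))) break
    if (attempt == 200L) {
      stop("generation error: could not occupy all levels of every factor")
    }
  }

  flips <- which(stats::runif(n) < spec$noise)
  y <- y_rule
  y[flips] <- 1L - y[flips]

  # monthly vaccination levels: all-low iff outcome present
  vax <- matrix(0L, nrow = n, ncol = 3L,
                dimnames = list(NULL, c("VAX_MAR", "VAX_APR", "VAX_MAY")))
  not_low <- which(y == 0L)
  if (length(not_low)) {
    alt <- as.matrix(expand.grid(0:2, 0:2, 0:2))
    alt <- alt[rowSums(alt == 0L) < 3L, , drop = FALSE]
    vax[not_low, ] <- alt[sample(nrow(alt), length(not_low),
                                 replace = TRUE), ]
  }

  ids <- sprintf("19%03d", seq_len(n))
  raw <- data.frame(zcta = ids, stringsAsFactors = FALSE)
  for (f in facs) raw[[schemes[[f]]$column]] <- backfill_raw(levels[, f],
                                                             schemes[[f]])
  for (j in 1:3) {
    nm <- colnames(vax)[j]
    raw[[schemes[[nm]]$column]] <- backfill_raw(vax[, j], schemes[[nm]])
  }
  raw <- structure(raw, case_id = "zcta",
                   class = c("raw_table", "data.frame"))

  case_df <- data.frame(zcta = ids, stringsAsFactors = FALSE)
  for (f in facs) case_df[[f]] <- levels[, f]
  for (j in 1:3) case_df[[colnames(vax)[j]]] <- vax[, j]
  case_df$LOWVAX <- y
  domains <- c(stats::setNames(rep(list(0:2), length(facs) + 3L),
                               c(facs, colnames(vax))),
               list(LOWVAX = 0:1))
  ct <- case_table(case_df, outcome = "LOWVAX", case_id = "zcta",
                   domains = domains,
                   exclude = c("VAX_MAR", "VAX_APR", "VAX_MAY"))

  list(raw = raw, case_table = ct, schemes = schemes,
       truth = list(rule = spec$planted_rule,
                    flipped = ids[flips],
                    y_rule = y_rule,
                    seed = spec$seed,
                    spec = spec))
}
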