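# Independent brute-force oracles for the configurational engine, written as
# straightforward generate-and-filter over explicit level-set enumerations
# (no shared code with the package internals beyond the canonical string
# grammar used for comparison).

# all nonempty proper subsets of a domain, smallest-first
oracle_subsets <- function(domain) {
  out <- list()
  for (k in seq_len(length(domain) - 1L)) {
    cmb <- utils::combn(domain, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

oracle_lit_str <- function(f, s) paste0(f, "=", paste(sort(s), collapse = "|"))

# exhaustive msc enumeration: every conjunction of <= max_order value-set
# literals, instantiated, consistency >= threshold, minimal (no passing
# conjunction asserts strictly less)
oracle_msc <- function(ct, outcome, max_order = 3L, threshold = 1) {
  df <- as.data.frame(ct)
  doms <- attr(ct, "domains")
  if (is.character(outcome)) outcome <- parse_condition(outcome)
  y <- df[[outcome$factor]] %in% outcome$levels
  facs <- setdiff(ct_factors(ct), c(outcome$factor, attr(ct, "exclude")))
  facs <- facs[vapply(facs, function(f) length(doms[[f]]) > 1L, logical(1))]
  n_out <- sum(y)

  recs <- list()
  for (ord in seq_len(min(max_order, length(facs)))) {
    for (fc in utils::combn(facs, ord, simplify = FALSE)) {
      choice_sets <- lapply(fc, function(f) oracle_subsets(doms[[f]]))
      pick <- rep(1L, ord)
      lens <- lengths(choice_sets)
      repeat {
        sets <- lapply(seq_len(ord), function(j) choice_sets[[j]][[pick[j]]])
        m <- rep(TRUE, nrow(df))
        for (j in seq_len(ord)) m <- m & (df[[fc[j]]] %in% sets[[j]])
        ninst <- sum(m)
        if (ninst > 0L) {
          ov <- sum(m & y)
          if (ov / ninst >= threshold - 1e-9) {
            recs[[length(recs) + 1L]] <- list(
              facs = fc, sets = sets,
              condition = paste(mapply(oracle_lit_str, fc, sets),
                                collapse = "*"),
              consistency = ov / ninst, coverage = ov / n_out,
              n_instantiating = ninst, n_overlap = ov, order = ord)
          }
        }
        j <- ord
        while (j >= 1L) {
          pick[j] <- pick[j] + 1L
          if (pick[j] <= lens[j]) break
          pick[j] <- 1L
          j <- j - 1L
        }
        if (j < 1L) break
      }
    }
  }

  # pairwise minimality: drop rec i if some other passing rec asserts
  # strictly less (factors a subset, accepted sets supersets on shared)
  n <- length(recs)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ri <- recs[[i]]; rj <- recs[[j]]
      if (!all(rj$facs %in% ri$facs)) next
      if (identical(rj$condition, ri$condition)) next
      relax <- TRUE
      for (t in seq_along(rj$facs)) {
        si <- ri$sets[[match(rj$facs[t], ri$facs)]]
        if (!all(si %in% rj$sets[[t]])) { relax <- FALSE; break }
      }
      if (relax) { keep[i] <- FALSE; break }
    }
  }
  recs <- recs[keep]
  if (!length(recs)) {
    return(data.frame(condition = character(0), consistency = numeric(0),
                      coverage = numeric(0), n_instantiating = integer(0),
                      n_overlap = integer(0), order = integer(0)))
  }
  out <- data.frame(
    condition = vapply(recs, `[[`, character(1), "condition"),
    consistency = vapply(recs, `[[`, numeric(1), "consistency"),
    coverage = vapply(recs, `[[`, numeric(1), "coverage"),
    n_instantiating = vapply(recs, function(r) as.integer(r$n_instantiating),
                             integer(1)),
    n_overlap = vapply(recs, function(r) as.integer(r$n_overlap), integer(1)),
    order = vapply(recs, function(r) as.integer(r$order), integer(1)),
    stringsAsFactors = FALSE)
  out[order(-out$consistency, -out$coverage, out$order, out$condition), ,
      drop = FALSE]
}

# brute-force candidate models from a condition table: subsets of rows
# (deduplicated by extension, first-in-table representative), scored on the
# union, filtered by thresholds, pairwise-subset freedom and leave-one-out
# coverage necessity
oracle_candidates <- function(msc_tab, ct, outcome, con_threshold,
                              cov_threshold = 0.75, max_disjuncts = 5L) {
  if (is.character(outcome)) outcome <- parse_condition(outcome)
  df <- as.data.frame(ct)
  ids <- ct_case_ids(ct)
  y_ids <- ids[df[[outcome$factor]] %in% outcome$levels]
  exts <- lapply(msc_tab$condition, function(s) sort(extension(s, ct)))
  keys <- vapply(exts, paste, character(1), collapse = ",")
  first <- !duplicated(keys)
  conds <- msc_tab$condition[first]
  exts <- exts[first]
  nr <- length(conds)
  res <- list()
  for (k in seq_len(min(max_disjuncts, nr))) {
    for (ss in utils::combn(nr, k, simplify = FALSE)) {
      pairfail <- FALSE
      if (k > 1L) {
        for (a in ss) for (b in ss) {
          if (a != b && all(exts[[a]] %in% exts[[b]])) pairfail <- TRUE
        }
      }
      if (pairfail) next
      un <- unique(unlist(exts[ss]))
      ov <- sum(un %in% y_ids)
      cons <- ov / length(un)
      cov <- ov / length(y_ids)
      if (cons < con_threshold - 1e-9 || cov < cov_threshold - 1e-9) next
      if (k > 1L) {
        red <- FALSE
        for (d in ss) {
          un2 <- unique(unlist(exts[setdiff(ss, d)]))
          if (sum(un2 %in% y_ids) / length(y_ids) >= cov_threshold - 1e-9) {
            red <- TRUE
            break
          }
        }
        if (red) next
      }
      parts <- sort(conds[ss])
      res[[length(res) + 1L]] <- list(
        formula = paste(parts, collapse = " + "),
        consistency = cons, coverage = cov)
    }
  }
  res
}

# small random multi-value case table for property tests
random_case_table <- function(seed, max_factors = 5L, max_cases = 50L) {
  set.seed(seed)
  nf <- sample(2:max_factors, 1L)
  n <- sample(8:max_cases, 1L)
  nm <- c(LETTERS[seq_len(nf)], "Y")
  repeat {
    df <- data.frame(id = sprintf("c%02d", seq_len(n)))
    for (f in LETTERS[seq_len(nf)]) {
      nl <- sample(2:3, 1L)
      df[[f]] <- sample(0:(nl - 1L), n, replace = TRUE)
    }
    df$Y <- stats::rbinom(n, 1L, stats::runif(1, 0.2, 0.8))
    if (length(unique(df$Y)) == 2L) break
  }
  doms <- c(lapply(df[LETTERS[seq_len(nf)]], function(v) 0:max(max(v), 1L)),
            list(Y = 0:1))
  case_table(df, outcome = "Y", case_id = "id", domains = doms)
}

# two-decimal half-up rounding, the reporting convention
round2 <- function(x) floor(x * 100 + 0.5) / 100

# the fixture analysis is used by several test files; compute it once
.fix_env <- new.env(parent = emptyenv())
fixture_analysis <- function() {
  if (is.null(.fix_env$ct)) {
    .fix_env$ct <- build_paper_fixture()
    .fix_env$reports <- asymmetric_analysis(.fix_env$ct)
  }
  list(ct = .fix_env$ct, reports = .fix_env$reports)
}
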