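# Minimally sufficient condition enumeration and the threshold-lowering
# search, checked against the brute-force oracle in helper-oracles.R.

toy_table <- function() {
  # 8 cases, Y = 1 exactly when A=1 and B=0
  df <- data.frame(
    id = sprintf("t%d", 1:8),
    A = c(1L, 1L, 1L, 0L, 0L, 1L, 0L, 0L),
    B = c(0L, 0L, 1L, 0L, 1L, 1L, 0L, 1L),
    C = c(0L, 1L, 0L, 1L, 0L, 1L, 1L, 0L))
  df$Y <- as.integer(df$A == 1L & df$B == 0L)
  case_table(df, "Y", case_id = "id",
             domains = list(A = 0:1, B = 0:1, C = 0:1, Y = 0:1))
}

test_that("a planted two-literal rule is recovered as an msc at full consistency", {
  ct <- toy_table()
  tab <- enumerate_msc(ct, threshold = 1)
  expect_true("A=1*B=0" %in% tab$condition)
  # exact agreement with the brute-force oracle
  otab <- oracle_msc(ct, ct_outcome_literal(ct), threshold = 1)
  expect_identical(tab$condition, otab$condition)
  expect_equal(tab$consistency, otab$consistency)
  expect_equal(tab$coverage, otab$coverage)
})

test_that("minimality suppresses specializations of a passing single literal", {
  df <- data.frame(id = sprintf("c%d", 1:12),
                   C = rep(0:2, each = 4),
                   D = rep(0:2, 4))
  df$Y <- as.integer(df$C == 2L)
  ct <- case_table(df, "Y", case_id = "id",
                   domains = list(C = 0:2, D = 0:2, Y = 0:1))
  tab <- enumerate_msc(ct, threshold = 1)
  expect_identical(tab$condition, "C=2")
})

test_that("a larger accepted set that suffices suppresses its narrower variants", {
  df <- data.frame(id = sprintf("c%d", 1:12),
                   C = rep(0:2, each = 4),
                   D = rep(0:2, 4))
  df$Y <- as.integer(df$C %in% c(0L, 1L))
  ct <- case_table(df, "Y", case_id = "id",
                   domains = list(C = 0:2, D = 0:2, Y = 0:1))
  tab <- enumerate_msc(ct, threshold = 1)
  expect_identical(tab$condition, "C=0|1")
  expect_false("C=0" %in% tab$condition)
})

test_that("enumerate_msc agrees exactly with the oracle on random tables", {
  for (i in 1:40) {
    ct <- random_case_table(i)
    th <- sample(c(1, 0.9, 0.8), 1L)
    tab <- enumerate_msc(ct, threshold = th)
    otab <- oracle_msc(ct, ct_outcome_literal(ct), threshold = th)
    expect_identical(tab$condition, otab$condition,
                     label = sprintf("seed %d threshold %.2f (impl)", i, th))
    expect_equal(tab$consistency, otab$consistency)
    expect_equal(tab$n_instantiating, otab$n_instantiating)
    expect_equal(tab$n_overlap, otab$n_overlap)
  }
})

test_that("lowering the threshold only adds rows up to re-minimization", {
  for (i in 1:10) {
    ct <- random_case_table(200 + i)
    hi <- enumerate_msc(ct, threshold = 0.95)
    lo <- enumerate_msc(ct, threshold = 0.8)
    # every high-threshold row is still consistent enough at the lower
    # threshold; it can only disappear through re-minimization, in which
    # case some relaxation of it must be present
    for (cond in hi$condition) {
      if (cond %in% lo$condition) next
      cj <- parse_condition(cond)
      relaxed_present <- any(vapply(lo$condition, function(lc) {
        lcj <- parse_condition(lc)
        lf <- vapply(lcj$literals, `[[`, character(1), "factor")
        cf <- vapply(cj$literals, `[[`, character(1), "factor")
        if (!all(lf %in% cf)) return(FALSE)
        all(vapply(lcj$literals, function(l) {
          all(cj$literals[[match(l$factor, cf)]]$levels %in% l$levels)
        }, logical(1)))
      }, logical(1)))
      expect_true(relaxed_present, label = paste("vanished row", cond))
    }
  }
})

test_that("degenerate outcomes and missing factors are rejected", {
  df <- data.frame(id = c("a", "b", "c"), A = c(0L, 1L, 2L),
                   Y = c(1L, 1L, 1L))
  ct <- case_table(df, "Y", case_id = "id",
                   domains = list(A = 0:2, Y = 0:1))
  expect_error(enumerate_msc(ct), "degenerate outcome")
})

test_that("threshold search stops at the first threshold admitting min_rows configurations", {
  ct <- toy_table()
  res <- threshold_search(ct, min_rows = 1L)
  expect_equal(res$threshold, 1)
  expect_identical(nrow(res$trail), 1L)
  # with a demanding min_rows the search walks down and records the trail
  res2 <- threshold_search(ct, min_rows = 3L)
  expect_gte(nrow(res2$trail), 2L)
  expect_true(all(diff(res2$trail$threshold) < 0))
  expect_true(all(res2$trail$n_rows[-nrow(res2$trail)] < 3L))
  expect_gte(res2$trail$n_rows[nrow(res2$trail)], 3L)
  # row counts at every visited threshold match oracle recounts
  for (r in seq_len(nrow(res2$trail))) {
    expect_identical(res2$trail$n_rows[r],
                     nrow(oracle_msc(ct, ct_outcome_literal(ct),
                                     threshold = res2$trail$threshold[r])))
  }
})

test_that("an unreachable row target exhausts the search with an error", {
  ct <- toy_table()
  expect_error(threshold_search(ct, min_rows = 1000L), "exhausted")
})
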