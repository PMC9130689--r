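# Candidate building, final-model selection, ambiguity, and the asymmetric
# outcome-present / outcome-absent analyses.

test_that("a noise-free conjunctive rule yields a single perfect candidate", {
  df <- data.frame(id = sprintf("t%d", 1:8),
                   A = c(1L, 1L, 1L, 0L, 0L, 1L, 0L, 0L),
                   B = c(0L, 0L, 1L, 0L, 1L, 1L, 0L, 1L),
                   C = c(0L, 1L, 0L, 1L, 0L, 1L, 1L, 0L))
  df$Y <- as.integer(df$A == 1L & df$B == 0L)
  ct <- case_table(df, "Y", case_id = "id",
                   domains = list(A = 0:1, B = 0:1, C = 0:1, Y = 0:1))
  tab <- enumerate_msc(ct, threshold = 1)
  cand <- build_candidates(tab, ct, con_threshold = 1, cov_threshold = 1)
  expect_length(cand, 1L)
  expect_identical(format(cand[[1]]), "A=1*B=0")
  expect_equal(cand[[1]]$consistency, 1)
  expect_equal(cand[[1]]$coverage, 1)
})

test_that("a disjunctive rule needs both pathways to reach full coverage", {
  # Y = 1 iff A=1 or C=2; neither alone covers all positives
  set.seed(42)
  df <- data.frame(id = sprintf("d%02d", 1:18),
                   A = rep(0:1, 9),
                   B = sample(0:1, 18, replace = TRUE),
                   C = rep(0:2, each = 6))
  df$Y <- as.integer(df$A == 1L | df$C == 2L)
  ct <- case_table(df, "Y", case_id = "id",
                   domains = list(A = 0:1, B = 0:1, C = 0:2, Y = 0:1))
  tab <- enumerate_msc(ct, threshold = 1)
  cand <- build_candidates(tab, ct, con_threshold = 1, cov_threshold = 1)
  expect_true("A=1 + C=2" %in% vapply(cand, format, character(1)))
  best <- select_final(cand)$final
  expect_identical(format(best), "A=1 + C=2")
  expect_lt(coverage("A=1", ct = ct), 1)
  expect_lt(coverage("C=2", ct = ct), 1)
  # agreement with the brute-force oracle over all disjunction subsets
  ocand <- oracle_candidates(tab, ct, ct_outcome_literal(ct),
                             con_threshold = 1, cov_threshold = 1)
  expect_setequal(vapply(cand, format, character(1)),
                  vapply(ocand, `[[`, character(1), "formula"))
})

test_that("build_candidates agrees with the oracle on random tables", {
  for (i in 1:25) {
    ct <- random_case_table(300 + i, max_factors = 4L, max_cases = 30L)
    th <- sample(c(1, 0.85), 1L)
    tab <- enumerate_msc(ct, threshold = th, max_order = 2L)
    if (nrow(tab) == 0L) next
    cand <- build_candidates(tab, ct, con_threshold = th,
                             cov_threshold = 0.6, max_disjuncts = 3L)
    ocand <- oracle_candidates(tab, ct, ct_outcome_literal(ct),
                               con_threshold = th, cov_threshold = 0.6,
                               max_disjuncts = 3L)
    expect_setequal(vapply(cand, format, character(1)),
                    vapply(ocand, `[[`, character(1), "formula"))
    # scores recompute from scratch
    for (m in cand) {
      expect_equal(m$consistency,
                   consistency(m, ct_outcome_literal(ct), ct))
      expect_equal(m$coverage, coverage(m, ct_outcome_literal(ct), ct))
    }
  }
})

test_that("selection ranks by consistency, then coverage, then complexity", {
  mk <- function(s, cons, cov) {
    m <- parse_condition(s)
    if (inherits(m, "geocna_conjunction")) m <- solution_formula(m)
    m$consistency <- cons; m$coverage <- cov
    m
  }
  r <- select_final(list(mk("A=1*B=0", 0.95, 0.90), mk("C=2", 0.92, 0.95)))
  expect_identical(format(r$final), "A=1*B=0")
  expect_false(r$ambiguity)
  # exact tie on all keys flags ambiguity and withholds a final model
  r2 <- select_final(list(mk("A=1*B=0", 0.9, 0.9), mk("C=2*D=1", 0.9, 0.9)))
  expect_true(r2$ambiguity)
  expect_null(r2$final)
  expect_length(r2$tied, 2L)
  # single candidate selected outright; empty list reports no model
  r3 <- select_final(list(mk("A=1", 0.8, 0.8)))
  expect_identical(format(r3$final), "A=1")
  r4 <- select_final(list())
  expect_null(r4$final)
  expect_match(r4$status, "no model")
})

test_that("two genuinely tied single-condition models are surfaced as ambiguity", {
  # Y=1 for cases 1-4; B=1 holds for {1,2,3,5}, C=1 for {2,3,4,6}: two
  # distinct conditions with identical consistency 3/4 and coverage 3/4
  df <- data.frame(id = sprintf("a%02d", 1:12), A = 0L, B = 0L, C = 0L)
  df$B[c(1, 2, 3, 5)] <- 1L
  df$C[c(2, 3, 4, 6)] <- 1L
  df$Y <- as.integer(seq_len(12) <= 4)
  ct <- case_table(df, "Y", case_id = "id",
                   domains = list(A = 0:1, B = 0:1, C = 0:1, Y = 0:1))
  tab <- enumerate_msc(ct, threshold = 0.75)
  cand <- build_candidates(tab, ct, con_threshold = 0.75,
                           cov_threshold = 0.7)
  expect_setequal(vapply(cand, format, character(1)), c("B=1", "C=1"))
  rep <- select_final(cand)
  expect_true(rep$ambiguity)
  expect_null(rep$final)
  expect_length(rep$tied, 2L)
})

test_that("asymmetric analysis recovers different structures for presence and absence", {
  ct <- build_paper_fixture()
  rep <- asymmetric_analysis(ct)
  expect_identical(format(rep$positive$final), "EDU=0*ICEBLACK=0|1")
  expect_identical(format(rep$negative$final), "EDU=1|2 + ICEBLACK=2")
  # structural asymmetry: one pathway in, two pathways out
  expect_length(rep$positive$final$disjuncts, 1L)
  expect_length(rep$negative$final$disjuncts, 2L)
  # stored scores recompute exactly from the case table
  for (side in names(rep)) {
    f <- rep[[side]]$final
    expect_equal(f$consistency, consistency(f, rep[[side]]$outcome, ct))
    expect_equal(f$coverage, coverage(f, rep[[side]]$outcome, ct))
  }
})

test_that("a noise-free planted conjunction gives matching asymmetric models", {
  gen <- generate_synthetic(synthetic_spec(seed = 404))
  rep <- asymmetric_analysis(gen$case_table)
  expect_identical(format(rep$positive$final), "A=0*B=0|1")
  expect_false(is.null(rep$negative$final))
  expect_gte(rep$negative$final$consistency, 0.9)
})

test_that("a single positive case leaves the negative side analysable", {
  df <- data.frame(id = sprintf("s%02d", 1:12),
                   A = rep(0:2, 4), B = rep(0:1, 6))
  df$Y <- c(1L, rep(0L, 11))
  ct <- case_table(df, "Y", case_id = "id",
                   domains = list(A = 0:2, B = 0:1, Y = 0:1))
  rep <- asymmetric_analysis(ct, cov_threshold = 0.9)
  expect_false(is.null(rep$negative$final))
  expect_gte(rep$negative$final$coverage, 0.9)
})
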