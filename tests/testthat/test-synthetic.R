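# The synthetic generator and the deterministic benchmark fixture.

test_that("calibrating the generated raw table reproduces the case table exactly", {
  for (s in c(1, 2, 77)) {
    gen <- generate_synthetic(synthetic_spec(seed = s))
    recal <- calibrate_table(gen$raw, schemes = gen$schemes)
    expect_identical(as.data.frame(recal), as.data.frame(gen$case_table),
                     label = paste("round-trip at seed", s))
  }
})

test_that("the same seed reproduces identical tables; different seeds differ", {
  g1 <- generate_synthetic(synthetic_spec(seed = 5))
  g2 <- generate_synthetic(synthetic_spec(seed = 5))
  g3 <- generate_synthetic(synthetic_spec(seed = 6))
  expect_identical(g1$raw, g2$raw)
  expect_identical(as.data.frame(g1$case_table),
                   as.data.frame(g2$case_table))
  expect_false(identical(g1$raw, g3$raw))
})

test_that("defaults emulate the study shape: 43 cases, 8 factors, 13 positives, all levels occupied", {
  gen <- generate_synthetic(synthetic_spec(seed = 9))
  ct <- gen$case_table
  expect_identical(nrow(ct), 43L)
  expect_identical(sum(ct$LOWVAX), 13L)
  facs <- setdiff(ct_factors(ct),
                  c("LOWVAX", "VAX_MAR", "VAX_APR", "VAX_MAY"))
  expect_length(facs, 8L)
  for (f in facs) expect_setequal(unique(ct[[f]]), 0:2)
  # outcome equals the planted rule at zero noise
  expect_identical(ct$LOWVAX,
                   as.integer(ct_case_ids(ct) %in%
                                extension("A=0*B=0|1", ct)))
  # monthly levels encode the outcome
  expect_identical(ct$LOWVAX, persistent_low_outcome(
    as.matrix(as.data.frame(ct)[c("VAX_MAR", "VAX_APR", "VAX_MAY")])))
})

test_that("outcome flips occur at the nominal noise rate", {
  flips <- 0L
  n_tot <- 0L
  for (s in 1:30) {
    gen <- generate_synthetic(synthetic_spec(seed = 600 + s, noise = 0.1))
    y <- gen$case_table$LOWVAX
    flips <- flips + sum(y != gen$truth$y_rule)
    n_tot <- n_tot + length(y)
    expect_setequal(gen$truth$flipped,
                    ct_case_ids(gen$case_table)[y != gen$truth$y_rule])
  }
  rate <- flips / n_tot
  se <- sqrt(0.1 * 0.9 / n_tot)
  expect_lt(abs(rate - 0.1), 4 * se)
})

test_that("an unsatisfiable planted rule is rejected", {
  expect_error(generate_synthetic(
    synthetic_spec(planted_rule = "A=0*Z=1")), "undeclared")
  expect_error(synthetic_spec(noise = 0.6), "noise")
})

test_that("the benchmark fixture reproduces the printed cross-classification where satisfiable", {
  ct <- build_paper_fixture()
  expect_identical(nrow(ct), 43L)
  expect_identical(sum(ct$LOWVAX), 13L)
  pos <- score_condition("EDU=0*ICEBLACK=0|1", ct_outcome_literal(ct), ct)
  expect_identical(pos$n_instantiating, 12L)
  expect_identical(pos$n_overlap, 11L)
  # the negative solution is the set complement of the positive one, so its
  # instantiating count is forced to 31 on a 43-case table
  neg <- score_condition("EDU=1|2 + ICEBLACK=2",
                         ct_outcome_literal(ct, 0L), ct)
  expect_identical(neg$n_instantiating, 31L)
  expect_identical(neg$n_overlap, 29L)
  expect_identical(neg$n_outcome, 30L)
  expect_identical(length(extension("EDU=0*ICEBLACK=0|1", ct)) +
                     length(extension("EDU=1|2 + ICEBLACK=2", ct)), 43L)
})

test_that("pure-noise tables do not support high-consistency high-coverage models", {
  # outcome independent of all factors: the chain should not find the kind
  # of strong model the planted-rule tables produce
  strong <- 0L
  runs <- 0L
  for (s in 1:12) {
    gen <- generate_synthetic(synthetic_spec(planted_rule = NULL,
                                             seed = 900 + s))
    ct <- gen$case_table
    ts <- threshold_search(ct)
    cand <- tryCatch(
      build_candidates(ts$table, ct, con_threshold = ts$threshold),
      geocna_search_overflow = function(e) list())
    runs <- runs + 1L
    best <- select_final(cand)$final
    if (!is.null(best) && best$consistency >= 0.92 &&
          best$coverage >= 0.75) {
      strong <- strong + 1L
    }
  }
  expect_lte(strong / runs, 0.35)
})
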