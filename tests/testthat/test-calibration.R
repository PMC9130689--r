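test_that("ICE is (privileged - deprived)/total with its boundary values", {
  expect_equal(compute_ice(1000, 0, 1000), 1)
  expect_equal(compute_ice(0, 1000, 1000), -1)
  expect_equal(compute_ice(300, 300, 1000), 0)
  expect_equal(compute_ice(0.4, 0.25, 1), 0.15)
  expect_error(compute_ice(1, 1, 0), "total")
  expect_error(compute_ice(800, 400, 1000), "exceed")
})

test_that("ICE is antisymmetric under swapping the two extremes", {
  set.seed(11)
  for (i in 1:50) {
    tot <- runif(1, 100, 1e5)
    p <- runif(1, 0, tot)
    d <- runif(1, 0, tot - p)
    expect_equal(compute_ice(p, d, tot), -compute_ice(d, p, tot))
    expect_true(abs(compute_ice(p, d, tot)) <= 1)
  }
})

test_that("fixed-cut calibration follows the closure convention at every printed boundary", {
  sch <- default_schemes()
  # education: <=20 low, (20, 40.1] medium, >40.1 high
  expect_identical(calibrate_fixed(c(18, 20, 20.1, 40.1, 40.2),
                                   sch$EDU$scheme), c(0L, 0L, 1L, 1L, 2L))
  # racial privilege index: cuts -0.37 / 0.47
  expect_identical(calibrate_fixed(c(-0.5, -0.37, -0.36, 0.47, 0.48),
                                   sch$ICEBLACK$scheme),
                   c(0L, 0L, 1L, 1L, 2L))
  # March vaccination rates per 10,000: cuts 1500 / 2000
  expect_identical(calibrate_fixed(c(1400, 1500, 1501, 2000, 2001),
                                   sch$VAX_MAR$scheme), c(0L, 0L, 1L, 1L, 2L))
  expect_error(calibrate_fixed(NaN, sch$EDU$scheme), "non-finite")
})

test_that("every finite value maps to exactly one level (total partition)", {
  sch <- calibration_scheme("X", c(-0.23, 0.07))
  vals <- c(-1e9, seq(-1, 1, by = 0.01), -0.23, 0.07, 1e9)
  lv <- calibrate_fixed(vals, sch)
  expect_true(all(lv %in% 0:2))
  expect_identical(length(lv), length(vals))
  # monotone in the raw value
  expect_true(all(diff(calibrate_fixed(sort(vals), sch)) >= 0))
})

test_that("tertile cuts match a hand-applied percentile definition and are permutation-invariant", {
  vals <- 1:9
  # type-7 linear interpolation done by hand: p*(n-1)+1 gives the fractional
  # order statistic
  hand <- function(p, v) {
    v <- sort(v)
    h <- p * (length(v) - 1) + 1
    v[floor(h)] + (h - floor(h)) * (v[floor(h) + 1] - v[floor(h)])
  }
  expect_equal(tertile_cuts(vals),
               c(hand(0.33, vals), hand(0.67, vals)))
  set.seed(7)
  for (i in 1:20) {
    v <- runif(sample(5:30, 1), 0, 100)
    expect_identical(tertile_cuts(v), tertile_cuts(sample(v)))
  }
  expect_error(tertile_cuts(rep(3, 10)), "degenerate")
})

test_that("tertile calibration sends boundary values outward (>=67th high, <=33rd low)", {
  v <- 1:9
  cuts <- tertile_cuts(v)
  lv <- calibrate_tertile(v)
  expect_identical(lv[v <= cuts[1]], rep(0L, sum(v <= cuts[1])))
  expect_identical(lv[v >= cuts[2]], rep(2L, sum(v >= cuts[2])))
  expect_true(all(lv[v > cuts[1] & v < cuts[2]] == 1L))
})

test_that("dual calibration satisfies its truth table and loses no information", {
  dc <- dual_calibrate(c(0L, 1L, 2L))
  expect_identical(dc$high, c(0L, 0L, 1L))
  expect_identical(dc$low, c(1L, 0L, 0L))
  expect_error(dual_calibrate(3L), "levels")
  # (high, low) == (0, 0) exactly for medium; never both 1
  set.seed(3)
  lv <- sample(0:2, 200, replace = TRUE)
  dc <- dual_calibrate(lv)
  expect_true(all(dc$high + dc$low <= 1L))
  expect_identical(dc$high == 0L & dc$low == 0L, lv == 1L)
})

test_that("persistent-low outcome is the conjunction of three monthly low indicators", {
  expect_identical(persistent_low_outcome(c(0L, 0L, 0L)), 1L)
  expect_identical(persistent_low_outcome(c(0L, 0L, 1L)), 0L)
  expect_identical(persistent_low_outcome(c(2L, 2L, 2L)), 0L)
  set.seed(5)
  m <- matrix(sample(0:2, 300, replace = TRUE), ncol = 3)
  expect_identical(persistent_low_outcome(m),
                   as.integer((m[, 1] == 0) & (m[, 2] == 0) & (m[, 3] == 0)))
  expect_error(persistent_low_outcome(c(0L, 0L)), "three")
})

test_that("calibrating uniform draws over the printed raw ranges occupies all levels", {
  set.seed(19)
  sch <- default_schemes()
  for (nm in c("EDU", "ICEBLACK", "ICEINC", "UNINS", "LEP", "TRANSIT",
               "SERVICE", "OVERCROWD")) {
    s <- sch[[nm]]
    v <- runif(500, s$raw_range[1], s$raw_range[2])
    expect_setequal(unique(calibrate_fixed(v, s$scheme)), 0:2)
  }
})

test_that("the shipped YAML config decodes to the built-in scheme set", {
  path <- system.file("extdata", "default_schemes.yaml", package = "geocna")
  cfg <- read_scheme_config(path)
  ref <- default_schemes()
  expect_setequal(names(cfg), names(ref))
  for (nm in names(ref)) {
    expect_equal(cfg[[nm]]$scheme$cuts, ref[[nm]]$scheme$cuts, label = nm)
    expect_identical(cfg[[nm]]$column, ref[[nm]]$column)
    expect_equal(cfg[[nm]]$raw_range, ref[[nm]]$raw_range)
  }
})
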