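# Deterministic 43-neighborhood benchmark fixture. The full per-case factor
# table behind the study's printed results is not public, so this fixture is
# a synthetic reconstruction engineered to match the printed
# cross-classification counts where they are jointly satisfiable: 13 of 43
# cases persistently low; the conjunction EDU=0*ICEBLACK=0|1 instantiated by
# 12 cases of which 11 are outcome-positive (11/12, 11/13). Because that
# conjunction and the disjunction EDU=1|2 + ICEBLACK=2 are exact set
# complements, the disjunction's extension is forced to 31 cases (29 of the
# 30 non-low cases): its coverage is 29/30 and its consistency 29/31.

#' Build the deterministic 43-case benchmark fixture
#'
#' Returns a \code{case_table} with 43 neighborhood cases, three-level
#' factors \code{EDU} and \code{ICEBLACK} plus six filler social factors,
#' three monthly vaccination levels (excluded from configurational search)
#' and the binary persistently-low outcome \code{LOWVAX}.
#'
#' The construction is block-structured: a 12-case block with low college
#' education and low/medium concentrated racial privilege holding 11 of the
#' 13 outcome-positive cases and one exception; two further positives
#' outside that block, each sharing its full profile with a group of
#' negative cases (so no spurious perfectly-consistent configuration covers
#' them); and 14 high-education negative cases with varied filler levels.
#' Count identities are re-verified on every build.
#'
#' @return A \code{case_table} (outcome \code{LOWVAX}).
#' @export
#' @examples
#' ct <- build_paper_fixture()
#' consistency("EDU=0*ICEBLACK=0|1", ct = ct)  # 11/12
#' coverage("EDU=0*ICEBLACK=0|1", ct = ct)     # 11/13
build_paper_fixture <- function() {
  fill1 <- c(ICEINC = 1L, UNINS = 1L, LEP = 1L, TRANSIT = 1L, SERVICE = 1L)
  row <- function(edu, ice, y, oc = 1L, f = fill1) {
    c(EDU = edu, ICEBLACK = ice, f, OVERCROWD = oc, LOWVAX = y)
  }
  rows <- list()
  # block: low education, low racial privilege (EDU=0, ICEBLACK=0)
  for (i in 1:10) rows[[length(rows) + 1L]] <- row(0L, 0L, 1L, oc = 0L)
  # one positive with medium racial privilege (EDU=0, ICEBLACK=1)
  rows[[length(rows) + 1L]] <- row(0L, 1L, 1L, oc = 1L)
  # the block's single exception: both conditions, outcome absent
  rows[[length(rows) + 1L]] <- row(0L, 0L, 0L, oc = 0L)
  # positive outside the block (medium education), with 8 profile-sharing
  # negatives
  rows[[length(rows) + 1L]] <- row(1L, 0L, 1L)
  for (i in 1:8) rows[[length(rows) + 1L]] <- row(1L, 0L, 0L)
  # positive outside the block (high racial privilege), with 7
  # profile-sharing negatives
  rows[[length(rows) + 1L]] <- row(0L, 2L, 1L)
  for (i in 1:7) rows[[length(rows) + 1L]] <- row(0L, 2L, 0L)
  # 14 high-education negatives with varied fillers
  f14 <- rbind(
    c(0, 2, 0, 2, 0), c(2, 0, 2, 0, 2), c(0, 0, 2, 2, 0), c(2, 2, 0, 0, 2),
    c(0, 2, 2, 0, 0), c(2, 0, 0, 2, 2), c(0, 2, 0, 0, 2), c(1, 1, 1, 1, 1),
    c(2, 0, 2, 2, 0), c(0, 0, 0, 2, 2), c(2, 2, 2, 0, 0), c(0, 2, 2, 2, 0),
    c(2, 0, 0, 0, 2), c(0, 1, 2, 0, 1))
  # row 8 (the first medium-privilege case) keeps the all-medium filler
  # profile so no medium-racial-privilege configuration is spuriously pure
  ice14 <- c(rep(0L, 7L), rep(1L, 4L), rep(2L, 3L))
  oc14 <- c(2L, 1L, 2L, 1L, 1L, 2L, 1L, 1L, 2L, 1L, 1L, 1L, 2L, 1L)
  for (i in seq_len(14L)) {
    rows[[length(rows) + 1L]] <- row(2L, ice14[i], 0L, oc = oc14[i],
                                     f = stats::setNames(as.integer(f14[i, ]),
                                                         names(fill1)))
  }

  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(data.frame(zcta = sprintf("191%02d", seq_len(nrow(tab))),
                          stringsAsFactors = FALSE), tab)

  # monthly vaccination levels: all-low exactly for outcome-positive cases;
  # a fixed cycle of not-all-low patterns otherwise
  alt <- rbind(c(1L, 1L, 1L), c(2L, 2L, 2L), c(0L, 1L, 2L),
               c(1L, 2L, 0L), c(2L, 0L, 1L))
  vax <- matrix(0L, nrow(tab), 3L,
                dimnames = list(NULL, c("VAX_MAR", "VAX_APR", "VAX_MAY")))
  neg_idx <- which(tab$LOWVAX == 0L)
  vax[neg_idx, ] <- alt[(seq_along(neg_idx) - 1L) %% nrow(alt) + 1L, ]
  tab <- cbind(tab[setdiff(names(tab), "LOWVAX")], as.data.frame(vax),
               LOWVAX = tab$LOWVAX)

  facs3 <- setdiff(names(tab), c("zcta", "LOWVAX"))
  domains <- c(stats::setNames(rep(list(0:2), length(facs3)), facs3),
               list(LOWVAX = 0:1))
  ct <- case_table(tab, outcome = "LOWVAX", case_id = "zcta",
                   domains = domains,
                   exclude = c("VAX_MAR", "VAX_APR", "VAX_MAY"))

  # count identities, re-verified on every build
  s_pos <- score_condition(parse_condition("EDU=0*ICEBLACK=0|1"),
                           ct_outcome_literal(ct), ct)
  stopifnot(sum(ct$LOWVAX) == 13L,
            identical(ct$LOWVAX, persistent_low_outcome(
              as.matrix(tab[c("VAX_MAR", "VAX_APR", "VAX_MAY")]))),
            s_pos$n_instantiating == 12L, s_pos$n_overlap == 11L,
            s_pos$n_outcome == 13L)
  s_neg <- score_condition(parse_condition("EDU=1|2 + ICEBLACK=2"),
                           ct_outcome_literal(ct, 0L), ct)
  stopifnot(s_neg$n_instantiating == 31L, s_neg$n_overlap == 29L,
            s_neg$n_outcome == 30L)
  ct
}
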