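# End-to-end pipeline: raw table -> calibration (including ICE factors) ->
# persistent outcome -> threshold-lowering msc search -> asymmetric model
# building -> artifacts on disk.

#' Assemble a run configuration
#'
#' @param schemes Calibration scheme set (default \code{default_schemes()}).
#' @param max_order Maximum configuration order for the msc scan (default 3).
#' @param start,step,min_rows Threshold-search settings (defaults 1.00,
#'   0.05, 2).
#' @param con_threshold Model consistency threshold (\code{NULL}: track the
#'   msc threshold).
#' @param cov_threshold Model coverage threshold (default 0.75).
#' @param max_disjuncts Maximum disjuncts per model (default 5).
#' @param outcome_name Name of the derived binary outcome (default
#'   \code{"LOWVAX"}).
#' @param case_id Case-id column (default \code{"zcta"}).
#' @return A \code{geocna_config} list.
#' @export
geocna_config <- function(schemes = default_schemes(), max_order = 3L,
                          start = 1, step = 0.05, min_rows = 2L,
                          con_threshold = NULL, cov_threshold = 0.75,
                          max_disjuncts = 5L, outcome_name = "LOWVAX",
                          case_id = "zcta") {
  structure(list(schemes = schemes, max_order = max_order, start = start,
                 step = step, min_rows = min_rows,
                 con_threshold = con_threshold,
                 cov_threshold = cov_threshold,
                 max_disjuncts = max_disjuncts,
                 outcome_name = outcome_name, case_id = case_id),
            class = "geocna_config")
}

#' Run the full geoconfigurational pipeline
#'
#' Calibrates the raw table, derives the persistently-low outcome, runs the
#' threshold-lowering msc search and the asymmetric (outcome present /
#' absent) model building, and — when \code{out_dir} is given — writes the
#' calibrated case table, both condition tables, both model reports (JSON),
#' the per-case membership table and a text summary. Identical inputs
#' produce byte-identical outputs.
#'
#' @param raw A \code{raw_table} or data.frame with the schemes' columns.
#' @param config A \code{geocna_config}.
#' @param out_dir Output directory (created if missing), or \code{NULL} to
#'   skip writing.
#' @return List with \code{case_table}, \code{reports} (positive/negative),
#'   \code{membership}, and \code{files} (paths written).
#' @export
geocna_run <- function(raw, config = geocna_config(), out_dir = NULL) {
  stage <- "calibration"
  res <- tryCatch({
    ct <- calibrate_table(raw, schemes = config$schemes,
                          outcome_name = config$outcome_name,
                          case_id = config$case_id)
    stage <- "model building"
    reports <- asymmetric_analysis(
      ct, max_order = config$max_order, start = config$start,
      step = config$step, min_rows = config$min_rows,
      con_threshold = config$con_threshold,
      cov_threshold = config$cov_threshold,
      max_disjuncts = config$max_disjuncts)
    stage <- "output"
    membership <- membership_table(ct, reports)
    files <- character(0)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      p <- function(f) file.path(out_dir, f)
      utils::write.csv(as.data.frame(ct), p("case_table.csv"),
                       row.names = FALSE, fileEncoding = "UTF-8")
      write_condition_table(reports$positive$condition_table,
                            p("condition_table_positive.csv"))
      write_condition_table(reports$negative$condition_table,
                            p("condition_table_negative.csv"))
      write_model_report(reports$positive, p("model_positive.json"))
      write_model_report(reports$negative, p("model_negative.json"))
      utils::write.csv(membership, p("membership.csv"), row.names = FALSE,
                       fileEncoding = "UTF-8")
      writeLines(summarize_run(ct, reports), p("summary.txt"))
      files <- p(c("case_table.csv", "condition_table_positive.csv",
                   "condition_table_negative.csv", "model_positive.json",
                   "model_negative.json", "membership.csv", "summary.txt"))
    }
    list(case_table = ct, reports = reports, membership = membership,
         files = files)
  }, error = function(e) {
    stop("pipeline failed during ", stage, ": ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

fmt2 <- function(x) {
  # half-up rounding to two decimals for display
  sprintf("%.2f", floor(x * 100 + 0.5) / 100)
}

#' Human-readable run summary
#'
#' @param ct The calibrated \code{case_table}.
#' @param reports Result of \code{\link{asymmetric_analysis}}.
#' @return Character vector of summary lines.
#' @export
summarize_run <- function(ct, reports) {
  lines <- c(
    sprintf("cases: %d", nrow(ct)),
    sprintf("factors: %s",
            paste(setdiff(ct_factors(ct),
                          c(attr(ct, "outcome"), attr(ct, "exclude"))),
                  collapse = ", ")),
    sprintf("outcome: %s (present in %d cases)", attr(ct, "outcome"),
            sum(ct[[attr(ct, "outcome")]])))
  for (side in names(reports)) {
    r <- reports[[side]]
    lines <- c(lines, sprintf("[%s outcome: %s]", side, format(r$outcome)))
    tr <- apply(r$trail, 1L, function(z) {
      sprintf("  threshold %.2f -> %d configuration(s)", z[1L], z[2L])
    })
    lines <- c(lines, tr)
    if (!is.null(r$final)) {
      lines <- c(lines, sprintf(
        "  final model: %s (consistency %s, coverage %s)",
        format(r$final), fmt2(r$final$consistency), fmt2(r$final$coverage)))
      cover <- sum(cond_mask(r$final, ct) &
                     cond_mask(r$outcome, ct))
      lines <- c(lines, sprintf("  cases covered: %d of %d", cover,
                                sum(cond_mask(r$outcome, ct))))
    } else if (r$ambiguity) {
      lines <- c(lines, "  model ambiguity: tied models",
                 vapply(r$tied, function(m) paste0("    ", format(m)),
                        character(1)))
    } else {
      lines <- c(lines, "  no model met the thresholds")
    }
  }
  lines
}
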