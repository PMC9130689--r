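# CSV / JSON / GeoJSON input and output for the pipeline's artifacts.

#' Read and validate a raw neighborhood variable table
#'
#' Reads a UTF-8 comma-separated file with a mandatory header row, validates
#' it against a declared schema and returns a \code{raw_table}. Case
#' identifiers (ZCTAs) are read as opaque strings so leading zeros survive.
#' Missing declared values are hard errors unless \code{drop_incomplete}
#' is set, in which case incomplete rows are dropped with a warning.
#'
#' @param path CSV file path.
#' @param columns Character vector of required numeric column names.
#' @param case_id Name of the case-identifier column (default \code{"zcta"}).
#' @param drop_incomplete Drop rows with missing declared values instead of
#'   erroring (default \code{FALSE}).
#' @return A \code{raw_table}: validated data.frame with attribute
#'   \code{case_id}.
#' @export
read_raw_table <- function(path, columns, case_id = "zcta",
                           drop_incomplete = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = stats::setNames("character", case_id),
                        check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(c(case_id, columns), names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df[[case_id]])) {
    stop("integrity error: duplicate case id(s) ",
         paste(unique(df[[case_id]][duplicated(df[[case_id]])]),
               collapse = ", "))
  }
  for (col in columns) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(as.character(v))))
    if (length(bad)) {
      stop("parse error: non-numeric value in column '", col,
           "', row ", bad[1L], " ('", v[bad[1L]], "')")
    }
    df[[col]] <- num
  }
  incomplete <- rowSums(is.na(df[columns])) > 0
  if (any(incomplete)) {
    if (drop_incomplete) {
      warning(sum(incomplete), " row(s) with missing values dropped")
      df <- df[!incomplete, , drop = FALSE]
    } else {
      stop("missing value(s) in row(s) ",
           paste(utils::head(which(incomplete), 5L), collapse = ", "),
           "; set drop_incomplete = TRUE to drop them")
    }
  }
  rate_cols <- grep("^vax_rate", columns, value = TRUE)
  for (col in rate_cols) {
    if (any(df[[col]] < 0)) stop("negative rate in column '", col, "'")
  }
  rownames(df) <- NULL
  structure(df, case_id = case_id, class = c("raw_table", "data.frame"))
}

#' Write a condition table to CSV
#'
#' One row per retained configuration with its outcome, canonical condition
#' string, consistency and coverage (full precision) and the defining
#' counts. Reading the file back reproduces the in-memory numbers.
#'
#' @param table A \code{condition_table}.
#' @param path Output CSV path.
#' @param allow_empty Permit writing a header-only file for an empty table
#'   (default \code{TRUE}).
#' @return Invisibly, the path.
#' @export
write_condition_table <- function(table, path, allow_empty = TRUE) {
  stopifnot(inherits(table, "condition_table"))
  if (nrow(table) == 0L && !allow_empty) {
    stop("refusing to write an empty condition table (allow_empty = FALSE)")
  }
  df <- as.data.frame(table)
  df$consistency <- formatC(df$consistency, digits = 15, format = "g")
  df$coverage <- formatC(df$coverage, digits = 15, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a condition table written by \code{\link{write_condition_table}}
#'
#' @param path CSV path.
#' @return A \code{condition_table} (threshold attribute unset).
#' @export
read_condition_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  structure(df, class = c("condition_table", "data.frame"))
}

#' Write a model report as JSON
#'
#' Serializes a \code{geocna_model_report}: outcome, final solution string
#' (canonical grammar), consistency, coverage, complexity, ambiguity flag,
#' the candidate list and the threshold trail.
#'
#' @param report A \code{geocna_model_report}.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_model_report <- function(report, path) {
  stopifnot(inherits(report, "geocna_model_report"))
  sol_json <- function(s) {
    list(solution = format(s), consistency = s$consistency,
         coverage = s$coverage, complexity = s$complexity)
  }
  obj <- list(
    outcome = format(report$outcome),
    status = report$status,
    ambiguity = report$ambiguity,
    final = if (is.null(report$final)) NULL else sol_json(report$final),
    tied = lapply(report$tied, sol_json),
    candidates = lapply(report$candidates, sol_json),
    consistency_threshold = report$threshold,
    coverage_threshold = report$cov_threshold,
    threshold_trail = report$trail
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Per-case membership table for a fitted model pair
#'
#' For each case: its id, outcome flag, and one 0/1 column per disjunct of
#' each final model (positive- and negative-side), named by the canonical
#' condition string. This is the data layer behind a choropleth join.
#'
#' @param ct A \code{case_table}.
#' @param reports Result of \code{\link{asymmetric_analysis}}.
#' @return data.frame, one row per case.
#' @export
membership_table <- function(ct, reports) {
  stopifnot(inherits(ct, "case_table"))
  out <- data.frame(case_id = ct_case_ids(ct),
                    outcome = ct[[attr(ct, "outcome")]],
                    stringsAsFactors = FALSE)
  names(out)[1L] <- attr(ct, "case_id")
  for (side in names(reports)) {
    fin <- reports[[side]]$final
    if (is.null(fin)) next
    for (d in fin$disjuncts) {
      col <- paste0(side, ".", format(d))
      out[[col]] <- as.integer(cond_mask(d, ct))
    }
  }
  out
}

#' Join model membership onto a GeoJSON FeatureCollection
#'
#' Reads a GeoJSON FeatureCollection whose features carry a ZCTA property,
#' adds per-feature properties (outcome flag, one boolean per solution
#' conjunct) from the membership table, and writes the annotated file.
#' Geometries are passed through untouched. Features with no matching case
#' are annotated \code{geocna_unmatched = TRUE}. Property-name collisions
#' are resolved by suffixing with \code{".geocna"} and a warning.
#'
#' @param membership data.frame from \code{\link{membership_table}}.
#' @param geo_path Input GeoJSON path.
#' @param out_path Output GeoJSON path.
#' @param zcta_property Name of the feature property holding the ZCTA
#'   (default \code{"zcta"}).
#' @param case_id Name of the membership id column (default \code{"zcta"}).
#' @return Invisibly, the number of matched features.
#' @export
export_membership_geojoin <- function(membership, geo_path, out_path,
                                      zcta_property = "zcta",
                                      case_id = "zcta") {
  geo <- jsonlite::read_json(geo_path, simplifyVector = FALSE)
  if (!identical(geo$type, "FeatureCollection")) {
    stop("GeoJSON input is not a FeatureCollection")
  }
  ids <- membership[[case_id]]
  feat_ids <- vapply(geo$features, function(f) {
    z <- f$properties[[zcta_property]]
    if (is.null(z)) NA_character_ else as.character(z)
  }, character(1))
  matched <- feat_ids %in% ids
  if (!any(matched)) {
    stop("join error: no overlap between GeoJSON ZCTAs and case ids")
  }
  value_cols <- setdiff(names(membership), case_id)
  for (i in seq_along(geo$features)) {
    props <- geo$features[[i]]$properties
    if (matched[i]) {
      row <- membership[ids == feat_ids[i], , drop = FALSE]
      for (col in value_cols) {
        key <- col
        if (key %in% names(props)) {
          key <- paste0(key, ".geocna")
          warning("property '", col, "' already present; writing '",
                  key, "'")
        }
        props[[key]] <- row[[col]][1L]
      }
      props$geocna_unmatched <- FALSE
    } else {
      props$geocna_unmatched <- TRUE
    }
    geo$features[[i]]$properties <- props
  }
  jsonlite::write_json(geo, out_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(sum(matched))
}
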