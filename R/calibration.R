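# Multi-value calibration: ICE construction, fixed-cut and tertile schemes,
# meta-factor dual calibration, and the persistent binary outcome.

#' Index of Concentration at the Extremes
#'
#' ICE = (privileged - deprived) / total, a dimensionless measure in
#' \[-1, 1\]: -1 is extreme concentration of the deprived group (e.g. Black
#' non-Hispanic residents, or low-income households), +1 extreme
#' concentration of the privileged group (White non-Hispanic, or
#' high-income). Inputs may be raw counts or proportions of the same total;
#' with proportions pass \code{total = 1}.
#'
#' @param privileged,deprived,total Numeric vectors (counts or proportions);
#'   recycled to a common length.
#' @return Numeric vector of ICE values in \[-1, 1\].
#' @export
#' @examples
#' compute_ice(1000, 0, 1000)   #  1: all privileged
#' compute_ice(0, 1000, 1000)   # -1: all deprived
#' compute_ice(300, 300, 1000)  #  0: balanced extremes
compute_ice <- function(privileged, deprived, total) {
  if (any(total <= 0)) stop("ICE undefined: total must be positive")
  if (any(privileged < 0) || any(deprived < 0)) {
    stop("ICE inputs must be nonnegative")
  }
  if (any(privileged + deprived > total * (1 + 1e-9))) {
    stop("ICE inputs exceed the total population")
  }
  (privileged - deprived) / total
}

#' Define a calibration scheme
#'
#' A scheme maps a raw continuous variable onto three ordered levels via two
#' cut-points under a fixed closure convention: level 0 ("low") on
#' (-Inf, lower\], level 1 ("medium") on (lower, upper\], level 2 ("high")
#' on (upper, Inf). The closure makes the partition total and deterministic.
#'
#' @param name Factor name the scheme produces.
#' @param cuts Numeric length-2, ordered (lower < upper), in raw units.
#' @param labels Optional length-3 character, semantic names of levels
#'   0/1/2 (default low/medium/high).
#' @param mode \code{"fixed"} (cuts given directly) or \code{"tertile"}
#'   (cuts to be derived from the data with \code{\link{tertile_cuts}}).
#' @return Object of class \code{calibration_scheme}.
#' @export
calibration_scheme <- function(name, cuts,
                               labels = c("low", "medium", "high"),
                               mode = c("fixed", "tertile")) {
  mode <- match.arg(mode)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(cuts), length(cuts) == 2L,
            length(labels) == 3L)
  if (!(cuts[1L] < cuts[2L])) stop("scheme '", name, "': cuts must be ordered")
  structure(list(name = name, cuts = as.numeric(cuts),
                 labels = as.character(labels), mode = mode),
            class = "calibration_scheme")
}

#' @export
print.calibration_scheme <- function(x, ...) {
  cat(sprintf("%s [%s]: %s <= %g < %s <= %g < %s\n", x$name, x$mode,
              x$labels[1L], x$cuts[1L], x$labels[2L], x$cuts[2L],
              x$labels[3L]))
  invisible(x)
}

#' Calibrate raw values with a fixed-cut scheme
#'
#' @param value Numeric vector of raw values (finite).
#' @param scheme A \code{calibration_scheme}.
#' @return Integer vector of levels in \{0, 1, 2\}.
#' @export
#' @examples
#' edu <- calibration_scheme("EDU", c(20, 40.1))
#' calibrate_fixed(c(18, 20, 20.1, 40.1, 40.2), edu)  # 0 0 1 1 2
calibrate_fixed <- function(value, scheme) {
  stopifnot(inherits(scheme, "calibration_scheme"))
  if (any(!is.finite(value))) {
    stop("scheme '", scheme$name, "': non-finite raw value")
  }
  ifelse(value <= scheme$cuts[1L], 0L,
         ifelse(value <= scheme$cuts[2L], 1L, 2L))
}

#' Empirical tertile cut-points
#'
#' Returns the 33rd and 67th percentiles of the observed values, the
#' breakpoints of a low/medium/high tertile calibration. The percentile
#' definition is configurable: linear interpolation between order statistics
#' (default) or nearest rank.
#'
#' @param values Numeric vector with at least 3 distinct values.
#' @param method \code{"interpolate"} (quantile type 7) or
#'   \code{"nearest_rank"} (quantile type 1).
#' @return Numeric length-2: (33rd percentile, 67th percentile).
#' @export
tertile_cuts <- function(values, method = c("interpolate", "nearest_rank")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(unique(values)) < 3L) {
    stop("degenerate factor: fewer than 3 distinct values, ",
         "tertiles cannot be formed")
  }
  type <- if (method == "interpolate") 7L else 1L
  unname(stats::quantile(values, probs = c(0.33, 0.67), type = type))
}

#' Calibrate values into empirical tertiles
#'
#' Values at or above the 67th percentile are high (2), values at or below
#' the 33rd percentile are low (0), values strictly between are medium (1).
#' Note the boundary convention differs from \code{\link{calibrate_fixed}}:
#' here a value exactly at the upper cut goes to high.
#'
#' @inheritParams tertile_cuts
#' @return Integer vector of levels in \{0, 1, 2\}.
#' @export
calibrate_tertile <- function(values, method = c("interpolate", "nearest_rank")) {
  cuts <- tertile_cuts(values, method)
  ifelse(values >= cuts[2L], 2L, ifelse(values <= cuts[1L], 0L, 1L))
}

#' Dual (meta-factor) calibration of a three-level factor
#'
#' Derives two binary meta-factors from a three-level factor: \code{high} is
#' 1 exactly for cases in the highest tertile (level 2), \code{low} is 1
#' exactly for cases in the lowest tertile (level 0). A medium case (level 1)
#' is 0 on both; the pair therefore loses no information.
#'
#' @param levels Integer vector with values in \{0, 1, 2\}.
#' @return List with integer vectors \code{high} and \code{low}.
#' @export
#' @examples
#' dual_calibrate(c(0L, 1L, 2L))
dual_calibrate <- function(levels) {
  levels <- as.integer(levels)
  if (any(is.na(levels)) || any(!levels %in% 0:2)) {
    stop("dual calibration requires levels in {0, 1, 2}")
  }
  list(high = as.integer(levels == 2L), low = as.integer(levels == 0L))
}

#' Persistently-low binary outcome over repeated observations
#'
#' The outcome is present (1) exactly when the calibrated level is low (0)
#' at every one of the observation dates — here, three monthly
#' vaccination-rate levels.
#'
#' @param series Integer matrix or data.frame, one row per case and one
#'   column per date, levels in \{0, 1, 2\}; or an integer vector of three
#'   levels for a single case.
#' @return Integer vector: 1 if all levels are 0, else 0, per case.
#' @export
#' @examples
#' persistent_low_outcome(rbind(c(0, 0, 0), c(0, 0, 1)))  # 1 0
persistent_low_outcome <- function(series) {
  if (is.vector(series)) series <- matrix(series, nrow = 1L)
  series <- as.matrix(series)
  if (ncol(series) != 3L) {
    stop("the persistent outcome is defined over exactly three dates")
  }
  if (any(is.na(series)) || any(!series %in% 0:2)) {
    stop("vaccination levels must lie in {0, 1, 2}")
  }
  as.integer(rowSums(series == 0L) == 3L)
}

#' Default calibration schemes (shipped cut-points)
#'
#' The package's shipped configuration: fixed cut-points for the eight
#' social-condition factors (tertile boundaries of the source city data) and
#' the three monthly vaccination-rate reporting schemes (rates per 10,000
#' residents). \code{raw_range} records the observed range of each raw
#' variable and is used by the synthetic generator when back-filling raw
#' values.
#'
#' @return Named list; each element carries a \code{calibration_scheme} plus
#'   its \code{raw_range} and the raw-table \code{column} it reads.
#' @export
default_schemes <- function() {
  sch <- function(name, column, cuts, range, labels = c("low", "medium", "high")) {
    list(scheme = calibration_scheme(name, cuts, labels),
         column = column, raw_range = range)
  }
  list(
    EDU       = sch("EDU", "pct_college", c(20, 40.1), c(4.5, 85.6)),
    ICEBLACK  = sch("ICEBLACK", "ice_black", c(-0.37, 0.47), c(-1, 1)),
    ICEINC    = sch("ICEINC", "ice_income", c(-0.23, 0.07), c(-1, 1)),
    UNINS     = sch("UNINS", "pct_uninsured", c(6.5, 9.7), c(2.7, 13.8)),
    LEP       = sch("LEP", "pct_limited_english", c(2.2, 4.7), c(0.4, 25.1)),
    TRANSIT   = sch("TRANSIT", "pct_public_transit", c(21.4, 29.5), c(9.2, 45.3)),
    SERVICE   = sch("SERVICE", "pct_service", c(7.9, 9.8), c(1.9, 16.9)),
    OVERCROWD = sch("OVERCROWD", "pct_overcrowded", c(1.7, 2.4), c(0, 6.1)),
    VAX_MAR   = sch("VAX_MAR", "vax_rate_mar", c(1500, 2000), c(0, 3000)),
    VAX_APR   = sch("VAX_APR", "vax_rate_apr", c(2500, 3400), c(0, 5100)),
    VAX_MAY   = sch("VAX_MAY", "vax_rate_may", c(3400, 4500), c(0, 6750))
  )
}

#' Read a calibration scheme set from a YAML or JSON config file
#'
#' Each entry maps a factor name to its raw-table source \code{column}, the
#' two \code{cuts}, an optional raw \code{range}, optional \code{labels}
#' and an optional \code{mode} (\code{"fixed"}, the default, or
#' \code{"tertile"}). The shipped configuration (the published cut-point
#' sets) is at \code{system.file("extdata", "default_schemes.yaml",
#' package = "geocna")} and is what \code{\link{default_schemes}} encodes.
#'
#' @param path Config file path (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return Scheme set in the shape of \code{\link{default_schemes}}.
#' @export
read_scheme_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- lapply(names(cfg), function(nm) {
    e <- cfg[[nm]]
    if (is.null(e$column) || is.null(e$cuts)) {
      stop("scheme '", nm, "': config requires 'column' and 'cuts'")
    }
    list(scheme = calibration_scheme(
           nm, as.numeric(e$cuts),
           labels = if (is.null(e$labels)) c("low", "medium", "high") else
             e$labels,
           mode = if (is.null(e$mode)) "fixed" else e$mode),
         column = e$column,
         raw_range = if (is.null(e$range)) NULL else as.numeric(e$range))
  })
  stats::setNames(out, names(cfg))
}

#' Calibrate a raw table into a case table
#'
#' Applies a set of calibration schemes to a validated raw table, builds the
#' persistently-low binary outcome from the three monthly vaccination-rate
#' levels, and returns the calibrated \code{case_table}. Factors whose raw
#' column is constant (degenerate under tertiles) are dropped with a
#' warning.
#'
#' @param raw A \code{raw_table} (see \code{\link{read_raw_table}}) or plain
#'   data.frame with the schemes' source columns.
#' @param schemes Scheme set as returned by \code{\link{default_schemes}}.
#' @param outcome_name Name for the binary outcome factor (default
#'   \code{"LOWVAX"}).
#' @param case_id Case-id column name in \code{raw}.
#' @return A \code{case_table} with the social factors, the three monthly
#'   vaccination levels and the binary outcome.
#' @export
calibrate_table <- function(raw, schemes = default_schemes(),
                            outcome_name = "LOWVAX", case_id = "zcta") {
  stopifnot(is.data.frame(raw))
  vax_names <- c("VAX_MAR", "VAX_APR", "VAX_MAY")
  out <- data.frame(id = as.character(raw[[case_id]]),
                    stringsAsFactors = FALSE)
  names(out) <- case_id
  for (nm in names(schemes)) {
    s <- schemes[[nm]]
    col <- s$column
    if (!col %in% names(raw)) stop("raw table lacks column '", col, "'")
    vals <- raw[[col]]
    if (s$scheme$mode == "tertile") {
      lv <- tryCatch(calibrate_tertile(vals), error = function(e) {
        warning("factor '", nm, "' is degenerate and was dropped: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(lv)) next
    } else {
      if (length(unique(vals)) == 1L) {
        warning("factor '", nm, "' is constant and was dropped")
        next
      }
      lv <- calibrate_fixed(vals, s$scheme)
    }
    out[[nm]] <- lv
  }
  if (!all(vax_names %in% names(out))) {
    stop("vaccination-rate schemes (VAX_MAR/VAX_APR/VAX_MAY) are required ",
         "to build the persistent outcome")
  }
  out[[outcome_name]] <- persistent_low_outcome(
    as.matrix(out[vax_names]))
  domains <- c(
    stats::setNames(rep(list(0:2), length(setdiff(names(out), c(case_id, outcome_name)))),
                    setdiff(names(out), c(case_id, outcome_name))),
    stats::setNames(list(0:1), outcome_name))
  case_table(out, outcome = outcome_name, case_id = case_id,
             domains = domains,
             exclude = intersect(vax_names, names(out)))
}
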