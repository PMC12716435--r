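#' Reference range for an analyte
#'
#' A reference range holds the lower and upper reference limits of a healthy
#' population for a laboratory analyte, interpreted as estimates of the 2.5th
#' and 97.5th percentiles. It defines the zlog transformation for that
#' analyte. When no lower limit is available, the conventional heuristic of
#' 15\% of the upper limit is applied (see [lower_from_upper()]).
#'
#' @param upper Upper reference limit (97.5th percentile), in analyte units.
#' @param lower Lower reference limit (2.5th percentile). Defaults to
#'   `0.15 * upper` when `NULL`.
#' @param analyte Analyte name, e.g. `"CA125"`.
#' @param units Unit string, e.g. `"U/mL"`.
#' @return An object of class `"reference_range"` with fields `lower`,
#'   `upper`, `analyte`, `units`.
#' @examples
#' ca125 <- reference_range(35, analyte = "CA125", units = "U/mL")
#' zlog(35, ca125)   # 1.96 by construction
#' @export
reference_range <- function(upper, lower = NULL, analyte = "", units = "") {
  stopifnot(is.numeric(upper), length(upper) == 1L, is.finite(upper))
  if (upper <= 0) stop("upper reference limit must be positive")
  if (is.null(lower)) lower <- lower_from_upper(upper)
  stopifnot(is.numeric(lower), length(lower) == 1L, is.finite(lower))
  if (lower <= 0) stop("lower reference limit must be positive")
  if (lower >= upper) stop("lower reference limit must be below the upper limit")
  structure(
    list(lower = lower, upper = upper,
         analyte = as.character(analyte), units = as.character(units)),
    class = "reference_range"
  )
}

#' @export
print.reference_range <- function(x, ...) {
  cat(sprintf("Reference range%s: [%g, %g] %s\n",
              if (nzchar(x$analyte)) paste0(" for ", x$analyte) else "",
              x$lower, x$upper, x$units))
  invisible(x)
}

#' Lower reference limit from the upper limit
#'
#' When no population-based lower reference limit is available, a common
#' recommendation is to set it to 15\% of the upper limit (e.g. 5.25 U/mL for
#' a CA125 upper limit of 35 U/mL, 21 pmol/L for an HE4 upper limit of
#' 140 pmol/L).
#'
#' @param upper Upper reference limit, positive scalar or vector.
#' @return `0.15 * upper`.
#' @export
lower_from_upper <- function(upper) {
  if (!is.numeric(upper) || any(!is.finite(upper)) || any(upper <= 0))
    stop("upper reference limit must be positive and finite")
  0.15 * upper
}

#' zlog transformation of analyte concentrations
#'
#' Maps a concentration to an approximately standard-normal scale using the
#' log-transformed reference limits as 2.5th/97.5th percentile anchors:
#' \deqn{z = \frac{\log x - (\log L + \log U)/2}{(\log U - \log L)/3.92}}
#' so that `zlog(L) = -1.96`, `zlog(U) = +1.96` and the geometric mean of the
#' limits maps to 0. Natural logarithms are used. The transform compensates
#' for pathological values lying an order of magnitude above the healthy
#' range, and centres healthy values near zero without estimating moments
#' from the data at hand.
#'
#' @param x Concentration(s), strictly positive, in the range's units.
#' @param range A [reference_range()].
#' @return zlog value(s), dimensionless.
#' @seealso [inverse_zlog()]
#' @examples
#' ca125 <- reference_range(35, analyte = "CA125", units = "U/mL")
#' zlog(sqrt(5.25 * 35), ca125)  # 0
#' inverse_zlog(2.78, ca125)     # ~52.1 U/mL
#' @export
zlog <- function(x, range) {
  stopifnot(inherits(range, "reference_range"), is.numeric(x))
  if (any(!is.finite(x)) || any(x <= 0))
    stop("concentrations must be positive and finite for the zlog transform")
  mid <- (log(range$lower) + log(range$upper)) / 2
  scale <- (log(range$upper) - log(range$lower)) / 3.92
  (log(x) - mid) / scale
}

#' Inverse zlog transformation
#'
#' Recovers the concentration corresponding to a zlog value under a given
#' reference range: `inverse_zlog(zlog(x, r), r) == x` up to numerical
#' precision.
#'
#' @param z zlog value(s).
#' @param range A [reference_range()].
#' @return Concentration(s) in the range's units.
#' @export
inverse_zlog <- function(z, range) {
  stopifnot(inherits(range, "reference_range"), is.numeric(z))
  mid <- (log(range$lower) + log(range$upper)) / 2
  scale <- (log(range$upper) - log(range$lower)) / 3.92
  exp(mid + z * scale)
}

#' Default protein reference ranges
#'
#' Upper limits of 35 U/mL for CA125 and 140 pmol/L for HE4, with lower
#' limits from the 15\%-of-upper heuristic (5.25 and 21 respectively).
#'
#' @return Named list of [reference_range()] objects (`ca125`, `he4`).
#' @export
default_reference_ranges <- function() {
  list(
    ca125 = reference_range(35, analyte = "CA125", units = "U/mL"),
    he4   = reference_range(140, analyte = "HE4", units = "pmol/L")
  )
}

#' Append zlog-transformed protein features to a feature table
#'
#' For each named range whose name matches a `protein_concentration` column
#' of the table, appends a `zlog_<name>` column tagged `protein_zlog`.
#'
#' @param table A [feature_table()].
#' @param ranges Named list of [reference_range()] objects; names must match
#'   protein concentration columns (default [default_reference_ranges()]).
#' @return The table with zlog columns appended.
#' @export
add_zlog_features <- function(table, ranges = default_reference_ranges()) {
  stopifnot(inherits(table, "feature_table"))
  missing <- setdiff(names(ranges), colnames(table$values))
  if (length(missing) > 0L)
    stop("no concentration column for analyte(s): ", paste(missing, collapse = ", "))
  vals <- table$values
  cats <- table$categories
  for (nm in names(ranges)) {
    if (cats[[nm]] != "protein_concentration")
      stop("column '", nm, "' is not tagged protein_concentration")
    zname <- paste0("zlog_", nm)
    vals <- cbind(vals, zlog(vals[, nm], ranges[[nm]]))
    colnames(vals)[ncol(vals)] <- zname
    cats[zname] <- "protein_zlog"
  }
  feature_table(vals, cats)
}
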