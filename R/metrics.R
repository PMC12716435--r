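#' Minimal score threshold achieving a specificity floor
#'
#' A sample is called positive when its score strictly exceeds the threshold
#' `t`, so specificity is the fraction of negatives with score `<= t`. The
#' default `"min_floor"` rule chooses the smallest negative-class score
#' achieving specificity at or above the floor -- the
#' `ceiling(floor * n)`-th order statistic of the negative scores -- so with
#' 182 negatives and a 0.99 floor the achieved specificity is 181/182
#' (99.5\%). The alternative `"zero_fp"` rule places the threshold at the
#' maximum negative score (100\% specificity in-sample); it is provided for
#' comparison because it tracks any single extreme negative outlier, which
#' the minimal-floor rule is robust to.
#'
#' @param scores Numeric scores (higher = more cancer-like).
#' @param labels Binary labels (1 = positive/cancer).
#' @param floor Specificity floor in (0, 1\]; default 0.99.
#' @param prevalence Disease prevalence used for the PPV (default 0.00145,
#'   the 0.145\% U.S. ovarian-cancer prevalence).
#' @param rule `"min_floor"` (default) or `"zero_fp"`.
#' @return Object of class `"threshold_report"`: `threshold`, `specificity`
#'   (fraction), `spec_k`/`spec_n` (count form), `sensitivity`, `ppv`,
#'   `floor`, `rule`.
#' @export
threshold_at_specificity <- function(scores, labels, floor = 0.99,
                                     prevalence = 0.00145,
                                     rule = c("min_floor", "zero_fp")) {
  rule <- match.arg(rule)
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0 || floor > 1)
    stop("specificity floor must be in (0, 1]")
  neg <- sort(scores[labels == 0L])
  pos <- scores[labels == 1L]
  if (length(neg) == 0L || length(pos) == 0L)
    stop("both classes must be present")
  n <- length(neg)
  t <- if (rule == "zero_fp") neg[n] else neg[ceiling(floor * n)]
  spec_k <- sum(neg <= t)
  sens <- mean(pos > t)
  spec <- spec_k / n
  structure(list(
    threshold = unname(t),
    specificity = spec, spec_k = spec_k, spec_n = n,
    sensitivity = sens,
    ppv = ppv(sens, spec, prevalence),
    prevalence = prevalence, floor = floor, rule = rule
  ), class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("Threshold %.4f (%s rule, floor %.0f%% specificity)\n",
              x$threshold, x$rule, 100 * x$floor))
  cat(sprintf("  specificity %.1f%% (%d/%d), sensitivity %.1f%%\n",
              100 * x$specificity, x$spec_k, x$spec_n, 100 * x$sensitivity))
  cat(sprintf("  PPV %.1f%% at %.3f%% prevalence\n",
              100 * x$ppv, 100 * x$prevalence))
  if (!is.null(x$zlog))
    cat(sprintf("  threshold as zlog %.2f = concentration %.1f %s\n",
                x$zlog, x$concentration, x$units))
  invisible(x)
}

#' Sensitivity at a given score threshold
#'
#' Fraction of positive samples with score strictly above `t`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = positive).
#' @param t Threshold.
#' @return Fraction in \[0, 1\].
#' @export
sensitivity_at_threshold <- function(scores, labels, t) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]
  if (length(pos) == 0L) stop("no positive samples")
  mean(pos > t)
}

#' Positive predictive value of a screening test
#'
#' \deqn{PPV = \frac{se \cdot p}{se \cdot p + (1 - sp)(1 - p)}}
#' for sensitivity `se`, specificity `sp` and prevalence `p`. At very low
#' prevalence even small false-positive rates dominate, which is why
#' screening requires specificity well above 99\%.
#'
#' @param sensitivity,specificity,prevalence Fractions in \[0, 1\].
#' @return PPV fraction; 0 (with a warning) when no one tests positive.
#' @examples
#' ppv(0.70, 181 / 182, 0.00145)  # ~0.156
#' @export
ppv <- function(sensitivity, specificity, prevalence) {
  args <- c(sensitivity, specificity, prevalence)
  if (any(args < 0 | args > 1)) stop("all arguments must be in [0, 1]")
  num <- sensitivity * prevalence
  den <- num + (1 - specificity) * (1 - prevalence)
  if (den == 0) {
    warning("no positive calls at this operating point; PPV defined as 0")
    return(0)
  }
  num / den
}

#' Convert a single-marker model score threshold back to a concentration
#'
#' For a one-feature logistic model on a zlog-transformed marker, a score
#' threshold `t` corresponds to the zlog value `(logit(t) - b) / w`, and
#' hence through the inverse zlog transform to a concentration in the
#' marker's units -- e.g. a CA125 score threshold of 0.88 under coefficients
#' (w = 1.39, b = -1.84) maps to a zlog value near 2.78 and about 52 U/mL.
#'
#' @param t Score threshold in (0, 1).
#' @param model A fitted [plr()] model with exactly one nonzero-coefficient
#'   feature.
#' @param range The marker's [reference_range()].
#' @return List with `zlog` and `concentration`.
#' @export
threshold_to_concentration <- function(t, model, range) {
  stopifnot(inherits(model, "plr"), inherits(range, "reference_range"),
            t > 0, t < 1)
  w <- model$coefficients[-1L]
  nz <- which(w != 0)
  if (length(nz) != 1L)
    stop("model must have exactly one feature with a nonzero coefficient, has ",
         length(nz))
  b <- model$coefficients[1L]
  z <- (stats::qlogis(t) - b) / w[nz]
  list(zlog = unname(z), concentration = unname(inverse_zlog(z, range)))
}

#' Clinical operating-point report for a model's scores
#'
#' Combines [threshold_at_specificity()] with, for single-marker models, the
#' threshold-to-concentration conversion.
#'
#' @inheritParams threshold_at_specificity
#' @param model Optional fitted [plr()] model (needed for the concentration
#'   conversion).
#' @param range Optional [reference_range()] for the single marker.
#' @return A `"threshold_report"`, with `zlog`, `concentration` and `units`
#'   fields when a single-marker model and range are given.
#' @export
clinical_report <- function(scores, labels, floor = 0.99, prevalence = 0.00145,
                            rule = c("min_floor", "zero_fp"),
                            model = NULL, range = NULL) {
  rep <- threshold_at_specificity(scores, labels, floor = floor,
                                  prevalence = prevalence, rule = rule)
  if (!is.null(model) && !is.null(range)) {
    conv <- threshold_to_concentration(rep$threshold, model, range)
    rep$zlog <- conv$zlog
    rep$concentration <- conv$concentration
    rep$units <- range$units
  }
  rep
}
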