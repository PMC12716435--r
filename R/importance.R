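#' Scaled coefficients of a fitted linear model
#'
#' Scales each feature's coefficient by the standard deviation of that
#' feature within the training dataset. The primary mode divides the
#' coefficient by the SD; the conventional standardized coefficient
#' (multiplying by the SD, so that the value reflects the effect of a 1-SD
#' change of the feature) is available as an explicitly labelled alternative.
#' The two conventions rank features differently; never mix modes within a
#' comparison.
#'
#' @param model A fitted [plr()] model carrying `feature_sd` (captured at
#'   fit time).
#' @param mode `"divide"` (coefficient / SD, default) or `"multiply"`
#'   (coefficient * SD).
#' @return Named numeric vector of scaled coefficients (no intercept), with
#'   attribute `mode`.
#' @export
scaled_coefficients <- function(model, mode = c("divide", "multiply")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "plr"))
  w <- model$coefficients[-1L]
  s <- model$feature_sd
  if (is.null(s)) stop("model does not carry training-set feature SDs")
  s <- s[names(w)]
  bad <- s == 0 & w != 0
  if (any(bad))
    stop("zero training SD with nonzero coefficient for: ",
         paste(names(w)[bad], collapse = ", "))
  out <- if (mode == "divide") ifelse(w == 0, 0, w / s) else w * s
  attr(out, "mode") <- mode
  out
}

#' Normalized feature importances from scaled coefficients
#'
#' A feature's importance is the absolute value of its scaled coefficient
#' divided by the sum of all features' absolute scaled coefficients, so
#' importances are fractions summing to 1 and a zero-coefficient feature has
#' importance exactly 0. Importances are additionally summed by feature
#' category when tags are supplied.
#'
#' @param scaled Named vector of scaled coefficients (see
#'   [scaled_coefficients()]).
#' @param categories Optional named character vector of category tags per
#'   feature.
#' @return Object of class `"importance_table"`: data frame (`feature`,
#'   `category`, `scaled`, `importance`) with a `category_importance`
#'   attribute (named vector summing to 1) and the scaling `mode`.
#' @export
importances <- function(scaled, categories = NULL) {
  stopifnot(is.numeric(scaled), !is.null(names(scaled)))
  total <- sum(abs(scaled))
  if (total == 0) stop("all scaled coefficients are zero; importances undefined")
  imp <- abs(scaled) / total
  cat_tags <- if (is.null(categories)) rep(NA_character_, length(scaled)) else {
    unname(categories[names(scaled)])
  }
  out <- data.frame(feature = names(scaled), category = cat_tags,
                    scaled = as.vector(scaled), importance = as.vector(imp),
                    stringsAsFactors = FALSE)
  if (!is.null(categories)) {
    ci <- tapply(out$importance, out$category, sum)
    attr(out, "category_importance") <- ci[order(-ci)]
  }
  attr(out, "mode") <- attr(scaled, "mode")
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Importance table for a fitted model
#'
#' Convenience wrapper: [scaled_coefficients()] then [importances()], with
#' category tags taken from a feature table when given.
#'
#' @param model A fitted [plr()] model.
#' @param table Optional [feature_table()] supplying category tags.
#' @param mode Scaling mode, see [scaled_coefficients()].
#' @return An `"importance_table"`.
#' @export
importance_table <- function(model, table = NULL, mode = c("divide", "multiply")) {
  mode <- match.arg(mode)
  categories <- if (!is.null(table)) table$categories else NULL
  importances(scaled_coefficients(model, mode), categories)
}

#' @export
print.importance_table <- function(x, digits = 4, ...) {
  ord <- order(-x$importance)
  df <- as.data.frame(x)[ord, , drop = FALSE]
  rownames(df) <- NULL
  print(utils::head(round_df(df, digits), 20L))
  if (nrow(df) > 20L) cat("... (", nrow(df) - 20L, " more features)\n", sep = "")
  ci <- attr(x, "category_importance")
  if (!is.null(ci)) {
    cat("\nCategory importances:\n")
    print(round(ci, digits))
  }
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Compare two importance tables
#'
#' Aligns two importance tables on the union of their features (a feature
#' absent from one table is treated as zero-coefficient there), omitting
#' features that are zero in both, and reports per-feature and per-category
#' importance deltas (B minus A).
#'
#' @param table_a,table_b `"importance_table"` objects, e.g. from the
#'   original and a restricted model. Both must use the same scaling mode.
#' @return Data frame (`feature`, `category`, `importance_a`,
#'   `importance_b`, `delta`) with a `category_delta` attribute.
#' @export
compare_importances <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "importance_table"),
            inherits(table_b, "importance_table"))
  ma <- attr(table_a, "mode"); mb <- attr(table_b, "mode")
  if (!is.null(ma) && !is.null(mb) && !identical(ma, mb))
    stop("cannot compare importances computed under different scaling modes")
  feats <- union(table_a$feature, table_b$feature)
  ia <- stats::setNames(rep(0, length(feats)), feats)
  ib <- ia
  ia[table_a$feature] <- table_a$importance
  ib[table_b$feature] <- table_b$importance
  cats <- stats::setNames(rep(NA_character_, length(feats)), feats)
  cats[table_a$feature] <- table_a$category
  cats[table_b$feature] <- ifelse(is.na(cats[table_b$feature]),
                                  table_b$category, cats[table_b$feature])
  keep <- ia != 0 | ib != 0
  out <- data.frame(feature = feats[keep], category = unname(cats[keep]),
                    importance_a = unname(ia[keep]), importance_b = unname(ib[keep]),
                    delta = unname(ib[keep] - ia[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$delta)), , drop = FALSE]
  rownames(out) <- NULL
  if (!all(is.na(out$category))) {
    cd <- tapply(out$delta, out$category, sum)
    attr(out, "category_delta") <- cd
  }
  out
}
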