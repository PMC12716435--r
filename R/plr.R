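#' Penalised logistic regression with balanced class weights
#'
#' Fits a binary linear-logistic classifier by minimising
#' \deqn{\tfrac12 \|w\|_2^2 + C \sum_i \omega_i
#'   \log\!\big(1 + e^{-\tilde y_i (w \cdot x_i + b)}\big)}
#' where \eqn{\tilde y_i \in \{-1, +1\}}, the intercept \eqn{b} is not
#' penalised, and with balanced class weighting
#' \eqn{\omega_i = n / (2\, n_{\mathrm{class}(i)})} so that both classes
#' contribute equally regardless of imbalance. `C = 1` (the default) weighs
#' the ridge penalty equally with the error term. The problem is strictly
#' convex, solved by damped Newton iterations to a gradient tolerance of
#' 1e-8, so the fit is deterministic.
#'
#' @param x Numeric feature matrix (samples x features), a data frame, or a
#'   formula.
#' @param ... Further arguments passed to methods.
#' @return An object of class `"plr"` with components `coefficients` (named,
#'   including `"(Intercept)"`), `feature_names`, `feature_sd` (training-set
#'   sample SDs, retained for scaled-coefficient importances), `C`,
#'   `class_weight`, `levels` (negative, positive class), `fitted.values`,
#'   `converged`, `iterations` and `call`. Supported methods: `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `simulate`.
#' @examples
#' x <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
#' fit <- plr(x, c(0, 0, 1, 1))
#' predict(fit, x)
#' @export
plr <- function(x, ...) UseMethod("plr")

#' @rdname plr
#' @param data Data frame holding the formula's variables.
#' @export
plr.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  mm <- stats::model.matrix(attr(mf, "terms"), mf)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  fit <- plr.default(mm, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname plr
#' @param y Binary response: 0/1, logical, or a two-level factor (second
#'   level is the positive class).
#' @param C Inverse penalty weight (> 0); the penalty is `0.5 * ||w||^2`
#'   against `C` times the weighted log-loss.
#' @param class_weight `"balanced"` (default) or `"none"`.
#' @param standardize If `TRUE`, features are centred and scaled to unit SD
#'   before fitting and coefficients are mapped back to the original scale.
#'   Defaults to `FALSE`: zlog protein features are already on a reference
#'   scale.
#' @param tol Convergence tolerance on the gradient's maximum absolute entry.
#' @param max_iter Maximum Newton iterations.
#' @export
plr.default <- function(x, y, C = 1, class_weight = c("balanced", "none"),
                        standardize = FALSE, tol = 1e-8, max_iter = 500L, ...) {
  class_weight <- match.arg(class_weight)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (anyNA(x)) stop("missing values in features")
  if (!is.numeric(C) || C <= 0) stop("C must be positive")

  if (is.factor(y)) {
    lev <- levels(y)
    if (length(lev) != 2L) stop("response must have exactly two levels")
    y01 <- as.integer(y == lev[2L])
  } else if (is.logical(y)) {
    lev <- c("FALSE", "TRUE"); y01 <- as.integer(y)
  } else {
    uy <- sort(unique(y))
    if (!all(uy %in% c(0, 1))) stop("numeric response must be coded 0/1")
    lev <- c("0", "1"); y01 <- as.integer(y)
  }
  if (length(y01) != nrow(x)) stop("length of response does not match rows of x")
  n1 <- sum(y01); n0 <- length(y01) - n1
  if (n0 < 2L || n1 < 2L) stop("need at least 2 samples in each class")

  feature_sd <- apply(x, 2L, stats::sd)
  xs <- x; center <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (standardize) {
    if (any(feature_sd == 0)) stop("cannot standardize constant feature(s): ",
                                   paste(colnames(x)[feature_sd == 0], collapse = ", "))
    center <- colMeans(x); scl <- feature_sd
    xs <- sweep(sweep(x, 2L, center), 2L, scl, "/")
  }

  n <- length(y01)
  w_obs <- if (class_weight == "balanced") {
    ifelse(y01 == 1L, n / (2 * n1), n / (2 * n0))
  } else rep(1, n)

  fit <- plr_newton(xs, y01, w_obs, C, tol, max_iter)
  beta <- fit$beta
  # map back to the original feature scale
  w_orig <- beta[-1L] / scl
  b_orig <- beta[1L] - sum(w_orig * center)
  coefs <- c("(Intercept)" = unname(b_orig), stats::setNames(w_orig, colnames(x)))

  eta <- drop(x %*% w_orig) + b_orig
  structure(list(
    coefficients = coefs,
    feature_names = colnames(x),
    feature_sd = stats::setNames(feature_sd, colnames(x)),
    C = C, class_weight = class_weight, standardize = standardize,
    levels = lev, y = y01, obs_weights = w_obs,
    fitted.values = stats::plogis(eta), linear.predictors = eta,
    converged = fit$converged, iterations = fit$iterations,
    objective = fit$objective, max_grad = fit$max_grad,
    call = match.call()
  ), class = "plr")
}

# Damped Newton on the (strictly convex) penalised weighted log-loss.
# beta = (intercept, w); intercept unpenalised.
plr_newton <- function(x, y01, w_obs, C, tol, max_iter) {
  n <- nrow(x); p <- ncol(x)
  xa <- cbind(1, x)
  pen <- c(0, rep(1, p))
  beta <- numeric(p + 1L)
  obj <- function(beta) {
    eta <- drop(xa %*% beta)
    # log(1 + exp(-ys*eta)) computed stably
    ys <- ifelse(y01 == 1L, 1, -1)
    ll <- log1p(exp(-abs(ys * eta))) + pmax(-ys * eta, 0)
    0.5 * sum(pen * beta^2) + C * sum(w_obs * ll)
  }
  f <- obj(beta)
  converged <- FALSE; it <- 0L; g <- NULL
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(xa %*% beta)
    mu <- stats::plogis(eta)
    g <- pen * beta + C * drop(crossprod(xa, w_obs * (mu - y01)))
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    s <- C * w_obs * mu * (1 - mu)
    h <- crossprod(xa, xa * s) + diag(pen, p + 1L)
    step <- solve(h, g)
    t_ <- 1
    repeat {
      cand <- beta - t_ * step
      fc <- obj(cand)
      if (fc <= f - 1e-4 * t_ * sum(g * step) || t_ < 1e-10) break
      t_ <- t_ / 2
    }
    # negligible objective improvement left: converged to float precision
    if (f - fc < 1e-12 * (abs(f) + 1) && max(abs(g)) < 1e-6) {
      beta <- cand
      converged <- TRUE
      break
    }
    beta <- cand
    f <- fc
  }
  if (!converged) {
    eta <- drop(xa %*% beta)
    mu <- stats::plogis(eta)
    g <- pen * beta + C * drop(crossprod(xa, w_obs * (mu - y01)))
    converged <- max(abs(g)) < tol
    if (!converged)
      warning(sprintf("plr did not converge in %d iterations (max |gradient| %.3g)",
                      max_iter, max(abs(g))))
  }
  list(beta = beta, converged = converged, iterations = it,
       objective = f, max_grad = max(abs(g)))
}

#' @export
print.plr <- function(x, digits = 4, ...) {
  cat("Penalised logistic regression (L2, C =", format(x$C), ", class_weight =",
      x$class_weight, ")\n")
  cat("Positive class:", x$levels[2L], "\n\nCoefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.plr <- function(object, ...) {
  imp <- tryCatch(importances(scaled_coefficients(object)), error = function(e) NULL)
  structure(list(
    call = object$call, C = object$C, class_weight = object$class_weight,
    levels = object$levels, coefficients = object$coefficients,
    feature_sd = object$feature_sd,
    importance = imp,
    n = length(object$y), n_pos = sum(object$y),
    converged = object$converged, iterations = object$iterations,
    train_auc = auc_rank(object$fitted.values, object$y)
  ), class = "summary.plr")
}

#' @export
print.summary.plr <- function(x, digits = 4, ...) {
  cat("Penalised logistic regression (L2, C =", format(x$C), ", class_weight =",
      x$class_weight, ")\n")
  cat(sprintf("n = %d (%d positive, class '%s'); converged in %d iterations\n",
              x$n, x$n_pos, x$levels[2L], x$iterations))
  tab <- data.frame(coefficient = x$coefficients)
  tab$training_sd <- c(NA, x$feature_sd)
  if (!is.null(x$importance))
    tab$importance <- c(NA, x$importance$importance[match(rownames(tab)[-1L],
                                                          x$importance$feature)])
  print(round(tab, digits))
  cat(sprintf("Training AUC: %.4f\n", x$train_auc))
  invisible(x)
}

#' @export
coef.plr <- function(object, ...) object$coefficients

#' Predict method for penalised logistic regression
#'
#' @param object A fitted [plr()] model.
#' @param newdata Feature matrix, data frame, or [feature_table()]; columns
#'   are matched to the model's features by name and must all be present.
#' @param type `"response"` for probabilities of the positive (cancer) class,
#'   `"link"` for the linear predictor.
#' @param ... Unused.
#' @return Numeric vector of scores, named by row names of `newdata`.
#' @export
predict.plr <- function(object, newdata = NULL,
                        type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
  } else {
    if (inherits(newdata, "feature_table")) newdata <- newdata$values
    newdata <- as.matrix(newdata)
    missing <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing) > 0L)
      stop("missing feature column(s): ", paste(missing, collapse = ", "))
    xm <- newdata[, object$feature_names, drop = FALSE]
    storage.mode(xm) <- "double"
    eta <- drop(xm %*% object$coefficients[-1L]) + object$coefficients[1L]
    names(eta) <- rownames(newdata)
  }
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.plr <- function(object, type = c("deviance", "pearson", "response"), ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted.values
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 - mu)),
    deviance = sign(y - mu) * sqrt(-2 * (y * log(mu) + (1 - y) * log(1 - mu)))
  )
}

#' @export
simulate.plr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(mu), 1L, mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Decision boundary of a two-feature linear-logistic model
#'
#' For a model with exactly two features, the boundary where the linear
#' predictor is zero is the line `y = slope * x + intercept` in the
#' (feature 1, feature 2) plane, with `slope = -w1/w2` and
#' `intercept = -b/w2`.
#'
#' @param model A fitted [plr()] model with exactly two features, or a named
#'   list/vector of coefficients (see [as_plr()]).
#' @return List with `slope` and `intercept`.
#' @examples
#' m <- as_plr(c(1.25, 1.02), intercept = -2.22,
#'             features = c("zlog_ca125", "zlog_he4"))
#' decision_boundary(m)$slope  # ~ -1.23
#' @export
decision_boundary <- function(model) {
  stopifnot(inherits(model, "plr"))
  w <- model$coefficients[-1L]
  b <- model$coefficients[1L]
  if (length(w) != 2L)
    stop("decision_boundary requires a model with exactly 2 features, got ", length(w))
  if (w[2L] == 0) stop("second feature's coefficient is zero; boundary is vertical")
  list(slope = unname(-w[1L] / w[2L]), intercept = unname(-b / w[2L]))
}

#' Construct a plr model object from known coefficients
#'
#' Builds a minimal fitted-model object from externally given coefficients
#' (for example, published ones), so that scoring, decision-boundary and
#' threshold utilities can be applied to it.
#'
#' @param coefficients Numeric vector of per-feature coefficients.
#' @param intercept Intercept term.
#' @param features Feature names (defaults to names of `coefficients`).
#' @param feature_sd Optional training-set SDs (needed for importances).
#' @return An object of class `"plr"`.
#' @export
as_plr <- function(coefficients, intercept = 0, features = names(coefficients),
                   feature_sd = NULL) {
  force(features)
  coefficients <- as.numeric(coefficients)
  if (is.null(features)) features <- paste0("x", seq_along(coefficients))
  stopifnot(length(features) == length(coefficients))
  if (!is.null(feature_sd)) feature_sd <- stats::setNames(as.numeric(feature_sd), features)
  structure(list(
    coefficients = c("(Intercept)" = unname(intercept),
                     stats::setNames(coefficients, features)),
    feature_names = features,
    feature_sd = feature_sd,
    C = NA_real_, class_weight = "unknown", standardize = FALSE,
    levels = c("0", "1"), converged = TRUE, iterations = 0L,
    call = match.call()
  ), class = "plr")
}

#' Score samples with a fitted model
#'
#' Pure function of the model and the features: applies the logistic score
#' to feature columns matched by name. Thin, explicitly named wrapper around
#' [predict.plr()] used when scoring an external (validation) cohort.
#'
#' @param model A fitted [plr()] model.
#' @param features Feature matrix, data frame, or [feature_table()].
#' @return Per-sample scores in (0, 1).
#' @export
score_external <- function(model, features) {
  predict(model, newdata = features, type = "response")
}
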