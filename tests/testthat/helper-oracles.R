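# Independent oracles used to check the package's implementations.

# All-pairs concordance AUC with half credit for ties.
auc_bruteforce <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive scan over all candidate thresholds (positive call: score > t).
# Returns the smallest threshold among observed score values (and -Inf)
# achieving specificity >= floor, with its achieved specificity.
threshold_bruteforce <- function(scores, labels, floor) {
  neg <- scores[labels == 0]
  cand <- sort(unique(c(-Inf, scores)))
  for (t in cand) {
    spec <- mean(neg <= t)
    if (spec >= floor) return(list(threshold = t, specificity = spec))
  }
  stop("unreachable: specificity 1 is always attained at max score")
}

# Direct numerical optimization of the penalised weighted logistic loss
# 0.5*||w||^2 + C * sum_i omega_i * logloss_i (intercept unpenalised),
# independent of the package's Newton solver.
plr_oracle <- function(x, y01, w_obs, C = 1, start = NULL) {
  x <- as.matrix(x)
  xa <- cbind(1, x)
  pen <- c(0, rep(1, ncol(x)))
  obj <- function(beta) {
    eta <- drop(xa %*% beta)
    ys <- ifelse(y01 == 1, 1, -1)
    ll <- log1p(exp(-abs(ys * eta))) + pmax(-ys * eta, 0)
    0.5 * sum(pen * beta^2) + C * sum(w_obs * ll)
  }
  gr <- function(beta) {
    mu <- plogis(drop(xa %*% beta))
    pen * beta + C * drop(crossprod(xa, w_obs * (mu - y01)))
  }
  if (is.null(start)) start <- numeric(ncol(xa))
  fit <- optim(start, obj, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  list(intercept = fit$par[1], w = fit$par[-1], value = fit$value)
}

balanced_weights <- function(y01) {
  n <- length(y01); n1 <- sum(y01); n0 <- n - n1
  ifelse(y01 == 1, n / (2 * n1), n / (2 * n0))
}

# Small synthetic cohort for fast unit tests.
small_spec <- function(...) {
  counts <- data.frame(
    cohort    = c("discovery", "discovery", "discovery", "discovery", "discovery",
                  "validation", "validation"),
    condition = c("healthy", "benign", "cancer", "benign", "cancer",
                  "healthy", "cancer"),
    affected  = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    n         = c(40L, 12L, 16L, 12L, 14L, 20L, 10L)
  )
  cohort_spec(counts = counts, ...)
}
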