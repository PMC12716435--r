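test_that("a separable toy problem is fit perfectly", {
  x <- cbind(a = c(0, 0.2, 1, 1.2), b = c(0.1, 0, 1.1, 1))
  y <- c(0, 0, 1, 1)
  fit <- plr(x, y)
  expect_true(fit$converged)
  expect_equal(auc_bruteforce(fit$fitted.values, y), 1.0)
  expect_true(all(fit$fitted.values > 0 & fit$fitted.values < 1))
})

test_that("the fit matches direct optimization of the stated objective", {
  set.seed(42)
  n <- 60
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  y <- rbinom(n, 1, plogis(0.8 * x[, 1] - 0.5 * x[, 2]))
  y[1:4] <- c(0, 0, 1, 1)  # guarantee both classes
  for (C in c(0.3, 1, 4)) {
    fit <- plr(x, y, C = C)
    oracle <- plr_oracle(x, y, balanced_weights(y), C = C)
    expect_equal(unname(fit$coefficients[-1]), oracle$w, tolerance = 1e-6)
    expect_equal(unname(fit$coefficients[1]), oracle$intercept, tolerance = 1e-6)
  }
})

test_that("balanced weighting equals duplicating the minority class", {
  # With n0 = 2*n1, balanced weights are 0.75/1.5 per class while duplication
  # gives effective weights 1/2: the same objective up to the overall loss
  # scale, so the balanced fit at C equals the unweighted fit on the
  # duplicated data at C * n/(2*n0) = 0.75 * C.
  set.seed(9)
  n1 <- 15; n0 <- 30
  x <- cbind(f1 = c(rnorm(n0), rnorm(n1) + 1),
             f2 = c(rnorm(n0), rnorm(n1) - 0.5))
  y <- c(rep(0, n0), rep(1, n1))
  dup <- c(seq_along(y), which(y == 1))
  fit_bal <- plr(x, y, C = 4 / 3, class_weight = "balanced")
  fit_dup <- plr(x[dup, ], y[dup], C = 1, class_weight = "none")
  expect_equal(fit_bal$coefficients, fit_dup$coefficients, tolerance = 1e-6)
  # verified independently by optimizing both objectives directly
  ora_bal <- plr_oracle(x, y, balanced_weights(y), C = 4 / 3)
  ora_dup <- plr_oracle(x[dup, ], y[dup], rep(1, length(dup)), C = 1)
  expect_equal(ora_bal$w, ora_dup$w, tolerance = 1e-5)
})

test_that("a constant feature gets a zero coefficient under the L2 penalty", {
  set.seed(1)
  x <- cbind(inform = c(rnorm(20), rnorm(20) + 2), flat = rep(3.7, 40))
  y <- rep(0:1, each = 20)
  fit <- plr(x, y)
  expect_equal(unname(fit$coefficients["flat"]), 0, tolerance = 1e-7)
})

test_that("the convex problem has a unique optimum regardless of initialization", {
  set.seed(4)
  x <- matrix(rnorm(50 * 3), 50, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rbinom(50, 1, plogis(x[, 1]))
  y[1:4] <- c(0, 0, 1, 1)
  fit <- plr(x, y)
  for (s in 1:3) {
    start <- rnorm(4, sd = 3)
    ora <- plr_oracle(x, y, balanced_weights(y), C = 1, start = start)
    expect_equal(unname(fit$coefficients), c(ora$intercept, ora$w),
                 tolerance = 1e-5)
  }
})

test_that("the fit agrees with glmnet ridge logistic regression", {
  skip_if_not_installed("glmnet")
  set.seed(12)
  n <- 80  # equal classes, so balanced weights are all 1
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(0:1, each = n / 2)
  x[y == 1, 1] <- x[y == 1, 1] + 1
  fit <- plr(x, y, C = 1)
  # glmnet: (1/n) sum logloss + lambda/2 ||w||^2  <=>  ours with lambda = 1/(n*C)
  g <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                      lambda = 1 / n, standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(fit$coefficients[-1]), as.numeric(g$beta), tolerance = 1e-4)
  expect_equal(unname(fit$coefficients[1]), as.numeric(g$a0), tolerance = 1e-4)
})

test_that("input validation catches degenerate problems", {
  x <- cbind(a = rnorm(6))
  expect_error(plr(x, c(1, 1, 1, 1, 1, 0)), "at least 2 samples")
  expect_error(plr(x, c(0, 1, 2, 0, 1, 2)), "0/1")
  expect_error(plr(x, rep(0:1, 3), C = 0), "positive")
  xna <- x; xna[2, 1] <- NA
  expect_error(plr(xna, rep(0:1, 3)), "missing")
})

test_that("decision boundaries follow -w1/w2 and -b/w2", {
  m <- as_plr(c(1.25, 1.02), intercept = -2.22,
              features = c("zlog_ca125", "zlog_he4"))
  db <- decision_boundary(m)
  expect_equal(round(db$slope, 2), -1.23)
  expect_equal(db$intercept, 2.22 / 1.02)
  m2 <- as_plr(c(0.14, 1.15), intercept = -1.66)
  expect_equal(round(decision_boundary(m2)$slope, 2), -0.12)
  m3 <- as_plr(c(1, 1), intercept = 0)
  expect_equal(decision_boundary(m3), list(slope = -1, intercept = 0))
  expect_error(decision_boundary(as_plr(c(1, 2, 3))), "exactly 2")
  expect_error(decision_boundary(as_plr(c(1, 0))), "zero")
})

test_that("scoring is a pure function of coefficients and named features", {
  m0 <- as_plr(c(f1 = 0, f2 = 0), intercept = 0)
  x <- cbind(f1 = rnorm(5), f2 = rnorm(5))
  expect_equal(unname(score_external(m0, x)), rep(0.5, 5))
  # published CA125-only model: score at zlog 2.78 is ~0.88
  ca <- as_plr(c(zlog_ca125 = 1.39), intercept = -1.84)
  expect_equal(unname(score_external(ca, cbind(zlog_ca125 = 2.78))),
               0.88, tolerance = 0.005)
  # mean-feature sample scores at logistic(w . mean + b)
  m <- as_plr(c(f1 = 0.7, f2 = -1.2), intercept = 0.3)
  xm <- cbind(f1 = mean(x[, "f1"]), f2 = mean(x[, "f2"]))
  expect_equal(unname(score_external(m, xm)),
               plogis(0.7 * xm[1] - 1.2 * xm[2] + 0.3))
  # column order must not matter; missing columns must
  expect_equal(score_external(m, x[, c("f2", "f1")]), score_external(m, x))
  expect_error(score_external(m, x[, "f1", drop = FALSE]), "missing feature")
})

test_that("plr methods behave like standard modelling methods", {
  set.seed(2)
  x <- cbind(a = c(rnorm(20), rnorm(20) + 1.5), b = rnorm(40))
  y <- rep(0:1, each = 20)
  fit <- plr(x, y)
  expect_named(coef(fit), c("(Intercept)", "a", "b"))
  expect_equal(predict(fit, x), fit$fitted.values, ignore_attr = TRUE)
  expect_equal(predict(fit, x, type = "link"),
               qlogis(predict(fit, x)), ignore_attr = TRUE)
  expect_output(print(fit), "Penalised logistic regression")
  expect_output(print(summary(fit)), "Training AUC")
  r <- residuals(fit, "response")
  expect_equal(r, y - fit$fitted.values, ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(40L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  # formula interface matches the matrix interface
  df <- data.frame(y = y, a = x[, "a"], b = x[, "b"])
  fit2 <- plr(y ~ a + b, data = df)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-9)
})
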