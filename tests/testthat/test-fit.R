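toy_dyad <- function(n = 100, nch = 18, seed = 1, fs = 7.81) {
  set.seed(seed)
  dyad_recording(matrix(rnorm(n * nch), n, nch),
                 matrix(rnorm(n * nch), n, nch), fs)
}

test_that("chronological split uses the ceiling rule and rejects empty segments", {
  d <- toy_dyad(7000)
  sp <- split_series(d, 0.5)
  expect_equal(sp$boundary, 3500)
  expect_equal(nrow(sp$teacher_test), 3500)

  d7 <- toy_dyad(7)
  sp7 <- split_series(d7, 0.5)
  expect_equal(sp7$boundary, 4)         # ceiling(3.5)
  expect_equal(nrow(sp7$teacher_test), 3)
  expect_identical(rbind(sp7$student_train, sp7$student_test), d7$student)

  expect_error(split_series(d, 1.0), "fraction")
  expect_error(split_series(d, 0), "fraction")
})

test_that("OLS recovers an exact affine construction and matches normal equations", {
  set.seed(4)
  X <- matrix(rnorm(40 * 18), 40, 18)
  y <- 2 * X[, 1] - X[, 2] + 0.5
  m <- fit_ols(y, X)
  expect_equal(m$weights[1:2], c(2, -1), tolerance = 1e-9)
  expect_equal(m$weights[3:18], rep(0, 16), tolerance = 1e-9)
  expect_equal(m$intercept, 0.5, tolerance = 1e-9)

  yn <- y + rnorm(40)
  m2 <- fit_ols(yn, X)
  Z <- cbind(1, X)
  beta <- solve(t(Z) %*% Z, t(Z) %*% yn)   # closed-form oracle
  expect_equal(c(m2$intercept, m2$weights), as.vector(beta), tolerance = 1e-9)
})

test_that("OLS weights for an unrelated response stay within sampling bounds", {
  set.seed(8)
  n <- 3500
  Q <- qr.Q(qr(matrix(rnorm(n * 18), n, 18))) * sqrt(n)  # orthonormalized, unit variance
  y <- rnorm(n)
  m <- fit_ols(y, Q)
  expect_true(all(abs(m$weights) < 4 / sqrt(n)))
})

test_that("rank-deficient predictors are a hard error naming the channels", {
  set.seed(5)
  X <- matrix(rnorm(50 * 18), 50, 18)
  X[, 7] <- X[, 3]
  expect_error(fit_ols(rnorm(50), X), "collinear")
  expect_error(fit_ols(rnorm(10), X[1:10, ]), "at least 20")
})

test_that("SVR handles a constant response exactly and validates hyperparameters", {
  X <- matrix(rnorm(60 * 5), 60, 5)
  m <- fit_svr(rep(3.3, 60), X, epsilon = 0.1)
  expect_equal(m$weights, rep(0, 5))
  expect_equal(m$intercept, 3.3)
  expect_error(fit_svr(rnorm(60), X, epsilon = -1), "epsilon")
  expect_error(fit_svr(rnorm(60), X, cost = 0), "cost")
})

test_that("linear SVR matches the exact dual QP on tiny instances", {
  for (s in 1:3) {
    set.seed(s)
    X <- matrix(rnorm(6 * 2), 6, 2)
    y <- rnorm(6)
    o <- svr_dual_oracle(X, y, eps = 0.1, C = 1)
    m <- fit_svr(y, X, epsilon = 0.1, cost = 1, standardize = FALSE,
                 tolerance = 1e-8)
    expect_equal(m$weights, o$w, tolerance = 1e-6)
    expect_equal(m$intercept, o$b, tolerance = 1e-6)
  }
})

test_that("internal standardization un-scales to the same predictions", {
  set.seed(6)
  X <- matrix(rnorm(80 * 4, mean = 5, sd = c(1, 10, 0.1, 3)), 80, 4, byrow = TRUE)
  y <- X %*% c(0.5, -0.1, 2, 0) + rnorm(80)
  m1 <- fit_svr(y, X, standardize = TRUE, tolerance = 1e-8)
  # same problem solved on manually standardized data, then un-scaled
  mx <- colMeans(X); sx <- apply(X, 2, sd); my <- mean(y); sy <- sd(y)
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  m2 <- fit_svr((y - my) / sy, Xs, standardize = FALSE, tolerance = 1e-8)
  Xnew <- matrix(rnorm(20 * 4, mean = 5), 20, 4)
  p1 <- predict(m1, Xnew)
  p2 <- my + sy * predict(m2, sweep(sweep(Xnew, 2, mx), 2, sx, "/"))
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("prediction is the stated affine map of teacher inputs", {
  m0 <- interbrain:::new_model_spec("OLS", 1L, rep(0, 18), 0)
  Xt <- matrix(rnorm(30 * 18), 30, 18)
  expect_equal(predict(m0, Xt), rep(0, 30))
  w <- rep(0, 18); w[7] <- 1
  m7 <- interbrain:::new_model_spec("OLS", 7L, w, 0)
  expect_equal(predict(m7, Xt), Xt[, 7])
  set.seed(10)
  m <- interbrain:::new_model_spec("SVR", 1L, rnorm(18), 0.3)
  a <- 2.5
  expect_equal(predict(m, a * Xt), a * (predict(m, Xt) - 0.3) + 0.3)
  expect_error(predict(m, Xt[, 1:5]), "channels")
})

test_that("a fitted model's predictions on its train data equal the fitted values", {
  d <- toy_dyad(200, seed = 3)
  fit <- fit_coupling(d, families = c("SVR", "OLS"))
  sp <- fit$split
  for (fam in c("SVR", "OLS")) {
    m <- fit$models[[fam]][[4]]
    expect_equal(predict(m, sp$teacher_train), fitted(fit, family = fam)[, 4])
  }
  # OLS fitted values agree with lm on the same training data
  lmfit <- lm(sp$student_train[, 4] ~ sp$teacher_train)
  expect_equal(fitted(fit, family = "OLS")[, 4], unname(fitted(lmfit)),
               tolerance = 1e-8)
})

test_that("the full model grid has 18 models per family with skip records", {
  d <- toy_dyad(200, seed = 7)
  fit <- fit_coupling(d)
  expect_equal(interbrain:::n_models(fit), 36)
  cf <- coef(fit)
  expect_equal(nrow(cf), 36)
  expect_equal(ncol(cf), 3 + 18)

  fit2 <- fit_coupling(d, exclude_channels = c(2, 9))
  expect_equal(interbrain:::n_models(fit2), 32)
  expect_equal(nrow(fit2$skipped), 4)
  expect_true(all(fit2$skipped$channel %in% c(2, 9)))

  # fitting is deterministic
  expect_equal(coef(fit), coef(fit_coupling(d)))
})

test_that("OLS train MSE never exceeds SVR train MSE on the same instance", {
  for (s in 1:5) {
    d <- toy_dyad(150, seed = 100 + s)
    fit <- fit_coupling(d)
    mse <- function(fam) colMeans(residuals(fit, family = fam)^2)
    expect_true(all(mse("OLS") <= mse("SVR") + 1e-10))
  }
})

test_that("both families recover the coupling gains when student noise vanishes", {
  # a dyad whose student is an exact linear map of the teacher's channels:
  # the teacher carries full-rank content (signal + physiological noise),
  # the student response has no noise of its own
  cfg <- sim_config(duration = 120, seed = 23)
  base <- generate_dyad(cfg)
  G <- matrix(0, 18, 18)
  G[3, 9] <- 1.5; G[5, 9] <- -0.7; G[12, 14] <- 0.8
  d <- dyad_recording(base$teacher, base$teacher %*% G, base$sampling_rate)
  sp <- split_series(d)
  for (j in c(9, 14)) {
    mo <- fit_ols(sp$student_train[, j], sp$teacher_train, channel = j)
    expect_lt(max(abs(mo$weights - G[, j])), 1e-6)
    expect_lt(abs(mo$intercept), 1e-6)
    suppressWarnings(
      ms <- fit_svr(sp$student_train[, j], sp$teacher_train,
                    epsilon = 1e-6, cost = 100, tolerance = 1e-8,
                    channel = j))
    expect_lt(max(abs(ms$weights - G[, j])), 1e-6)
  }
})
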