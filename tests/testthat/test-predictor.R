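test_that("z-scoring uses training rows only", {
  z <- zscore(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.vector(z$scaled), c(-1, 0, 1))

  set.seed(71)
  X <- matrix(rnorm(10 * 3), 10)
  fitr <- 1:7
  z2 <- zscore(X, fit_rows = fitr)
  expect_equal(colMeans(z2$scaled[fitr, ]), rep(0, 3))
  expect_equal(apply(z2$scaled[fitr, ], 2, sd), rep(1, 3))
  ## held-out rows transformed with the training parameters
  expect_equal(z2$scaled[9, 2],
               (X[9, 2] - mean(X[fitr, 2])) / sd(X[fitr, 2]))

  Xz <- X; Xz[fitr, 1] <- 5
  expect_error(zscore(Xz, fit_rows = fitr), "zero-variance")
})

test_that("single-feature regression matches the normal equations", {
  x <- c(1, 2, 3, 4, 5)
  fit <- suppressWarnings(fit_single(x, 2 * x + 1))
  expect_equal(fit$stats$R2, 1)
  expect_equal(fit$stats$MSE, 0, tolerance = 1e-20)
  expect_equal(unname(fit$model$weights), 2)

  set.seed(72)
  y5 <- c(2.3, 1.1, 4.2, 3.3, 5.0)
  f5 <- fit_single(x, y5)
  ## brute-force normal equations
  A <- cbind(1, x)
  beta <- solve(t(A) %*% A, t(A) %*% y5)
  expect_equal(unname(f5$model$weights), beta[2])
  expect_equal(f5$model$intercept, beta[1])
  expect_equal(f5$stats$r, cor(x, y5))

  ## null limit
  xn <- rnorm(200)
  expect_lt(fit_single(xn, rnorm(200))$stats$R2, 0.05)
  expect_error(fit_single(rep(1, 5), y5), "zero-variance")
})

test_that("multiple regression matches the pseudo-inverse solution", {
  set.seed(73)
  X <- matrix(rnorm(20 * 5), 20,
              dimnames = list(NULL, paste0("f", 1:5)))
  w <- c(0.5, -1, 0, 2, 0.3)
  y_exact <- as.vector(X %*% w) + 1
  fe <- suppressWarnings(fit_multiple(X, y_exact))
  expect_equal(fe$stats$R2, 1)
  expect_lt(max(abs(y_exact - (fe$model$intercept +
                               X %*% fe$model$weights))), 1e-10)

  y <- y_exact + rnorm(20)
  fm <- fit_multiple(X, y)
  A <- cbind(1, X)
  beta <- solve(t(A) %*% A, t(A) %*% y)
  expect_equal(unname(fm$model$weights), unname(beta[-1]),
               tolerance = 1e-10)

  ## permutation invariance of the fitted weights
  p <- sample(20)
  fp <- fit_multiple(X[p, ], y[p])
  expect_equal(fp$model$weights, fm$model$weights, tolerance = 1e-10)
})

test_that("stepwise regression isolates the informative feature", {
  ## y depends only on the fifth feature; the informative feature must
  ## always enter first. With four null candidates screened at
  ## p_enter = 0.05, a spurious co-selection occurs with probability
  ## about 1 - 0.95^4 = 0.185 per run, so "exactly {X5}" follows a
  ## Binomial(20, 0.815): >= 13 hits covers 97% of runs.
  hits <- 0
  for (s in 1:20) {
    set.seed(700 + s)
    X <- matrix(rnorm(48 * 5), 48,
                dimnames = list(NULL, c("t1_percent", "p300_amplitude",
                                        "p300_latency", "amp_trial_sd",
                                        "lat_trial_sd")))
    y <- -X[, 5] + rnorm(48, sd = 0.3)
    fit <- fit_stepwise(zscore(X)$scaled, y)
    sel <- unname(fit$model$selected)
    expect_equal(sel[1], 5L)         # the true feature always leads
    if (identical(sel, 5L)) hits <- hits + 1
  }
  expect_gte(hits, 13)

  ## nothing informative: intercept-only model predicts the mean
  set.seed(74)
  Xn <- matrix(rnorm(30 * 5), 30)
  colnames(Xn) <- paste0("f", 1:5)
  yn <- rnorm(30)
  fn <- fit_stepwise(zscore(Xn)$scaled, yn, p_enter = 1e-6)
  expect_length(fn$model$selected, 0)
  expect_equal(unname(predict(fn$model, Xn)), rep(mean(yn), 30))

  ## nested-model property: stepwise in-sample R2 never beats the full fit
  set.seed(75)
  X <- matrix(rnorm(40 * 5), 40); colnames(X) <- paste0("f", 1:5)
  y <- X[, 1] * 0.8 - X[, 3] * 0.5 + rnorm(40)
  Xz <- zscore(X)$scaled
  expect_lte(fit_stepwise(Xz, y)$stats$R2,
             fit_multiple(Xz, y)$stats$R2 + 1e-12)
})

test_that("leave-one-subject-out never touches the held-out subject", {
  set.seed(76)
  n <- 12
  X <- matrix(rnorm(n * 5), n)
  colnames(X) <- c("t1_percent", "p300_amplitude", "p300_latency",
                   "amp_trial_sd", "lat_trial_sd")
  y <- 0.7 * X[, 2] - 0.6 * X[, 5] + rnorm(n, sd = 0.4)

  ev <- loso_evaluate(X, y, "multiple")
  expect_length(ev$predictions, n)
  expect_true(is.finite(ev$r))

  ## leakage oracle: corrupting subject i's outcome and features leaves
  ## its own prediction unchanged
  for (i in c(1, 5)) {
    y2 <- y; y2[i] <- y2[i] + 100
    X2 <- X; X2[i, ] <- X2[i, ] + 50
    ev2 <- loso_evaluate(X2, y2, "multiple")
    ## the held-out row enters only through the (training-fitted) z-scores
    z <- zscore(X, fit_rows = setdiff(1:n, i))
    z2 <- zscore(X2, fit_rows = setdiff(1:n, i))
    expect_equal(z$center, z2$center)
    fit <- fit_multiple(z$scaled[-i, ], y[-i])
    expect_equal(ev$predictions[i],
                 unname(predict(fit$model, z$scaled[i, , drop = FALSE])))
  }

  ## tiny exact case: y is a noiseless function of one feature
  x4 <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "f"))
  ev4 <- suppressWarnings(
    loso_evaluate(x4, c(1, 2, 3, 4), "single", feature = "f"))
  expect_equal(ev4$predictions, c(1, 2, 3, 4), tolerance = 1e-8)
  expect_lt(ev4$MSE, 1e-12)

  expect_error(loso_evaluate(X, rep(0.5, n), "multiple"), "zero variance")
})

test_that("the predictor report covers all seven predictors", {
  set.seed(77)
  n <- 20
  X <- matrix(rnorm(n * 5), n)
  colnames(X) <- c("t1_percent", "p300_amplitude", "p300_latency",
                   "amp_trial_sd", "lat_trial_sd")
  feats <- tibble::as_tibble(X)
  y <- 0.05 * X[, 2] - 0.04 * X[, 5] + 0.8 + rnorm(n, sd = 0.03)
  rep <- predictor_report(feats, y)
  expect_equal(nrow(rep), 7)
  expect_setequal(rep$predictor,
                  c(colnames(X), "multi_regular", "multi_stepwise"))
  expect_true(all(rep$MSE >= 0))
  expect_true(all(is.na(rep$R2) | rep$R2 <= 1))
})
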