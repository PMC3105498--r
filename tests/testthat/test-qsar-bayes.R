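test_that("with fixed variances the sampler matches the conjugate posterior", {
  sim <- simulateWeightedRegression(100, 5, seed = 501L)
  ctrl <- gibbsControl(iterations = 21000L, burnIn = 1000L, seed = 502L,
                       fixVariances = c(0.5, 2))
  fit <- gibbsFit(sim$X, sim$y, sim$w, ctrl)
  S <- nrow(fit$beta)
  expect_equal(S, 20000L)
  # posterior mean vs closed-form weighted ridge, within 3 MC standard errors
  cf <- ridgeClosedForm(sim$X, sim$y, sim$w, sigma2 = 0.5, tau2 = 2)
  mcse <- apply(fit$beta, 2, stats::sd) / sqrt(S)
  expect_true(all(abs(colMeans(fit$beta) - cf) < 3 * mcse))
  # posterior covariance vs the exact Gaussian, within 10% Frobenius
  XtW <- t(sim$X * sim$w)
  A <- XtW %*% sim$X / 0.5 + diag(1 / 2, 5)
  exact <- solve(A)
  emp <- stats::cov(fit$beta)
  expect_lt(norm(emp - exact, "F") / norm(exact, "F"), 0.1)
  # unit weights reduce to plain ridge
  fit1 <- gibbsFit(sim$X, sim$y, control = ctrl)
  cf1 <- ridgeClosedForm(sim$X, sim$y, sigma2 = 0.5, tau2 = 2)
  mcse1 <- apply(fit1$beta, 2, stats::sd) / sqrt(S)
  expect_true(all(abs(colMeans(fit1$beta) - cf1) < 3 * mcse1))
})

test_that("a single orthonormal predictor follows the 1-D conjugate form", {
  set.seed(503L)
  n <- 50L
  x <- scale(rnorm(n)); x <- x / sqrt(sum(x^2))  # x'x = 1
  y <- drop(2 * x) + rnorm(n, sd = 0.3)
  s2 <- 0.09; t2 <- 4
  fit <- gibbsFit(x, y, control = gibbsControl(iterations = 21000L,
                                               burnIn = 1000L, seed = 504L,
                                               fixVariances = c(s2, t2)))
  prec <- 1 / s2 + 1 / t2
  postMean <- sum(x * y) / s2 / prec
  postVar <- 1 / prec
  draws <- fit$beta[, 1]
  expect_lt(abs(mean(draws) - postMean),
            3 * stats::sd(draws) / sqrt(length(draws)))
  expect_lt(abs(stats::var(draws) / postVar - 1), 0.1)
})

test_that("the noiseless degenerate limit recovers the true coefficients", {
  set.seed(505L)
  X <- scale(matrix(rnorm(80 * 3), 80, 3))
  betaStar <- c(1.5, -0.7, 0.3)
  y <- drop(X %*% betaStar)
  fit <- gibbsFit(X, y, control = gibbsControl(
    iterations = 3000L, burnIn = 500L, seed = 506L,
    fixVariances = c(1e-8, 1e6)))
  expect_lt(max(abs(colMeans(fit$beta) - betaStar)), 1e-3)
})

test_that("chains are bit-identical under identical configuration", {
  sim <- simulateWeightedRegression(60, 4, seed = 507L)
  ctrl <- gibbsControl(iterations = 800L, burnIn = 200L, seed = 508L)
  f1 <- gibbsFit(sim$X, sim$y, sim$w, ctrl)
  f2 <- gibbsFit(sim$X, sim$y, sim$w, ctrl)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma2, f2$sigma2)
  ctrl2 <- ctrl; ctrl2$seed <- 509L
  expect_false(identical(gibbsFit(sim$X, sim$y, sim$w, ctrl2)$beta,
                         f1$beta))
  expect_error(gibbsFit(matrix(numeric(0), 10, 0), rnorm(10)),
               "zero columns")
  expect_error(gibbsFit(sim$X, sim$y, w = rep(-1, 60)), "positive")
})

test_that("posterior prediction is centered, monotone in noise, and shaped", {
  sim <- simulateWeightedRegression(80, 4, seed = 510L)
  fit <- gibbsFit(sim$X, sim$y, sim$w,
                  gibbsControl(iterations = 3000L, burnIn = 500L,
                               seed = 511L))
  # an all-zero row predicts about zero on the standardized scale
  p0 <- posteriorPredict(fit, matrix(0, 1, 4))
  expect_lt(abs(p0$mean), 0.1)
  # intervals widen as the fixed error variance grows
  widths <- vapply(c(0.1, 1, 4), function(s2) {
    f <- gibbsFit(sim$X, sim$y, sim$w,
                  gibbsControl(iterations = 2000L, burnIn = 500L,
                               seed = 512L, fixVariances = c(s2, 2)))
    p <- posteriorPredict(f, matrix(0, 1, 4))
    p$upper - p$lower
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  expect_error(posteriorPredict(fit, matrix(0, 1, 3)), "columns")
})

test_that("predictive intervals cover held-out simulated points", {
  sim <- simulateWeightedRegression(200, 5, noiseBaseSd = 0.5,
                                    heteroscedastic = FALSE, seed = 513L)
  fit <- gibbsFit(sim$X, sim$y, control = gibbsControl(
    iterations = 4000L, burnIn = 1000L, seed = 514L))
  set.seed(515L)
  Xnew <- matrix(rnorm(500 * 5), 500, 5)
  ynew <- drop(Xnew %*% sim$beta) + rnorm(500, sd = sim$noiseSd[1])
  pp <- posteriorPredict(fit, Xnew)
  coverage <- mean(ynew >= pp$lower & ynew <= pp$upper)
  expect_gte(coverage, 0.92)
  expect_lte(coverage, 0.98)
})

test_that("fold assignment is balanced, seeded, and exhaustive", {
  folds <- makeFolds(103L, 10L, seed = 516L)
  expect_equal(sort(unique(folds)), 1:10)
  sizes <- as.integer(table(folds))
  expect_equal(sizes, c(rep(11L, 3), rep(10L, 7)))
  expect_identical(folds, makeFolds(103L, 10L, seed = 516L))
  expect_false(identical(folds, makeFolds(103L, 10L, seed = 517L)))
})

test_that("cross-validation is exact on noiseless data and self-consistent", {
  set.seed(518L)
  X <- scale(matrix(rnorm(120 * 3), 120, 3))
  y <- drop(X %*% c(1, -1, 0.5))
  ctrl <- gibbsControl(iterations = 1500L, burnIn = 500L, seed = 519L)
  cv <- crossValidate(X, y, k = 10L, control = ctrl)
  expect_lt(cv$pressMean, 0.01 * length(y))
  expect_true(all(table(cv$foldAssignment) >= 1))
  expect_gte(cv$pressMean, cv$pressInterval95[1])
  expect_lte(cv$pressMean, cv$pressInterval95[2])
  expect_true(all(cv$pressDraws >= 0))
})

test_that("PRESS draws are invariant to row permutation given the folds", {
  sim <- simulateWeightedRegression(90, 4, seed = 520L)
  ctrl <- gibbsControl(iterations = 1000L, burnIn = 200L, seed = 521L)
  folds <- makeFolds(90L, 9L, seed = 522L)
  cv1 <- crossValidate(sim$X, sim$y, sim$w, k = 9L, control = ctrl,
                       folds = folds)
  perm <- sample(90L)
  cv2 <- crossValidate(sim$X[perm, ], sim$y[perm], sim$w[perm], k = 9L,
                       control = ctrl, folds = folds[perm])
  expect_equal(cv1$pressDraws, cv2$pressDraws)
})

test_that("weighted and unweighted runs share their folds", {
  sim <- simulateWeightedRegression(60, 3, seed = 523L)
  cmp <- compareWeightedUnweighted(sim$X, sim$y, sim$w, k = 6L,
                                   control = gibbsControl(
                                     iterations = 600L, burnIn = 100L,
                                     seed = 524L))
  expect_identical(cmp$weighted$foldAssignment,
                   cmp$unweighted$foldAssignment)
  expect_equal(cmp$differenceMean,
               cmp$weighted$pressMean - cmp$unweighted$pressMean)
})

test_that("on homoscedastic data the weights change little", {
  sim <- simulateWeightedRegression(150, 5, noiseBaseSd = 0.6,
                                    heteroscedastic = FALSE, seed = 525L)
  cmp <- compareWeightedUnweighted(sim$X, sim$y, sim$w, k = 10L,
                                   control = gibbsControl(
                                     iterations = 1200L, burnIn = 200L,
                                     seed = 526L))
  width <- mean(cmp$weighted$pressInterval95[2] -
                  cmp$weighted$pressInterval95[1],
                cmp$unweighted$pressInterval95[2] -
                  cmp$unweighted$pressInterval95[1])
  expect_lt(abs(cmp$differenceMean), width)
})

test_that("posterior means recover planted coefficients", {
  sim <- simulateWeightedRegression(300, 10, noiseBaseSd = 0.6,
                                    seed = 527L)
  fit <- gibbsFit(sim$X, sim$y, sim$w,
                  gibbsControl(iterations = 3000L, burnIn = 500L,
                               seed = 528L))
  expect_gt(stats::cor(colMeans(fit$beta), sim$beta), 0.95)
})
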