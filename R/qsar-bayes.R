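# Bayesian weighted ridge regression fitted by Gibbs sampling.
#
# Model:  y | beta, sigma2 ~ N(X beta, sigma2 * diag(w)^-1)
#         beta | tau2      ~ N(0, tau2 * I)
#         sigma2 ~ InvGamma(aSigma, bSigma),  tau2 ~ InvGamma(aTau, bTau)
# where w are observation weights encoding assay confidence (higher
# confidence = larger weight = smaller error variance). Full conditionals:
#   beta   ~ N(A^-1 X'W y / sigma2, A^-1),  A = X'WX/sigma2 + I/tau2
#   sigma2 ~ InvGamma(aSigma + n/2, bSigma + r'Wr/2),  r = y - X beta
#   tau2   ~ InvGamma(aTau + p/2,  bTau + beta'beta/2)
# Cross-validated predictive ability is summarized as the posterior of
# PRESS (predicted residual sum of squares over held-out rows), reported
# as mean and central 95% interval.

#' Gibbs sampler configuration
#'
#' @param iterations total Gibbs iterations.
#' @param burnIn discarded initial iterations.
#' @param thin keep every thin-th draw after burn-in.
#' @param seed chain seed; identical configuration and seed reproduce the
#'   chain exactly.
#' @param aSigma,bSigma inverse-gamma shape/rate hyperparameters for the
#'   error variance (weakly informative default 0.001/0.001).
#' @param aTau,bTau the same for the coefficient variance.
#' @param fixVariances optional c(sigma2, tau2): skip the variance updates
#'   and condition on these values (used by the conjugate closed-form
#'   checks).
#' @return list of class \code{gibbsControl}.
#' @export
gibbsControl <- function(iterations = 12000L, burnIn = 2000L, thin = 1L,
                         seed = 1L, aSigma = 0.001, bSigma = 0.001,
                         aTau = 0.001, bTau = 0.001, fixVariances = NULL) {
  stopifnot(iterations > burnIn, burnIn >= 0L, thin >= 1L,
            aSigma > 0, bSigma > 0, aTau > 0, bTau > 0)
  if (!is.null(fixVariances))
    stopifnot(length(fixVariances) == 2L, all(fixVariances > 0))
  structure(as.list(environment()), class = "gibbsControl")
}

rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1L, shape, rate = rate)

#' Fit the Bayesian weighted ridge model by Gibbs sampling
#'
#' @param X n x p descriptor matrix (standardized, as produced by
#'   \code{\link{qsarMatrix}}).
#' @param y length-n standardized response.
#' @param w positive observation weights (defaults to unit weights).
#' @param control a \code{\link{gibbsControl}}.
#' @return object of class \code{posteriorSamples}: \code{beta} (S x p),
#'   \code{sigma2}, \code{tau2} (length S), and the configuration echo.
#' @examples
#' sim <- simulateWeightedRegression(50, 3, seed = 7)
#' fit <- gibbsFit(sim$X, sim$y, sim$w,
#'                 gibbsControl(iterations = 600, burnIn = 100, seed = 7))
#' colMeans(fit$beta)
#' @export
gibbsFit <- function(X, y, w = rep(1, length(y)),
                     control = gibbsControl()) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p == 0L) stop("descriptor matrix has zero columns")
  stopifnot(length(y) == n, length(w) == n)
  if (any(w <= 0)) stop("weights must be positive")
  stopifnot(inherits(control, "gibbsControl"))
  set.seed(control$seed)

  XtW <- t(X * w)
  XtWX <- XtW %*% X
  XtWy <- drop(XtW %*% y)
  fixed <- !is.null(control$fixVariances)
  sigma2 <- if (fixed) control$fixVariances[1] else 1
  tau2 <- if (fixed) control$fixVariances[2] else 1
  beta <- numeric(p)

  S <- (control$iterations - control$burnIn) %/% control$thin
  betaDraws <- matrix(0, S, p)
  sigma2Draws <- tau2Draws <- numeric(S)
  keep <- 0L
  for (it in seq_len(control$iterations)) {
    A <- XtWX / sigma2 + diag(1 / tau2, p)
    R <- tryCatch(chol(A), error = function(e)
      stop("conditional precision is not positive definite (sigma2 = ",
           signif(sigma2, 4), ", tau2 = ", signif(tau2, 4), "): ",
           conditionMessage(e)))
    mu <- backsolve(R, backsolve(R, XtWy / sigma2, transpose = TRUE))
    beta <- mu + backsolve(R, stats::rnorm(p))
    if (!fixed) {
      r <- y - drop(X %*% beta)
      sigma2 <- rinvgamma1(control$aSigma + n / 2,
                           control$bSigma + sum(w * r^2) / 2)
      tau2 <- rinvgamma1(control$aTau + p / 2,
                         control$bTau + sum(beta^2) / 2)
    }
    if (it > control$burnIn &&
        (it - control$burnIn) %% control$thin == 0L) {
      keep <- keep + 1L
      betaDraws[keep, ] <- beta
      sigma2Draws[keep] <- sigma2
      tau2Draws[keep] <- tau2
    }
  }
  colnames(betaDraws) <- colnames(X)
  structure(list(beta = betaDraws, sigma2 = sigma2Draws, tau2 = tau2Draws,
                 n = n, p = p, control = control),
            class = "posteriorSamples")
}

#' @export
print.posteriorSamples <- function(x, ...) {
  cat("posteriorSamples:", nrow(x$beta), "draws over", x$p,
      "coefficients (n =", x$n, ")\n")
  cat("  posterior mean beta:",
      paste(signif(colMeans(x$beta), 3), collapse = ", "), "\n")
  if (is.null(x$control$fixVariances))
    cat("  E[sigma2] =", signif(mean(x$sigma2), 3),
        " E[tau2] =", signif(mean(x$tau2), 3), "\n")
  invisible(x)
}

#' Posterior predictive summaries for new rows
#'
#' Per posterior draw s the predictive draw for row i is
#' \code{Xnew[i,] beta(s) + e}, \code{e ~ N(0, sigma2(s) / wNew[i])}.
#'
#' @param samples a \code{posteriorSamples}.
#' @param Xnew matrix with the training column count.
#' @param wNew weights for the new observations (default 1).
#' @param level interval level (default 0.95).
#' @param predictionNoise include the observation noise term (TRUE, the
#'   predictive interval) or summarize the mean response only.
#' @return data.frame: mean, lower, upper per row.
#' @export
posteriorPredict <- function(samples, Xnew, wNew = NULL, level = 0.95,
                             predictionNoise = TRUE) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != samples$p)
    stop("Xnew has ", ncol(Xnew), " columns; model has ", samples$p)
  if (is.null(wNew)) wNew <- rep(1, nrow(Xnew))
  stopifnot(length(wNew) == nrow(Xnew), all(wNew > 0))
  S <- nrow(samples$beta)
  M <- Xnew %*% t(samples$beta)               # n x S mean draws
  if (predictionNoise) {
    noise <- matrix(stats::rnorm(length(M)), nrow(Xnew), S) *
      sqrt(outer(1 / wNew, samples$sigma2))
    M <- M + noise
  }
  alpha <- (1 - level) / 2
  data.frame(mean = rowMeans(M),
             lower = apply(M, 1, stats::quantile, probs = alpha),
             upper = apply(M, 1, stats::quantile, probs = 1 - alpha))
}

#' Seeded k-fold assignment
#'
#' Rows are permuted with the seed and cut into contiguous blocks; when n
#' is not divisible by k the earlier folds receive the extra row.
#' @param n rows; @param k folds; @param seed permutation seed.
#' @return integer fold label per row (1..k).
#' @export
makeFolds <- function(n, k, seed) {
  stopifnot(k >= 2L, n >= k)
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  folds <- integer(n)
  folds[perm] <- rep(seq_len(k), times = sizes)
  folds
}

#' Cross-validated PRESS posterior for the weighted ridge model
#'
#' Each fold is refitted by \code{\link{gibbsFit}} on the remaining rows
#' (with a fold-specific seed derived from the control seed) and its
#' held-out rows predicted per draw; the PRESS posterior draw s is the sum
#' over all rows of the squared deviation from that draw's prediction.
#'
#' @param X,y,w as in \code{\link{gibbsFit}}.
#' @param k folds (the reference analysis uses 10).
#' @param control a \code{\link{gibbsControl}}.
#' @param folds optional explicit fold assignment overriding the seeded
#'   one.
#' @return list of class \code{cvResult}: foldAssignment, predictions
#'   (n x S per-draw held-out predictions), pressDraws, pressMean,
#'   pressInterval95.
#' @export
crossValidate <- function(X, y, w = rep(1, length(y)), k = 10L,
                          control = gibbsControl(), folds = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= k)
  if (is.null(folds)) folds <- makeFolds(n, k, control$seed)
  stopifnot(length(folds) == n)
  S <- (control$iterations - control$burnIn) %/% control$thin
  pred <- matrix(NA_real_, n, S)
  for (fold in sort(unique(folds))) {
    test <- folds == fold
    ctrl <- control
    ctrl$seed <- control$seed + 1000L * fold
    if (sum(!test) < ncol(X) && is.null(ctrl$fixVariances)) {
      warning("fold ", fold, " trains on fewer rows than descriptors; ",
              "fixing variances at 1 for stability")
      ctrl$fixVariances <- c(1, 1)
    }
    fit <- gibbsFit(X[!test, , drop = FALSE], y[!test], w[!test], ctrl)
    pred[test, ] <- X[test, , drop = FALSE] %*% t(fit$beta)
  }
  pressDraws <- colSums((y - pred)^2)
  structure(list(foldAssignment = folds, predictions = pred,
                 pressDraws = pressDraws, pressMean = mean(pressDraws),
                 pressInterval95 = unname(stats::quantile(pressDraws,
                                                          c(0.025, 0.975))),
                 k = k, control = control),
            class = "cvResult")
}

#' @export
print.cvResult <- function(x, ...) {
  cat(sprintf("%d-fold CV PRESS: %.2f (%.2f; %.2f)\n", x$k, x$pressMean,
              x$pressInterval95[1], x$pressInterval95[2]))
  invisible(x)
}

#' Weighted versus unweighted cross-validated PRESS
#'
#' Runs \code{\link{crossValidate}} twice on identical folds -- once with
#' the supplied confidence weights, once with unit weights -- and reports
#' both PRESS posteriors and their difference, the check of whether
#' incorporating assay confidence improves predictive performance.
#'
#' @inheritParams crossValidate
#' @return list of class \code{weightComparison}: weighted, unweighted
#'   (both \code{cvResult}), pressDifference (weighted - unweighted,
#'   posterior draws), and its mean and central 95% interval.
#' @export
compareWeightedUnweighted <- function(X, y, w, k = 10L,
                                      control = gibbsControl()) {
  folds <- makeFolds(nrow(as.matrix(X)), k, control$seed)
  weighted <- crossValidate(X, y, w, k, control, folds = folds)
  unweighted <- crossValidate(X, y, rep(1, length(y)), k, control,
                              folds = folds)
  diffDraws <- weighted$pressDraws - unweighted$pressDraws
  structure(list(weighted = weighted, unweighted = unweighted,
                 pressDifference = diffDraws,
                 differenceMean = mean(diffDraws),
                 differenceInterval95 = unname(stats::quantile(diffDraws,
                                                               c(0.025, 0.975)))),
            class = "weightComparison")
}

#' @export
print.weightComparison <- function(x, ...) {
  cat(sprintf("weighted   PRESS %.2f (%.2f; %.2f)\n", x$weighted$pressMean,
              x$weighted$pressInterval95[1], x$weighted$pressInterval95[2]))
  cat(sprintf("unweighted PRESS %.2f (%.2f; %.2f)\n", x$unweighted$pressMean,
              x$unweighted$pressInterval95[1],
              x$unweighted$pressInterval95[2]))
  cat(sprintf("difference %.2f (%.2f; %.2f)\n", x$differenceMean,
              x$differenceInterval95[1], x$differenceInterval95[2]))
  invisible(x)
}

#' Closed-form ridge solution (fixed variances)
#'
#' The conditional posterior mean of beta given fixed sigma2 and tau2:
#' \code{(X'WX + (sigma2/tau2) I)^-1 X'Wy}. Used as the independent check
#' of the sampler.
#' @param X,y,w as in \code{\link{gibbsFit}}.
#' @param sigma2,tau2 fixed variances.
#' @export
ridgeClosedForm <- function(X, y, w = rep(1, length(y)), sigma2 = 1,
                            tau2 = 1) {
  X <- as.matrix(X)
  XtW <- t(X * w)
  drop(solve(XtW %*% X + diag(sigma2 / tau2, ncol(X)), XtW %*% y))
}
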