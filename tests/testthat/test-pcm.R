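test_that("the z-scale table is complete and sequence encoding is faithful", {
  zs <- zScaleTable()
  expect_equal(sort(rownames(zs)), sort(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                 "")[[1]]))
  expect_equal(ncol(zs), 3L)
  enc <- encodeSequences(c("ACD", "ACD"))
  expect_equal(enc[1, ], enc[2, ])          # identical sequences
  expect_equal(dim(enc), c(2L, 9L))
  e1 <- encodeSequences(c("A", "A"))
  expect_equal(e1[1, ] - e1[2, ], setNames(c(0, 0, 0), colnames(e1)))
  # distinct sequences give distinct rows
  e2 <- encodeSequences(c("ACDEF", "ACDEG"))
  expect_false(all(e2[1, ] == e2[2, ]))
  expect_error(encodeSequences(c("AXB", "ACD")), "unknown residue")
  expect_error(encodeSequences(c("AC", "ACD")), "aligned length")
})

test_that("gaps impute the position mean; all-gap columns are flagged", {
  zs <- zScaleTable()
  enc <- encodeSequences(c("A-D", "ACD", "AWD"), zs)
  expect_equal(enc[1, 4:6],
               setNames(colMeans(zs[c("C", "W"), ]), colnames(enc)[4:6]))
  encAll <- encodeSequences(c("A-D", "A-D"))
  expect_equal(attr(encAll, "allGapPositions"), 2L)
  expect_equal(unname(encAll[, 4:6]), matrix(0, 2, 3))
})

test_that("aligned FASTA reads through the standard reader", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seq1", "ACD-EF", ">seq2", "ACDWEF"), path)
  seqs <- readAlignedFasta(path)
  expect_equal(unname(seqs), c("ACD-EF", "ACDWEF"))
  writeLines(c(">s1", "ACD", ">s2", "ACDE"), path)
  expect_error(readAlignedFasta(path), "not aligned")
})

test_that("PCA scores are orthogonal and reconstruct at full rank", {
  set.seed(601L)
  M <- matrix(rnorm(20 * 6), 20, 6)
  pca <- pcaReduce(M, 6L)
  G <- crossprod(pca$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  rec <- pca$scores %*% t(pca$loadings) +
    matrix(pca$center, 20, 6, byrow = TRUE)
  expect_lt(max(abs(rec - M)), 1e-8)
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_error(pcaReduce(M, 7L), "rank bound")
  # constant columns are dropped before the decomposition
  M2 <- cbind(M, 5)
  expect_equal(pcaReduce(M2, 6L)$kept, 1:6)
})

test_that("cross-terms are elementwise products in ligand-major order", {
  XL <- matrix(1:6, 3, 2); XP <- matrix(c(1, 0, 2, 3, 1, 0), 3, 2)
  ct <- crossTerms(XL, XP)
  expect_equal(dim(ct), c(3L, 4L))
  expect_equal(ct[, 1], XL[, 1] * XP[, 1])
  expect_equal(ct[, 2], XL[, 1] * XP[, 2])
  expect_equal(ct[, 4], XL[, 2] * XP[, 2])
  expect_equal(unname(crossTerms(XL, matrix(0, 3, 2))),
               matrix(0, 3, 4))
  one <- crossTerms(XL[, 1, drop = FALSE], XP[, 1, drop = FALSE])
  expect_equal(drop(one), XL[, 1] * XP[, 1])
})

test_that("single-predictor PLS equals ordinary least squares", {
  set.seed(602L)
  x <- matrix(rnorm(40), 40, 1)
  y <- drop(1.7 * x) + rnorm(40, sd = 0.4)
  fit <- plsFit(x, y, 1L)
  ols <- stats::lm(y ~ x)
  expect_lt(max(abs(predict(fit, x) - stats::fitted(ols))), 1e-8)
})

test_that("full-rank PLS fits noiseless linear data exactly", {
  set.seed(603L)
  X <- matrix(rnorm(50 * 4), 50, 4)
  y <- drop(X %*% c(1, -2, 0.5, 3))
  fit <- plsFit(X, y, 4L)
  expect_lt(max(abs(predict(fit, X) - y)), 1e-6)
  # residual norm is nonincreasing in the component count
  yn <- y + rnorm(50, sd = 0.5)
  rn <- vapply(1:4, function(h)
    sqrt(sum((yn - predict(plsFit(X, yn, h), X))^2)), numeric(1))
  expect_true(all(diff(rn) <= 1e-10))
})

test_that("PLS predictions match a reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(604L)
  for (i in 1:10) {
    n <- sample(20:35, 1L); m <- sample(3:8, 1L)
    nc <- sample(1:3, 1L)
    X <- matrix(rnorm(n * m), n, m,
                dimnames = list(NULL, paste0("V", 1:m)))
    y <- rnorm(n)
    mine <- plsFit(X, y, nc, scale = TRUE)
    ref <- mixOmics::pls(X, y, ncomp = nc, mode = "regression",
                         scale = TRUE)
    refPred <- predict(ref, X)$predict[, , nc]
    expect_lt(max(abs(predict(mine, X) - refPred)), 1e-6)
  }
})

test_that("PLS stops early when the covariance is exhausted", {
  X <- matrix(rnorm(30), 30, 1)
  y <- drop(2 * X)
  expect_warning(fit <- plsFit(X, y, 3L), "exhausted")
  expect_lt(fit$nComponents, 3L)
})

test_that("VIP scores are normalized and find the informative column", {
  set.seed(605L)
  X <- matrix(rnorm(60 * 5), 60, 5)
  fit <- plsFit(X, drop(X %*% rnorm(5)) + rnorm(60, sd = 0.2), 3L)
  expect_lt(abs(mean(vipScores(fit)^2) - 1), 1e-10)
  hits <- 0L
  for (r in 1:20) {
    Xr <- matrix(rnorm(50 * 8), 50, 8)
    yr <- 2 * Xr[, 3] + rnorm(50, sd = 0.3)
    rk <- importanceRanking(plsFit(Xr, yr, 2L))
    if (rk$column[1] == 3) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  # all-noise columns: no column dominates across replicates
  tops <- vapply(1:20, function(r) {
    Xr <- matrix(rnorm(40 * 6), 40, 6)
    as.integer(importanceRanking(plsFit(Xr, rnorm(40), 2L))$column[1])
  }, integer(1))
  expect_gte(length(unique(tops)), 3L)
})

test_that("the PCM pipeline recovers the planted bilinear signal", {
  gen <- generateChemblStore(chemblSynthConfig(
    seed = 606L, nMolecules = 80L, activitiesPerTarget = 17L))
  pcm <- extractPcmDataset(gen$store, "channel")
  expect_gte(nrow(pcm), 300L)
  cv <- pcmCrossValidate(pcm, k = 7L, seed = 607L)
  expect_gt(cv$pearsonR, 0.9)
  # identical call, identical statistic
  cv2 <- pcmCrossValidate(pcm, k = 7L, seed = 607L,
                          nComponents = cv$nComponents)
  expect_equal(cv2$pearsonR, cv$pearsonR)
  # shuffled response destroys the correlation
  set.seed(608L)
  shuffled <- pcm
  shuffled$val <- sample(shuffled$val)
  cvNull <- pcmCrossValidate(shuffled, k = 7L, seed = 607L,
                             nComponents = cv$nComponents)
  expect_lt(abs(cvNull$pearsonR), 0.2)
  # the protein block supports exactly 17 components for 18 proteins
  expect_equal(pcmDesign(pcm)$protComponentsUsed, 17L)
  # missing sequences are an error
  broken <- pcm
  broken$seq[3] <- ""
  expect_error(pcmCrossValidate(broken), "sequence absent")
})
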