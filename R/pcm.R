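# Proteochemometric pipeline: aligned protein sequences are encoded
# position-wise with the classic three-component amino-acid z-scales,
# reduced by PCA to a small set of orthogonal protein descriptors
# (17 by default), combined with ligand descriptors and ligand x protein
# cross-terms, and regressed on -log10 molar activity with NIPALS partial
# least squares. Predictive ability is estimated by k-fold (default
# 7-fold) cross-validation as the Pearson correlation between held-out
# predictions and observations; VIP scores rank descriptor importance.

#' The packaged amino-acid z-scale table
#'
#' Three principal-property descriptors per canonical residue
#' (z1 hydrophilicity, z2 bulk, z3 electronic character).
#' @return 20 x 3 numeric matrix with residue rownames.
#' @export
zScaleTable <- function() {
  path <- system.file("extdata", "zscales.tsv", package = "chemrdf")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "zscales.tsv")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("z1", "z2", "z3")])
  rownames(m) <- df$aa
  m
}

#' Read an aligned FASTA file of protein sequences
#'
#' Sequences must share one length (gaps '-' allowed); alignment is an
#' upstream input, no aligner is provided.
#' @param path FASTA file path.
#' @return named character vector of aligned sequences.
#' @export
readAlignedFasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aas))
  names(seqs) <- names(aas)
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences are not aligned: lengths ",
         paste(unique(nchar(seqs)), collapse = ", "))
  seqs
}

#' Encode aligned sequences with z-scales
#'
#' Each alignment position contributes three columns (z1, z2, z3) of the
#' residue at that position, ordered position-major. A gap takes the
#' position-wise mean of the non-gap residues' z-values (imputation); a
#' position that is gap in every sequence yields three all-zero columns
#' and is flagged in the \code{allGapPositions} attribute for dropping.
#'
#' @param sequences character vector of equal-length aligned sequences
#'   over the 20 residues plus '-'.
#' @param table z-scale matrix as from \code{\link{zScaleTable}}.
#' @return n x (3L) numeric matrix with an \code{allGapPositions}
#'   attribute.
#' @export
encodeSequences <- function(sequences, table = zScaleTable()) {
  stopifnot(length(sequences) >= 1L)
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must share one aligned length")
  chars <- do.call(rbind, strsplit(sequences, ""))
  bad <- !(chars %in% c(rownames(table), "-"))
  dim(bad) <- dim(chars)
  if (any(bad)) {
    ix <- which(bad, arr.ind = TRUE)[1, ]
    stop("unknown residue '", chars[bad][1], "' in sequence ", ix[1],
         " at position ", ix[2])
  }
  n <- length(sequences)
  out <- matrix(0, n, 3L * L)
  colnames(out) <- paste0("p", rep(seq_len(L), each = 3L), "_",
                          rep(c("z1", "z2", "z3"), L))
  allGap <- logical(L)
  for (j in seq_len(L)) {
    col <- chars[, j]
    gap <- col == "-"
    block <- matrix(0, n, 3L)
    if (all(gap)) {
      allGap[j] <- TRUE
    } else {
      block[!gap, ] <- table[col[!gap], , drop = FALSE]
      if (any(gap))
        block[gap, ] <- matrix(colMeans(table[col[!gap], , drop = FALSE]),
                               sum(gap), 3L, byrow = TRUE)
    }
    out[, 3L * (j - 1L) + 1:3] <- block
  }
  attr(out, "allGapPositions") <- which(allGap)
  out
}

#' Column-centered principal component analysis
#'
#' Zero-variance columns are dropped before decomposition; requesting more
#' components than \code{min(n - 1, q)} afterwards is an error.
#'
#' @param M numeric matrix (n x q).
#' @param k number of components to extract.
#' @return list: \code{scores} (n x k, mutually orthogonal),
#'   \code{loadings} (q' x k over the kept columns), \code{explained}
#'   (nonincreasing variance per component), \code{center} (column means),
#'   \code{kept} (indices of non-constant columns).
#' @export
pcaReduce <- function(M, k) {
  stopifnot(is.matrix(M), nrow(M) >= 2L)
  sds <- apply(M, 2, stats::sd)
  kept <- which(sds > 0)
  if (!length(kept)) stop("all columns are constant")
  Mk <- M[, kept, drop = FALSE]
  kmax <- min(nrow(M) - 1L, length(kept))
  if (k > kmax)
    stop("k = ", k, " exceeds the available rank bound ", kmax)
  pc <- stats::prcomp(Mk, center = TRUE, scale. = FALSE)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = pc$sdev[seq_len(k)]^2,
       center = pc$center, kept = kept)
}

#' Ligand x protein cross-terms
#'
#' Column (a, b) is the elementwise product of ligand column a and protein
#' column b, ordered ligand-major. Scaling is left to the caller (the
#' modeling pipeline centers and unit-scales each cross-term column).
#'
#' @param XL n x p ligand block.
#' @param XP n x k protein block.
#' @return n x (p * k) matrix.
#' @export
crossTerms <- function(XL, XP) {
  stopifnot(nrow(XL) == nrow(XP))
  p <- ncol(XL); k <- ncol(XP)
  out <- matrix(0, nrow(XL), p * k)
  cn <- character(p * k)
  for (a in seq_len(p)) for (b in seq_len(k)) {
    j <- (a - 1L) * k + b
    out[, j] <- XL[, a] * XP[, b]
    cn[j] <- paste0(colnames(XL)[a] %||% paste0("L", a), "x",
                    colnames(XP)[b] %||% paste0("P", b))
  }
  colnames(out) <- cn
  out
}

#' Fit a PLS1 regression by NIPALS
#'
#' Sequentially extracts components maximizing covariance with the
#' response, deflating X after each; stops early (with a warning) when the
#' residual covariance vanishes. Centering is always applied; unit-variance
#' scaling of X and y is optional and recorded in the model.
#'
#' @param X n x m predictor matrix.
#' @param y length-n response.
#' @param nComponents components requested.
#' @param scale autoscale X and y before fitting (default TRUE).
#' @return object of class \code{plsModel}: weights W, loadings P, scores
#'   T, y-loadings q, coefficient vector (raw-X scale), centering/scaling
#'   constants and the per-component explained covariance.
#' @export
plsFit <- function(X, y, nComponents, scale = TRUE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nComponents >= 1L)
  xc <- colMeans(X)
  xs <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  xs[xs == 0] <- 1
  yc <- mean(y)
  ys <- if (scale) stats::sd(y) else 1
  if (ys == 0) ys <- 1
  E <- sweep(sweep(X, 2, xc), 2, xs, "/")
  f <- (y - yc) / ys
  m <- ncol(X)
  W <- P <- matrix(0, m, 0)
  Tm <- matrix(0, nrow(X), 0)
  q <- numeric(0)
  for (h in seq_len(nComponents)) {
    wv <- drop(crossprod(E, f))
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) {
      warning("covariance exhausted after ", h - 1L,
              " components; returning fewer than requested")
      break
    }
    wv <- wv / nw
    tv <- drop(E %*% wv)
    tt <- sum(tv^2)
    if (tt < 1e-24) {
      warning("degenerate score vector at component ", h)
      break
    }
    pv <- drop(crossprod(E, tv)) / tt
    qv <- sum(f * tv) / tt
    E <- E - tcrossprod(tv, pv)
    f <- f - tv * qv
    W <- cbind(W, wv); P <- cbind(P, pv); Tm <- cbind(Tm, tv)
    q <- c(q, qv)
  }
  if (!ncol(W)) stop("no PLS component could be extracted (zero covariance)")
  # coefficients on the scaled X block, then fold the scaling in
  Bstar <- W %*% solve(crossprod(P, W), q)
  coef <- drop(Bstar) / xs * ys
  structure(list(nComponents = ncol(W), weights = W, loadings = P,
                 scores = Tm, yLoadings = q, coefficients = coef,
                 intercept = yc - sum(xc * coef),
                 xCenter = xc, xScale = xs, yCenter = yc, yScale = ys,
                 columnNames = colnames(X)),
            class = "plsModel")
}

#' @export
print.plsModel <- function(x, ...) {
  cat("NIPALS PLS1 model:", x$nComponents, "components over",
      length(x$coefficients), "predictors\n")
  invisible(x)
}

#' Predict from a fitted PLS model
#' @param object a \code{plsModel}.
#' @param newdata matrix with the training column count.
#' @param ... unused.
#' @export
predict.plsModel <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$coefficients))
  drop(newdata %*% object$coefficients) + object$intercept
}

#' VIP (variable importance in projection) scores
#'
#' Standard VIP: the mean square over columns equals one; higher scores
#' mark columns that carry the covariance the components exploited.
#' @param model a \code{plsModel}.
#' @return numeric vector, one score per predictor column.
#' @export
vipScores <- function(model) {
  W <- model$weights
  ssy <- model$yLoadings^2 * colSums(model$scores^2)
  m <- nrow(W)
  vip <- sqrt(m * drop(W^2 %*% ssy) / sum(ssy))
  names(vip) <- model$columnNames
  vip
}

#' Rank predictor columns by VIP score
#'
#' @param model a \code{plsModel}.
#' @param metadata optional data.frame (one row per column) carried along.
#' @return data.frame: column, vip, rank; sorted by descending VIP, ties
#'   broken by column order.
#' @export
importanceRanking <- function(model, metadata = NULL) {
  vip <- vipScores(model)
  ord <- order(-vip, seq_along(vip))
  out <- data.frame(column = if (!is.null(names(vip))) names(vip)[ord]
                             else ord,
                    vip = vip[ord], rank = seq_along(vip),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(metadata)) out <- cbind(out, metadata[ord, , drop = FALSE])
  out
}

# choose the component count minimizing cross-validated PRESS on 1..grid
selectNComponents <- function(X, y, grid = 1:10, k = 5L, seed = 1L) {
  folds <- makeFolds(length(y), min(k, length(y)), seed)
  grid <- grid[grid <= min(dim(X)) - 1L | grid == 1L]
  press <- numeric(length(grid))
  for (fi in seq_along(grid)) {
    err <- 0
    for (fold in sort(unique(folds))) {
      test <- folds == fold
      fit <- tryCatch(
        suppressWarnings(plsFit(X[!test, , drop = FALSE], y[!test],
                                grid[fi])),
        error = function(e) NULL)
      if (is.null(fit)) { err <- Inf; break }
      err <- err + sum((y[test] - predict(fit, X[test, , drop = FALSE]))^2)
    }
    press[fi] <- err
  }
  grid[which.min(press)]
}

#' Assemble the proteochemometric design matrix
#'
#' X = [autoscaled ligand descriptors | protein PCA scores | autoscaled
#' ligand x protein cross-terms]; y = -log10 molar activity (values in
#' nM). Protein PCA runs over the distinct sequences' autoscaled
#' position-wise z-scale encoding, clamped to the available rank with a
#' warning when fewer than \code{protComponents} are supported.
#'
#' @param dataset a \code{pcmDataset} (columns smiles, val, seq at least).
#' @param descriptorIds ligand descriptor ids.
#' @param protComponents protein principal components (default 17).
#' @return list X, y, and column metadata (block label per column).
#' @export
pcmDesign <- function(dataset, descriptorIds = qsarDescriptorIds(),
                      protComponents = 17L) {
  stopifnot(nrow(dataset) >= 2L)
  if (any(is.na(dataset$seq) | !nzchar(dataset$seq)))
    stop("protein sequence absent for row(s) ",
         paste(utils::head(which(is.na(dataset$seq) | !nzchar(dataset$seq))),
               collapse = ", "))
  uniqSmiles <- unique(dataset$smiles)
  dl <- descriptorMatrix(lapply(uniqSmiles, parseSmiles), descriptorIds)$matrix
  XLu <- dl[match(dataset$smiles, uniqSmiles), , drop = FALSE]
  sds <- apply(XLu, 2, stats::sd)
  XLu <- XLu[, sds > 0, drop = FALSE]
  XL <- scale(XLu)
  colnames(XL) <- colnames(XLu)

  uniqSeq <- unique(dataset$seq)
  Z <- encodeSequences(uniqSeq)
  zsd <- apply(Z, 2, stats::sd)
  Zs <- Z[, zsd > 0, drop = FALSE]
  if (!ncol(Zs)) stop("protein encoding is constant across sequences")
  Zs <- scale(Zs)
  kmax <- min(nrow(Zs) - 1L, ncol(Zs))
  k <- protComponents
  if (k > kmax) {
    warning("protein components clamped from ", k, " to the rank bound ",
            kmax)
    k <- kmax
  }
  pca <- pcaReduce(Zs, k)
  XPu <- pca$scores[match(dataset$seq, uniqSeq), , drop = FALSE]
  colnames(XPu) <- paste0("protPC", seq_len(ncol(XPu)))
  XP <- scale(XPu)
  psd <- attr(XP, "scaled:scale")
  XP[, psd == 0] <- 0
  colnames(XP) <- colnames(XPu)

  XC <- crossTerms(XL, XP)
  XCs <- scale(XC)
  XCs[, attr(XCs, "scaled:scale") == 0] <- 0
  colnames(XCs) <- colnames(XC)

  X <- cbind(XL, XP, XCs)
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  y <- -log10(dataset$val * 1e-9)
  meta <- data.frame(column = colnames(X),
                     block = c(rep("ligand", ncol(XL)),
                               rep("protein", ncol(XP)),
                               rep("cross", ncol(XCs)))[keep],
                     stringsAsFactors = FALSE)
  list(X = X, y = y, metadata = meta, protComponentsUsed = k)
}

#' Cross-validated proteochemometric model
#'
#' Builds the PCM design matrix, draws seeded folds, fits a NIPALS PLS
#' model per fold and predicts its held-out rows. The headline statistic
#' is the Pearson correlation between held-out predictions and observed
#' -log10 activities.
#'
#' @param dataset a \code{pcmDataset}.
#' @param descriptorIds ligand descriptor ids.
#' @param k folds (default 7).
#' @param nComponents PLS components; when NULL, chosen once on the full
#'   data as the 1..10 grid value minimizing 5-fold PRESS.
#' @param protComponents protein principal components (default 17, clamped
#'   to rank).
#' @param seed fold (and component-selection) seed.
#' @return list: predictions (data.frame row, fold, observed, predicted),
#'   pearsonR, nComponents, foldAssignment, model (PLS fit on all data)
#'   and the column metadata.
#' @export
pcmCrossValidate <- function(dataset, descriptorIds = qsarDescriptorIds(),
                             k = 7L, nComponents = NULL,
                             protComponents = 17L, seed = 1L) {
  stopifnot(nrow(dataset) >= k, k >= 2L)
  design <- pcmDesign(dataset, descriptorIds, protComponents)
  X <- design$X; y <- design$y
  if (is.null(nComponents))
    nComponents <- selectNComponents(X, y, seed = seed)
  folds <- makeFolds(length(y), k, seed)
  pred <- numeric(length(y))
  for (fold in sort(unique(folds))) {
    test <- folds == fold
    fit <- suppressWarnings(plsFit(X[!test, , drop = FALSE], y[!test],
                                   nComponents))
    pred[test] <- predict(fit, X[test, , drop = FALSE])
  }
  full <- suppressWarnings(plsFit(X, y, nComponents))
  list(predictions = data.frame(row = seq_along(y), fold = folds,
                                observed = y, predicted = pred),
       pearsonR = stats::cor(y, pred),
       nComponents = nComponents,
       foldAssignment = folds,
       model = full,
       metadata = design$metadata)
}
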