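#' @name association-module
#' @title Matrix association: PCoA, Mantel, partial Mantel, partial RDA
#'
#' @description
#' The association layer asks how much of the structure in one distance
#' matrix is explained by another while controlling for a third. Distance
#' matrices are first reduced to principal coordinates (axes explaining
#' more than 10 percent of the positive-eigenvalue variance); redundancy
#' analysis then regresses the response axes on the explanatory axes
#' (both residualized on the conditioning axes when present), summarised
#' by the Ezekiel-adjusted R-squared with a permutation p-value. Mantel
#' tests correlate the distance matrices directly, with the partial
#' variant correlating residuals.
NULL

#' Principal coordinates analysis
#'
#' Eigendecomposition of the Gower-centered squared distances. Negative
#' eigenvalues are excluded from the variance denominator; coordinates
#' are returned for positive axes only.
#'
#' @param d a \linkS4class{DistMat}.
#' @return a \linkS4class{PcoaResult}.
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop("need >= 3 units")
  C <- gowerCenter(m)
  e <- eigen(C, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  if (!length(pos)) stop("no positive eigenvalues: distances carry no metric structure")
  lam <- e$values[pos]
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam), length(pos))
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("Axis", seq_along(pos))
  new("PcoaResult", coords = coords, eigenvalues = e$values,
      percentVar = 100 * lam / sum(lam))
}

#' @describeIn pcoa coordinates of the axes explaining more than
#'   \code{minPercent} of the positive-eigenvalue variance.
#' @param p a \linkS4class{PcoaResult}.
#' @param minPercent axis retention threshold (default 10).
#' @export
pcoaAxes <- function(p, minPercent = 10) {
  keep <- which(p@percentVar > minPercent)
  if (!length(keep)) keep <- 1L  # always retain the leading axis
  p@coords[, keep, drop = FALSE]
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the upper-triangle entries, with significance
#' from simultaneous row/column permutations of one matrix.
#'
#' @param a,b \linkS4class{DistMat} objects sharing labels.
#' @param nPerm permutations (default 999).
#' @param seed RNG seed.
#' @param alternative \code{"two.sided"} (default) or \code{"greater"}.
#' @return an \linkS4class{AssociationResult}.
#' @export
mantel <- function(a, b, nPerm = 999, seed = 1,
                   alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  al <- dmAlign(a, b)
  ma <- as.matrix(al[[1]]); mb <- as.matrix(al[[2]])
  if (nrow(ma) < 4) stop("need >= 4 units")
  va <- upperTri(ma); vb <- upperTri(mb)
  if (sd(va) == 0 || sd(vb) == 0) stop("constant distance matrix: correlation undefined")
  rObs <- cor(va, vb)
  n <- nrow(ma)
  cnt <- 0
  withSeed(seed, {
    for (i in seq_len(nPerm)) {
      p <- sample.int(n)
      rp <- cor(va, upperTri(mb[p, p]))
      if (if (alternative == "two.sided") abs(rp) >= abs(rObs) else rp >= rObs) {
        cnt <- cnt + 1
      }
    }
  })
  new("AssociationResult", statistic = rObs, statName = "mantel_r",
      p = if (nPerm > 0) (cnt + 1) / (nPerm + 1) else NA_real_,
      nPerm = as.numeric(nPerm), conditioning = "", extra = list())
}

# residualize the upper triangle of m on the upper triangle of z,
# returning a full symmetric residual matrix (zero diagonal)
residualMatrix <- function(m, z) {
  vm <- upperTri(m); vz <- upperTri(z)
  if (sd(vz) == 0) stop("constant conditioning matrix")
  res <- residuals(lm(vm ~ vz))
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  out[upper.tri(out)] <- res
  out <- out + t(out)
  out
}

#' Partial Mantel test
#'
#' Correlates the residuals of \code{a ~ c} and \code{b ~ c} (upper
#' triangles); significance from row/column permutations of the
#' residualized response.
#'
#' @param a,b,c \linkS4class{DistMat} objects sharing labels; \code{c}
#'   is the conditioning matrix.
#' @inheritParams mantel
#' @return an \linkS4class{AssociationResult}.
#' @export
partialMantel <- function(a, b, c, nPerm = 999, seed = 1,
                          alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  al <- dmAlign(a, b, c)
  ma <- as.matrix(al[[1]]); mb <- as.matrix(al[[2]]); mc <- as.matrix(al[[3]])
  if (nrow(ma) < 4) stop("need >= 4 units")
  if (sd(upperTri(ma)) == 0 || sd(upperTri(mb)) == 0) {
    stop("constant distance matrix: correlation undefined")
  }
  ra <- residualMatrix(ma, mc)
  rb <- residualMatrix(mb, mc)
  va <- upperTri(ra); vb <- upperTri(rb)
  if (sd(va) < 1e-14) stop("zero residual variance in the response after conditioning")
  if (sd(vb) < 1e-14) {
    # the conditioning matrix explains the explanatory one exactly:
    # no partial association remains
    return(new("AssociationResult", statistic = 0,
               statName = "partial_mantel_r", p = 1,
               nPerm = as.numeric(nPerm), conditioning = "third matrix",
               extra = list()))
  }
  rObs <- cor(va, vb)
  n <- nrow(ma)
  cnt <- 0
  withSeed(seed, {
    for (i in seq_len(nPerm)) {
      p <- sample.int(n)
      rp <- cor(upperTri(ra[p, p]), vb)
      if (if (alternative == "two.sided") abs(rp) >= abs(rObs) else rp >= rObs) {
        cnt <- cnt + 1
      }
    }
  })
  new("AssociationResult", statistic = rObs, statName = "partial_mantel_r",
      p = if (nPerm > 0) (cnt + 1) / (nPerm + 1) else NA_real_,
      nPerm = as.numeric(nPerm), conditioning = "third matrix", extra = list())
}

fitRda <- function(Y, X) {
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  qx <- qr(Xc)
  fitted <- qr.fitted(qx, Yc)
  sum(fitted^2) / sum(Yc^2)
}

residOn <- function(M, Z) {
  Zc <- cbind(1, Z)
  M - Zc %*% qr.coef(qr(Zc), M)
}

#' Redundancy analysis between distance matrices, optionally partial
#'
#' Both matrices (and the conditioning matrix, when given) are reduced
#' to principal-coordinate axes explaining more than \code{minPercent}
#' of the positive variance. With conditioning, response and explanatory
#' axes are residualized on the conditioning axes first. The statistic
#' is the Ezekiel-adjusted R-squared
#' \code{1 - (1 - R2) (n - 1) / (n - m - 1)} with m explanatory axes
#' (option \code{adjust = "permutation"} uses the permutation-based
#' estimator \code{1 - (1 - R2) / (1 - mean(R2_perm))} instead);
#' significance from permuting the rows of the explanatory axes.
#'
#' @param response,explanatory \linkS4class{DistMat} objects.
#' @param conditioning optional \linkS4class{DistMat}.
#' @param nPerm permutations (default 999).
#' @param seed RNG seed.
#' @param minPercent PCoA axis retention threshold (default 10).
#' @param adjust \code{"ezekiel"} (default) or \code{"permutation"}.
#' @return an \linkS4class{AssociationResult}; \code{extra} holds the
#'   unadjusted R2 and axis counts.
#' @export
partialRda <- function(response, explanatory, conditioning = NULL,
                       nPerm = 999, seed = 1, minPercent = 10,
                       adjust = c("ezekiel", "permutation")) {
  adjust <- match.arg(adjust)
  mats <- if (is.null(conditioning)) dmAlign(response, explanatory) else
    dmAlign(response, explanatory, conditioning)
  Y <- pcoaAxes(pcoa(mats[[1]]), minPercent)
  X <- pcoaAxes(pcoa(mats[[2]]), minPercent)
  Z <- if (is.null(conditioning)) NULL else pcoaAxes(pcoa(mats[[3]]), minPercent)
  n <- nrow(Y)
  m <- ncol(X)
  if (n - m - 1 <= 0) stop("overparameterized: n - m - 1 <= 0")
  if (!is.null(Z)) {
    Y <- residOn(Y, Z)
    X <- residOn(X, Z)
  }
  r2 <- fitRda(Y, X)
  r2perm <- numeric(0)
  cnt <- 0
  withSeed(seed, {
    if (nPerm > 0) {
      r2perm <- vapply(seq_len(nPerm), function(i) {
        fitRda(Y, X[sample.int(n), , drop = FALSE])
      }, 0)
      cnt <- sum(r2perm >= r2)
    }
  })
  adjR2 <- if (adjust == "ezekiel") {
    1 - (1 - r2) * (n - 1) / (n - m - 1)
  } else {
    if (!length(r2perm)) stop("permutation-based adjustment requires nPerm > 0")
    1 - (1 - r2) / (1 - mean(r2perm))
  }
  new("AssociationResult", statistic = adjR2, statName = "rda_adj_r2",
      p = if (nPerm > 0) (cnt + 1) / (nPerm + 1) else NA_real_,
      nPerm = as.numeric(nPerm),
      conditioning = if (is.null(conditioning)) "" else "conditioning matrix",
      extra = list(r2 = r2, nResponseAxes = ncol(Y), nExplanatoryAxes = m))
}

#' Grid of partial associations, heat-map ready
#'
#' For every explanatory process and every other process as control,
#' computes the partial RDA adjusted R-squared and the partial Mantel r
#' of the response against the explanatory, controlling for the control:
#' the cells of the usual response-by-(predictor | control) heat map.
#'
#' @param response \linkS4class{DistMat} (e.g. a musical Phi_ST matrix).
#' @param predictors named list of \linkS4class{DistMat} objects
#'   (e.g. Genes, Language, Geography).
#' @param nPerm permutations per test.
#' @param seed RNG seed.
#' @param responseName label for the output rows.
#' @return tidy data.frame: response, predictor, conditioning, adj_r2,
#'   r2, rda_p, mantel_r, mantel_p.
#' @export
associationGrid <- function(response, predictors, nPerm = 999, seed = 1,
                            responseName = "response") {
  stopifnot(length(predictors) >= 2, !is.null(names(predictors)))
  rows <- list()
  k <- 0
  for (pn in names(predictors)) {
    for (cn in setdiff(names(predictors), pn)) {
      k <- k + 1
      rda <- partialRda(response, predictors[[pn]], predictors[[cn]],
                        nPerm = nPerm, seed = splitSeed(seed, k))
      pm <- partialMantel(response, predictors[[pn]], predictors[[cn]],
                          nPerm = nPerm, seed = splitSeed(seed, 1000 + k))
      rows[[k]] <- data.frame(response = responseName, predictor = pn,
                              conditioning = cn,
                              adj_r2 = rda@statistic, r2 = rda@extra$r2,
                              rda_p = rda@p, mantel_r = pm@statistic,
                              mantel_p = pm@p)
    }
  }
  do.call(rbind, rows)
}
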