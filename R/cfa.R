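#' @name latentModel
#' @title Latent measurement model for dimensions of song style
#'
#' @description
#' Song-style indicators are modelled as continuous reflections of a
#' small number of correlated latent dimensions (Articulation, Tension,
#' Ornamentation, Rhythm, Dynamics) by maximum-likelihood confirmatory
#' factor analysis. The model is identified by fixing latent variances to
#' one, so the reported solution is completely standardized. Fit is
#' summarised by RMSEA (with a 90\% noncentral-chi-square CI), SRMR, and
#' CFI against the independence baseline.
NULL

#' Read a latent model specification from YAML
#'
#' The specification maps indicators to latents (each indicator loads on
#' exactly one latent) and lists extra residual covariances between
#' indicator pairs not explained by the latents.
#'
#' @param path YAML file with blocks \code{latents} (latent ->
#'   indicator list) and optional \code{residual_covariances} (list of
#'   2-element indicator pairs).
#' @return list with elements \code{latents}, \code{residCov}.
#' @export
readLatentSpec <- function(path) {
  raw <- yaml::read_yaml(path)
  spec <- list(latents = lapply(raw$latents, as.character),
               residCov = lapply(raw$residual_covariances %||% list(), as.character))
  validateLatentSpec(spec)
  spec
}

#' @describeIn readLatentSpec the five-dimension model shipped with the
#'   package.
#' @export
defaultLatentSpec <- function() {
  readLatentSpec(system.file("extdata", "latent_model.yaml", package = "songlines"))
}

#' @describeIn readLatentSpec validate a latent model specification.
#' @param spec latent model spec list.
#' @export
validateLatentSpec <- function(spec) {
  inds <- unlist(spec$latents, use.names = FALSE)
  if (anyDuplicated(inds)) {
    stop("indicators mapped to more than one latent: ",
         paste(unique(inds[duplicated(inds)]), collapse = ", "))
  }
  for (rc in spec$residCov) {
    if (length(rc) != 2 || rc[1] == rc[2]) {
      stop("residual covariances must be pairs of distinct indicators")
    }
    if (!all(rc %in% inds)) stop("residual covariance names unknown indicator: ",
                                 paste(setdiff(rc, inds), collapse = ", "))
  }
  invisible(spec)
}

# --- internal model machinery -------------------------------------------

# Index bookkeeping for the free parameter vector:
# loadings (non-singleton latents), log residual variances (ditto),
# latent-correlation Cholesky rows (normalized vectors), residual covs.
cfaLayout <- function(spec, indicators) {
  latents <- names(spec$latents)
  m <- length(latents)
  singleton <- vapply(spec$latents, function(x) length(x) == 1, TRUE)
  loadRows <- integer(0); loadCols <- integer(0)
  for (j in seq_len(m)) {
    if (singleton[j]) next
    for (ind in spec$latents[[j]]) {
      loadRows <- c(loadRows, match(ind, indicators))
      loadCols <- c(loadCols, j)
    }
  }
  freeTheta <- setdiff(seq_along(indicators),
                       match(unlist(spec$latents[singleton]), indicators))
  nPhi <- if (m > 1) sum(2:m) else 0L  # raw packing slots
  rcIdx <- lapply(spec$residCov, function(rc) match(rc, indicators))
  # each normalized Cholesky row j spends j slots on j - 1 effective
  # parameters, so the latent correlations contribute m(m-1)/2 to df
  list(latents = latents, m = m, p = length(indicators), singleton = singleton,
       loadRows = loadRows, loadCols = loadCols, freeTheta = freeTheta,
       nPhi = nPhi, rcIdx = rcIdx,
       nRaw = length(loadRows) + length(freeTheta) + nPhi + length(rcIdx),
       nFree = length(loadRows) + length(freeTheta) + m * (m - 1) / 2 +
         length(rcIdx))
}

cfaUnpack <- function(th, lay, spec, indicators) {
  p <- lay$p; m <- lay$m
  Lambda <- matrix(0, p, m, dimnames = list(indicators, lay$latents))
  k <- 0L
  if (length(lay$loadRows)) {
    Lambda[cbind(lay$loadRows, lay$loadCols)] <- th[seq_along(lay$loadRows)]
    k <- length(lay$loadRows)
  }
  for (j in which(lay$singleton)) {
    Lambda[match(spec$latents[[j]], indicators), j] <- 1
  }
  theta <- rep(1e-6, p)
  theta[lay$freeTheta] <- exp(th[k + seq_along(lay$freeTheta)])
  k <- k + length(lay$freeTheta)
  Phi <- diag(m)
  if (m > 1) {
    L <- matrix(0, m, m); L[1, 1] <- 1
    for (j in 2:m) {
      w <- th[k + seq_len(j)]
      k <- k + j
      nrm <- sqrt(sum(w^2))
      if (nrm < 1e-12) w <- c(rep(0, j - 1), 1) else w <- w / nrm
      L[j, seq_len(j)] <- w
    }
    Phi <- L %*% t(L)
  }
  Theta <- diag(theta, p)
  for (i in seq_along(lay$rcIdx)) {
    idx <- lay$rcIdx[[i]]
    Theta[idx[1], idx[2]] <- Theta[idx[2], idx[1]] <- th[k + i]
  }
  dimnames(Theta) <- list(indicators, indicators)
  dimnames(Phi) <- list(lay$latents, lay$latents)
  list(Lambda = Lambda, Phi = Phi, Theta = Theta)
}

cfaImplied <- function(par) par$Lambda %*% par$Phi %*% t(par$Lambda) + par$Theta

fmlValue <- function(Sigma, S, logdetS) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdetSig <- 2 * sum(log(diag(ch)))
  Sinv <- chol2inv(ch)
  f <- logdetSig - logdetS + sum(Sinv * S) - nrow(S)
  if (!is.finite(f)) 1e10 else f
}

cfaStart <- function(lay, jitter = 0) {
  th <- numeric(lay$nRaw)
  k <- 0L
  if (length(lay$loadRows)) {
    th[seq_along(lay$loadRows)] <- 0.7
    k <- length(lay$loadRows)
  }
  th[k + seq_along(lay$freeTheta)] <- log(0.5)
  k <- k + length(lay$freeTheta)
  if (lay$nPhi > 0) {
    for (j in 2:lay$m) {
      th[k + j] <- 1  # identity start: w_j = e_j
      k <- k + j
    }
  }
  # residual covariances start at 0 (already)
  if (jitter > 0) th <- th + rnorm(length(th), 0, jitter)
  th
}

# --- fitting -------------------------------------------------------------

#' Fit the latent measurement model by maximum likelihood
#'
#' Minimises the ML discrepancy
#' \code{F = log det(Sigma) - log det(S) + tr(S Sigma^-1) - p} over
#' loadings, latent correlations (via a correlation-Cholesky
#' parameterisation that keeps the latent correlation matrix positive
#' definite with unit diagonal), log-parameterised residual variances,
#' and any declared residual covariances. The model is fitted to the
#' Pearson correlation matrix of the indicators, so the reported solution
#' is completely standardized. Singleton latents (one indicator) are
#' passthrough: loading fixed at 1, residual variance at ~0.
#'
#' @param data standardized SongTable (numeric features) or a song x
#'   indicator numeric matrix.
#' @param spec latent model specification (\code{\link{readLatentSpec}}).
#' @param restarts number of seeded random restarts around the default
#'   start (default 10).
#' @param seed integer seed for the restarts.
#' @param tol convergence tolerance on the discrepancy (default 1e-8).
#' @return a \linkS4class{CfaFit}; non-convergence is flagged, not an
#'   error.
#' @export
fitCfa <- function(data, spec, restarts = 10, seed = 1, tol = 1e-8) {
  validateLatentSpec(spec)
  if (is.data.frame(data)) {
    validateSongTable(data)
    X <- as.matrix(data[, featureCols(data), drop = FALSE])
  } else X <- as.matrix(data)
  inds <- unlist(spec$latents, use.names = FALSE)
  missing <- setdiff(inds, colnames(X))
  if (length(missing)) stop("indicators absent from data: ", paste(missing, collapse = ", "))
  X <- X[, inds, drop = FALSE]
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl <= 0)) stop("constant indicator(s): ",
                          paste(inds[scl <= 0], collapse = ", "))
  S <- cor(X)
  fit <- fitCfaCov(S, n, spec, restarts = restarts, seed = seed, tol = tol)
  fit@center <- ctr
  fit@scale <- scl
  fit
}

#' @describeIn fitCfa fit directly from a sample covariance/correlation
#'   matrix \code{S} and sample size \code{n} (the matrix is standardized
#'   to a correlation internally).
#' @param S sample covariance or correlation matrix with indicator
#'   dimnames.
#' @param n sample size.
#' @export
fitCfaCov <- function(S, n, spec, restarts = 10, seed = 1, tol = 1e-8) {
  validateLatentSpec(spec)
  inds <- unlist(spec$latents, use.names = FALSE)
  S <- as.matrix(S)[inds, inds]
  Dh <- diag(1 / sqrt(diag(S)), nrow(S))
  S <- Dh %*% S %*% Dh
  dimnames(S) <- list(inds, inds)
  chS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(chS)) stop("sample covariance matrix is not positive definite")
  logdetS <- 2 * sum(log(diag(chS)))
  lay <- cfaLayout(spec, inds)
  bad <- vapply(spec$latents, function(x) length(x) == 0, TRUE)
  if (any(bad)) stop("latents with no indicators: ",
                     paste(names(spec$latents)[bad], collapse = ", "))
  if (n <= lay$nFree) stop("sample size (", n, ") must exceed free parameters (", lay$nFree, ")")
  # The normalized-row Cholesky parameterisation of the latent
  # correlations is scale-invariant along each row vector; a tiny
  # penalty anchoring each row norm at 1 removes the flat ridge without
  # moving the optimum (the penalty is exactly 0 there).
  phiNormPenalty <- function(th) {
    if (lay$nPhi == 0) return(0)
    k <- length(lay$loadRows) + length(lay$freeTheta)
    pen <- 0
    for (j in 2:lay$m) {
      w <- th[k + seq_len(j)]
      k <- k + j
      pen <- pen + (sqrt(sum(w^2)) - 1)^2
    }
    pen
  }
  obj <- function(th) {
    fmlValue(cfaImplied(cfaUnpack(th, lay, spec, inds)), S, logdetS) +
      1e-4 * phiNormPenalty(th)
  }
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(max(1, restarts))) {
      th0 <- cfaStart(lay, jitter = if (r == 1) 0 else 0.15)
      res <- tryCatch(
        optim(th0, obj, method = "BFGS",
              control = list(maxit = 3000, reltol = tol)),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
    }
  })
  if (is.null(best)) stop("optimization failed to produce any result")
  conv <- best$value < 1e9 && best$convergence == 0
  par <- cfaUnpack(best$par, lay, spec, inds)
  Sigma <- cfaImplied(par)
  # completely standardized solution: rescale by implied indicator sds
  dS <- sqrt(diag(Sigma))
  LambdaStd <- par$Lambda / dS
  ThetaStd <- par$Theta / outer(dS, dS)
  # sign convention: majority-positive loadings per latent
  for (j in seq_len(ncol(LambdaStd))) {
    nz <- LambdaStd[, j][par$Lambda[, j] != 0]
    if (length(nz) && sum(nz) < 0) {
      LambdaStd[, j] <- -LambdaStd[, j]
      par$Phi[j, ] <- -par$Phi[j, ]
      par$Phi[, j] <- -par$Phi[, j]
      diag(par$Phi) <- 1
    }
  }
  fml <- fmlValue(Sigma, S, logdetS)  # penalty-free discrepancy at the optimum
  df <- lay$p * (lay$p + 1) / 2 - lay$nFree
  chisq <- (n - 1) * fml
  fb <- -logdetS  # independence baseline on a correlation matrix
  dfb <- lay$p * (lay$p - 1) / 2
  chisqB <- (n - 1) * fb
  idx <- fitIndices(chisq, df, n, chisqB, dfb, sampleCov = S, impliedCov = Sigma)
  new("CfaFit", loadings = LambdaStd, latentCor = par$Phi, residuals = ThetaStd,
      fml = fml, chisq = chisq, df = df, n = n,
      rmsea = idx$rmsea, rmseaCI = idx$rmsea.ci, srmr = idx$srmr, cfi = idx$cfi,
      converged = conv, sampleCov = S,
      center = setNames(rep(0, lay$p), inds), scale = setNames(rep(1, lay$p), inds))
}

#' Goodness-of-fit indices for a fitted latent model
#'
#' RMSEA (with 90\% CI by noncentral chi-square inversion), SRMR over
#' standardized residuals of the sample vs implied matrices, and CFI
#' against the independence baseline:
#' \itemize{
#' \item RMSEA = sqrt(max(chisq - df, 0) / (df (N - 1))),
#' \item CFI = 1 - max(chisq - df, 0) / max(chisqB - dfB, chisq - df, 0),
#' \item SRMR = root mean square of the lower-triangle (plus diagonal)
#'   standardized residuals.
#' }
#'
#' @param chisq,df,n model chi-square, degrees of freedom, sample size;
#'   \code{chisq} may also be a \linkS4class{CfaFit}, in which case all
#'   other arguments are taken from it and its stored baseline.
#' @param chisqBaseline,dfBaseline independence-model chi-square and df.
#' @param sampleCov,impliedCov optional matrices for SRMR (NULL skips it).
#' @return list with rmsea, rmsea.ci (90\%), srmr, cfi.
#' @export
fitIndices <- function(chisq, df, n, chisqBaseline, dfBaseline,
                       sampleCov = NULL, impliedCov = NULL) {
  if (is(chisq, "CfaFit")) {
    fit <- chisq
    p <- nrow(fit@loadings)
    fb <- -determinant(fit@sampleCov, logarithm = TRUE)$modulus[1]
    return(fitIndices(fit@chisq, fit@df, fit@n, (fit@n - 1) * fb, p * (p - 1) / 2,
                      sampleCov = fit@sampleCov,
                      impliedCov = fit@loadings %*% fit@latentCor %*% t(fit@loadings) +
                        fit@residuals))
  }
  if (df == 0) {
    warning("df = 0: RMSEA defined as 0")
    rmsea <- 0; ci <- c(0, 0)
  } else {
    rmsea <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
    ci <- rmseaCI(chisq, df, n)
  }
  num <- max(chisq - df, 0)
  den <- max(chisqBaseline - dfBaseline, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  srmr <- NA_real_
  if (!is.null(sampleCov) && !is.null(impliedCov)) {
    sS <- sqrt(diag(sampleCov)); sI <- sqrt(diag(impliedCov))
    rS <- sampleCov / outer(sS, sS)
    rI <- impliedCov / outer(sI, sI)
    res <- (rS - rI)[lower.tri(rS, diag = TRUE)]
    srmr <- sqrt(mean(res^2))
  }
  list(rmsea = rmsea, rmsea.ci = ci, srmr = srmr, cfi = cfi)
}

# 90% CI by inverting the noncentral chi-square distribution
rmseaCI <- function(chisq, df, n) {
  bound <- function(target) {
    f <- function(ncp) pchisq(chisq, df, ncp = ncp) - target
    if (f(0) < 0) return(0)  # even ncp = 0 leaves too little mass below chisq
    hi <- max(chisq * 2, df * 2, 10)
    while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
    uniroot(f, c(0, hi), tol = 1e-8)$root
  }
  lo <- bound(0.95)
  hi <- bound(0.05)
  sqrt(c(lo, hi) / (df * (n - 1)))
}

#' Per-song latent factor scores
#'
#' Regression-method scores: for each song with standardized indicator
#' vector z, eta = Phi Lambda' Sigma^-1 z, using the completely
#' standardized solution. Deterministic given the fit.
#'
#' @param fit a converged \linkS4class{CfaFit}.
#' @param data SongTable or matrix with the fitted indicators.
#' @return song x latent score matrix (with song labels when available).
#' @export
factorScores <- function(fit, data) {
  if (!fit@converged) warning("scoring a non-converged fit")
  if (is.data.frame(data)) {
    validateSongTable(data)
    X <- as.matrix(data[, featureCols(data), drop = FALSE])
    ids <- as.character(data$song)
  } else {
    X <- as.matrix(data)
    ids <- rownames(X)
  }
  inds <- rownames(fit@loadings)
  X <- X[, inds, drop = FALSE]
  Z <- sweep(sweep(X, 2, fit@center[inds]), 2, fit@scale[inds], "/")
  Sigma <- fit@loadings %*% fit@latentCor %*% t(fit@loadings) + fit@residuals
  ch <- tryCatch(chol(Sigma), error = function(e) stop("implied covariance is singular"))
  W <- fit@latentCor %*% t(fit@loadings) %*% chol2inv(ch)
  scores <- Z %*% t(W)
  colnames(scores) <- colnames(fit@loadings)
  rownames(scores) <- ids
  scores
}
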