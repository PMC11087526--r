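# A small two-latent model used throughout this file.
twoLatentSpec <- function(residCov = list()) {
  list(latents = list(L1 = c("a1", "a2", "a3"), L2 = c("b1", "b2", "b3")),
       residCov = residCov)
}

trueTwoLatent <- function(lam = c(0.8, 0.7, 0.6, 0.75, 0.65, 0.7), phi = 0.4) {
  inds <- c("a1", "a2", "a3", "b1", "b2", "b3")
  Lam <- matrix(0, 6, 2, dimnames = list(inds, c("L1", "L2")))
  Lam[1:3, 1] <- lam[1:3]; Lam[4:6, 2] <- lam[4:6]
  Phi <- matrix(c(1, phi, phi, 1), 2)
  Theta <- diag(1 - diag(Lam %*% Phi %*% t(Lam)))
  Sigma <- Lam %*% Phi %*% t(Lam) + Theta
  dimnames(Sigma) <- list(inds, inds)
  list(Lam = Lam, Phi = Phi, Theta = Theta, Sigma = Sigma, inds = inds)
}

simTwoLatent <- function(n, truth, seed) {
  withr::with_seed(seed, {
    Z <- matrix(rnorm(n * 2), n) %*% chol(truth$Phi)
    X <- Z %*% t(truth$Lam) +
      matrix(rnorm(n * 6), n) %*% diag(sqrt(diag(truth$Theta)))
    colnames(X) <- truth$inds
    list(X = X, Z = Z)
  })
}

test_that("exact-truth covariance yields a perfect fit", {
  tr <- trueTwoLatent()
  fit <- fitCfaCov(tr$Sigma, 500, twoLatentSpec(), restarts = 2, seed = 1)
  expect_true(fit@converged)
  expect_lt(fit@fml, 1e-7)
  expect_equal(fit@rmsea, 0)
  expect_equal(fit@cfi, 1)
  expect_lt(fit@srmr, 1e-3)
  expect_equal(fit@loadings[tr$Lam != 0], tr$Lam[tr$Lam != 0], tolerance = 1e-3)
  expect_equal(fit@latentCor[1, 2], 0.4, tolerance = 1e-3)
})

test_that("loadings and latent correlations are recovered from simulated songs", {
  tr <- trueTwoLatent()
  dat <- simTwoLatent(2000, tr, seed = 21)
  fit <- fitCfa(dat$X, twoLatentSpec(), restarts = 3, seed = 1)
  expect_true(fit@converged)
  expect_lt(max(abs(fit@loadings[tr$Lam != 0] - tr$Lam[tr$Lam != 0])), 0.05)
  expect_lt(abs(fit@latentCor[1, 2] - 0.4), 0.06)
  # implied covariance is symmetric PSD
  Sig <- fit@loadings %*% fit@latentCor %*% t(fit@loadings) + fit@residuals
  expect_equal(Sig, t(Sig))
  expect_gt(min(eigen(Sig, symmetric = TRUE)$values), 0)
  # df bookkeeping: 21 moments, 13 free parameters
  expect_equal(fit@df, 21 - 13)
})

test_that("fit indices follow their defining arithmetic", {
  # plug-in case: chisq = 200, df = 100, N = 101
  idx <- fitIndices(200, 100, 101, 1100, 120)
  expect_equal(idx$rmsea, sqrt(100 / (100 * 100)))
  expect_equal(idx$cfi, 1 - 100 / 980)
  # chi-square equal to df: exact-fit boundary
  expect_equal(fitIndices(100, 100, 101, 1100, 120)$rmsea, 0)
  # S = Sigma gives SRMR 0
  tr <- trueTwoLatent()
  expect_equal(fitIndices(0, 8, 500, 900, 15, sampleCov = tr$Sigma,
                          impliedCov = tr$Sigma)$srmr, 0)
  # df = 0 defines RMSEA as 0 with a warning
  expect_warning(i0 <- fitIndices(5, 0, 100, 50, 10), "df = 0")
  expect_equal(i0$rmsea, 0)
  # RMSEA CI brackets the point estimate
  ci <- fitIndices(200, 100, 101, 1100, 120)$rmsea.ci
  expect_lt(ci[1], 0.1)
  expect_gt(ci[2], 0.1)
})

test_that("regression factor scores are centered, deterministic, and track truth", {
  tr <- trueTwoLatent()
  dat <- simTwoLatent(1500, tr, seed = 5)
  fit <- fitCfa(dat$X, twoLatentSpec(), restarts = 2, seed = 1)
  sc <- factorScores(fit, dat$X)
  # indicator vector at the sample mean scores 0
  atMean <- matrix(fit@center, 1, dimnames = list("m", names(fit@center)))
  expect_equal(unname(factorScores(fit, atMean)), matrix(0, 1, 2),
               tolerance = 1e-12)
  expect_identical(sc, factorScores(fit, dat$X))
  expect_gt(cor(sc[, "L1"], dat$Z[, 1]), 0.8)
  expect_gt(cor(sc[, "L2"], dat$Z[, 2]), 0.8)
})

test_that("singleton latents pass the standardized indicator through", {
  spec <- list(latents = list(L1 = c("a1", "a2", "a3"), Solo = "s1"),
               residCov = list())
  withr::with_seed(9, {
    n <- 600
    z <- rnorm(n)
    X <- cbind(a1 = 0.8 * z + rnorm(n, 0, 0.6), a2 = 0.7 * z + rnorm(n, 0, 0.7),
               a3 = 0.6 * z + rnorm(n, 0, 0.8), s1 = rnorm(n))
  })
  fit <- fitCfa(X, spec, restarts = 2, seed = 1)
  sc <- factorScores(fit, X)
  zstd <- (X[, "s1"] - mean(X[, "s1"])) / sd(X[, "s1"])
  expect_equal(unname(sc[, "Solo"]), unname(zstd), tolerance = 1e-4)
})

test_that("the discrepancy is nonnegative and order-invariant, and extra parameters help", {
  tr <- trueTwoLatent()
  dat <- simTwoLatent(400, tr, seed = 31)
  fit <- fitCfa(dat$X, twoLatentSpec(), restarts = 2, seed = 1)
  expect_gte(fit@fml, 0)
  # permuting indicator columns leaves the fit unchanged
  perm <- c(4, 2, 6, 1, 3, 5)
  fitP <- fitCfa(dat$X[, perm], twoLatentSpec(), restarts = 2, seed = 1)
  expect_equal(fit@fml, fitP@fml, tolerance = 1e-6)
  # freeing a residual covariance can only improve the discrepancy
  fitRC <- fitCfa(dat$X, twoLatentSpec(residCov = list(c("a1", "b1"))),
                  restarts = 2, seed = 1)
  expect_lte(fitRC@fml, fit@fml + 1e-8)
  expect_equal(fitRC@df, fit@df - 1)
})

test_that("dropping one of several indicators barely moves the scores", {
  tr <- trueTwoLatent()
  dat <- simTwoLatent(1000, tr, seed = 41)
  full <- fitCfa(dat$X, twoLatentSpec(), restarts = 2, seed = 1)
  reduced <- list(latents = list(L1 = c("a1", "a2"), L2 = c("b1", "b2", "b3")),
                  residCov = list())
  red <- fitCfa(dat$X[, c("a1", "a2", "b1", "b2", "b3")], reduced,
                restarts = 2, seed = 1)
  s1 <- factorScores(full, dat$X)
  s2 <- factorScores(red, dat$X[, c("a1", "a2", "b1", "b2", "b3")])
  expect_gt(cor(s1[, "L1"], s2[, "L1"]), 0.9)
  expect_gt(cor(s1[, "L2"], s2[, "L2"]), 0.9)
})

test_that("pathological inputs are rejected or flagged, not silently fitted", {
  tr <- trueTwoLatent()
  # non-PD sample covariance
  bad <- tr$Sigma; bad[1, 2] <- bad[2, 1] <- 2
  expect_error(fitCfaCov(bad, 100, twoLatentSpec()), "positive definite")
  # sample size must exceed free parameters
  expect_error(fitCfaCov(tr$Sigma, 10, twoLatentSpec()), "free parameters")
  # unknown indicators
  expect_error(fitCfa(simTwoLatent(50, tr, 1)$X[, 1:5], twoLatentSpec()),
               "absent")
  # duplicate indicator mapping
  expect_error(validateLatentSpec(list(latents = list(L1 = "a", L2 = "a"),
                                       residCov = list())), "more than one")
})
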