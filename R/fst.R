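#' @name popgen-module
#' @title Weir-Cockerham F_ST from biallelic genotype dosages
#'
#' @description
#' The Weir & Cockerham (1984) theta estimator of F_ST between labelled
#' populations, computed from allele frequencies, sample sizes and
#' observed heterozygosity per SNP, combined across SNPs as a ratio of
#' averages (sum of the a components over the sum of a + b + c) — never
#' as an average of per-SNP ratios. Missing dosages are excluded
#' per SNP per population; a SNP is skipped for a pair when either
#' population has fewer than 2 called individuals or when it is
#' monomorphic across both populations.
NULL

# Per-SNP Weir-Cockerham variance components for two populations.
# nVec: called diploid individuals per pop; pVec: alt allele frequency;
# hVec: observed heterozygote frequency.
wcComponents <- function(nVec, pVec, hVec) {
  r <- 2
  nbar <- mean(nVec)
  nc <- (sum(nVec) - sum(nVec^2) / sum(nVec)) / (r - 1)
  pbar <- sum(nVec * pVec) / sum(nVec)
  s2 <- sum(nVec * (pVec - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(nVec * hVec) / sum(nVec)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Pairwise Weir-Cockerham theta between two populations
#'
#' @param panel genotype panel data.frame (see
#'   \code{\link{validateGenotypePanel}}).
#' @param popA,popB population labels present in the panel.
#' @param minIndiv warn when either population has fewer called
#'   individuals than this (default 5, the usual desk rule for stable
#'   frequency estimates); computation proceeds from 2.
#' @return list with \code{theta} (ratio of averages), \code{nSnpsUsed},
#'   and \code{nSnpsSkipped}.
#' @export
wcFstPair <- function(panel, popA, popB, minIndiv = 5) {
  validateGenotypePanel(panel)
  snps <- dosageCols(panel)
  gA <- as.matrix(panel[panel$population == popA, snps, drop = FALSE])
  gB <- as.matrix(panel[panel$population == popB, snps, drop = FALSE])
  if (nrow(gA) < 2 || nrow(gB) < 2) {
    stop("both populations need >= 2 individuals (", popA, ": ", nrow(gA),
         ", ", popB, ": ", nrow(gB), ")")
  }
  if (nrow(gA) < minIndiv || nrow(gB) < minIndiv) {
    warning("population(s) below ", minIndiv, " individuals; theta may be noisy")
  }
  # vectorised over SNPs; wcComponents documents the per-SNP formula and
  # is kept in step by the unit tests
  n1 <- colSums(!is.na(gA)); n2 <- colSums(!is.na(gB))
  p1 <- colMeans(gA, na.rm = TRUE) / 2; p2 <- colMeans(gB, na.rm = TRUE) / 2
  h1 <- colMeans(gA == 1, na.rm = TRUE); h2 <- colMeans(gB == 1, na.rm = TRUE)
  ok <- n1 >= 2 & n2 >= 2
  mono <- (p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1)
  ok <- ok & !is.na(mono) & !mono
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  ok <- ok & is.finite(a) & is.finite(b) & is.finite(cc)
  used <- sum(ok)
  skipped <- length(snps) - used
  sumA <- sum(a[ok])
  sumABC <- sum(a[ok] + b[ok] + cc[ok])
  if (used == 0L) stop("no usable SNPs for pair ", popA, " / ", popB)
  if (sumABC == 0) stop("zero total variance across usable SNPs for pair ",
                        popA, " / ", popB)
  list(theta = unname(sumA / sumABC), nSnpsUsed = used, nSnpsSkipped = skipped)
}

#' Pairwise Weir-Cockerham F_ST matrix over all populations
#'
#' @param panel genotype panel data.frame.
#' @param minIndiv see \code{\link{wcFstPair}}.
#' @return a \linkS4class{DistMat} of theta values (negative estimates
#'   reported raw).
#' @export
wcFstMatrix <- function(panel, minIndiv = 5) {
  validateGenotypePanel(panel)
  pops <- sort(unique(as.character(panel$population)))
  if (length(pops) < 2) stop("need >= 2 populations")
  out <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in (i + 1):length(pops)) {
      th <- wcFstPair(panel, pops[i], pops[j], minIndiv = minIndiv)$theta
      out[i, j] <- out[j, i] <- th
    }
  }
  DistMat(out)
}
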