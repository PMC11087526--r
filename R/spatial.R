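#' @name spatial-module
#' @title Distance-class spatial autocorrelation (variogram)
#'
#' @description
#' Multivariate autocorrelation in the Smouse-Peakall style: the trait
#' distance matrix is Gower-centered to an inner-product matrix C, and
#' for each geographic distance class h the coefficient
#' \deqn{r_h = 2 \sum_{i<j \in h} c_{ij} / \sum_{i<j \in h} (c_{ii} + c_{jj})}
#' compares the average trait similarity of society pairs inside the
#' class to the overall level. Positive r at short distances means
#' nearby societies are more similar than average. Significance comes
#' from permuting the society-to-location assignment; confidence
#' intervals from bootstrapping pairs within each class.
NULL

#' Evenly spaced distance classes
#'
#' @param bandKm class width in km (default 500).
#' @param maxKm maximum distance in km (default 20000).
#' @return list with bandKm, maxKm, and the class upper edges. A pair
#'   falls in class k iff its distance lies in ((k-1) band, k band];
#'   zero-distance pairs are assigned to class 1.
#' @export
distanceClasses <- function(bandKm = 500, maxKm = 20000) {
  if (bandKm <= 0 || maxKm <= 0 || maxKm < bandKm) stop("invalid class specification")
  k <- maxKm / bandKm
  if (abs(k - round(k)) > 1e-9) stop("maxKm must be a multiple of bandKm")
  list(bandKm = bandKm, maxKm = maxKm, edges = seq(bandKm, maxKm, by = bandKm))
}

# class index per pair (0 = beyond maxKm)
pairClass <- function(gd, spec) {
  k <- ceiling(gd / spec$bandKm)
  k[gd == 0] <- 1L
  k[gd > spec$maxKm] <- 0L
  k
}

rOfClass <- function(cNum, cDen) {
  if (!length(cNum) || sum(cDen) == 0) return(NA_real_)
  2 * sum(cNum) / sum(cDen)
}

# all-class r values for one assignment (perm = index permutation of the
# geographic matrix relative to the trait matrix)
classR <- function(C, classIdx, iIdx, jIdx, nClass) {
  r <- rep(NA_real_, nClass)
  dC <- diag(C)
  num <- C[cbind(iIdx, jIdx)]
  den <- dC[iIdx] + dC[jIdx]
  for (k in seq_len(nClass)) {
    sel <- classIdx == k
    if (any(sel)) r[k] <- rOfClass(num[sel], den[sel])
  }
  r
}

#' Spatial autocorrelation profile across distance classes
#'
#' @param traitD \linkS4class{DistMat} of trait distances (music, F_ST,
#'   patristic, ...).
#' @param geoD \linkS4class{DistMat} of geographic distances in km.
#' @param spec distance classes from \code{\link{distanceClasses}}.
#' @param nPerm permutations of the society-location assignment
#'   (default 999).
#' @param nBoot bootstrap resamples of pairs within class (default 999).
#' @param seed RNG seed.
#' @param alternative \code{"two.sided"} (default) or \code{"greater"}.
#' @return a \linkS4class{Variogram}.
#' @export
autocorrVariogram <- function(traitD, geoD, spec = distanceClasses(),
                              nPerm = 999, nBoot = 999, seed = 1,
                              alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  al <- dmAlign(traitD, geoD)
  traitD <- al[[1]]; geoD <- al[[2]]
  n <- nrow(as.matrix(traitD))
  if (n < 4) stop("need >= 4 societies")
  C <- gowerCenter(traitD)
  G <- as.matrix(geoD)
  ut <- which(upper.tri(G), arr.ind = TRUE)
  iIdx <- ut[, 1]; jIdx <- ut[, 2]
  classIdx <- pairClass(G[ut], spec)
  nClass <- length(spec$edges)
  rObs <- classR(C, classIdx, iIdx, jIdx, nClass)
  nPairs <- vapply(seq_len(nClass), function(k) sum(classIdx == k), 0L)
  pv <- rep(NA_real_, nClass)
  ciLo <- rep(NA_real_, nClass); ciHi <- rep(NA_real_, nClass)
  withSeed(seed, {
    if (nPerm > 0) {
      exceed <- rep(0, nClass)
      valid <- rep(0, nClass)
      for (b in seq_len(nPerm)) {
        perm <- sample.int(n)
        # shuffle which society sits at which location: traits follow perm
        Cp <- C[perm, perm]
        rp <- classR(Cp, classIdx, iIdx, jIdx, nClass)
        ok <- !is.na(rp) & !is.na(rObs)
        cmp <- if (alternative == "two.sided") abs(rp) >= abs(rObs) else rp >= rObs
        exceed[ok & cmp] <- exceed[ok & cmp] + 1
        valid <- valid + as.numeric(ok)
      }
      pv <- ifelse(is.na(rObs), NA_real_, (exceed + 1) / (valid + 1))
    }
    if (nBoot > 0) {
      dC <- diag(C)
      num <- C[cbind(iIdx, jIdx)]
      den <- dC[iIdx] + dC[jIdx]
      for (k in seq_len(nClass)) {
        sel <- which(classIdx == k)
        if (length(sel) < 2 || is.na(rObs[k])) next
        rb <- vapply(seq_len(nBoot), function(b) {
          res <- sample(sel, length(sel), replace = TRUE)
          rOfClass(num[res], den[res])
        }, 0)
        qs <- quantile(rb, c(0.025, 0.975), na.rm = TRUE)
        ciLo[k] <- qs[1]; ciHi[k] <- qs[2]
      }
    }
  })
  tab <- data.frame(class_upper_km = spec$edges, n_pairs = nPairs,
                    r = rObs, p = pv, ci_lo = ciLo, ci_hi = ciHi)
  new("Variogram", table = tab, bandKm = spec$bandKm, maxKm = spec$maxKm,
      nPerm = as.numeric(nPerm), nBoot = as.numeric(nBoot))
}

#' Distance up to which autocorrelation persists
#'
#' The largest distance d such that every class up to d has positive r
#' with permutation p below alpha; 0 when the first class already fails.
#'
#' @param v a \linkS4class{Variogram}.
#' @param alpha significance level (default 0.01).
#' @return distance in km.
#' @export
significantRange <- function(v, alpha = 0.01) {
  tab <- v@table
  range <- 0
  for (k in seq_len(nrow(tab))) {
    if (is.na(tab$r[k]) || is.na(tab$p[k])) break
    if (tab$r[k] > 0 && tab$p[k] < alpha) range <- tab$class_upper_km[k] else break
  }
  range
}

#' Mean autocorrelation over classes within a distance
#'
#' @param v a \linkS4class{Variogram}.
#' @param withinKm average r over classes with upper edge <= this.
#' @return mean r.
#' @export
meanAutocorr <- function(v, withinKm) {
  tab <- v@table
  mean(tab$r[tab$class_upper_km <= withinKm], na.rm = TRUE)
}
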