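#' @name delta-module
#' @title Quartet delta scores: departure from treelikeness
#'
#' @description
#' For four taxa x, y, u, v with pairwise distances d, form the three
#' pairing sums d(x,y)+d(u,v), d(x,u)+d(y,v), d(x,v)+d(y,u) and order
#' them m1 >= m2 >= m3. On an additive (tree) metric the two largest are
#' equal (the four-point condition), so
#' \deqn{\delta = (m1 - m2) / (m1 - m3)}
#' is 0 for a perfectly treelike quartet and 1 for a maximally
#' conflicting one; when m1 = m3 (all pairings equal, e.g. star trees)
#' delta is 0 by convention. The delta score of a distance matrix is the
#' mean over quartets.
NULL

deltaFromSums <- function(s1, s2, s3) {
  m1 <- pmax(s1, s2, s3)
  m3 <- pmin(s1, s2, s3)
  m2 <- s1 + s2 + s3 - m1 - m3
  span <- m1 - m3
  out <- ifelse(span <= 1e-12 * pmax(m1, 1e-300), 0, (m1 - m2) / span)
  out
}

#' Delta score of a single quartet
#'
#' @param d a \linkS4class{DistMat} or labelled square matrix.
#' @param x,y,u,v four distinct labels.
#' @return delta in [0, 1].
#' @export
quartetDelta <- function(d, x, y, u, v) {
  m <- if (is(d, "DistMat")) as.matrix(d) else d
  labs <- c(x, y, u, v)
  if (anyDuplicated(labs)) stop("quartet labels must be distinct")
  if (!all(labs %in% rownames(m))) {
    stop("labels absent from matrix: ",
         paste(setdiff(labs, rownames(m)), collapse = ", "))
  }
  deltaFromSums(m[x, y] + m[u, v], m[x, u] + m[y, v], m[x, v] + m[y, u])
}

#' Mean delta score over quartets of a distance matrix
#'
#' All C(n, 4) quartets are enumerated when there are at most
#' \code{maxQuartets} of them; otherwise a seeded random subsample of
#' \code{maxQuartets} quartets is scored. Optionally the taxa themselves
#' are first subsampled to \code{sampleSize}.
#'
#' @param d a \linkS4class{DistMat} or labelled square matrix.
#' @param sampleSize optional number of taxa to subsample (without
#'   replacement) before scoring.
#' @param seed RNG seed for any subsampling.
#' @param maxQuartets enumeration cutoff (default 1e6) and subsample
#'   count when beyond it (default 1e5 scored).
#' @param nSubsample quartets scored when enumeration is infeasible.
#' @return list with \code{mean}, \code{perTaxon} (named mean delta over
#'   quartets containing each taxon), and \code{nQuartets}.
#' @export
deltaScore <- function(d, sampleSize = NULL, seed = 1,
                       maxQuartets = 1e6, nSubsample = 1e5) {
  m <- if (is(d, "DistMat")) as.matrix(d) else d
  labs <- rownames(m)
  withSeed(seed, {
    if (!is.null(sampleSize)) {
      if (sampleSize > length(labs)) stop("sampleSize exceeds number of taxa")
      labs <- sort(sample(labs, sampleSize))
      m <- m[labs, labs]
    }
    n <- length(labs)
    if (n < 4) stop("need >= 4 taxa")
    if (choose(n, 4) <= maxQuartets) {
      q <- combn(n, 4)
    } else {
      q <- replicate(nSubsample, sample.int(n, 4))
    }
  })
  x <- q[1, ]; y <- q[2, ]; u <- q[3, ]; v <- q[4, ]
  dd <- function(a, b) m[cbind(a, b)]
  del <- deltaFromSums(dd(x, y) + dd(u, v), dd(x, u) + dd(y, v), dd(x, v) + dd(y, u))
  sums <- rep(0, n); cnts <- rep(0, n)
  for (r in 1:4) {
    t1 <- tapply(del, q[r, ], sum)
    idx <- as.integer(names(t1))
    sums[idx] <- sums[idx] + t1
    t2 <- tabulate(q[r, ], nbins = n)
    cnts <- cnts + t2
  }
  perTaxon <- ifelse(cnts > 0, sums / cnts, NA_real_)
  names(perTaxon) <- labs
  # undefined entries (e.g. NaN fixation values) drop their quartets
  list(mean = mean(del, na.rm = TRUE), perTaxon = perTaxon, nQuartets = ncol(q))
}

#' Delta scores per region and latent variable
#'
#' For each region, subsample \code{sampleSize} societies (seeded) and
#' compute the mean delta score per variable. By default each latent
#' variable is scored on its 1-D absolute-difference distance matrix and
#' "All" on the joint Euclidean matrix; note that a 1-D Euclidean metric
#' is a path metric and therefore exactly additive, so per-variable
#' deltas are identically 0 in that mode — supply \code{dists} (e.g. the
#' per-dimension Phi_ST matrices, the musical distances used elsewhere
#' in the pipeline) to score non-trivial per-variable treelikeness.
#'
#' @param latents society x latent numeric matrix.
#' @param regions region label per society (aligned with the rows).
#' @param sampleSize societies sampled per region (default 50).
#' @param seed RNG seed.
#' @param dists optional named list of \linkS4class{DistMat} objects
#'   (one per variable, optionally including "All") used instead of the
#'   1-D score distances.
#' @param maxQuartets,nSubsample see \code{\link{deltaScore}}.
#' @return data.frame: variable x region matrix of mean delta scores.
#' @export
deltaByRegion <- function(latents, regions, sampleSize = 50, seed = 1,
                          dists = NULL, maxQuartets = 1e6, nSubsample = 1e5) {
  latents <- as.matrix(latents)
  if (is.null(rownames(latents))) stop("latents must have society rownames")
  if (length(regions) != nrow(latents)) stop("one region label per society required")
  regions <- as.character(regions)
  regs <- sort(unique(regions))
  small <- regs[vapply(regs, function(r) sum(regions == r), 0L) < sampleSize]
  if (length(small)) {
    stop("region(s) with fewer than ", sampleSize, " societies: ",
         paste(small, collapse = ", "))
  }
  vars <- c(colnames(latents), "All")
  out <- matrix(NA_real_, length(vars), length(regs), dimnames = list(vars, regs))
  for (ri in seq_along(regs)) {
    idx <- which(regions == regs[ri])
    pick <- withSeed(splitSeed(seed, ri), sort(sample(idx, sampleSize)))
    sub <- latents[pick, , drop = FALSE]
    for (v in colnames(latents)) {
      if (!is.null(dists) && v %in% names(dists)) {
        dm <- as.matrix(dmSubset(dists[[v]], rownames(sub)))
      } else {
        dm <- abs(outer(sub[, v], sub[, v], "-"))
        rownames(dm) <- colnames(dm) <- rownames(sub)
      }
      out[v, ri] <- deltaScore(dm, seed = splitSeed(seed, 100 + ri),
                               maxQuartets = maxQuartets, nSubsample = nSubsample)$mean
    }
    if (!is.null(dists) && "All" %in% names(dists)) {
      dm <- as.matrix(dmSubset(dists[["All"]], rownames(sub)))
    } else {
      dm <- as.matrix(dist(sub))
    }
    out["All", ri] <- deltaScore(dm, seed = splitSeed(seed, 200 + ri),
                                 maxQuartets = maxQuartets, nSubsample = nSubsample)$mean
  }
  as.data.frame(out)
}
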