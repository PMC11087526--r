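#' @name amova-module
#' @title Hierarchical AMOVA on song-level distances
#'
#' @description
#' Analysis of molecular variance adapted to songs nested in societies
#' (optionally nested in macro-groups such as language families or
#' regions): squared Euclidean distances between songs are decomposed
#' into within-society, among-society (within group), and among-group
#' variance components with the standard unequal-sample-size
#' coefficients, yielding the Phi fixation statistics. Negative
#' components are reported as-is; Phi is NaN when its denominator is
#' non-positive.
NULL

# sum of squared Euclidean distances within a set of rows, divided by set size
ssdWithin <- function(d2, idx) {
  if (length(idx) < 2) return(0)
  sum(d2[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]) / length(idx)
}

amovaComponents <- function(d2, society, group = NULL) {
  society <- as.character(society)
  N <- nrow(d2)
  socs <- unique(society)
  S <- length(socs)
  ssTot <- sum(upperTri(d2)) / N
  ssWP <- sum(vapply(socs, function(s) ssdWithin(d2, which(society == s)), 0))
  nPerSoc <- as.numeric(table(society)[socs])
  if (is.null(group)) {
    ssAP <- ssTot - ssWP
    dfAP <- S - 1; dfWP <- N - S
    msAP <- ssAP / dfAP; msWP <- ssWP / dfWP
    n0 <- (N - sum(nPerSoc^2) / N) / (S - 1)
    sw <- msWP
    sa <- (msAP - msWP) / n0
    tot <- sa + sw
    list(ss = c(among_societies = ssAP, within_societies = ssWP),
         df = c(among_societies = dfAP, within_societies = dfWP),
         components = c(among_societies = sa, within_societies = sw),
         phi = c(PhiST = if (tot > 0) sa / tot else NaN))
  } else {
    group <- as.character(group)
    socGroup <- vapply(socs, function(s) group[society == s][1], "")
    if (any(vapply(socs, function(s) length(unique(group[society == s])) > 1, TRUE))) {
      stop("each society must belong to exactly one group")
    }
    grps <- unique(socGroup)
    G <- length(grps)
    if (G < 2) stop("two-level AMOVA requires >= 2 groups")
    Ng <- vapply(grps, function(g) sum(society %in% socs[socGroup == g]), 0)
    ssWG <- sum(vapply(grps, function(g) {
      ssdWithin(d2, which(society %in% socs[socGroup == g]))
    }, 0))
    ssAG <- ssTot - ssWG
    ssAP <- ssWG - ssWP
    dfAG <- G - 1; dfAP <- S - G; dfWP <- N - S
    msAG <- ssAG / dfAG; msAP <- ssAP / dfAP; msWP <- ssWP / dfWP
    sumSq <- sum(nPerSoc^2)
    sumSqByG <- vapply(grps, function(g) sum(nPerSoc[socGroup == g]^2) /
                         sum(nPerSoc[socGroup == g]), 0)
    nco <- (N - sum(sumSqByG)) / (S - G)
    ncoP <- (sum(sumSqByG) - sumSq / N) / (G - 1)
    ncoPP <- (N - sum(Ng^2) / N) / (G - 1)
    sw <- msWP
    sb <- (msAP - msWP) / nco
    sa <- (msAG - msWP - ncoP * sb) / ncoPP
    tot <- sa + sb + sw
    list(ss = c(among_groups = ssAG, among_societies = ssAP, within_societies = ssWP),
         df = c(among_groups = dfAG, among_societies = dfAP, within_societies = dfWP),
         components = c(among_groups = sa, among_societies = sb, within_societies = sw),
         phi = c(PhiCT = if (tot > 0) sa / tot else NaN,
                 PhiSC = if (sb + sw > 0) sb / (sb + sw) else NaN,
                 PhiST = if (tot > 0) (sa + sb) / tot else NaN))
  }
}

#' Hierarchical AMOVA of song traits
#'
#' @param values song x trait numeric matrix (or vector for a single
#'   trait): factor scores or standardized features.
#' @param society society label per song.
#' @param group optional macro-group label per song (language family or
#'   region) for the two-level hierarchy.
#' @param nPerm permutations for the Phi p-values (0 = none; default 999).
#' @param seed permutation seed.
#' @return an \linkS4class{AmovaResult}.
#' @export
amova <- function(values, society, group = NULL, nPerm = 999, seed = 1) {
  X <- as.matrix(values)
  society <- as.character(society)
  if (nrow(X) != length(society)) stop("values and society lengths differ")
  if (!is.null(group) && length(group) != length(society)) {
    stop("group must have one label per song")
  }
  if (length(unique(society)) < 2) stop("AMOVA requires >= 2 societies")
  d2 <- as.matrix(dist(X))^2
  N <- nrow(d2)
  if (sum(upperTri(d2)) <= 0) stop("all songs identical: variance components undefined")
  res <- amovaComponents(d2, society, group)
  if (!is.null(group)) {
    socPerGroup <- vapply(split(society, group), function(s) length(unique(s)), 0L)
    if (any(socPerGroup < 2)) {
      warning("group(s) with a single society: ",
              paste(names(socPerGroup)[socPerGroup < 2], collapse = ", "),
              "; among-society component weakly identified")
    }
  }
  pv <- rep(NA_real_, length(res$phi))
  names(pv) <- names(res$phi)
  if (nPerm > 0) {
    obs <- res$phi
    cnt <- setNames(rep(0, length(obs)), names(obs))
    withSeed(seed, {
      for (b in seq_len(nPerm)) {
        if (is.null(group)) {
          prm <- sample.int(N)
          phiPerm <- amovaComponents(d2[prm, prm], society)$phi
        } else {
          # PhiST: permute songs across everything; PhiSC: permute songs
          # within groups; PhiCT: permute whole societies among groups
          prm <- sample.int(N)
          phiST <- amovaComponents(d2[prm, prm], society, group)$phi["PhiST"]
          prmW <- seq_len(N)
          for (g in unique(group)) {
            idx <- which(group == g)
            prmW[idx] <- idx[sample.int(length(idx))]
          }
          phiSC <- amovaComponents(d2[prmW, prmW], society, group)$phi["PhiSC"]
          socs <- unique(society)
          permGrp <- sample(vapply(socs, function(s) group[society == s][1], ""))
          names(permGrp) <- socs
          phiCT <- amovaComponents(d2, society, unname(permGrp[society]))$phi["PhiCT"]
          phiPerm <- c(PhiCT = unname(phiCT), PhiSC = unname(phiSC),
                       PhiST = unname(phiST))
        }
        cnt <- cnt + as.numeric(!is.na(phiPerm) & phiPerm >= obs[names(cnt)])
      }
    })
    pv <- (cnt + 1) / (nPerm + 1)
    pv[is.na(obs)] <- NA_real_
  }
  comp <- res$components
  new("AmovaResult", components = comp,
      percentages = 100 * comp / sum(comp),
      phi = res$phi, ss = res$ss, df = res$df, pvalues = pv,
      nPerm = as.numeric(nPerm))
}

#' Pairwise Phi_ST fixation matrix between societies
#'
#' For every pair of societies, a two-population AMOVA on the songs of
#' that pair; Phi_ST = sigma2_among / (sigma2_among + sigma2_within),
#' reported raw (can be negative; NaN when the pair has zero total
#' variance).
#'
#' @param values song x trait matrix (one column for a per-dimension
#'   matrix; all features for the aggregate).
#' @param society society label per song.
#' @param minSongs inclusion filter: societies with fewer songs are
#'   dropped with a message (default 2).
#' @return a \linkS4class{DistMat} of Phi_ST values.
#' @export
pairwisePhist <- function(values, society, minSongs = 2) {
  X <- as.matrix(values)
  society <- as.character(society)
  counts <- table(society)
  keep <- names(counts)[counts >= minSongs]
  if (length(keep) < length(counts)) {
    message("pairwisePhist: dropping ", length(counts) - length(keep),
            " societies with < ", minSongs, " songs")
  }
  if (length(keep) < 2) stop("fewer than 2 societies with >= ", minSongs, " songs")
  socs <- sort(keep)
  out <- matrix(0, length(socs), length(socs), dimnames = list(socs, socs))
  anyNaN <- FALSE
  for (i in seq_along(socs)[-length(socs)]) {
    for (j in (i + 1):length(socs)) {
      idx <- which(society %in% c(socs[i], socs[j]))
      d2 <- as.matrix(dist(X[idx, , drop = FALSE]))^2
      if (sum(upperTri(d2)) <= 0) {
        out[i, j] <- out[j, i] <- NaN
        anyNaN <- TRUE
        next
      }
      phi <- amovaComponents(d2, society[idx])$phi["PhiST"]
      out[i, j] <- out[j, i] <- unname(phi)
      if (is.nan(out[i, j])) anyNaN <- TRUE
    }
  }
  if (anyNaN) warning("some pairs have zero total variance: Phi_ST undefined (NaN)")
  DistMat(out)
}

#' Compare musical and genetic fixation matrices
#'
#' Elementwise paired comparison of Phi_ST and F_ST over shared society
#' pairs: quantiles of the difference Phi_ST - F_ST and of the ratio
#' Phi_ST / F_ST (ratio restricted to pairs with F_ST > 0).
#'
#' @param phist \linkS4class{DistMat} of musical Phi_ST.
#' @param fst \linkS4class{DistMat} of genetic F_ST.
#' @param probs quantiles to report.
#' @return list with pair count, difference and ratio quantiles, and the
#'   median ratio.
#' @export
fixationComparison <- function(phist, fst, probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  al <- dmAlign(phist, fst)
  a <- upperTri(as.matrix(al[[1]]))
  b <- upperTri(as.matrix(al[[2]]))
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("fewer than 3 shared society pairs")
  a <- a[ok]; b <- b[ok]
  ratio <- (a / b)[b > 0]
  list(nPairs = length(a),
       diffQuantiles = quantile(a - b, probs),
       ratioQuantiles = if (length(ratio)) quantile(ratio, probs) else NULL,
       medianRatio = if (length(ratio)) unname(quantile(ratio, 0.5)) else NA_real_)
}
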