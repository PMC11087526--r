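# Independent brute-force oracles: explicit loops, no matrix shortcuts,
# written against the definitions rather than the package's code paths.

oracleGower <- function(d) {
  m <- as.matrix(d)^2
  n <- nrow(m)
  C <- matrix(0, n, n)
  rowM <- sapply(seq_len(n), function(i) mean(m[i, ]))
  colM <- sapply(seq_len(n), function(j) mean(m[, j]))
  grand <- mean(m)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    C[i, j] <- -0.5 * (m[i, j] - rowM[i] - colM[j] + grand)
  }
  C
}

# one-level AMOVA from explicit sums of squares
oracleAmova1 <- function(X, society) {
  X <- as.matrix(X)
  society <- as.character(society)
  N <- nrow(X)
  socs <- unique(society)
  S <- length(socs)
  d2 <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    d2[i, j] <- sum((X[i, ] - X[j, ])^2)
  }
  ssTot <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) ssTot <- ssTot + d2[i, j]
  ssTot <- ssTot / N
  ssW <- 0
  nPer <- numeric(S)
  for (k in seq_len(S)) {
    idx <- which(society == socs[k])
    nPer[k] <- length(idx)
    if (length(idx) >= 2) {
      s <- 0
      for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
        s <- s + d2[idx[a], idx[b]]
      }
      ssW <- ssW + s / length(idx)
    }
  }
  ssA <- ssTot - ssW
  msA <- ssA / (S - 1)
  msW <- ssW / (N - S)
  n0 <- (N - sum(nPer^2) / N) / (S - 1)
  sw <- msW
  sa <- (msA - msW) / n0
  list(ss = c(among = ssA, within = ssW), sigma = c(a = sa, w = sw),
       phiST = sa / (sa + sw))
}

# two-level AMOVA from explicit sums of squares
oracleAmova2 <- function(X, society, group) {
  X <- as.matrix(X)
  society <- as.character(society)
  group <- as.character(group)
  N <- nrow(X)
  d2 <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) d2[i, j] <- sum((X[i, ] - X[j, ])^2)
  ssSet <- function(idx) {
    if (length(idx) < 2) return(0)
    s <- 0
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
      s <- s + d2[idx[a], idx[b]]
    }
    s / length(idx)
  }
  ssTot <- ssSet(seq_len(N))
  socs <- unique(society)
  grps <- unique(group)
  S <- length(socs); G <- length(grps)
  ssWP <- sum(sapply(socs, function(s) ssSet(which(society == s))))
  ssWG <- sum(sapply(grps, function(g) ssSet(which(group == g))))
  ssAP <- ssWG - ssWP
  ssAG <- ssTot - ssWG
  nPer <- sapply(socs, function(s) sum(society == s))
  grpOf <- sapply(socs, function(s) group[society == s][1])
  Ng <- sapply(grps, function(g) sum(group == g))
  msAG <- ssAG / (G - 1); msAP <- ssAP / (S - G); msWP <- ssWP / (N - S)
  sumSqByG <- sapply(grps, function(g) sum(nPer[grpOf == g]^2) / sum(nPer[grpOf == g]))
  n1 <- (N - sum(sumSqByG)) / (S - G)
  n2 <- (sum(sumSqByG) - sum(nPer^2) / N) / (G - 1)
  n3 <- (N - sum(Ng^2) / N) / (G - 1)
  sw <- msWP
  sb <- (msAP - msWP) / n1
  sa <- (msAG - msWP - n2 * sb) / n3
  list(ss = c(AG = ssAG, AP = ssAP, WP = ssWP),
       sigma = c(a = sa, b = sb, w = sw),
       phi = c(CT = sa / (sa + sb + sw), SC = sb / (sb + sw),
               ST = (sa + sb) / (sa + sb + sw)))
}

# all-quartet delta by explicit enumeration
oracleDelta <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  tot <- 0; cnt <- 0
  for (x in 1:(n - 3)) for (y in (x + 1):(n - 2)) for (u in (y + 1):(n - 1)) for (v in (u + 1):n) {
    s <- sort(c(m[x, y] + m[u, v], m[x, u] + m[y, v], m[x, v] + m[y, u]),
              decreasing = TRUE)
    del <- if (s[1] - s[3] <= 1e-12 * max(s[1], 1e-300)) 0 else (s[1] - s[2]) / (s[1] - s[3])
    tot <- tot + del; cnt <- cnt + 1
  }
  tot / cnt
}

# distance-class autocorrelation r by explicit indicator sums
oracleAutocorr <- function(traitD, geoD, bandKm, maxKm) {
  C <- oracleGower(traitD)
  G <- as.matrix(geoD)
  n <- nrow(G)
  nClass <- maxKm / bandKm
  r <- rep(NA_real_, nClass)
  for (k in seq_len(nClass)) {
    lo <- (k - 1) * bandKm; hi <- k * bandKm
    num <- 0; den <- 0; any <- FALSE
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      g <- G[i, j]
      inClass <- if (g == 0) k == 1 else (g > lo && g <= hi)
      if (inClass) {
        any <- TRUE
        num <- num + 2 * C[i, j]
        den <- den + C[i, i] + C[j, j]
      }
    }
    if (any && den != 0) r[k] <- num / den
  }
  r
}

allPerms <- function(v) {
  if (length(v) == 1) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(allPerms(v[-i]), function(p) c(v[i], p))
  }), recursive = FALSE)
}

# exact Mantel p for n = 4 by full enumeration of the 24 permutations
oracleMantelP4 <- function(a, b, twoSided = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  ut <- upper.tri(a)
  rObs <- cor(a[ut], b[ut])
  cnt <- 0
  ps <- allPerms(1:4)
  for (p in ps) {
    rp <- cor(a[ut], b[p, p][ut])
    if (if (twoSided) abs(rp) >= abs(rObs) - 1e-12 else rp >= rObs - 1e-12) cnt <- cnt + 1
  }
  cnt / length(ps)
}

# Weir-Cockerham theta for one SNP, direct formula transcription
oracleWcSnp <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}
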