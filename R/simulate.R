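#' @name synthetic-module
#' @title Synthetic comparative worlds with known ground truth
#'
#' @description
#' Generates a world in which every pipeline stage has a recoverable
#' target: a Yule society tree (depth scaled to 1), Brownian latent
#' musical traits evolved along its branches, spatially autocorrelated
#' coordinates (Brownian diffusion of longitude/latitude on the same
#' tree), optional horizontal transmission (with probability h each of a
#' society's latent dimensions is adopted wholesale from a random one of
#' its k nearest geographic neighbours),
#' songs with within-society noise coded on ordinal indicators through a
#' known loading vector, and a biallelic genotype panel whose allele
#' frequencies drift along the same tree under the Balding-Nichols
#' model.
NULL

#' Configuration for a synthetic world
#'
#' @param nSocieties number of societies (tree tips).
#' @param songsPerSociety songs per society (>= 2).
#' @param birthRate Yule birth rate for the society tree.
#' @param traitRate Brownian rate (variance per unit depth) of each
#'   latent dimension.
#' @param hMix horizontal transmission rate in [0, 1]: the probability
#'   that each latent dimension of a society is adopted wholesale from a
#'   random one of its k nearest geographic neighbours (0 = purely
#'   vertical transmission, 1 = fully borrowed repertoire).
#' @param kNeighbors size of the spatial neighbourhood traits can be
#'   borrowed from.
#' @param songNoise within-society standard deviation of song latents
#'   around the society mean.
#' @param uniqueNoise add indicator-level unique variance 1 - lambda^2
#'   (the standard factor-model residual); disable to make songs exact
#'   deterministic images of their latents.
#' @param loadings named numeric vector of true standardized loadings,
#'   one per indicator of \code{latentSpec} (NULL = drawn once, seeded,
#'   uniform on [0.55, 0.85]).
#' @param latentSpec indicator-to-latent map (default
#'   \code{\link{defaultLatentSpec}}).
#' @param scheme coding scheme supplying each indicator's ordinal code
#'   set and reversal flag (default \code{\link{defaultCodingScheme}}).
#' @param multiCodeRate fraction of song x feature cells duplicated as
#'   multi-coded (default 0.03).
#' @param geoScale Brownian standard deviation (degrees per unit depth)
#'   of the coordinate diffusion.
#' @param nSnps biallelic SNPs in the genotype panel.
#' @param driftF Balding-Nichols drift applied on every branch.
#' @param indivPerPop diploid individuals sampled per population.
#' @param seed global seed; fans out to per-component seeds via
#'   \code{\link{splitSeed}}.
#' @return validated configuration list.
#' @export
simConfig <- function(nSocieties = 30, songsPerSociety = 10, birthRate = 1,
                      traitRate = 1, hMix = 0, kNeighbors = 5,
                      songNoise = 0.5, uniqueNoise = TRUE, loadings = NULL,
                      latentSpec = defaultLatentSpec(),
                      scheme = defaultCodingScheme(),
                      multiCodeRate = 0.03, geoScale = 40,
                      nSnps = 500, driftF = 0.05, indivPerPop = 10, seed = 1) {
  cfg <- list(nSocieties = nSocieties, songsPerSociety = songsPerSociety,
              birthRate = birthRate, traitRate = traitRate, hMix = hMix,
              kNeighbors = kNeighbors, songNoise = songNoise,
              uniqueNoise = uniqueNoise, loadings = loadings,
              latentSpec = latentSpec, scheme = scheme,
              multiCodeRate = multiCodeRate, geoScale = geoScale,
              nSnps = nSnps, driftF = driftF, indivPerPop = indivPerPop,
              seed = seed)
  if (nSocieties < 4) stop("need >= 4 societies")
  if (songsPerSociety < 2) stop("songsPerSociety must be >= 2")
  if (hMix < 0 || hMix > 1) stop("hMix must be in [0, 1]")
  if (any(c(birthRate, traitRate, songNoise, geoScale, driftF) < 0)) {
    stop("rates must be nonnegative")
  }
  if (driftF >= 1) stop("driftF must be < 1")
  validateLatentSpec(latentSpec)
  inds <- unlist(latentSpec$latents, use.names = FALSE)
  if (!all(inds %in% names(scheme$features))) {
    stop("latentSpec indicators missing from coding scheme: ",
         paste(setdiff(inds, names(scheme$features)), collapse = ", "))
  }
  if (!is.null(loadings)) {
    if (is.null(names(loadings)) || !all(inds %in% names(loadings))) {
      stop("loadings must be named with every indicator")
    }
    if (any(loadings <= 0 | loadings >= 1)) stop("loadings must lie in (0, 1)")
  }
  cfg
}

# Brownian evolution of one trait along every edge of a tree; returns
# tip values (root at 0).
bmOnTree <- function(tree, sigma) {
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  val <- numeric(nNode)
  ord <- reorder(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; chd <- ord$edge[e, 2]
    val[chd] <- val[par] + rnorm(1, 0, sigma * sqrt(ord$edge.length[e]))
  }
  setNames(val[seq_len(nTip)], tree$tip.label)
}

# Balding-Nichols drift of allele frequencies along every edge.
bnOnTree <- function(tree, p0, F) {
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  nSnp <- length(p0)
  freq <- matrix(NA_real_, nNode, nSnp)
  root <- nTip + 1
  freq[root, ] <- p0
  ord <- reorder(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; chd <- ord$edge[e, 2]
    p <- freq[par, ]
    if (F <= 0) {
      freq[chd, ] <- p
    } else {
      a <- p * (1 - F) / F
      b <- (1 - p) * (1 - F) / F
      q <- rbeta(nSnp, a, b)
      # Beta collapses at fixed frequencies; keep fixation explicit
      q[p <= 0] <- 0; q[p >= 1] <- 1
      freq[chd, ] <- q
    }
  }
  out <- freq[seq_len(nTip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate a synthetic comparative world
#'
#' @param cfg configuration from \code{\link{simConfig}}.
#' @return a \linkS4class{SimWorld}.
#' @export
simulateWorld <- function(cfg) {
  n <- cfg$nSocieties
  socs <- sprintf("soc%03d", seq_len(n))
  inds <- unlist(cfg$latentSpec$latents, use.names = FALSE)
  latNames <- names(cfg$latentSpec$latents)
  m <- length(latNames)

  tree <- withSeed(splitSeed(cfg$seed, 1), ape::rphylo(n, cfg$birthRate, 0))
  tree$tip.label <- socs
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth  # unit-depth tree

  latents <- withSeed(splitSeed(cfg$seed, 2), {
    sapply(seq_len(m), function(j) bmOnTree(tree, sqrt(cfg$traitRate)))
  })
  colnames(latents) <- latNames

  geo <- withSeed(splitSeed(cfg$seed, 3), {
    lon <- bmOnTree(tree, cfg$geoScale)
    lat <- bmOnTree(tree, cfg$geoScale)
    lon <- ((lon + 180) %% 360) - 180
    lat <- pmax(pmin(lat, 85), -85)
    data.frame(society = socs, longitude = unname(lon[socs]),
               latitude = unname(lat[socs]))
  })

  if (cfg$hMix > 0) {
    # Horizontal transmission as trait adoption: with probability h each
    # latent dimension is replaced wholesale by the value of a random one
    # of the k nearest geographic neighbours. Copying (rather than
    # averaging against the neighbourhood mean) transfers traits without
    # shrinking between-society variance, which is what makes borrowing
    # measurably less treelike.
    gd <- as.matrix(haversineMatrix(geo))
    mixed <- latents
    withSeed(splitSeed(cfg$seed, 7), {
      for (i in seq_len(n)) {
        nbrs <- order(gd[i, ])[2:(cfg$kNeighbors + 1)]
        for (j in seq_len(m)) {
          if (runif(1) < cfg$hMix) {
            mixed[i, j] <- latents[sample(nbrs, 1), j]
          }
        }
      }
    })
    latents <- mixed
  }

  lam <- cfg$loadings
  if (is.null(lam)) {
    lam <- withSeed(splitSeed(cfg$seed, 4),
                    setNames(runif(length(inds), 0.55, 0.85), inds))
  }
  latOf <- setNames(rep(latNames, lengths(cfg$latentSpec$latents)), inds)

  songs <- withSeed(splitSeed(cfg$seed, 5), {
    nSongs <- n * cfg$songsPerSociety
    eta <- latents[rep(seq_len(n), each = cfg$songsPerSociety), , drop = FALSE] +
      matrix(rnorm(nSongs * m, 0, cfg$songNoise), nSongs, m)
    # standardize song-level latents so the loadings are in the
    # completely standardized metric
    etaSd <- apply(eta, 2, sd)
    etaStd <- sweep(sweep(eta, 2, colMeans(eta)), 2, pmax(etaSd, 1e-12), "/")
    tab <- data.frame(song = sprintf("song%05d", seq_len(nSongs)),
                      society = rep(socs, each = cfg$songsPerSociety),
                      family = "", region = "",
                      stringsAsFactors = FALSE)
    for (f in inds) {
      x <- lam[f] * etaStd[, latOf[f]]
      if (cfg$uniqueNoise) x <- x + rnorm(nSongs, 0, sqrt(1 - lam[f]^2))
      codes <- sort(as.numeric(cfg$scheme$features[[f]]$codes))
      K <- length(codes)
      # equal-width bins over +-3 sd
      k <- pmin(pmax(floor((x + 3) / 6 * K) + 1, 1), K)
      rank <- if (isTRUE(cfg$scheme$features[[f]]$reversed)) K + 1 - k else k
      cell <- as.character(codes[rank])
      multi <- runif(nSongs) < cfg$multiCodeRate
      if (any(multi)) {
        k2 <- pmin(pmax(k[multi] + sample(c(-1, 1), sum(multi), replace = TRUE), 1), K)
        r2 <- if (isTRUE(cfg$scheme$features[[f]]$reversed)) K + 1 - k2 else k2
        cell[multi] <- paste(cell[multi], codes[r2], sep = "|")
      }
      tab[[f]] <- cell
    }
    tab
  })

  # macro labels: families from tree clades, regions from longitude bands
  fam <- cutree(hclust(as.dist(ape::cophenetic.phylo(tree)), method = "average"),
                k = min(5, max(2, n %/% 6)))
  famLab <- setNames(paste0("fam", fam), names(fam))
  regBreaks <- quantile(geo$longitude, c(0, 1/3, 2/3, 1))
  regBreaks[1] <- -Inf; regBreaks[length(regBreaks)] <- Inf
  regLab <- setNames(paste0("region", as.integer(cut(geo$longitude, regBreaks))),
                     geo$society)
  songs$family <- unname(famLab[songs$society])
  songs$region <- unname(regLab[songs$society])

  genotypes <- withSeed(splitSeed(cfg$seed, 6), {
    p0 <- runif(cfg$nSnps, 0.1, 0.9)
    freq <- bnOnTree(tree, p0, cfg$driftF)
    rows <- list()
    for (i in seq_len(n)) {
      g <- matrix(rbinom(cfg$indivPerPop * cfg$nSnps, 2,
                         rep(freq[socs[i], ], each = cfg$indivPerPop)),
                  cfg$indivPerPop, cfg$nSnps)
      df <- data.frame(individual = sprintf("%s_ind%02d", socs[i],
                                            seq_len(cfg$indivPerPop)),
                       population = socs[i], stringsAsFactors = FALSE)
      colnames(g) <- sprintf("snp%04d", seq_len(cfg$nSnps))
      rows[[i]] <- cbind(df, as.data.frame(g))
    }
    do.call(rbind, rows)
  })
  rownames(genotypes) <- NULL

  new("SimWorld", tree = tree, geo = geo, latents = latents, songs = songs,
      genotypes = genotypes,
      config = c(cfg[setdiff(names(cfg), c("latentSpec", "scheme"))],
                 list(trueLoadings = lam)))
}

#' Write a simulated world to plain-text fixtures
#'
#' Emits songs.tsv, geo.csv, tree.nwk, genotypes.csv and truth.json
#' (generating parameters, true loadings, true latent means) into a
#' directory.
#'
#' @param world a \linkS4class{SimWorld}.
#' @param dir output directory (created if absent).
#' @return named vector of file paths, invisibly.
#' @export
emitFixtures <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(songs = file.path(dir, "songs.tsv"),
             geo = file.path(dir, "geo.csv"),
             tree = file.path(dir, "tree.nwk"),
             genotypes = file.path(dir, "genotypes.csv"),
             truth = file.path(dir, "truth.json"))
  writeSongTable(world@songs, paths["songs"])
  geoOut <- world@geo
  geoOut$longitude <- format(geoOut$longitude, digits = 17, trim = TRUE)
  geoOut$latitude <- format(geoOut$latitude, digits = 17, trim = TRUE)
  write.csv(geoOut, paths["geo"], row.names = FALSE, quote = FALSE)
  writeNewickTree(world@tree, paths["tree"])
  writeGenotypePanel(world@genotypes, paths["genotypes"])
  truth <- world@config
  truth$trueLatents <- as.data.frame(world@latents)
  truth$loadings <- NULL  # duplicated by trueLoadings
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
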