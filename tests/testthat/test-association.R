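test_that("principal coordinates reproduce known geometries", {
  # collinear points 0, 1, 2: one positive axis holding all the variance
  pts <- c(p0 = 0, p1 = 1, p2 = 2)
  m <- abs(outer(pts, pts, "-"))
  dimnames(m) <- list(names(pts), names(pts))
  p <- pcoa(DistMat(m))
  expect_equal(sum(p@percentVar > 1e-8), 1)
  expect_equal(p@percentVar[1], 100)
  # Euclidean distances from 2-D coordinates are reproduced exactly
  withr::with_seed(71, {
    X <- matrix(rnorm(16), 8, 2)
    dm <- DistMat(as.matrix(dist(X)), labels = paste0("u", 1:8))
    p2 <- pcoa(dm)
    expect_equal(as.matrix(dist(p2@coords)), as.matrix(dm), tolerance = 1e-8,
                 ignore_attr = TRUE)
  })
  # equilateral triple: two equal positive eigenvalues at 50% each
  eq <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(eq) <- 0
  p3 <- pcoa(DistMat(eq))
  expect_equal(p3@percentVar, c(50, 50), tolerance = 1e-8)
  expect_equal(ncol(pcoaAxes(p3, minPercent = 10)), 2)  # both retained
  expect_error(pcoa(DistMat(eq[1:2, 1:2])), ">= 3")
})

test_that("principal coordinates agree with the independent cmdscale oracle", {
  withr::with_seed(73, {
    for (rep in 1:8) {
      dm <- randomDistMat(7, seed = 900 + rep)
      p <- pcoa(dm)
      ora <- suppressWarnings(cmdscale(as.matrix(dm), k = 6, eig = TRUE))
      keep <- ora$eig > max(abs(ora$eig)) * 1e-9
      expect_equal(sort(p@eigenvalues, decreasing = TRUE)[seq_len(sum(keep))],
                   sort(ora$eig[keep], decreasing = TRUE), tolerance = 1e-8)
      expect_equal(abs(p@coords[, 1]), abs(ora$points[, 1]), tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
  })
})

test_that("Mantel r is symmetric, exact on self-comparison, and matches vegan", {
  a <- randomDistMat(10, seed = 81)
  b <- randomDistMat(10, seed = 82)
  expect_equal(mantel(a, a, nPerm = 0)@statistic, 1)
  expect_identical(mantel(a, b, nPerm = 0)@statistic,
                   mantel(b, a, nPerm = 0)@statistic)
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(as.dist(as.matrix(a)), as.dist(as.matrix(b)),
                      permutations = 0)
  expect_equal(mantel(a, b, nPerm = 0)@statistic, unname(vg$statistic),
               tolerance = 1e-12)
})

test_that("Mantel permutation p at n = 4 matches exhaustive enumeration", {
  withr::with_seed(83, {
    for (rep in 1:6) {
      a <- randomDistMat(4, seed = 1000 + rep)
      b <- randomDistMat(4, seed = 2000 + rep)
      exact <- oracleMantelP4(as.matrix(a), as.matrix(b))
      res <- mantel(a, b, nPerm = 4999, seed = rep)
      expect_lt(abs(res@p - exact), 0.04)
    }
  })
})

test_that("independent matrices rarely look associated", {
  withr::with_seed(89, {
    hits <- replicate(60, {
      a <- randomDistMat(50, seed = sample.int(1e6, 1))
      b <- randomDistMat(50, seed = sample.int(1e6, 1))
      res <- mantel(a, b, nPerm = 99, seed = sample.int(1e6, 1))
      abs(res@statistic) < 0.3 && res@p > 0.01
    })
    expect_gte(mean(hits), 0.95)
  })
})

test_that("partial Mantel controls correctly and matches vegan", {
  withr::with_seed(97, {
    a <- randomDistMat(12, seed = 301)
    b <- randomDistMat(12, seed = 302)
    c <- randomDistMat(12, seed = 303)
    pm <- partialMantel(a, b, c, nPerm = 0)
    skip_if_not_installed("vegan")
    vp <- vegan::mantel.partial(as.dist(as.matrix(a)), as.dist(as.matrix(b)),
                                as.dist(as.matrix(c)), permutations = 0)
    expect_equal(pm@statistic, unname(vp$statistic), tolerance = 1e-10)
  })
  # controlling for the explanatory itself leaves nothing
  a <- randomDistMat(12, seed = 304)
  b <- randomDistMat(12, seed = 305)
  expect_lt(abs(partialMantel(a, b, b, nPerm = 0)@statistic), 1e-10)
  # fully degenerate case: zero residual variance
  expect_error(partialMantel(a, a, a, nPerm = 0), "residual")
  # an unrelated conditioning matrix barely changes the statistic
  withr::with_seed(101, {
    diffs <- replicate(20, {
      x <- randomDistMat(30, seed = sample.int(1e6, 1))
      y <- randomDistMat(30, seed = sample.int(1e6, 1))
      z <- randomDistMat(30, seed = sample.int(1e6, 1))
      abs(mantel(x, y, nPerm = 0)@statistic -
            partialMantel(x, y, z, nPerm = 0)@statistic)
    })
    expect_lt(median(diffs), 0.05)
  })
})

test_that("redundancy analysis follows the Ezekiel arithmetic and its limits", {
  a <- randomDistMat(12, seed = 401)
  # explanatory = response: perfect fit
  expect_equal(partialRda(a, a, nPerm = 0)@statistic, 1, tolerance = 1e-10)
  # R2 = 0.5, n = 11, m = 1: adjusted = 1 - 0.5 * 10 / 9
  expect_equal(1 - (1 - 0.5) * (11 - 1) / (11 - 1 - 1), 0.4444444444444444)
  # single-axis RDA is the Ezekiel-adjusted squared correlation of the axes
  withr::with_seed(103, {
    x <- sort(rnorm(15)); y <- x + rnorm(15, 0, 0.4)
    dmx <- DistMat(abs(outer(x, x, "-")), labels = paste0("u", 1:15))
    dmy <- DistMat(abs(outer(y, y, "-")), labels = paste0("u", 1:15))
    res <- partialRda(dmy, dmx, nPerm = 49, seed = 2)
    ax <- pcoaAxes(pcoa(dmx)); ay <- pcoaAxes(pcoa(dmy))
    expect_equal(ncol(ax), 1)
    r2 <- cor(ax[, 1], ay[, 1])^2
    n <- 15
    expect_equal(res@statistic, 1 - (1 - r2) * (n - 1) / (n - 2),
                 tolerance = 1e-10)
    expect_lt(res@p, 0.05)
  })
  # overparameterization guard
  tiny <- randomDistMat(4, seed = 402, dim = 8)
  wide <- randomDistMat(4, seed = 403, dim = 8)
  expect_error(suppressWarnings(partialRda(
    tiny, wide, nPerm = 0, minPercent = 0)), "overparameterized")
})

test_that("partial RDA separates shared-tree signal from independent noise", {
  # music evolved on the same tree as language explains more than genes
  # evolved on an unrelated tree
  withr::with_seed(107, {
    tr1 <- ape::rcoal(25)
    tr2 <- ape::rcoal(25)
    lang <- patristicMatrix(tr1)
    genesIndep <- patristicMatrix(tr2)
    music <- DistMat(as.matrix(dist(
      sapply(1:5, function(i) songlines:::bmOnTree(tr1, 1)))),
      labels = tr1$tip.label)
    rLang <- partialRda(music, lang, nPerm = 0)@statistic
    rGenes <- partialRda(music, genesIndep, nPerm = 0)@statistic
    expect_gt(rLang, rGenes)
  })
})

test_that("permutation-based adjustment and the association grid behave", {
  a <- randomDistMat(15, seed = 501)
  b <- randomDistMat(15, seed = 502)
  c <- randomDistMat(15, seed = 503)
  rp <- partialRda(a, b, nPerm = 199, seed = 3, adjust = "permutation")
  re <- partialRda(a, b, nPerm = 199, seed = 3)
  expect_equal(rp@extra$r2, re@extra$r2)
  expect_false(identical(rp@statistic, re@statistic))
  grid <- associationGrid(a, list(B = b, C = c), nPerm = 49, seed = 4,
                          responseName = "resp")
  expect_equal(nrow(grid), 2)
  expect_setequal(grid$predictor, c("B", "C"))
  expect_true(all(grid$conditioning != grid$predictor))
  expect_true(all(grid$mantel_p > 0 & grid$mantel_p <= 1))
})
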