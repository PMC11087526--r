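randomGeo <- function(n, seed, labels = sprintf("u%02d", seq_len(n))) {
  withr::with_seed(seed, data.frame(society = labels,
                                    longitude = runif(n, -60, 60),
                                    latitude = runif(n, -50, 50)))
}

test_that("class r equals the explicit double-loop oracle", {
  # 4-society hand-sized example
  geo <- data.frame(society = c("a", "b", "c", "d"),
                    longitude = c(0, 1, 20, 21), latitude = c(0, 0, 10, 10))
  gd <- haversineMatrix(geo)
  td <- randomDistMat(4, seed = 3, labels = c("a", "b", "c", "d"))
  spec <- distanceClasses(1000, 4000)
  v <- autocorrVariogram(td, gd, spec, nPerm = 0, nBoot = 0)
  expect_equal(v@table$r, oracleAutocorr(td, gd, 1000, 4000), tolerance = 1e-12)
  # random instances
  withr::with_seed(19, {
    for (rep in 1:10) {
      n <- sample(5:9, 1)
      labs <- sprintf("u%02d", 1:n)
      geo <- randomGeo(n, seed = 500 + rep, labels = labs)
      gd <- haversineMatrix(geo)
      td <- randomDistMat(n, seed = 600 + rep, labels = labs)
      v <- autocorrVariogram(td, gd, distanceClasses(2500, 15000),
                             nPerm = 0, nBoot = 0)
      expect_equal(v@table$r, oracleAutocorr(td, gd, 2500, 15000),
                   tolerance = 1e-12)
    }
  })
})

test_that("distance classes partition all pairs exhaustively and disjointly", {
  labs <- sprintf("u%02d", 1:10)
  geo <- randomGeo(10, seed = 7, labels = labs)
  gd <- haversineMatrix(geo)
  td <- randomDistMat(10, seed = 8, labels = labs)
  spec <- distanceClasses(2000, 20000)   # covers every possible pair
  v <- autocorrVariogram(td, gd, spec, nPerm = 0, nBoot = 0)
  expect_equal(sum(v@table$n_pairs), choose(10, 2))
  # per-class numerators sum to the total off-diagonal sum of C
  C <- gowerCenter(td)
  G <- as.matrix(gd)
  tot <- 0
  for (k in seq_along(spec$edges)) {
    sel <- upper.tri(G) & (songlines:::pairClass(G, spec) == k)
    tot <- tot + 2 * sum(C[sel])
  }
  expect_equal(tot, sum(C) - sum(diag(C)), tolerance = 1e-8)
})

test_that("traits built from the coordinates are significantly autocorrelated nearby", {
  withr::with_seed(29, {
    n <- 25
    labs <- sprintf("u%02d", 1:n)
    geo <- data.frame(society = labs, longitude = runif(n, -40, 40),
                      latitude = runif(n, -40, 40))
    gd <- haversineMatrix(geo)
    td <- DistMat(as.matrix(dist(cbind(geo$longitude, geo$latitude))),
                  labels = labs)
    v <- autocorrVariogram(td, gd, distanceClasses(2000, 12000),
                           nPerm = 199, nBoot = 49, seed = 5)
    expect_gt(v@table$r[1], 0)
    expect_lt(v@table$p[1], 0.05)
    expect_equal(significantRange(v, alpha = 0.05) >= 2000, TRUE)
    # bootstrap CI brackets the estimate in the first class
    expect_lte(v@table$ci_lo[1], v@table$r[1])
    expect_gte(v@table$ci_hi[1], v@table$r[1])
  })
})

test_that("random traits show no systematic autocorrelation", {
  withr::with_seed(37, {
    ps <- replicate(20, {
      n <- 16
      labs <- sprintf("u%02d", 1:n)
      geo <- data.frame(society = labs, longitude = runif(n, -40, 40),
                        latitude = runif(n, -40, 40))
      td <- randomDistMat(n, seed = sample.int(1e6, 1), labels = labs)
      v <- autocorrVariogram(td, haversineMatrix(geo),
                             distanceClasses(4000, 12000),
                             nPerm = 99, nBoot = 0, seed = sample.int(1e6, 1))
      v@table$p[1]
    })
    # permutation p should behave like a null p-value, not pile up low
    expect_gt(mean(ps, na.rm = TRUE), 0.25)
    expect_lt(mean(ps < 0.05, na.rm = TRUE), 0.3)
  })
})

test_that("the significant range walks classes until the first failure", {
  tab <- data.frame(class_upper_km = c(500, 1000, 1500, 2000),
                    n_pairs = 5, r = c(0.4, 0.3, 0.2, 0.1),
                    p = c(0.001, 0.001, 0.5, 0.001),
                    ci_lo = NA, ci_hi = NA)
  v <- new("Variogram", table = tab, bandKm = 500, maxKm = 2000,
           nPerm = 999, nBoot = 0)
  expect_equal(significantRange(v), 1000)
  v@table$p <- rep(0.001, 4)
  expect_equal(significantRange(v), 2000)       # all significant -> max
  v@table$p[1] <- 0.5
  expect_equal(significantRange(v), 0)          # none -> 0
  v@table$p <- rep(0.001, 4); v@table$r[2] <- -0.1
  expect_equal(significantRange(v), 500)        # positive r required
  expect_equal(meanAutocorr(v, 1000), mean(c(0.4, -0.1)))
})

test_that("empty classes are flagged, not fatal, and inputs are validated", {
  labs <- c("a", "b", "c", "d")
  geo <- data.frame(society = labs, longitude = c(0, 0.5, 0, 0.5),
                    latitude = c(0, 0, 0.5, 0.5))
  gd <- haversineMatrix(geo)
  td <- randomDistMat(4, seed = 4, labels = labs)
  v <- autocorrVariogram(td, gd, distanceClasses(500, 2000), nPerm = 19,
                         nBoot = 0, seed = 2)
  expect_true(all(is.na(v@table$r[v@table$n_pairs == 0])))
  expect_true(all(v@table$n_pairs[1] > 0))
  expect_error(distanceClasses(500, 1750), "multiple")
  expect_error(distanceClasses(-1, 2000), "invalid")
})
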