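test_that("single-code selection is seeded, minimal, and reports its scope", {
  st <- tinySongTable()
  expect_message(out1 <- selectSingleCode(st, seed = 1), "multi-coded")
  # singleton cells untouched
  expect_identical(out1$line_8[1:2], st$line_8[1:2])
  expect_identical(out1$line_9, st$line_9)
  # resolved cell is one of the listed codes
  expect_true(out1$line_8[3] %in% c("4", "13"))
  # deterministic given seed
  out2 <- suppressMessages(selectSingleCode(st, seed = 1))
  expect_identical(out1, out2)
  # different seeds change only multi-coded cells
  outs <- lapply(1:20, function(s) suppressMessages(selectSingleCode(st, seed = s)))
  for (o in outs) {
    expect_identical(o$line_8[-3], st$line_8[-3])
    expect_identical(o$line_9, st$line_9)
  }
  expect_gt(length(unique(vapply(outs, function(o) o$line_8[3], ""))), 1)
  bad <- st; bad$line_8[2] <- ""
  expect_error(suppressMessages(selectSingleCode(bad, seed = 1)), "line_8")
  expect_error(selectSingleCode(st), "seed")
})

test_that("standardisation maps ranks to [0,1], honours reversal, and is idempotent", {
  st <- suppressMessages(selectSingleCode(tinySongTable(), seed = 1))
  sch <- tinyScheme()
  out <- standardizeCodes(st, sch)
  # endpoints
  expect_equal(out$line_8[st$line_8 == "13"], 1)
  expect_equal(out$line_8[st$line_8 == "1"], 0)
  # reversal: code 1 on a reversed feature becomes 1.0
  expect_equal(out$line_9[st$line_9 == "1"], c(1, 1))
  expect_equal(out$line_9[st$line_9 == "13"], 0)
  # 3-level ordinal: middle code is 0.5 regardless of spacing
  sch3 <- list(features = list(line_8 = list(codes = c(1, 7, 13), include = TRUE)),
               keep = character())
  st3 <- data.frame(song = "s1", society = "A", family = "f", region = "r",
                    line_8 = "7", stringsAsFactors = FALSE)
  expect_equal(standardizeCodes(st3, sch3)$line_8, 0.5)
  # idempotence
  expect_equal(standardizeCodes(out, sch), out)
  # out-of-set code errors with the feature named
  stBad <- st; stBad$line_8[1] <- "2"
  expect_error(standardizeCodes(stBad, sch), "line_8")
  # constant feature dropped with warning
  schC <- sch
  schC$features$line_9$codes <- 5
  expect_warning(outC <- standardizeCodes(st, schC), "line_9")
  expect_false("line_9" %in% colnames(outC))
})

test_that("minimum-song filter keeps exactly the societies at or above k", {
  st <- tinySongTable()
  out <- suppressMessages(filterMinSongs(st, 2))
  expect_setequal(unique(out$society), c("A", "B"))
  expect_identical(suppressMessages(filterMinSongs(st, 1))[, -1],
                   st[, -1])  # identity apart from row names
  out3 <- suppressMessages(filterMinSongs(st, 3))
  expect_setequal(unique(out3$society), "A")
  expect_error(suppressMessages(filterMinSongs(st, 10)), "no societies")
  expect_error(filterMinSongs(st, 0), ">= 1")
})

test_that("reliability filter excludes below-threshold features except the keep-list", {
  sch <- list(features = list(
    f1 = list(codes = 1:3, kappa = 0.39, include = TRUE),
    f2 = list(codes = 1:3, kappa = 0.40, include = TRUE),
    f3 = list(codes = 1:3, kappa = 0.20, include = TRUE),
    f4 = list(codes = 1:3, kappa = 0.95, include = TRUE)),
    keep = "f3")
  expect_warning(out <- filterReliability(sch, 0.4), "f3")
  expect_false(out$features$f1$include)
  expect_true(out$features$f2$include)   # threshold is a strict inequality
  expect_true(out$features$f3$include)   # keep-list overrides
  expect_true(out$features$f4$include)
  noKappa <- sch; noKappa$features$f1$kappa <- NULL
  expect_error(filterReliability(noKappa, 0.4), "f1")
})

test_that("society profiles are per-feature means over songs", {
  st <- data.frame(song = paste0("s", 1:4),
                   society = c("A", "B", "B", "C"),
                   family = "f", region = "r",
                   x = c(0.2, 0, 1, 0.7), y = c(0.4, 1, 0, 0.1),
                   stringsAsFactors = FALSE)
  prof <- societyProfile(st)
  expect_equal(prof["A", ], c(x = 0.2, y = 0.4))  # one-song society
  expect_equal(prof["B", ], c(x = 0.5, y = 0.5))  # mean of (0,1) and (1,0)
  expect_equal(prof["C", ], c(x = 0.7, y = 0.1))
  expect_error(societyProfile(tinySongTable()), "standardized")
})

test_that("re-running the seeded prep changes factor scores only marginally", {
  # multi-coded cells (3% of the table) are the only seed-sensitive input;
  # scores from independently resolved tables should agree strongly
  world <- simulateWorld(simConfig(nSocieties = 20, songsPerSociety = 15,
                                   nSnps = 10, indivPerPop = 2, seed = 60))
  spec <- defaultLatentSpec()
  scheme <- defaultCodingScheme()
  scores <- lapply(1:3, function(s) {
    st <- suppressMessages(selectSingleCode(world@songs, seed = s))
    st <- standardizeCodes(st, scheme)
    fit <- fitCfa(st, spec, restarts = 1, seed = 1)
    factorScores(fit, st)
  })
  for (a in 2:3) {
    cors <- diag(cor(scores[[1]], scores[[a]]))
    expect_true(all(cors > 0.95))
  }
})
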