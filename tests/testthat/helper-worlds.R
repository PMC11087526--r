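# Shared fixture builders. Everything is generated in code at test time.

randomDistMat <- function(n, seed, labels = sprintf("u%02d", seq_len(n)),
                          dim = 3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * dim), n)
    m <- as.matrix(dist(X))
    dimnames(m) <- list(labels, labels)
    DistMat(m)
  })
}

tinySongTable <- function() {
  data.frame(
    song = paste0("s", 1:6),
    society = c("A", "A", "A", "B", "B", "C"),
    family = c("f1", "f1", "f1", "f1", "f1", "f2"),
    region = "r1",
    line_8 = c("1", "4", "4|13", "7", "10", "13"),
    line_9 = c("13", "10", "7", "4", "1", "1"),
    stringsAsFactors = FALSE
  )
}

tinyScheme <- function() {
  list(features = list(
    line_8 = list(codes = c(1, 4, 7, 10, 13), reversed = FALSE, kappa = 0.7,
                  include = TRUE),
    line_9 = list(codes = c(1, 4, 7, 10, 13), reversed = TRUE, kappa = 0.5,
                  include = TRUE)),
    keep = character())
}

smallWorld <- function(seed = 3, ...) {
  simulateWorld(simConfig(nSocieties = 12, songsPerSociety = 5, nSnps = 120,
                          indivPerPop = 6, seed = seed, ...))
}

# society-level mean factor-score distances for a world (true latents)
worldMusicDist <- function(world) {
  DistMat(as.matrix(dist(world@latents)))
}
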