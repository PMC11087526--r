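#' @name pipeline-module
#' @title End-to-end comparative pipeline
#'
#' @description
#' Runs the full flow on one set of inputs: prepare the song table
#' (single-code resolution, 0-1 standardisation, minimum-song filter),
#' fit the latent model and score songs, decompose variance by AMOVA,
#' build the per-dimension and aggregate Phi_ST matrices, the genetic
#' F_ST matrix, the geographic and patristic distance matrices, the
#' spatial autocorrelation variograms, delta scores by region, and the
#' partial association grid. Every stage writes a tidy CSV/JSON
#' artifact; a manifest lists them with MD5 hashes. Deterministic given
#' the seeds in the run configuration.
NULL

#' Read a pipeline run configuration from YAML
#'
#' Fields: \code{input} (paths songs/geo/tree/genotypes), \code{minSongs}
#' (default 2), \code{seed}, \code{nPerm}, \code{band_km}/\code{max_km},
#' \code{deltaSampleSize}, \code{outputDir}, optional \code{modelSpec}
#' and \code{scheme} paths.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("songs", "geo", "tree", "genotypes")) {
    p <- cfg$input[[f]]
    if (is.null(p) || !file.exists(p)) stop("input file missing for '", f, "': ", p)
  }
  cfg$minSongs <- cfg$minSongs %||% 2
  cfg$seed <- cfg$seed %||% 1
  cfg$nPerm <- cfg$nPerm %||% 999
  cfg$band_km <- cfg$band_km %||% 500
  cfg$max_km <- cfg$max_km %||% 20000
  cfg
}

writeStage <- function(obj, path) {
  if (is.data.frame(obj)) {
    write.csv(obj, path, row.names = !is.null(rownames(obj)) &&
                !identical(rownames(obj), as.character(seq_len(nrow(obj)))))
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  path
}

amovaAsDf <- function(a) {
  data.frame(component = names(a@components), df = unname(a@df),
             SS = unname(a@ss), variance = unname(a@components),
             percent = unname(a@percentages))
}

#' Run the full comparative pipeline
#'
#' @param config a run configuration (list or YAML path; see
#'   \code{\link{readRunConfig}}).
#' @return manifest list (also written to \code{manifest.json} in the
#'   output directory): per stage, the artifact path and MD5 hash.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  outDir <- config$outputDir %||% "pipeline_out"
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  seed <- config$seed %||% 1
  nPerm <- config$nPerm %||% 999
  artifacts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  scheme <- if (!is.null(config$scheme)) readCodingScheme(config$scheme) else
    defaultCodingScheme()
  modelSpec <- if (!is.null(config$modelSpec)) readLatentSpec(config$modelSpec) else
    defaultLatentSpec()

  songs <- stage("read", readSongTable(config$input$songs))
  geo <- stage("read", readGeoTable(config$input$geo))
  tree <- stage("read", readNewickTree(config$input$tree))
  panel <- stage("read", readGenotypePanel(config$input$genotypes))

  prep <- stage("prep", {
    st <- selectSingleCode(songs, seed = splitSeed(seed, 1))
    st <- standardizeCodes(st, scheme)
    filterMinSongs(st, config$minSongs %||% 2)
  })
  artifacts$prep <- writeStage(prep, file.path(outDir, "songs_standardized.csv"))

  fit <- stage("cfa", fitCfa(prep, modelSpec, restarts = config$restarts %||% 5,
                             seed = splitSeed(seed, 2)))
  artifacts$cfa <- writeStage(list(
    converged = fit@converged, fml = fit@fml, chisq = fit@chisq, df = fit@df,
    n = fit@n, rmsea = fit@rmsea, rmsea_ci = fit@rmseaCI, srmr = fit@srmr,
    cfi = fit@cfi, loadings = as.data.frame(fit@loadings),
    latent_correlations = as.data.frame(fit@latentCor)),
    file.path(outDir, "cfa_fit.json"))

  scores <- stage("scores", factorScores(fit, prep))
  artifacts$scores <- writeStage(
    data.frame(song = prep$song, society = prep$society, scores),
    file.path(outDir, "factor_scores.csv"))

  am <- stage("amova", amova(scores, prep$society, group = prep$family,
                             nPerm = nPerm, seed = splitSeed(seed, 3)))
  artifacts$amova <- writeStage(amovaAsDf(am), file.path(outDir, "amova.csv"))

  phist <- stage("phist", {
    out <- list(All = pairwisePhist(as.matrix(
      prep[, featureCols(prep), drop = FALSE]), prep$society,
      minSongs = config$minSongs %||% 2))
    for (v in colnames(scores)) {
      out[[v]] <- pairwisePhist(scores[, v, drop = FALSE], prep$society,
                                minSongs = config$minSongs %||% 2)
    }
    out
  })
  for (v in names(phist)) {
    artifacts[[paste0("phist_", v)]] <-
      writeDistMat(phist[[v]], file.path(outDir, paste0("phist_", v, ".csv")))
  }

  fst <- stage("fst", wcFstMatrix(panel))
  artifacts$fst <- writeDistMat(fst, file.path(outDir, "fst.csv"))

  geoD <- stage("geo", haversineMatrix(geo))
  lingD <- stage("patristic", patristicMatrix(tree))
  artifacts$geo_dist <- writeDistMat(geoD, file.path(outDir, "geo_dist.csv"))
  artifacts$patristic <- writeDistMat(lingD, file.path(outDir, "patristic.csv"))

  vario <- stage("variogram", {
    spec <- distanceClasses(config$band_km %||% 500, config$max_km %||% 20000)
    list(music = autocorrVariogram(phist$All, geoD, spec, nPerm = nPerm,
                                   nBoot = nPerm, seed = splitSeed(seed, 4)),
         genes = autocorrVariogram(fst, geoD, spec, nPerm = nPerm,
                                   nBoot = nPerm, seed = splitSeed(seed, 5)),
         language = autocorrVariogram(lingD, geoD, spec, nPerm = nPerm,
                                      nBoot = nPerm, seed = splitSeed(seed, 6)))
  })
  for (v in names(vario)) {
    artifacts[[paste0("variogram_", v)]] <- writeStage(
      vario[[v]]@table, file.path(outDir, paste0("variogram_", v, ".csv")))
  }

  delta <- stage("delta", {
    prof <- societyProfile(prep)
    socScores <- rowsum(scores, prep$society) /
      as.vector(table(prep$society)[sort(unique(prep$society))])
    regOf <- vapply(rownames(prof), function(s)
      prep$region[prep$society == s][1], "")
    nPer <- table(regOf)
    ss <- config$deltaSampleSize %||% min(50, min(nPer))
    deltaByRegion(socScores, regOf[rownames(socScores)], sampleSize = ss,
                  dists = phist, seed = splitSeed(seed, 7))
  })
  artifacts$delta <- writeStage(data.frame(variable = rownames(delta), delta),
                                file.path(outDir, "delta_scores.csv"))

  assoc <- stage("associations", {
    preds <- list(Genes = fst, Language = lingD, Geography = geoD)
    grids <- lapply(names(phist), function(v) {
      associationGrid(phist[[v]], preds, nPerm = nPerm,
                      seed = splitSeed(seed, 8), responseName = v)
    })
    do.call(rbind, grids)
  })
  artifacts$associations <- writeStage(assoc, file.path(outDir, "associations.csv"))

  manifest <- lapply(artifacts, function(p)
    list(path = p, md5 = unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
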