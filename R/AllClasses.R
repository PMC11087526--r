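#' @import methods
#' @importFrom stats cor cov dist lm optim pchisq pnorm qnorm quantile
#'   residuals rnorm runif rbeta rbinom sd setNames uniroot var nlminb
#'   complete.cases rexp hclust cutree as.dist reorder
#' @importFrom utils combn head read.csv write.csv read.delim write.table
#' @importFrom tools md5sum
NULL

#' Labelled society-level distance matrix
#'
#' The lingua franca between all pipeline stages: a square, symmetric,
#' zero-diagonal matrix of pairwise distances between labelled units
#' (societies, populations, languages). Units of the values depend on the
#' source: kilometres (geography), F_ST (genes), Phi_ST (music), or branch
#' length (patristic distance on a phylogeny).
#'
#' @slot values numeric matrix, square and symmetric with zero diagonal;
#'   dimnames carry the unit labels.
#' @export
setClass("DistMat", representation(values = "matrix"), validity = function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "matrix must be square")
  lab <- rownames(v)
  if (is.null(lab) || is.null(colnames(v))) {
    msgs <- c(msgs, "row and column labels are required")
  } else {
    if (!identical(lab, colnames(v))) msgs <- c(msgs, "row and column labels must match")
    if (anyDuplicated(lab)) msgs <- c(msgs, "labels must be unique")
  }
  if (any(!is.finite(v)) && !all(is.na(v[!is.finite(v)]))) {
    msgs <- c(msgs, "values must be finite or NA")
  }
  if (nrow(v) == ncol(v)) {
    if (max(abs(v - t(v)), na.rm = TRUE) > 1e-10) msgs <- c(msgs, "matrix must be symmetric within 1e-10")
    if (max(abs(diag(v)), na.rm = TRUE) > 1e-10) msgs <- c(msgs, "diagonal must be zero")
  }
  if (length(msgs)) msgs else TRUE
})

#' Confirmatory factor analysis fit
#'
#' Maximum-likelihood fit of a latent measurement model: loadings,
#' latent correlations, residual (co)variances, the minimised ML
#' discrepancy, and absolute/relative fit indices.
#'
#' @slot loadings indicator x latent matrix of completely standardized
#'   loadings (zeros where an indicator does not load).
#' @slot latentCor latent correlation matrix.
#' @slot residuals residual covariance matrix of the indicators
#'   (standardized metric).
#' @slot fml minimised ML discrepancy.
#' @slot chisq,df,n likelihood-ratio statistic, model degrees of freedom,
#'   and sample size.
#' @slot rmsea,rmseaCI,srmr,cfi fit indices; \code{rmseaCI} is the 90\%
#'   confidence interval.
#' @slot converged logical convergence flag.
#' @slot sampleCov sample correlation matrix the model was fitted to.
#' @slot center,scale sample means and standard deviations of the
#'   indicators, used for factor scoring.
#' @export
setClass("CfaFit", representation(
  loadings = "matrix", latentCor = "matrix", residuals = "matrix",
  fml = "numeric", chisq = "numeric", df = "numeric", n = "numeric",
  rmsea = "numeric", rmseaCI = "numeric", srmr = "numeric", cfi = "numeric",
  converged = "logical", sampleCov = "matrix",
  center = "numeric", scale = "numeric"))

#' Hierarchical AMOVA decomposition
#'
#' Variance components of song-level squared Euclidean distances
#' decomposed across a one- or two-level grouping hierarchy, with the
#' derived Phi fixation statistics.
#'
#' @slot components named numeric vector of raw variance components
#'   (among groups, among societies within groups, within societies);
#'   negative components are reported as-is.
#' @slot percentages components as percentages of their sum.
#' @slot phi named vector of Phi statistics (PhiCT, PhiSC, PhiST as
#'   applicable).
#' @slot ss,df sums of squares and degrees of freedom per stratum.
#' @slot pvalues permutation p-values for the Phi statistics (NA when no
#'   permutations were run).
#' @slot nPerm number of permutations used.
#' @export
setClass("AmovaResult", representation(
  components = "numeric", percentages = "numeric", phi = "numeric",
  ss = "numeric", df = "numeric", pvalues = "numeric", nPerm = "numeric"))

#' Distance-class spatial autocorrelation profile
#'
#' Per-distance-class multivariate autocorrelation coefficients r with
#' permutation p-values and bootstrap confidence intervals — the
#' "variogram" view of how similarity decays with geographic separation.
#'
#' @slot table data.frame with one row per distance class:
#'   class_upper_km, n_pairs, r, p, ci_lo, ci_hi.
#' @slot bandKm,maxKm distance class width and maximum distance (km).
#' @slot nPerm,nBoot permutation and bootstrap replicate counts.
#' @export
setClass("Variogram", representation(
  table = "data.frame", bandKm = "numeric", maxKm = "numeric",
  nPerm = "numeric", nBoot = "numeric"))

#' Principal coordinates of a distance matrix
#'
#' Eigen-embedding of the Gower-centered squared distances. Axes are
#' sorted by decreasing eigenvalue; percent variance is computed over the
#' positive-eigenvalue total only.
#'
#' @slot coords unit x axis coordinate matrix (positive axes only).
#' @slot eigenvalues all eigenvalues, sorted descending.
#' @slot percentVar percent of positive-eigenvalue variance per positive
#'   axis.
#' @export
setClass("PcoaResult", representation(
  coords = "matrix", eigenvalues = "numeric", percentVar = "numeric"))

#' Matrix-association test result
#'
#' Result of a Mantel, partial Mantel, or (partial) redundancy analysis:
#' the association statistic, its permutation p-value, and a description
#' of the conditioning set.
#'
#' @slot statistic Mantel r or RDA adjusted R-squared.
#' @slot statName one of "mantel_r", "partial_mantel_r", "rda_adj_r2".
#' @slot p permutation p-value.
#' @slot nPerm number of permutations.
#' @slot conditioning description of the conditioning matrix ("" if none).
#' @slot extra named list of auxiliary quantities (e.g. unadjusted
#'   R-squared, axis counts).
#' @export
setClass("AssociationResult", representation(
  statistic = "numeric", statName = "character", p = "numeric",
  nPerm = "numeric", conditioning = "character", extra = "list"))

#' Synthetic comparative world with known ground truth
#'
#' A simulated system of societies: a dated society phylogeny, spatially
#' autocorrelated coordinates, latent musical trait means evolved on the
#' tree (optionally mixed horizontally between geographic neighbours),
#' songs with within-society noise coded on ordinal indicators, and a
#' biallelic genotype panel drifted along the same tree.
#'
#' @slot tree \code{ape::phylo} society tree.
#' @slot geo data.frame with society, longitude, latitude.
#' @slot latents society x latent matrix of true trait means (after
#'   horizontal mixing).
#' @slot songs song-level table of ordinal indicator codes plus labels.
#' @slot genotypes genotype panel data.frame (individual, population,
#'   dosage columns).
#' @slot config the generating configuration list.
#' @export
setClass("SimWorld", representation(
  tree = "ANY", geo = "data.frame", latents = "matrix",
  songs = "data.frame", genotypes = "data.frame", config = "list"))

setMethod("show", "DistMat", function(object) {
  v <- object@values
  cat(sprintf("DistMat: %d units\n", nrow(v)))
  cat("labels:", paste(head(rownames(v), 5), collapse = ", "),
      if (nrow(v) > 5) "..." else "", "\n")
  cat(sprintf("range: [%.4g, %.4g]\n", min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "CfaFit", function(object) {
  cat(sprintf("CfaFit: %d indicators, %d latents, N = %d%s\n",
              nrow(object@loadings), ncol(object@loadings), object@n,
              if (object@converged) "" else " (NOT CONVERGED)"))
  cat(sprintf("chi-square = %.2f on %d df; RMSEA = %.3f (90%% CI %.3f-%.3f); SRMR = %.3f; CFI = %.3f\n",
              object@chisq, object@df, object@rmsea,
              object@rmseaCI[1], object@rmseaCI[2], object@srmr, object@cfi))
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA variance components:\n")
  print(round(data.frame(df = object@df, SS = object@ss,
                         variance = object@components,
                         percent = object@percentages), 4))
  cat("Phi statistics:\n")
  print(round(object@phi, 4))
})

setMethod("show", "Variogram", function(object) {
  cat(sprintf("Variogram: %d classes of %g km up to %g km (%d permutations, %d bootstraps)\n",
              nrow(object@table), object@bandKm, object@maxKm,
              object@nPerm, object@nBoot))
  print(head(object@table, 8))
})

setMethod("show", "PcoaResult", function(object) {
  cat(sprintf("PCoA: %d units, %d positive axes\n",
              nrow(object@coords), ncol(object@coords)))
  cat("percent variance:", paste(sprintf("%.1f", head(object@percentVar, 6)),
                                 collapse = ", "), "\n")
})

setMethod("show", "AssociationResult", function(object) {
  cond <- if (nzchar(object@conditioning)) paste0(" | ", object@conditioning) else ""
  cat(sprintf("%s = %.4f%s (p = %.4g, %d permutations)\n",
              object@statName, object@statistic, cond, object@p, object@nPerm))
})

setMethod("show", "SimWorld", function(object) {
  cat(sprintf("SimWorld: %d societies, %d songs, %d individuals x %d SNPs\n",
              nrow(object@latents), nrow(object@songs), nrow(object@genotypes),
              sum(grepl("^snp", colnames(object@genotypes)))))
})
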