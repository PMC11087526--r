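#' Construct a labelled distance matrix
#'
#' Validates and wraps a square matrix of pairwise distances. Mild
#' asymmetry (up to \code{tol}) is symmetrised by averaging; larger
#' asymmetry is an error. The diagonal must be zero within \code{tol}.
#'
#' @param values square numeric matrix with matching row/column labels,
#'   or an object coercible via \code{as.matrix} (e.g. a \code{dist}).
#' @param labels optional character vector of labels overriding dimnames.
#' @param tol symmetry/diagonal tolerance before erroring (default 1e-8).
#' @return a \linkS4class{DistMat}.
#' @examples
#' m <- as.matrix(dist(matrix(rnorm(10), 5)))
#' rownames(m) <- colnames(m) <- letters[1:5]
#' DistMat(m)
#' @export
DistMat <- function(values, labels = NULL, tol = 1e-8) {
  v <- as.matrix(values)
  if (!is.null(labels)) {
    if (length(labels) != nrow(v)) stop("labels length must match matrix dimension")
    rownames(v) <- colnames(v) <- as.character(labels)
  }
  if (nrow(v) != ncol(v)) stop("distance matrix must be square")
  if (is.null(rownames(v))) stop("distance matrix requires labels")
  storage.mode(v) <- "double"
  asym <- max(abs(v - t(v)), na.rm = TRUE)
  if (asym > tol) stop(sprintf("matrix is asymmetric (max |d_ij - d_ji| = %g > %g)", asym, tol))
  v <- (v + t(v)) / 2
  dg <- max(abs(diag(v)), na.rm = TRUE)
  if (dg > tol) stop(sprintf("diagonal must be zero (max |d_ii| = %g)", dg))
  diag(v) <- 0
  new("DistMat", values = v)
}

#' @describeIn DistMat labels of a distance matrix.
#' @param x a DistMat.
#' @export
dmLabels <- function(x) rownames(x@values)

#' @export
setMethod("as.matrix", "DistMat", function(x, ...) x@values)

#' @export
setMethod("dim", "DistMat", function(x) dim(x@values))

#' Subset a distance matrix to a set of labels
#'
#' @param x a \linkS4class{DistMat}.
#' @param labels character vector of labels to retain, in the order given.
#' @return a \linkS4class{DistMat} restricted to \code{labels}.
#' @export
dmSubset <- function(x, labels) {
  missing <- setdiff(labels, dmLabels(x))
  if (length(missing)) stop("labels absent from matrix: ", paste(missing, collapse = ", "))
  DistMat(x@values[labels, labels, drop = FALSE])
}

#' Align several distance matrices on their shared labels
#'
#' @param ... DistMat objects.
#' @return list of DistMat objects subset to the common labels, in a
#'   common order.
#' @export
dmAlign <- function(...) {
  ms <- list(...)
  shared <- Reduce(intersect, lapply(ms, dmLabels))
  if (length(shared) < 3) stop("fewer than 3 shared labels across matrices")
  lapply(ms, dmSubset, labels = shared)
}

#' Great-circle distance matrix from coordinates
#'
#' Haversine distances in kilometres between all pairs of societies on a
#' sphere of the given radius.
#'
#' @param geo data.frame with columns \code{society}, \code{longitude},
#'   \code{latitude} (degrees).
#' @param radiusKm sphere radius in km (default 6371, the Earth's mean
#'   radius).
#' @return a \linkS4class{DistMat} in km.
#' @export
haversineMatrix <- function(geo, radiusKm = 6371) {
  validateGeoTable(geo)
  if (radiusKm <= 0) stop("radiusKm must be positive")
  xy <- as.matrix(geo[, c("longitude", "latitude")])
  d <- geosphere::distm(xy, fun = function(a, b) geosphere::distHaversine(a, b, r = radiusKm))
  rownames(d) <- colnames(d) <- as.character(geo$society)
  DistMat(d, tol = 1e-6)
}

#' Patristic distance matrix from a rooted tree
#'
#' Tip-to-tip path lengths (sum of branch lengths) on a phylogeny.
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @param tips optional subset of tip labels to retain.
#' @return a \linkS4class{DistMat} in branch-length units.
#' @export
patristicMatrix <- function(tree, tips = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  d <- ape::cophenetic.phylo(tree)
  d <- d[tree$tip.label, tree$tip.label]
  if (!is.null(tips)) {
    missing <- setdiff(tips, tree$tip.label)
    if (length(missing)) stop("tips absent from tree: ", paste(missing, collapse = ", "))
    d <- d[tips, tips, drop = FALSE]
  }
  DistMat(d, tol = 1e-8)
}

#' Matern distance-decay correlation
#'
#' Converts a distance matrix to a correlation matrix via the Matern
#' family in its (kappa, phi) smoothness/range parameterisation:
#' rho(u) = 2^(1-kappa)/Gamma(kappa) * (u/phi)^kappa * K_kappa(u/phi)
#' for u > 0 and rho(0) = 1. At kappa = 1/2 this reduces to the
#' exponential correlation exp(-u/phi).
#'
#' @param d a \linkS4class{DistMat} or nonnegative numeric vector/matrix.
#' @param kappa smoothness, > 0.
#' @param phi range, > 0 (same units as \code{d}).
#' @return object of the same shape as \code{d} with correlations in
#'   (0, 1].
#' @export
maternCorrelation <- function(d, kappa, phi) {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0) stop("kappa must be a positive scalar")
  if (!is.numeric(phi) || length(phi) != 1 || phi <= 0) stop("phi must be a positive scalar")
  u <- if (is(d, "DistMat")) d@values else d
  if (any(u < 0, na.rm = TRUE)) stop("distances must be nonnegative")
  s <- u / phi
  rho <- ifelse(s == 0, 1,
                (2^(1 - kappa) / gamma(kappa)) * s^kappa * besselK(s, kappa))
  # besselK underflows to 0 for very large arguments; the limit is correct
  rho[is.na(rho) & !is.na(u)] <- 0
  if (is(d, "DistMat")) {
    dimnames(rho) <- dimnames(u)
    rho
  } else rho
}

#' Gower double-centering
#'
#' The centered inner-product matrix underlying principal coordinates and
#' distance-based autocorrelation: C = -1/2 J D2 J where D2 is the
#' elementwise square of the distances and J = I - 11'/n. Rows and
#' columns of C sum to zero.
#'
#' @param d a \linkS4class{DistMat} or square numeric matrix of distances.
#' @return square numeric matrix C with the same labels.
#' @export
gowerCenter <- function(d) {
  m <- if (is(d, "DistMat")) d@values else as.matrix(d)
  d2 <- m^2
  rm <- rowMeans(d2)
  gm <- mean(d2)
  -0.5 * (d2 - outer(rm, rm, function(a, b) a + b) + gm)
}
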