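#' @name songlines-io
#' @title Readers and writers for the pipeline's plain-text formats
#'
#' @description
#' All stages exchange data through small plain-text formats: song tables
#' as TSV (multiple codes per cell joined by \code{|}), distance matrices
#' as square CSV with labels in the header and first column, coordinate
#' tables and genotype dosage panels as CSV, and trees as Newick. Every
#' writer/reader pair round-trips values at full double precision.
NULL

labelCols <- c("song", "society", "family", "region")

#' Validate a song-level trait table
#'
#' @param x data.frame with columns song, society, family, region and one
#'   column per feature (character codes, multiple codes \code{|}-joined,
#'   or numeric once standardized).
#' @return x invisibly; errors describe the offending rows.
#' @export
validateSongTable <- function(x) {
  if (!is.data.frame(x)) stop("SongTable must be a data.frame")
  miss <- setdiff(labelCols, colnames(x))
  if (length(miss)) stop("SongTable missing columns: ", paste(miss, collapse = ", "))
  if (!length(featureCols(x))) stop("SongTable has no feature columns")
  bad <- which(is.na(x$society) | !nzchar(as.character(x$society)))
  if (length(bad)) stop("empty society id in rows: ", paste(head(bad, 5), collapse = ", "))
  if (anyDuplicated(x$song)) stop("song ids must be unique")
  invisible(x)
}

#' @describeIn validateSongTable names of the feature columns of a song
#'   table (everything that is not a label column).
#' @export
featureCols <- function(x) setdiff(colnames(x), c(labelCols, "glottocode"))

#' Validate a society coordinate table
#'
#' @param x data.frame with columns society, longitude, latitude.
#' @return x invisibly.
#' @export
validateGeoTable <- function(x) {
  if (!is.data.frame(x)) stop("GeoTable must be a data.frame")
  miss <- setdiff(c("society", "longitude", "latitude"), colnames(x))
  if (length(miss)) stop("GeoTable missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$society)) stop("society ids must be unique")
  bad <- which(!is.finite(x$longitude) | x$longitude < -180 | x$longitude > 180 |
               !is.finite(x$latitude) | x$latitude < -90 | x$latitude > 90)
  if (length(bad)) {
    stop("coordinates out of range in rows: ", paste(head(bad, 5), collapse = ", "),
         " (society ", paste(head(x$society[bad], 5), collapse = ", "), ")")
  }
  invisible(x)
}

#' Validate a genotype dosage panel
#'
#' @param x data.frame with columns individual, population and one
#'   \code{snp*} column per biallelic site holding dosages 0/1/2 or NA.
#' @return x invisibly.
#' @export
validateGenotypePanel <- function(x) {
  if (!is.data.frame(x)) stop("GenotypePanel must be a data.frame")
  miss <- setdiff(c("individual", "population"), colnames(x))
  if (length(miss)) stop("GenotypePanel missing columns: ", paste(miss, collapse = ", "))
  snps <- dosageCols(x)
  if (!length(snps)) stop("GenotypePanel has no snp columns")
  g <- as.matrix(x[, snps, drop = FALSE])
  if (!all(g %in% c(0, 1, 2, NA))) stop("dosages must be 0, 1, 2 or NA")
  if (any(!nzchar(as.character(x$population)))) stop("empty population labels")
  invisible(x)
}

#' @describeIn validateGenotypePanel names of the dosage columns.
#' @export
dosageCols <- function(x) grep("^snp", colnames(x), value = TRUE)

#' @rdname songlines-io
#' @param path file path.
#' @param x object to write.
#' @export
readDistMat <- function(path) {
  m <- tryCatch(read.csv(path, row.names = 1, check.names = FALSE),
                error = function(e) stop("cannot parse distance matrix CSV '", path, "': ",
                                         conditionMessage(e)))
  DistMat(as.matrix(m))
}

#' @rdname songlines-io
#' @export
writeDistMat <- function(x, path) {
  stopifnot(is(x, "DistMat"))
  m <- format(x@values, digits = 17, trim = TRUE, scientific = FALSE)
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname songlines-io
#' @export
readGeoTable <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  validateGeoTable(x)
  x
}

#' @rdname songlines-io
#' @export
writeGeoTable <- function(x, path) {
  validateGeoTable(x)
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname songlines-io
#' @export
readSongTable <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  feats <- setdiff(colnames(x), c(labelCols, "glottocode"))
  for (f in feats) {
    # keep as character: cells may hold several |-joined codes
    x[[f]] <- as.character(x[[f]])
  }
  validateSongTable(x)
  x
}

#' @rdname songlines-io
#' @export
writeSongTable <- function(x, path) {
  validateSongTable(x)
  out <- x
  for (f in featureCols(out)) {
    if (is.numeric(out[[f]])) out[[f]] <- format(out[[f]], digits = 17, trim = TRUE)
  }
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname songlines-io
#' @export
readGenotypePanel <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  validateGenotypePanel(x)
  x
}

#' @rdname songlines-io
#' @export
writeGenotypePanel <- function(x, path) {
  validateGenotypePanel(x)
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname songlines-io
#' @export
readNewickTree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("cannot parse Newick '", path, "': ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("cannot parse Newick '", path, "'")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("Newick tree has negative branch lengths")
  }
  if (anyDuplicated(tree$tip.label)) stop("Newick tree has duplicate tip labels")
  tree
}

#' @rdname songlines-io
#' @param tree an \code{ape::phylo}.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 17)
  invisible(path)
}
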