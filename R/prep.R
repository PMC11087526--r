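#' @name cantoPrep
#' @title From raw ordinal song codings to the analysis-ready table
#'
#' @description
#' Raw song codings arrive as ordinal codes, sometimes with several codes
#' per song x feature cell (a song can display multiple characteristics of
#' a feature across a performance). The preparation stage resolves each
#' cell to a single code (seeded random choice), rescales every feature to
#' the 0-1 interval by rank within its declared code set (reversing the
#' features whose scales run against the trait they measure), filters
#' societies by a minimum song count, optionally drops low-reliability
#' features, and aggregates songs into society-level profiles.
NULL

#' Read a coding scheme from YAML
#'
#' A coding scheme declares, per feature: the ordered code set, whether
#' the scale is reversed, an inter-rater reliability kappa, and an include
#' flag; plus a keep-list of features retained regardless of reliability.
#'
#' @param path YAML file; see
#'   \code{system.file("extdata", "cantometrics_scheme.yaml", package = "songlines")}.
#' @return list with elements \code{features} (named list) and
#'   \code{keep} (character).
#' @export
readCodingScheme <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$features)) stop("coding scheme must have a 'features' block")
  sch <- list(features = raw$features, keep = as.character(raw$keep %||% character()))
  validateCodingScheme(sch)
  sch
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn readCodingScheme the coding scheme shipped with the
#'   package (24 included ordinal features, reversal flags, kappas).
#' @export
defaultCodingScheme <- function() {
  readCodingScheme(system.file("extdata", "cantometrics_scheme.yaml",
                               package = "songlines"))
}

#' @describeIn readCodingScheme validate a coding scheme structure.
#' @param scheme a coding scheme list.
#' @export
validateCodingScheme <- function(scheme) {
  for (f in names(scheme$features)) {
    ft <- scheme$features[[f]]
    if (!length(ft$codes)) stop("feature ", f, " has an empty code set")
    if (anyDuplicated(ft$codes)) stop("feature ", f, " has duplicate codes")
    if (!is.null(ft$kappa) && (ft$kappa < -1 || ft$kappa > 1)) {
      stop("feature ", f, " has kappa outside [-1, 1]")
    }
  }
  invisible(scheme)
}

#' Resolve multi-coded cells to a single code
#'
#' Cells holding several \code{|}-joined codes are resolved by a uniform
#' random choice among the listed codes; singleton cells are untouched.
#' The choice is deterministic given \code{seed}. The fraction of
#' multi-coded cells is reported via \code{message}.
#'
#' @param table a SongTable with character feature columns.
#' @param seed integer seed.
#' @return SongTable with exactly one code per cell (still character).
#' @export
selectSingleCode <- function(table, seed) {
  validateSongTable(table)
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is required")
  feats <- featureCols(table)
  nMulti <- 0L
  nCells <- 0L
  out <- table
  withSeed(seed, {
    for (f in feats) {
      cell <- as.character(out[[f]])
      if (any(!nzchar(cell) | is.na(cell))) {
        stop("empty code list in feature ", f, " (rows ",
             paste(head(which(!nzchar(cell) | is.na(cell)), 5), collapse = ", "), ")")
      }
      parts <- strsplit(cell, "|", fixed = TRUE)
      multi <- lengths(parts) > 1
      nMulti <- nMulti + sum(multi)
      nCells <- nCells + length(cell)
      if (any(multi)) {
        cell[multi] <- vapply(parts[multi], function(p) p[sample.int(length(p), 1)], "")
      }
      out[[f]] <- cell
    }
  })
  message(sprintf("selectSingleCode: %d of %d cells (%.2f%%) were multi-coded",
                  nMulti, nCells, 100 * nMulti / nCells))
  out
}

#' Rescale ordinal codes to the 0-1 interval
#'
#' Each feature's codes are mapped by rank within the declared ordered
#' code set: value = (rank - 1) / (K - 1) for K codes. Reversed features
#' use the reversed rank, so high values always mean a more frequent
#' occurrence of what the feature measures. Features whose values are
#' already on the standardized grid are passed through unchanged, making
#' the operation idempotent. Constant (single-code) features are dropped
#' with a warning.
#'
#' @param table SongTable with one code per cell.
#' @param scheme coding scheme (see \code{\link{readCodingScheme}});
#'   only its included features are retained.
#' @return SongTable with numeric feature columns in [0, 1].
#' @export
standardizeCodes <- function(table, scheme) {
  validateSongTable(table)
  validateCodingScheme(scheme)
  feats <- intersect(featureCols(table), names(scheme$features))
  feats <- feats[vapply(feats, function(f) isTRUE(scheme$features[[f]]$include %||% TRUE), TRUE)]
  if (!length(feats)) stop("no included features present in table")
  out <- table[, c(intersect(colnames(table), c(labelCols, "glottocode"))), drop = FALSE]
  dropped <- character()
  for (f in feats) {
    codes <- sort(as.numeric(scheme$features[[f]]$codes))
    K <- length(codes)
    if (K < 2) {
      dropped <- c(dropped, f)
      next
    }
    vals <- suppressWarnings(as.numeric(table[[f]]))
    if (any(is.na(vals))) {
      stop("non-numeric code in feature ", f, " (rows ",
           paste(head(which(is.na(vals)), 5), collapse = ", "), ")")
    }
    grid <- (seq_len(K) - 1) / (K - 1)
    if (all(vapply(vals, function(v) any(abs(v - grid) < 1e-9), TRUE))) {
      out[[f]] <- vals  # already standardized
      next
    }
    rank <- match(vals, codes)
    if (any(is.na(rank))) {
      stop("feature ", f, ": codes outside declared set in rows ",
           paste(head(which(is.na(rank)), 5), collapse = ", "))
    }
    if (isTRUE(scheme$features[[f]]$reversed)) rank <- K + 1 - rank
    out[[f]] <- (rank - 1) / (K - 1)
  }
  if (length(dropped)) {
    warning("dropped constant features: ", paste(dropped, collapse = ", "))
  }
  out
}

#' Keep only societies with at least k songs
#'
#' @param table a SongTable.
#' @param k minimum number of songs per society (>= 1).
#' @return filtered SongTable; before/after counts reported via message.
#' @export
filterMinSongs <- function(table, k) {
  validateSongTable(table)
  if (k < 1) stop("k must be >= 1")
  counts <- table(as.character(table$society))
  keep <- names(counts)[counts >= k]
  out <- table[as.character(table$society) %in% keep, , drop = FALSE]
  if (!nrow(out)) stop("no societies with >= ", k, " songs")
  message(sprintf("filterMinSongs(k=%d): %d songs / %d societies -> %d songs / %d societies",
                  k, nrow(table), length(counts), nrow(out), length(keep)))
  rownames(out) <- NULL
  out
}

#' Drop low-reliability features from a coding scheme
#'
#' Features with inter-rater kappa strictly below the threshold are
#' excluded, except features on the keep-list, which are retained with a
#' warning (some features are kept despite low reliability because of
#' their importance to model convergence).
#'
#' @param scheme a coding scheme.
#' @param threshold minimum kappa (default 0.4).
#' @return scheme with include flags updated.
#' @export
filterReliability <- function(scheme, threshold = 0.4) {
  validateCodingScheme(scheme)
  for (f in names(scheme$features)) {
    ft <- scheme$features[[f]]
    if (!isTRUE(ft$include %||% TRUE)) next
    if (is.null(ft$kappa)) stop("feature ", f, " has no kappa; cannot filter by reliability")
    if (ft$kappa < threshold) {
      if (f %in% scheme$keep) {
        warning("feature ", f, " retained despite kappa = ", ft$kappa,
                " < ", threshold, " (keep-list)")
      } else {
        scheme$features[[f]]$include <- FALSE
      }
    }
  }
  scheme
}

#' Aggregate songs into society-level profiles
#'
#' One row per society: the per-feature mean over that society's songs
#' (the "modal profile" style aggregate).
#'
#' @param table standardized SongTable (numeric features).
#' @return society x feature numeric matrix.
#' @export
societyProfile <- function(table) {
  validateSongTable(table)
  feats <- featureCols(table)
  if (!all(vapply(feats, function(f) is.numeric(table[[f]]), TRUE))) {
    stop("societyProfile requires a standardized (numeric) table")
  }
  socs <- sort(unique(as.character(table$society)))
  m <- matrix(NA_real_, length(socs), length(feats), dimnames = list(socs, feats))
  for (s in socs) {
    rows <- table[as.character(table$society) == s, feats, drop = FALSE]
    m[s, ] <- colMeans(as.matrix(rows))
  }
  m
}
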