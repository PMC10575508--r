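#' Construct a CovariateStack
#'
#' @param grids named list of aligned [RasterGrid-class] objects.
#' @return a [CovariateStack-class].
#' @export
covariateStack <- function(grids) {
  new("CovariateStack", grids = grids)
}

#' Accessors for CovariateStack objects
#'
#' @param x a [CovariateStack-class].
#' @name CovariateStack-accessors
#' @aliases nLayers layerNames
NULL

#' @rdname CovariateStack-accessors
#' @export
setMethod("nLayers", "CovariateStack", function(x) length(x@grids))

#' @rdname CovariateStack-accessors
#' @export
setMethod("layerNames", "CovariateStack", function(x) names(x@grids))

#' @rdname CovariateStack-accessors
#' @param i layer name or index.
#' @export
setMethod("[[", "CovariateStack", function(x, i) x@grids[[i]])

setMethod("show", "CovariateStack", function(object) {
  g <- object@grids[[1L]]
  cat(sprintf("CovariateStack: %d layers on a %d x %d grid (%g km cells)\n",
              length(object@grids), nrows(g), ncols(g), cellSize(g)))
  cat("  layers:", paste(names(object@grids), collapse = ", "), "\n")
})

#' Cell-by-layer value matrix of a stack
#'
#' Cells are unrolled column-major (the order of `as.vector` on the value
#' matrix); one column per layer.
#'
#' @param stack a [CovariateStack-class].
#' @return numeric matrix, cells x layers.
#' @export
stackValues <- function(stack) {
  vapply(stack@grids, function(g) as.vector(g@values),
         numeric(nrows(stack@grids[[1L]]) * ncols(stack@grids[[1L]])))
}

#' Extract covariate rows at point locations
#'
#' @param stack a [CovariateStack-class].
#' @param points data.frame with map coordinates `x`, `y`.
#' @return numeric matrix, points x layers; rows outside the grid are NA.
#' @export
extractCovariates <- function(stack, points) {
  g <- stack@grids[[1L]]
  rc <- cellFromXY(g, points$x, points$y)
  out <- matrix(NA_real_, nrow(points), nLayers(stack),
                dimnames = list(NULL, layerNames(stack)))
  ok <- !is.na(rc$row)
  for (j in seq_len(nLayers(stack)))
    out[ok, j] <- stack@grids[[j]]@values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Drop collinear covariates by pairwise Pearson screening
#'
#' Computes the Pearson correlation matrix over cells that are valid in
#' every layer, then greedily removes the later-listed member of each
#' pair with |r| above the threshold until all retained pairs satisfy
#' |r| <= threshold. A zero-variance layer is flagged and its
#' correlations are defined as 0 (it is never dropped for collinearity).
#'
#' @param stack a [CovariateStack-class] with at least two layers.
#' @param threshold maximum allowed |r|, in (0, 1] (default 0.7).
#' @return list with elements `stack` (filtered [CovariateStack-class]),
#'   `dropped` (character), `r` (full correlation matrix) and
#'   `zeroVariance` (names of constant layers).
#' @export
collinearityFilter <- function(stack, threshold = 0.7) {
  stopifnot(is(stack, "CovariateStack"))
  if (nLayers(stack) < 2L) stop("need at least two covariates to screen")
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  vals <- stackValues(stack)
  ok <- complete.cases(vals)
  v <- vals[ok, , drop = FALSE]
  sds <- apply(v, 2L, sd)
  zv <- colnames(v)[sds == 0]
  r <- suppressWarnings(cor(v))
  r[is.na(r)] <- 0
  diag(r) <- 1
  keep <- layerNames(stack)
  repeat {
    sub <- abs(r[keep, keep, drop = FALSE])
    diag(sub) <- 0
    bad <- which(sub > threshold, arr.ind = TRUE)
    if (nrow(bad) == 0L) break
    ## first offending pair in listing order; drop the later-listed name
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    bad <- bad[order(bad[, 1], bad[, 2]), , drop = FALSE]
    keep <- setdiff(keep, keep[bad[1, 2]])
  }
  dropped <- setdiff(layerNames(stack), keep)
  list(stack = covariateStack(stack@grids[keep]), dropped = dropped,
       r = r, zeroVariance = zv)
}
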