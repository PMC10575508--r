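#' @import methods
#' @importFrom stats cor predict rnorm runif rbinom rpois sd quantile
#'   binomial glm setNames complete.cases
#' @importFrom utils head read.csv write.csv
NULL

#' Single-band gridded surface
#'
#' `RasterGrid` is the package's raster container: a numeric matrix with a
#' cell size (km), the map coordinates of the upper-left corner, and a
#' nodata sentinel used at I/O time. Internally nodata cells are stored as
#' `NA` so every statistic excludes them without special casing. Row 1 is
#' the northernmost row and column 1 the westernmost; all distances are
#' cell-center to cell-center.
#'
#' @slot values numeric matrix (rows x cols); `NA` marks nodata.
#' @slot cellsize cell edge length in km.
#' @slot origin numeric length-2, (x, y) of the upper-left corner.
#' @slot nodata sentinel written/read in ESRI ASCII files.
#' @export
setClass("RasterGrid",
  representation(values = "matrix", cellsize = "numeric",
                 origin = "numeric", nodata = "numeric"),
  prototype(values = matrix(numeric(0), 0, 0), cellsize = 1,
            origin = c(0, 0), nodata = -9999))

setValidity("RasterGrid", function(object) {
  msg <- character(0)
  if (!is.numeric(object@values) && !is.logical(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (length(object@cellsize) != 1L || !is.finite(object@cellsize) ||
      object@cellsize <= 0)
    msg <- c(msg, "cellsize must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be two finite coordinates")
  if (length(object@nodata) != 1L)
    msg <- c(msg, "nodata must be a single value")
  if (length(msg)) msg else TRUE
})

#' Aligned, named set of covariate grids
#'
#' All member grids share shape, cell size and origin; layer names are
#' unique. This is the input container for the distribution models and
#' for collinearity screening.
#'
#' @slot grids named list of [RasterGrid] objects, pairwise aligned.
#' @export
setClass("CovariateStack", representation(grids = "list"))

setValidity("CovariateStack", function(object) {
  g <- object@grids
  if (length(g) == 0L) return("stack must contain at least one grid")
  if (is.null(names(g)) || anyDuplicated(names(g)) || any(names(g) == ""))
    return("grids must carry unique non-empty names")
  if (!all(vapply(g, is, logical(1), "RasterGrid")))
    return("all elements must be RasterGrid objects")
  ref <- g[[1L]]
  for (x in g[-1L]) {
    if (!identical(dim(x@values), dim(ref@values)) ||
        !isTRUE(all.equal(x@cellsize, ref@cellsize)) ||
        !isTRUE(all.equal(x@origin, ref@origin)))
      return("all grids must be aligned (same shape, cellsize, origin)")
  }
  TRUE
})

#' One plug-in learner for the ensemble
#'
#' A learner is a fit/predict pair: `fitFun(x, y, seed)` returns an opaque
#' fitted object, `predictFun(fit, x)` returns scores in \[0, 1\]. Scores
#' are deterministic given the fitted state; all randomness is driven by
#' the seed passed to `fitFun`.
#'
#' @slot name learner identifier.
#' @slot fitFun function(x, y, seed) -> fitted object.
#' @slot predictFun function(fit, x) -> numeric scores in \[0, 1\].
#' @slot hyper free-form list of hyperparameters (recorded, not enforced).
#' @export
setClass("LearnerSpec",
  representation(name = "character", fitFun = "function",
                 predictFun = "function", hyper = "list"),
  prototype(hyper = list()))

#' Fitted accuracy-weighted ensemble
#'
#' Holds the per-learner, per-replication fitted objects, the learner x
#' replication AUC table from held-out splits, and the AUC-proportional
#' ensemble weights (non-negative, summing to 1).
#'
#' @slot learners list of [LearnerSpec] objects.
#' @slot fits list (per learner) of lists (per replication) of fitted objects.
#' @slot aucTable numeric matrix, learners x replications.
#' @slot weights named numeric, per-learner ensemble weights.
#' @slot replications number of train/test replications.
#' @slot trainFraction fraction of points used for training per replication.
#' @slot covariates names of the covariates the model was fitted on.
#' @export
setClass("EnsembleModel",
  representation(learners = "list", fits = "list", aucTable = "matrix",
                 weights = "numeric", replications = "numeric",
                 trainFraction = "numeric", covariates = "character"))

setValidity("EnsembleModel", function(object) {
  w <- object@weights
  if (any(w < -1e-12)) return("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-8) return("weights must sum to 1")
  a <- object@aucTable
  if (any(!is.na(a) & (a < 0 | a > 1))) return("AUC values must lie in [0, 1]")
  TRUE
})

#' Continuous habitat-suitability surface
#'
#' A [RasterGrid] of suitability values in \[0, 1\], optionally carrying a
#' three-level natural-breaks class grid (1 = marginal, 2 = moderate,
#' 3 = high) and a binarization threshold.
#'
#' @slot grid suitability [RasterGrid], values in \[0, 1\].
#' @slot classes optional integer class [RasterGrid] (or NULL stand-in grid).
#' @slot breaks ascending class break values (length 0 if unclassed).
#' @slot threshold binarization cut (NA until set).
#' @export
setClass("SuitabilitySurface",
  representation(grid = "RasterGrid", classes = "ANY", breaks = "numeric",
                 threshold = "numeric"),
  prototype(classes = NULL, breaks = numeric(0), threshold = NA_real_))

setValidity("SuitabilitySurface", function(object) {
  v <- object@grid@values
  if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
    return("suitability values must lie in [0, 1]")
  if (length(object@breaks) > 1L && any(diff(object@breaks) <= 0))
    return("class breaks must be strictly increasing")
  TRUE
})

#' Landscape resistance surface
#'
#' Per-cell movement cost in \[1, 100\], strictly decreasing in habitat
#' suitability; produced by [suitabilityToResistance()].
#'
#' @slot grid resistance [RasterGrid], values in \[1, 100\].
#' @slot c shape factor used in the transformation.
#' @export
setClass("ResistanceSurface",
  representation(grid = "RasterGrid", c = "numeric"))

setValidity("ResistanceSurface", function(object) {
  v <- object@grid@values
  if (any(v < 1 - 1e-9 | v > 100 + 1e-9, na.rm = TRUE))
    return("resistance values must lie in [1, 100]")
  if (object@c <= 0) return("shape factor c must be positive")
  TRUE
})

#' One corridor link between a pair of protected areas
#'
#' Carries the least-cost metrics for one PA pair: cost-weighted distance
#' of the optimal path (`lcpCost`, cw-km), its geometric length
#' (`lcpLength`, km), the edge-to-edge Euclidean distance (`euclidDist`,
#' km), the two corridor-quality ratios, the truncated corridor mask, and
#' -- once the circuit stage has run -- the current-density map and the
#' link's current-flow centrality.
#'
#' @slot paFrom,paTo protected-area identifiers.
#' @slot lcpCost least-cost path cost in cw-km (CWD at destination).
#' @slot lcpLength geometric least-cost path length in km.
#' @slot euclidDist minimum edge-to-edge PA distance in km.
#' @slot cwdEudRatio lcpCost / euclidDist.
#' @slot cwdLcpRatio lcpCost / lcpLength (mean resistance along the path).
#' @slot corridorMask logical [RasterGrid]: truncated corridor swath.
#' @slot path integer matrix (row, col) of the least-cost path cells.
#' @slot reachable whether a finite-cost path exists.
#' @slot centrality current-flow centrality in Amps (NA until filled).
#' @slot currentMap current-density [RasterGrid] or NULL until filled.
#' @export
setClass("CorridorLink",
  representation(paFrom = "character", paTo = "character",
                 lcpCost = "numeric", lcpLength = "numeric",
                 euclidDist = "numeric", cwdEudRatio = "numeric",
                 cwdLcpRatio = "numeric", corridorMask = "ANY",
                 path = "matrix", reachable = "logical",
                 centrality = "numeric", currentMap = "ANY"),
  prototype(centrality = NA_real_, currentMap = NULL, reachable = TRUE))
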