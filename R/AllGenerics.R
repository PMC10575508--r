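#' @rdname RasterGrid-accessors
#' @export
setGeneric("nrows", function(x) standardGeneric("nrows"))

#' @rdname RasterGrid-accessors
#' @export
setGeneric("ncols", function(x) standardGeneric("ncols"))

#' @rdname RasterGrid-accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname RasterGrid-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname RasterGrid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname RasterGrid-accessors
#' @export
setGeneric("gridValues<-", function(x, value) standardGeneric("gridValues<-"))

#' @rdname CovariateStack-accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname CovariateStack-accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname ensemble-accessors
#' @export
setGeneric("ensembleWeights", function(x) standardGeneric("ensembleWeights"))

#' @rdname ensemble-accessors
#' @export
setGeneric("aucTable", function(x) standardGeneric("aucTable"))
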