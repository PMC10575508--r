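#' Construct a RasterGrid
#'
#' @param values numeric matrix (row 1 = northernmost row). Values equal to
#'   `nodata` are converted to `NA` on construction.
#' @param cellsize cell edge length in km (default 1, the working
#'   resolution of the analysis).
#' @param origin (x, y) map coordinates of the upper-left corner.
#' @param nodata sentinel value used when the grid is written to disk.
#' @return a [RasterGrid-class] object.
#' @examples
#' g <- rasterGrid(matrix(1:6, 2, 3))
#' nrows(g); ncols(g)
#' @export
rasterGrid <- function(values, cellsize = 1, origin = c(0, 0),
                       nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  values[!is.na(values) & values == nodata] <- NA_real_
  new("RasterGrid", values = values, cellsize = as.numeric(cellsize),
      origin = as.numeric(origin), nodata = as.numeric(nodata))
}

#' Accessors for RasterGrid objects
#'
#' @param x a [RasterGrid-class].
#' @param value replacement value matrix.
#' @name RasterGrid-accessors
#' @aliases nrows ncols cellSize gridOrigin gridValues gridValues<-
NULL

#' @rdname RasterGrid-accessors
#' @export
setMethod("nrows", "RasterGrid", function(x) nrow(x@values))

#' @rdname RasterGrid-accessors
#' @export
setMethod("ncols", "RasterGrid", function(x) ncol(x@values))

#' @rdname RasterGrid-accessors
#' @export
setMethod("cellSize", "RasterGrid", function(x) x@cellsize)

#' @rdname RasterGrid-accessors
#' @export
setMethod("gridOrigin", "RasterGrid", function(x) x@origin)

#' @rdname RasterGrid-accessors
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @rdname RasterGrid-accessors
#' @export
setReplaceMethod("gridValues", "RasterGrid", function(x, value) {
  if (!is.matrix(value)) value <- matrix(value, nrow(x@values), ncol(x@values))
  storage.mode(value) <- "double"
  x@values <- value
  validObject(x)
  x
})

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid: %d x %d cells, cellsize %g km\n",
              nrow(v), ncol(v), object@cellsize))
  cat(sprintf("  origin (UL): (%g, %g); nodata cells: %d\n",
              object@origin[1], object@origin[2], sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  value range: [%g, %g]\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

#' Map coordinates of cell centers
#'
#' Row 1 is northernmost; x increases eastwards, y northwards. Cell
#' (r, c) has center x = origin_x + (c - 0.5) * cellsize,
#' y = origin_y - (r - 0.5) * cellsize.
#'
#' @param grid a [RasterGrid-class].
#' @param rows,cols cell indices (recycled together).
#' @return data.frame with columns `x`, `y`.
#' @export
cellCenters <- function(grid, rows, cols) {
  data.frame(x = grid@origin[1] + (cols - 0.5) * grid@cellsize,
             y = grid@origin[2] - (rows - 0.5) * grid@cellsize)
}

#' Cell indices containing map coordinates
#'
#' @param grid a [RasterGrid-class].
#' @param x,y map coordinates.
#' @return data.frame with columns `row`, `col`; `NA` outside the grid.
#' @export
cellFromXY <- function(grid, x, y) {
  col <- floor((x - grid@origin[1]) / grid@cellsize) + 1L
  row <- floor((grid@origin[2] - y) / grid@cellsize) + 1L
  bad <- row < 1L | row > nrows(grid) | col < 1L | col > ncols(grid)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Read a raster from disk
#'
#' Supports the ESRI ASCII grid interchange format (header keywords
#' ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value followed by
#' north-to-south rows of values). Malformed headers or a value block
#' whose shape disagrees with the header raise an error naming the
#' offending field.
#'
#' @param path file to read.
#' @param format only `"ascii-grid"` is supported.
#' @return a [RasterGrid-class].
#' @export
readRaster <- function(path, format = c("ascii-grid")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("raster file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(tok[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      val <- suppressWarnings(as.numeric(tok[2]))
      if (length(tok) < 2L || is.na(val))
        stop("malformed ASCII grid header field: ", key)
      hdr[[key]] <- val
      i <- i + 1L
    } else break
  }
  for (req in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[req]]))
      stop("ASCII grid header is missing required field: ", req)
  if (is.null(hdr$nodata_value)) hdr$nodata_value <- -9999
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != nr * nc)
    stop(sprintf(
      "ASCII grid value block has %d values but nrows x ncols = %d: %s",
      length(body), nr * nc, "field nrows/ncols disagrees with data"))
  vals <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  rasterGrid(vals, cellsize = hdr$cellsize, origin = origin,
             nodata = hdr$nodata_value)
}

#' Write a raster to disk
#'
#' Values are written at full double precision (`%.17g`), so a
#' read-back reproduces the grid bit-for-bit at that precision; `NA`
#' cells are written as the grid's nodata sentinel.
#'
#' @param grid a [RasterGrid-class].
#' @param path destination file.
#' @param format only `"ascii-grid"` is supported.
#' @return `path`, invisibly.
#' @export
writeRaster <- function(grid, path, format = c("ascii-grid")) {
  format <- match.arg(format)
  stopifnot(is(grid, "RasterGrid"))
  v <- grid@values
  v[is.na(v)] <- grid@nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.17g", grid@origin[1]),
           sprintf("yllcorner %.17g", grid@origin[2] - nrow(v) * grid@cellsize),
           sprintf("cellsize %.17g", grid@cellsize),
           sprintf("NODATA_value %.17g", grid@nodata))
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

## 1-D squared distance transform (lower envelope of parabolas);
## exact separable pass of the Euclidean distance transform.
.dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (s <= z[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance surface to the nearest mask cell
#'
#' Exact center-to-center Euclidean distance (km) from every cell to the
#' nearest `TRUE` cell of a binary mask, computed with the separable
#' two-pass squared distance transform. Mask cells hold 0.
#'
#' @param mask a [RasterGrid-class] whose values are 0/1 or logical;
#'   `NA` counts as not-in-mask.
#' @return a [RasterGrid-class] of distances in km.
#' @export
euclideanDistanceSurface <- function(mask) {
  stopifnot(is(mask, "RasterGrid"))
  m <- mask@values
  on <- !is.na(m) & m != 0
  if (!any(on)) stop("distance surface undefined: mask has no TRUE cell")
  ## finite "far" value larger than any attainable squared cell distance,
  ## so the envelope algebra never hits Inf - Inf
  far <- nrow(m)^2 + ncol(m)^2 + 1
  f <- matrix(far, nrow(m), ncol(m)); f[on] <- 0
  for (j in seq_len(ncol(f))) f[, j] <- .dt1d(f[, j])
  for (i in seq_len(nrow(f))) f[i, ] <- .dt1d(f[i, ])
  rasterGrid(sqrt(f) * mask@cellsize, cellsize = mask@cellsize,
             origin = mask@origin, nodata = mask@nodata)
}

#' Align a grid to a template, resampling values
#'
#' `rule = "mean"` averages all non-nodata source cells whose centers
#' fall inside each template cell (requires the template's cells to be at
#' least as large as the source's); `rule = "nearest"` takes the source
#' cell containing each template cell center.
#'
#' @param grid source [RasterGrid-class].
#' @param target template [RasterGrid-class] supplying shape, cellsize
#'   and origin (its values are ignored).
#' @param rule resampling rule, `"mean"` or `"nearest"`.
#' @return a [RasterGrid-class] aligned to `target`.
#' @export
alignAndResample <- function(grid, target, rule = c("mean", "nearest")) {
  rule <- match.arg(rule)
  stopifnot(is(grid, "RasterGrid"), is(target, "RasterGrid"))
  sx0 <- grid@origin[1]; sy0 <- grid@origin[2]
  tx0 <- target@origin[1]; ty0 <- target@origin[2]
  sw <- ncols(grid) * grid@cellsize; sh <- nrows(grid) * grid@cellsize
  tw <- ncols(target) * target@cellsize; th <- nrows(target) * target@cellsize
  if (sx0 >= tx0 + tw || tx0 >= sx0 + sw ||
      sy0 - sh >= ty0 || ty0 - th >= sy0)
    stop("source and template extents are disjoint")
  if (rule == "mean" && target@cellsize < grid@cellsize - 1e-12)
    stop("mean rule requires template cellsize >= source cellsize")
  out <- matrix(NA_real_, nrows(target), ncols(target))
  if (rule == "nearest") {
    idx <- expand.grid(row = seq_len(nrows(target)),
                       col = seq_len(ncols(target)))
    ctr <- cellCenters(target, idx$row, idx$col)
    src <- cellFromXY(grid, ctr$x, ctr$y)
    ok <- !is.na(src$row)
    out[cbind(idx$row, idx$col)[ok, , drop = FALSE]] <-
      grid@values[cbind(src$row, src$col)[ok, , drop = FALSE]]
  } else {
    idx <- expand.grid(row = seq_len(nrows(grid)), col = seq_len(ncols(grid)))
    ctr <- cellCenters(grid, idx$row, idx$col)
    tgt <- cellFromXY(target, ctr$x, ctr$y)
    ok <- !is.na(tgt$row) & !is.na(grid@values[cbind(idx$row, idx$col)])
    if (any(ok)) {
      key <- (tgt$row[ok] - 1L) * ncols(target) + tgt$col[ok]
      vals <- grid@values[cbind(idx$row, idx$col)[ok, , drop = FALSE]]
      means <- tapply(vals, key, mean)
      k <- as.integer(names(means))
      out[cbind((k - 1L) %/% ncols(target) + 1L,
                (k - 1L) %% ncols(target) + 1L)] <- as.numeric(means)
    }
  }
  rasterGrid(out, cellsize = target@cellsize, origin = target@origin,
             nodata = target@nodata)
}
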