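#' Read and write point tables
#'
#' Points travel as plain CSV with `x`, `y` and optional attribute
#' columns.
#'
#' @param path CSV file.
#' @return data.frame with at least `x` and `y`.
#' @export
readPoints <- function(path) {
  df <- read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("point CSV must contain columns x and y")
  df
}

#' @rdname readPoints
#' @param points data.frame with `x`, `y`.
#' @export
writePoints <- function(points, path) {
  write.csv(points, path, row.names = FALSE)
  invisible(path)
}

## vectorized even-odd ray-casting point-in-polygon test
.pointInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Write protected-area masks as a GeoJSON FeatureCollection
#'
#' Each mask is traced as the polygon outline of its bounding box (the
#' generator places rectangular PAs); the feature's `name` property
#' carries the PA identifier.
#'
#' @param pas named list of binary [RasterGrid-class] masks.
#' @param path destination file.
#' @export
writePAGeoJSON <- function(pas, path) {
  feats <- lapply(names(pas), function(nm) {
    g <- pas[[nm]]
    idx <- which(!is.na(g@values) & g@values != 0, arr.ind = TRUE)
    cs <- g@cellsize
    x0 <- g@origin[1] + (min(idx[, 2]) - 1) * cs
    x1 <- g@origin[1] + max(idx[, 2]) * cs
    y1 <- g@origin[2] - (min(idx[, 1]) - 1) * cs
    y0 <- g@origin[2] - max(idx[, 1]) * cs
    ring <- list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
    list(type = "Feature", properties = list(name = nm),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize a GeoJSON FeatureCollection of PA polygons
#'
#' Cell centers inside each polygon become mask cells; the feature
#' `name` property (or `PA<i>`) names the mask.
#'
#' @param path GeoJSON file.
#' @param template [RasterGrid-class] supplying the grid geometry.
#' @return named list of binary [RasterGrid-class] masks.
#' @export
readPAGeoJSON <- function(path, template) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  nr <- nrows(template); nc <- ncols(template)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  ctr <- cellCenters(template, idx$row, idx$col)
  out <- list()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    nm <- if (!is.null(f$properties$name)) f$properties$name
          else paste0("PA", i)
    ring <- f$geometry$coordinates[[1L]]
    vx <- vapply(ring, function(p) as.numeric(p[[1L]]), numeric(1))
    vy <- vapply(ring, function(p) as.numeric(p[[2L]]), numeric(1))
    inside <- .pointInPolygon(ctr$x, ctr$y, vx, vy)
    m <- matrix(0, nr, nc)
    m[cbind(idx$row, idx$col)[inside, , drop = FALSE]] <- 1
    out[[nm]] <- rasterGrid(m, cellsize = template@cellsize,
                            origin = template@origin,
                            nodata = template@nodata)
  }
  out
}
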