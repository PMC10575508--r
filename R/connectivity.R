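#' Transform habitat suitability into landscape resistance
#'
#' Applies the negative-exponential transformation
#' `R = 100 - 99 * (1 - exp(-c * h)) / (1 - exp(-c))`
#' per cell, mapping suitability h = 1 to resistance 1 and h = 0 to
#' resistance 100. The shape factor `c` controls curvature: 0.25 is
#' approximately linear (the default), larger values discount
#' intermediate suitability more strongly. Nodata propagates.
#'
#' @param suit a [SuitabilitySurface-class] or a [RasterGrid-class] of
#'   values in \[0, 1\].
#' @param c shape factor, one of the conventional candidates
#'   2, 1, 0.5, 0.25 or any positive value (default 0.25).
#' @return a [ResistanceSurface-class].
#' @export
suitabilityToResistance <- function(suit, c = 0.25) {
  g <- if (is(suit, "SuitabilitySurface")) suit@grid else suit
  stopifnot(is(g, "RasterGrid"))
  if (c <= 0) stop("shape factor c must be positive")
  h <- g@values
  bad <- which(!is.na(h) & (h < 0 | h > 1))
  if (length(bad))
    stop("suitability outside [0, 1] at cell(s): ",
         paste(head(bad, 10L), collapse = ", "))
  r <- 100 - 99 * ((1 - exp(-c * h)) / (1 - exp(-c)))
  rg <- rasterGrid(r, cellsize = g@cellsize, origin = g@origin,
                   nodata = g@nodata)
  new("ResistanceSurface", grid = rg, c = c)
}

setMethod("show", "ResistanceSurface", function(object) {
  cat(sprintf("ResistanceSurface (shape factor c = %g)\n", object@c))
  show(object@grid)
})

## Cost of the move between two adjacent cells: step length times the
## mean of the endpoint resistances (the cost-distance tool convention).
.neighborOffsets <- function() {
  data.frame(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
             dc = c(-1, 0, 1, -1, 1, -1, 0, 1),
             d = c(sqrt(2), 1, sqrt(2), 1, 1, sqrt(2), 1, sqrt(2)))
}

#' Cost-weighted distance from a source set
#'
#' Multi-source shortest-path accumulated cost over the 8-connected
#' grid. The cost of moving between adjacent cells i and j is
#' `cellsize * d * (R_i + R_j) / 2` with d = 1 for cardinal and sqrt(2)
#' for diagonal moves; source cells have cost 0 and unreachable or
#' nodata cells are `Inf`. Computed by vectorized iterative relaxation
#' over the eight neighbour shifts until a fixpoint, which is exact for
#' positive costs.
#'
#' @param res a [ResistanceSurface-class].
#' @param sources binary [RasterGrid-class] (or logical matrix) marking
#'   source cells.
#' @return a [RasterGrid-class] of costs in cw-km; `Inf` = unreachable.
#' @export
costWeightedDistance <- function(res, sources) {
  stopifnot(is(res, "ResistanceSurface"))
  R <- res@grid@values
  src <- if (is(sources, "RasterGrid")) sources@values else sources
  src <- !is.na(src) & src != 0
  if (!identical(dim(src), dim(R))) stop("source mask shape mismatch")
  if (!any(src & !is.na(R)))
    stop("no source cell lies on a non-nodata cell")
  cs <- res@grid@cellsize
  nr <- nrow(R); nc <- ncol(R)
  Rinf <- R; Rinf[is.na(Rinf)] <- Inf
  D <- matrix(Inf, nr, nc)
  D[src & !is.na(R)] <- 0
  off <- .neighborOffsets()
  shift <- function(M, dr, dc, fill) {
    out <- matrix(fill, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cls <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cls] <- M[rs - dr, cls - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (k in seq_len(8L)) {
      dr <- off$dr[k]; dc <- off$dc[k]; d <- off$d[k]
      cand <- shift(D, dr, dc, Inf) +
        cs * d * (Rinf + shift(Rinf, dr, dc, Inf)) / 2
      upd <- cand < D
      if (any(upd)) { D[upd] <- cand[upd]; changed <- TRUE }
    }
    if (!changed) break
  }
  rasterGrid(D, cellsize = cs, origin = res@grid@origin,
             nodata = res@grid@nodata)
}

## backtrack one least-cost path on a CWD surface; deterministic
## tie-break: at equal cost prefer the lower row, then the lower column.
.backtrackPath <- function(D, R, cs, startRow, startCol) {
  off <- .neighborOffsets()
  nr <- nrow(D); nc <- ncol(D)
  path <- matrix(integer(0), 0, 2)
  r <- startRow; cc <- startCol
  steps <- 0; len <- 0
  tol <- function(x) 1e-9 * max(1, abs(x))
  while (D[r, cc] > 0 && steps <= nr * nc) {
    path <- rbind(path, c(r, cc))
    best <- NULL
    for (k in order(off$dr, off$dc)) {
      r2 <- r + off$dr[k]; c2 <- cc + off$dc[k]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.finite(D[r2, c2])) next
      ec <- cs * off$d[k] * (R[r, cc] + R[r2, c2]) / 2
      if (abs(D[r2, c2] + ec - D[r, cc]) <= tol(D[r, cc])) {
        step <- cs * off$d[k]
        if (is.null(best)) best <- list(r = r2, c = c2, step = step)
        ## order() above already walks candidates in (row, col) order
        break
      }
    }
    if (is.null(best)) stop("path backtracking failed (inconsistent CWD)")
    len <- len + best$step
    r <- best$r; cc <- best$c
    steps <- steps + 1
  }
  path <- rbind(path, c(r, cc))
  list(path = path, length = len)
}

#' Least-cost path between two cell sets
#'
#' Runs [costWeightedDistance()] from the source mask, picks the
#' destination cell with minimal cost (ties: lowest row, then lowest
#' column) and backtracks the optimal route. Source sets that overlap or
#' touch (8-adjacency) are separated by no matrix cells, so the path is
#' degenerate with cost and length 0.
#'
#' @param res a [ResistanceSurface-class].
#' @param srcMask,dstMask binary [RasterGrid-class] or logical matrices.
#' @param cwd optionally the precomputed CWD grid from `srcMask`.
#' @return list with `reachable`, `lcpCost` (cw-km), `lcpLength` (km),
#'   `path` (n x 2 matrix of row/col, source to destination) and `cwd`
#'   (the [RasterGrid-class] of source costs).
#' @export
leastCostPath <- function(res, srcMask, dstMask, cwd = NULL) {
  asMat <- function(m) {
    v <- if (is(m, "RasterGrid")) m@values else m
    !is.na(v) & v != 0
  }
  src <- asMat(srcMask); dst <- asMat(dstMask)
  if (!any(src) || !any(dst)) stop("both masks must be non-empty")
  ## degenerate case: masks overlap or touch (8-adjacent dilation)
  nr <- nrow(src); nc <- ncol(src)
  dil <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cls <- max(1, 1 + dc):min(nc, nc + dc)
    dil[rs, cls] <- dil[rs, cls] | src[rs - dr, cls - dc]
  }
  if (any(dil & dst)) {
    if (is.null(cwd)) cwd <- costWeightedDistance(res, src)
    return(list(reachable = TRUE, lcpCost = 0, lcpLength = 0,
                path = matrix(integer(0), 0, 2), cwd = cwd))
  }
  if (is.null(cwd)) cwd <- costWeightedDistance(res, src)
  D <- cwd@values
  cand <- which(dst & is.finite(D))
  if (length(cand) == 0L)
    return(list(reachable = FALSE, lcpCost = Inf, lcpLength = NA_real_,
                path = matrix(integer(0), 0, 2), cwd = cwd))
  rr <- (cand - 1L) %% nr + 1L; ccol <- (cand - 1L) %/% nr + 1L
  o <- order(D[cand], rr, ccol)
  bestR <- rr[o[1L]]; bestC <- ccol[o[1L]]
  R <- res@grid@values; R[is.na(R)] <- Inf
  bt <- .backtrackPath(D, R, res@grid@cellsize, bestR, bestC)
  list(reachable = TRUE, lcpCost = D[bestR, bestC],
       lcpLength = bt$length, path = bt$path[rev(seq_len(nrow(bt$path))), ,
                                             drop = FALSE],
       cwd = cwd)
}

#' Truncated normalized least-cost corridor
#'
#' The corridor value of a cell is `cwdA + cwdB - lcpCost`: 0 exactly on
#' the least-cost path and growing with detour cost. The corridor swath
#' is the set of cells at or below the cutoff (default 200 cw-km, with
#' 150/100/50 the conventional alternatives).
#'
#' @param cwdA,cwdB CWD [RasterGrid-class]s from the two PAs.
#' @param lcpCost least-cost path cost between them (cw-km).
#' @param cutoff truncation threshold in cw-km (default 200).
#' @return list with `mask` (logical [RasterGrid-class]) and `values`
#'   (corridor-value [RasterGrid-class], `Inf` off-network).
#' @export
normalizedCorridor <- function(cwdA, cwdB, lcpCost, cutoff = 200) {
  stopifnot(cutoff >= 0)
  if (!is.finite(lcpCost)) {
    warning("least-cost path unreachable; corridor mask is empty")
    empty <- rasterGrid(matrix(0, nrows(cwdA), ncols(cwdA)),
                        cellsize = cwdA@cellsize, origin = cwdA@origin)
    return(list(mask = empty, values = empty))
  }
  v <- cwdA@values + cwdB@values - lcpCost
  mask <- is.finite(v) & v <= cutoff + 1e-9
  list(mask = rasterGrid(mask + 0, cellsize = cwdA@cellsize,
                         origin = cwdA@origin),
       values = rasterGrid(v, cellsize = cwdA@cellsize,
                           origin = cwdA@origin))
}

#' Minimum Euclidean distance between two protected areas
#'
#' Edge-to-edge: the minimum center-to-center distance between any cell
#' of A and any cell of B, in km. Overlapping masks return 0 with a
#' warning.
#'
#' @param maskA,maskB binary [RasterGrid-class] or logical matrices.
#' @param cellsize cell size in km (taken from the grids when given).
#' @return distance in km.
#' @export
paEuclideanDistance <- function(maskA, maskB, cellsize = NULL) {
  get <- function(m) {
    if (is(m, "RasterGrid")) {
      if (is.null(cellsize)) cellsize <<- m@cellsize
      v <- m@values
    } else v <- m
    which(!is.na(v) & v != 0, arr.ind = TRUE)
  }
  a <- get(maskA); b <- get(maskB)
  if (is.null(cellsize)) cellsize <- 1
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both masks must be non-empty")
  if (nrow(merge(as.data.frame(a), as.data.frame(b))) > 0L) {
    warning("PA masks overlap; Euclidean distance is 0")
    return(0)
  }
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(min(d2)) * cellsize
}

#' Build the corridor link table for a PA network
#'
#' For every requested PA pair (default: all unordered pairs) with a
#' reachable least-cost path, assembles a [CorridorLink-class] with the
#' path cost (CWD, cw-km), geometric path length (km), edge-to-edge
#' Euclidean distance (km), the CWD:EUD and CWD:LCP quality ratios, and
#' the truncated corridor mask. CWD surfaces are computed once per PA
#' and shared across pairs. Centrality and current maps are filled later
#' by the circuit stage.
#'
#' @param pas named list of binary PA masks ([RasterGrid-class]s).
#' @param res a [ResistanceSurface-class].
#' @param pairs optional 2-column matrix/data.frame of PA names; default
#'   all unordered pairs.
#' @param cutoff corridor truncation in cw-km (default 200).
#' @return list of [CorridorLink-class] objects.
#' @export
buildLinkTable <- function(pas, res, pairs = NULL, cutoff = 200) {
  if (length(pas) < 2L) stop("need at least two protected areas")
  if (is.null(names(pas)) || anyDuplicated(names(pas)))
    stop("PA masks must carry unique names")
  if (is.null(pairs)) {
    cmb <- utils::combn(names(pas), 2L)
    pairs <- data.frame(from = cmb[1L, ], to = cmb[2L, ])
  } else {
    pairs <- data.frame(from = as.character(pairs[[1L]]),
                        to = as.character(pairs[[2L]]))
  }
  cwds <- lapply(pas, function(m) costWeightedDistance(res, m))
  links <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$from[i]; b <- pairs$to[i]
    lcp <- leastCostPath(res, pas[[a]], pas[[b]], cwd = cwds[[a]])
    eud <- paEuclideanDistance(pas[[a]], pas[[b]])
    if (!lcp$reachable) {
      links[[i]] <- new("CorridorLink", paFrom = a, paTo = b,
                        lcpCost = Inf, lcpLength = NA_real_,
                        euclidDist = eud, cwdEudRatio = NA_real_,
                        cwdLcpRatio = NA_real_, corridorMask = NULL,
                        path = matrix(integer(0), 0, 2),
                        reachable = FALSE)
      next
    }
    corr <- suppressWarnings(
      normalizedCorridor(cwds[[a]], cwds[[b]], lcp$lcpCost, cutoff))
    links[[i]] <- new("CorridorLink", paFrom = a, paTo = b,
                      lcpCost = lcp$lcpCost, lcpLength = lcp$lcpLength,
                      euclidDist = eud,
                      cwdEudRatio = if (eud > 0) lcp$lcpCost / eud
                                    else NA_real_,
                      cwdLcpRatio = if (lcp$lcpLength > 0)
                                      lcp$lcpCost / lcp$lcpLength
                                    else NA_real_,
                      corridorMask = corr$mask, path = lcp$path,
                      reachable = TRUE)
  }
  links
}

setMethod("show", "CorridorLink", function(object) {
  cat(sprintf("CorridorLink %s - %s: ", object@paFrom, object@paTo))
  if (!object@reachable) { cat("unreachable\n"); return(invisible()) }
  cat(sprintf("CWD %.2f cw-km, LCP %.2f km, EUD %.2f km\n",
              object@lcpCost, object@lcpLength, object@euclidDist))
  cat(sprintf("  CWD:EUD %.2f, CWD:LCP %.2f, centrality %s\n",
              object@cwdEudRatio, object@cwdLcpRatio,
              ifelse(is.na(object@centrality), "(unfilled)",
                     sprintf("%.3f A", object@centrality))))
})

#' Flatten corridor links into a data.frame
#'
#' One row per link with the Table-style attribute columns; sorted by
#' descending centrality when centrality has been filled.
#'
#' @param links list of [CorridorLink-class].
#' @return data.frame with columns from, to, lcp_cost, lcp_length,
#'   euclid_dist, cwd_eud, cwd_lcp, centrality, reachable.
#' @export
linkTable <- function(links) {
  df <- do.call(rbind, lapply(links, function(l) {
    data.frame(from = l@paFrom, to = l@paTo, lcp_cost = l@lcpCost,
               lcp_length = l@lcpLength, euclid_dist = l@euclidDist,
               cwd_eud = l@cwdEudRatio, cwd_lcp = l@cwdLcpRatio,
               centrality = l@centrality, reachable = l@reachable)
  }))
  if (any(!is.na(df$centrality)))
    df <- df[order(-df$centrality, df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  df
}
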