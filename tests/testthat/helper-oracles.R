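## Independent brute-force reference implementations ("oracles") used to
## cross-check the package's optimized algorithms. Each is written in
## the most literal formulation available, deliberately sharing no code
## with the package internals.

## Cost-weighted distance by exhaustive enumeration of simple paths on
## the 8-connected grid, with the optimal-prefix pruning that is exact
## for strictly positive edge costs (a subpath of a least-cost path is
## itself least-cost). Feasible for tiny grids only.
oracleCwdEnum <- function(R, srcMask, cellsize = 1) {
  nr <- nrow(R); nc <- ncol(R)
  best <- matrix(Inf, nr, nc)
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  dlen <- sqrt(offs[, 1]^2 + offs[, 2]^2)
  visit <- function(r, c, cost) {
    if (cost >= best[r, c]) return(invisible())
    best[r, c] <<- cost
    for (k in seq_len(8)) {
      r2 <- r + offs[k, 1]; c2 <- c + offs[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(R[r2, c2])) next
      visit(r2, c2,
            cost + cellsize * dlen[k] * (R[r, c] + R[r2, c2]) / 2)
    }
  }
  for (i in which(srcMask & !is.na(R))) {
    r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
    visit(r, c, 0)
  }
  best
}

## Cost-weighted distance through igraph's Dijkstra implementation, a
## second formulation used on larger grids.
oracleCwdIgraph <- function(R, srcMask, cellsize = 1) {
  nr <- nrow(R); nc <- ncol(R)
  id <- function(r, c) (c - 1L) * nr + r
  ei <- integer(0); ej <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(R[r, c])) next
    for (k in list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))) {
      r2 <- r + k[1]; c2 <- c + k[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(R[r2, c2])) next
      d <- sqrt(sum(k^2))
      ei <- c(ei, id(r, c)); ej <- c(ej, id(r2, c2))
      w <- c(w, cellsize * d * (R[r, c] + R[r2, c2]) / 2)
    }
  }
  g <- igraph::graph_from_edgelist(cbind(ei, ej), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nr * nc - igraph::vcount(g)))
  src <- which(srcMask & !is.na(R))
  d <- igraph::distances(g, v = src, weights = w)
  out <- matrix(apply(d, 2, min), nr, nc)
  out[is.na(R)] <- Inf
  out
}

## All optimal Jenks partitions by exhaustive search: every way of
## cutting the sorted data between distinct adjacent values into k
## non-empty contiguous classes, scored by total within-class sum of
## squared deviations. Returns the minimal score and every break vector
## achieving it (upper class boundaries, last class implicit).
oracleJenksAll <- function(values, k = 3) {
  x <- sort(values[is.finite(values)])
  ux <- unique(x)
  n <- length(ux)
  stopifnot(n >= k)
  cuts <- utils::combn(n - 1L, k - 1L)  # cut after unique index
  ssd <- function(v) sum((v - mean(v))^2)
  scoreOf <- function(cut) {
    b <- c(0L, cut, n)
    s <- 0
    for (j in seq_len(k)) {
      cls <- x[x > c(-Inf, ux)[b[j] + 1L] & x <= ux[b[j + 1L]]]
      s <- s + ssd(cls)
    }
    s
  }
  scores <- apply(cuts, 2L, scoreOf)
  best <- min(scores)
  hit <- which(scores <= best + 1e-9 * max(1, best))
  list(score = best,
       breaks = lapply(hit, function(h) ux[cuts[, h]]))
}

## Within-class sum of squared deviations achieved by a given break
## vector (class j is (b_{j-1}, b_j], open-ended outer classes).
jenksScore <- function(values, breaks) {
  x <- values[is.finite(values)]
  b <- c(-Inf, breaks, Inf)
  s <- 0
  for (j in seq_len(length(breaks) + 1L)) {
    cls <- x[x > b[j] & x <= b[j + 1L]]
    if (length(cls)) s <- s + sum((cls - mean(cls))^2)
  }
  s
}

## AUC by literal pair counting over every (positive, negative) pair,
## ties worth 1/2.
oracleAucPairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## Euclidean distance transform by scanning every feature cell per cell.
oracleEdt <- function(mask, cellsize = 1) {
  nr <- nrow(mask); nc <- ncol(mask)
  feat <- which(mask != 0, arr.ind = TRUE)
  out <- matrix(Inf, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    out[r, c] <- sqrt(min((feat[, 1] - r)^2 + (feat[, 2] - c)^2))
  out * cellsize
}

## Build a ResistanceSurface carrying exactly the given resistance
## values (bypassing the transform) for fixture construction.
resistanceFixture <- function(vals, cellsize = 1) {
  g <- rasterGrid(vals, cellsize = cellsize,
                  origin = c(0, nrow(vals) * cellsize))
  new("ResistanceSurface", grid = g, c = 0.25)
}

maskFixture <- function(nr, nc, cells, cellsize = 1) {
  m <- matrix(0, nr, nc)
  m[cells] <- 1
  rasterGrid(m, cellsize = cellsize, origin = c(0, nr * cellsize))
}
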