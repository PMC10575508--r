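#' Build the conductance graph of a resistance surface
#'
#' Nodes are the non-nodata cells of the (optionally restricted) domain;
#' each protected area is collapsed exactly into one supernode, the
#' zero-internal-resistance limit of the focal-region convention.
#' Adjacent cells i, j are joined by conductance
#' `g_ij = 1 / (cellsize * d * (R_i + R_j) / 2)` with d = 1 (cardinal)
#' or sqrt(2) (diagonal).
#'
#' @param res a [ResistanceSurface-class].
#' @param pas named list of binary PA masks.
#' @param domainMask optional binary [RasterGrid-class]/matrix limiting
#'   the graph (e.g. a truncated corridor); PA cells are always kept.
#' @return a `ConductanceGraph` (list) with the cell-level edge list,
#'   the cell-to-node map and the PA supernode ids.
#' @export
buildConductanceGraph <- function(res, pas, domainMask = NULL) {
  stopifnot(is(res, "ResistanceSurface"))
  R <- res@grid@values
  nr <- nrow(R); nc <- ncol(R)
  asMat <- function(m) {
    v <- if (is(m, "RasterGrid")) m@values else m
    !is.na(v) & v != 0
  }
  paM <- lapply(pas, asMat)
  dom <- if (is.null(domainMask)) matrix(TRUE, nr, nc) else asMat(domainMask)
  for (m in paM) dom <- dom | m
  dom <- dom & !is.na(R)
  for (p in names(paM))
    if (!any(paM[[p]] & dom))
      stop("PA ", p, " has no cell inside the graph domain")
  ## cell -> node: PA supernodes first, then free cells
  node <- matrix(NA_integer_, nr, nc)
  for (pi in seq_along(paM)) node[paM[[pi]] & dom] <- pi
  free <- dom & is.na(node)
  node[free] <- length(paM) + seq_len(sum(free))
  nNodes <- length(paM) + sum(free)
  cs <- res@grid@cellsize
  ## each undirected cell adjacency once: E, SE, S, SW offsets
  offs <- data.frame(dr = c(0, 1, 1, 1), dc = c(1, 1, 0, -1),
                     d = c(1, sqrt(2), 1, sqrt(2)))
  ei <- integer(0); ej <- integer(0); eg <- numeric(0)
  ci <- integer(0); cj <- integer(0)
  cells <- which(dom)
  rA <- (cells - 1L) %% nr + 1L; cA <- (cells - 1L) %/% nr + 1L
  for (k in seq_len(nrow(offs))) {
    r2 <- rA + offs$dr[k]; c2 <- cA + offs$dc[k]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- dom[cbind(r2[ok], c2[ok])]
    if (!any(ok)) next
    a <- cells[ok]; b <- (c2[ok] - 1L) * nr + r2[ok]
    g <- 1 / (cs * offs$d[k] * (R[a] + R[b]) / 2)
    ei <- c(ei, node[a]); ej <- c(ej, node[b]); eg <- c(eg, g)
    ci <- c(ci, a); cj <- c(cj, b)
  }
  structure(list(nNodes = nNodes, edgeFrom = ei, edgeTo = ej,
                 conductance = eg, cellFrom = ci, cellTo = cj,
                 node = node, paNode = setNames(seq_along(paM), names(paM)),
                 dims = c(nr, nc), cellsize = cs,
                 origin = res@grid@origin),
            class = "ConductanceGraph")
}

#' @export
print.ConductanceGraph <- function(x, ...) {
  cat(sprintf("ConductanceGraph: %d nodes (%d PA supernodes), %d edges\n",
              x$nNodes, length(x$paNode), length(x$conductance)))
  invisible(x)
}

## connected-component labels by min-label propagation over the edge list
.graphComponents <- function(graph) {
  lab <- seq_len(graph$nNodes)
  i <- graph$edgeFrom; j <- graph$edgeTo
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  repeat {
    m1 <- tapply(lab[j], i, min)
    m2 <- tapply(lab[i], j, min)
    new <- lab
    k1 <- as.integer(names(m1)); new[k1] <- pmin(new[k1], m1)
    k2 <- as.integer(names(m2)); new[k2] <- pmin(new[k2], m2)
    if (identical(new, lab)) break
    lab <- new
  }
  match(lab, sort(unique(lab)))
}

#' Solve the pairwise current flow between two protected areas
#'
#' Injects `injection` Amps at the source supernode and grounds the
#' destination, solving the Kirchhoff/Laplacian system by sparse
#' factorization. The per-cell current density is half the sum of the
#' absolute currents on the cell's incident edges (so a one-cell-wide
#' bottleneck carries the full injected current). The relative residual
#' of the solve is checked against `tol`.
#'
#' @param graph a `ConductanceGraph` from [buildConductanceGraph()].
#' @param srcPa,dstPa PA names.
#' @param injection injected current in Amps (default 1).
#' @param tol maximum relative solver residual (default 1e-8).
#' @return list with `grid` (density [RasterGrid-class], `NA` outside
#'   the domain), `effectiveResistance`, `injection`, `srcPa`, `dstPa`
#'   and `residual`.
#' @export
solvePairCurrent <- function(graph, srcPa, dstPa, injection = 1,
                             tol = 1e-8) {
  s <- graph$paNode[[srcPa]]; t <- graph$paNode[[dstPa]]
  comp <- .graphComponents(graph)
  if (comp[s] != comp[t])
    stop("PAs ", srcPa, " and ", dstPa,
         " are disconnected in the graph domain")
  n <- graph$nNodes
  i <- graph$edgeFrom; j <- graph$edgeTo; g <- graph$conductance
  keep <- i != j
  i <- i[keep]; j <- j[keep]; g <- g[keep]
  L <- Matrix::sparseMatrix(i = c(i, j, i, j), j = c(j, i, i, j),
                            x = c(-g, -g, g, g), dims = c(n, n))
  ## restrict to the component of the pair, ground t
  inComp <- which(comp == comp[s])
  red <- setdiff(inComp, t)
  b <- numeric(length(red))
  b[match(s, red)] <- injection
  Lred <- L[red, red, drop = FALSE]
  v <- as.numeric(Matrix::solve(Lred, b))
  resid <- sqrt(sum((as.numeric(Lred %*% v) - b)^2)) /
    max(sqrt(sum(b^2)), .Machine$double.eps)
  if (resid > tol)
    stop(sprintf("solver residual %.3g exceeds tolerance %.3g", resid, tol))
  pot <- rep(NA_real_, n)
  pot[red] <- v; pot[t] <- 0
  ## per-cell density on the original cell graph: PA member cells share
  ## their supernode's potential, so internal PA edges carry no current
  nr <- graph$dims[1]; nc <- graph$dims[2]
  potCell <- matrix(NA_real_, nr, nc)
  inDomain <- !is.na(graph$node)
  potCell[inDomain] <- pot[graph$node[inDomain]]
  Icur <- abs(graph$conductance *
                (potCell[graph$cellFrom] - potCell[graph$cellTo]))
  Icur[is.na(Icur)] <- 0
  dens <- numeric(nr * nc)
  dens <- dens + unname(tapply(c(Icur, Icur), c(graph$cellFrom, graph$cellTo),
                               sum)[as.character(seq_len(nr * nc))])
  dens[is.na(dens)] <- 0
  densM <- matrix(dens / 2, nr, nc)
  densM[!inDomain] <- NA_real_
  list(grid = rasterGrid(densM, cellsize = graph$cellsize,
                         origin = graph$origin),
       effectiveResistance = unname(pot[s] / injection),
       injection = injection, srcPa = srcPa, dstPa = dstPa,
       residual = resid)
}

#' Fill pinch-point current maps for corridor links
#'
#' For each reachable link, solves the pairwise current flow restricted
#' to the truncated corridor (plus the two PA masks) and stores the
#' density map on the link. Links whose corridor does not connect the
#' two PAs are flagged with a warning and left without a map.
#'
#' @param links list of [CorridorLink-class].
#' @param res a [ResistanceSurface-class].
#' @param pas named list of binary PA masks.
#' @param injection injected current in Amps (default 1).
#' @return the links with `currentMap` filled where solvable.
#' @export
pinchpointMaps <- function(links, res, pas, injection = 1) {
  for (k in seq_along(links)) {
    l <- links[[k]]
    if (!l@reachable || is.null(l@corridorMask)) next
    pair <- pas[c(l@paFrom, l@paTo)]
    ok <- tryCatch({
      graph <- buildConductanceGraph(res, pair, domainMask = l@corridorMask)
      sol <- solvePairCurrent(graph, l@paFrom, l@paTo, injection)
      links[[k]]@currentMap <- sol$grid
      TRUE
    }, error = function(e) {
      warning(sprintf("link %s-%s: %s", l@paFrom, l@paTo,
                      conditionMessage(e)))
      FALSE
    })
  }
  links
}

#' Per-corridor current-density summaries
#'
#' Mean and maximum current density over the corridor cells outside the
#' PA supernodes, one row per link with a filled current map.
#'
#' @param links list of [CorridorLink-class] after [pinchpointMaps()].
#' @param pas named list of binary PA masks (cells excluded from the
#'   summary).
#' @return data.frame with from, to, mean_density, max_density.
#' @export
pinchpointSummary <- function(links, pas) {
  asMat <- function(m) {
    v <- if (is(m, "RasterGrid")) m@values else m
    !is.na(v) & v != 0
  }
  rows <- lapply(links, function(l) {
    if (is.null(l@currentMap)) return(NULL)
    d <- l@currentMap@values
    excl <- asMat(pas[[l@paFrom]]) | asMat(pas[[l@paTo]])
    d[excl] <- NA_real_
    data.frame(from = l@paFrom, to = l@paTo,
               mean_density = mean(d, na.rm = TRUE),
               max_density = max(d, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Current-flow centrality of corridor links
#'
#' Builds the reduced PA network in which each link is a resistor of
#' resistance `lcpCost`; for every unordered PA pair in the same
#' component, 1 A is injected at one PA and grounded at the other, and
#' the absolute current through each link is recorded. A link's
#' centrality is the sum over all pairs (Amps). Disconnected networks
#' are handled per component with a warning.
#'
#' @param links list of [CorridorLink-class] (reachable links are used).
#' @param injection injected current per pair in Amps (default 1).
#' @return the links with `centrality` filled.
#' @export
linkCentrality <- function(links, injection = 1) {
  use <- which(vapply(links, function(l) l@reachable, logical(1)))
  if (length(use) < 1L) stop("no reachable links")
  pasAll <- unique(unlist(lapply(links[use],
                                 function(l) c(l@paFrom, l@paTo))))
  n <- length(pasAll)
  ei <- match(vapply(links[use], function(l) l@paFrom, character(1)), pasAll)
  ej <- match(vapply(links[use], function(l) l@paTo, character(1)), pasAll)
  rl <- vapply(links[use], function(l) l@lcpCost, numeric(1))
  g <- 1 / pmax(rl, 1e-9)  # zero-cost links become near-ideal conductors
  L <- matrix(0, n, n)
  for (k in seq_along(use)) {
    L[ei[k], ej[k]] <- L[ei[k], ej[k]] - g[k]
    L[ej[k], ei[k]] <- L[ej[k], ei[k]] - g[k]
    L[ei[k], ei[k]] <- L[ei[k], ei[k]] + g[k]
    L[ej[k], ej[k]] <- L[ej[k], ej[k]] + g[k]
  }
  ## components of the reduced network
  lab <- seq_len(n)
  repeat {
    new <- lab
    for (k in seq_along(use)) {
      m <- min(new[ei[k]], new[ej[k]])
      new[ei[k]] <- m; new[ej[k]] <- m
    }
    if (identical(new, lab)) break
    lab <- new
  }
  if (length(unique(lab)) > 1L)
    warning("PA network is disconnected; centrality computed per component")
  cent <- numeric(length(use))
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (lab[a] != lab[b]) next
    nodes <- which(lab == lab[a])
    red <- setdiff(nodes, b)
    rhs <- numeric(length(red)); rhs[match(a, red)] <- injection
    v <- rep(0, n)
    v[red] <- solve(L[red, red, drop = FALSE], rhs)
    cent <- cent + abs(g * (v[ei] - v[ej]))
  }
  for (k in seq_along(use)) links[[use[k]]]@centrality <- cent[k]
  links
}
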