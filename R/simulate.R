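#' Configuration for the synthetic landscape generator
#'
#' Defaults encode the statistical structure the downstream analysis
#' assumes: a ~60 x 60 km window at 1 km resolution, 9 protected areas,
#' ~300 presence points per time step, cropland growing 6.71% -> 8.79%
#' -> 13.14% across the steps labelled 2000/2010/2019, and a
#' suitability ground truth dominated by a positive effect of distance
#' to cropland (with distance to houses second), emulating the
#' avoidance of cultivated and settled areas that drives elephant
#' distributions.
#'
#' @slot nrows,ncols grid shape.
#' @slot cellsize cell size in km.
#' @slot nPas number of protected-area polygons.
#' @slot nPresence presence points per time step.
#' @slot timeSteps numeric step labels.
#' @slot croplandTargets target cropland fraction per step (non-decreasing).
#' @slot smoothness correlation length of the random fields, in cells.
#' @slot effectWeights named covariate weights of the true suitability;
#'   `dist_cropland` must carry the strictly dominant positive weight.
#' @slot seed master seed; fully determines all outputs.
#' @export
setClass("SimulationConfig",
  representation(nrows = "numeric", ncols = "numeric", cellsize = "numeric",
                 nPas = "numeric", nPresence = "numeric",
                 timeSteps = "numeric", croplandTargets = "numeric",
                 smoothness = "numeric", effectWeights = "numeric",
                 seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (any(diff(object@croplandTargets) < 0))
    return("cropland target fractions must be non-decreasing")
  if (length(object@croplandTargets) != length(object@timeSteps))
    return("one cropland target per time step required")
  w <- object@effectWeights
  if (!"dist_cropland" %in% names(w))
    return("effectWeights must include dist_cropland")
  if (w[["dist_cropland"]] <= 0 ||
      w[["dist_cropland"]] <= max(abs(w[setdiff(names(w), "dist_cropland")])))
    return("dist_cropland must carry the strictly dominant positive weight")
  TRUE
})

#' @rdname SimulationConfig-class
#' @param nrows,ncols,cellsize,nPas,nPresence,timeSteps,croplandTargets,smoothness,effectWeights,seed
#'   see the class slots.
#' @return a `SimulationConfig`.
#' @export
simulationConfig <- function(nrows = 60, ncols = 60, cellsize = 1,
                             nPas = 9, nPresence = 300,
                             timeSteps = c(2000, 2010, 2019),
                             croplandTargets = c(0.0671, 0.0879, 0.1314),
                             smoothness = 6,
                             effectWeights = c(dist_cropland = 5,
                                               dist_houses = 2.4,
                                               evi = 1.2, rainfall = 0.8,
                                               elevation = 0.4,
                                               slope = -1,
                                               dist_rivers = -0.8,
                                               dist_roads = 0.6),
                             seed = 1) {
  new("SimulationConfig", nrows = nrows, ncols = ncols, cellsize = cellsize,
      nPas = nPas, nPresence = nPresence, timeSteps = timeSteps,
      croplandTargets = croplandTargets, smoothness = smoothness,
      effectWeights = effectWeights, seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d x %d cells (%g km), %d PAs, %d presences/step\n",
    object@nrows, object@ncols, object@cellsize, object@nPas,
    object@nPresence))
  cat(sprintf("  steps %s; cropland targets %s; seed %d\n",
              paste(object@timeSteps, collapse = "/"),
              paste(sprintf("%.2f%%", 100 * object@croplandTargets),
                    collapse = "/"), object@seed))
})

## isotropic smooth Gaussian random field: white noise convolved with a
## separable Gaussian kernel of the configured correlation length
.smoothField <- function(nr, nc, len) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (len <= 0) return(z)
  rad <- max(1L, ceiling(2.5 * len))
  k <- exp(-(seq(-rad, rad))^2 / (2 * len^2))
  k <- k / sum(k)
  pad <- function(v, r) c(rev(v[seq_len(r)]), v, rev(v[length(v) - seq_len(r) + 1L]))
  conv1 <- function(v) {
    vp <- pad(v, rad)
    out <- stats::filter(vp, k, sides = 2)
    as.numeric(out[(rad + 1L):(rad + length(v))])
  }
  z <- apply(z, 2L, conv1)
  z <- t(apply(z, 1L, conv1))
  (z - mean(z)) / sd(z)
}

## slope as the maximum absolute central difference of elevation, per km
.slopeFromElevation <- function(elev, cellsize) {
  nr <- nrow(elev); nc <- ncol(elev)
  dx <- matrix(0, nr, nc); dy <- matrix(0, nr, nc)
  dx[, 2:(nc - 1)] <- abs(elev[, 3:nc] - elev[, 1:(nc - 2)]) / (2 * cellsize)
  dx[, 1] <- abs(elev[, 2] - elev[, 1]) / cellsize
  dx[, nc] <- abs(elev[, nc] - elev[, nc - 1]) / cellsize
  dy[2:(nr - 1), ] <- abs(elev[3:nr, ] - elev[1:(nr - 2), ]) / (2 * cellsize)
  dy[1, ] <- abs(elev[2, ] - elev[1, ]) / cellsize
  dy[nr, ] <- abs(elev[nr, ] - elev[nr - 1, ]) / cellsize
  pmax(dx, dy)
}

#' Simulate the protected-area network
#'
#' Places `nPas` disjoint rectangular PAs on a regular arrangement with
#' seeded jitter and at least two cells of separation.
#'
#' @param cfg a `SimulationConfig`.
#' @return named list of binary PA [RasterGrid-class] masks.
#' @export
simulatePAs <- function(cfg) {
  nr <- cfg@nrows; nc <- cfg@ncols
  .withSeed(.substream(cfg@seed, "pas"), {
    gridRows <- ceiling(sqrt(cfg@nPas))
    gridCols <- ceiling(cfg@nPas / gridRows)
    bh <- nr %/% gridRows; bw <- nc %/% gridCols
    pas <- list()
    i <- 0L
    for (gr in seq_len(gridRows)) for (gc in seq_len(gridCols)) {
      if (i >= cfg@nPas) break
      i <- i + 1L
      h <- sample(max(3, bh %/% 3):max(4, bh %/% 2), 1)
      w <- sample(max(3, bw %/% 3):max(4, bw %/% 2), 1)
      r0 <- (gr - 1L) * bh + sample.int(max(1, bh - h - 2), 1) + 1L
      c0 <- (gc - 1L) * bw + sample.int(max(1, bw - w - 2), 1) + 1L
      m <- matrix(0, nr, nc)
      m[r0:min(nr, r0 + h - 1L), c0:min(nc, c0 + w - 1L)] <- 1
      pas[[paste0("PA", i)]] <- rasterGrid(m, cellsize = cfg@cellsize,
                                           origin = c(0, nr * cfg@cellsize))
    }
    pas
  })
}

## random-walk polyline mask (rivers/roads); orientations is a logical
## vector (TRUE = north-south line), one entry per line
.lineMask <- function(nr, nc, orientations, drift) {
  m <- matrix(0, nr, nc)
  for (vertical in orientations) {
    pos <- sample.int(if (vertical) nc else nr, 1)
    for (t in seq_len(if (vertical) nr else nc)) {
      if (vertical) m[t, pos] <- 1 else m[pos, t] <- 1
      pos <- pos + sample(c(-1, 0, 1), 1, prob = c(drift, 1 - 2 * drift, drift))
      pos <- min(max(pos, 1), if (vertical) nc else nr)
    }
  }
  m
}

#' Simulate the environmental covariate stack
#'
#' Generates smooth correlated fields (elevation, an EVI proxy,
#' rainfall), slope as the maximum central difference of elevation, a
#' terrain-ruggedness layer built as slope plus small noise (so the
#' collinearity screen has a pair to catch), and houses/roads/rivers
#' feature masks with their Euclidean distance surfaces. Distance to
#' cropland is added per time step by [stackForStep()] once the
#' cropland series exists.
#'
#' @param cfg a `SimulationConfig`.
#' @param pas PA masks from [simulatePAs()] (houses are placed outside
#'   PAs).
#' @return list with `stack` (a [CovariateStack-class]) and `masks`
#'   (houses/roads/rivers binary [RasterGrid-class]s).
#' @export
simulateCovariates <- function(cfg, pas = simulatePAs(cfg)) {
  nr <- cfg@nrows; nc <- cfg@ncols; cs <- cfg@cellsize
  origin <- c(0, nr * cs)
  mk <- function(v) rasterGrid(v, cellsize = cs, origin = origin)
  .withSeed(.substream(cfg@seed, "covariates"), {
    elev <- .smoothField(nr, nc, cfg@smoothness)
    evi <- .smoothField(nr, nc, cfg@smoothness)
    rain <- .smoothField(nr, nc, cfg@smoothness * 1.5)
    slope <- .slopeFromElevation(elev, cs)
    rugg <- slope + rnorm(nr * nc, sd = 0.2 * sd(slope))
    paAny <- Reduce(`|`, lapply(pas, function(p) p@values != 0))
    outside <- which(!paAny)
    houses <- matrix(0, nr, nc)
    houses[sample(outside, min(25L, length(outside)))] <- 1
    ## settlement nuclei seeding the cropland expansion; distinct from
    ## the scattered houses so the two distance surfaces stay separable
    nuclei <- matrix(0, nr, nc)
    nuclei[sample(outside, min(8L, length(outside)))] <- 1
    roads <- .lineMask(nr, nc, c(TRUE, TRUE, FALSE), 0.03)
    rivers <- .lineMask(nr, nc, c(FALSE, TRUE), 0.35)
    masks <- list(houses = mk(houses), roads = mk(roads),
                  rivers = mk(rivers), nuclei = mk(nuclei))
    stack <- covariateStack(list(
      elevation = mk(elev), slope = mk(slope), ruggedness = mk(rugg),
      evi = mk(evi), rainfall = mk(rain),
      dist_houses = euclideanDistanceSurface(masks$houses),
      dist_roads = euclideanDistanceSurface(masks$roads),
      dist_rivers = euclideanDistanceSurface(masks$rivers)))
    list(stack = stack, masks = masks)
  })
}

#' Simulate the expanding cropland land-cover series
#'
#' Cropland grows outward from seeded settlement nuclei,
#' preferentially over flat, river-near cells outside PAs,
#' reaching each step's target fraction of the landscape to within one
#' cell (well inside +-0.5 percent points). Masks are nested over time.
#' Remaining cells are classed by thresholding the EVI proxy and the
#' river network: water (5) on river cells, burned (3) on the lowest
#' EVI quintile, dense woodland (1) on the top EVI tercile of the rest,
#' open woodland (2) elsewhere; cropland is 4.
#'
#' @param cfg a `SimulationConfig`.
#' @param cov output of [simulateCovariates()].
#' @param pas PA masks.
#' @return list of classified land-cover [RasterGrid-class]s, one per
#'   time step.
#' @export
simulateCroplandSeries <- function(cfg, cov, pas) {
  nr <- cfg@nrows; nc <- cfg@ncols
  n <- nr * nc
  paAny <- Reduce(`|`, lapply(pas, function(p) p@values != 0))
  maxFrac <- sum(!paAny) / n
  if (any(cfg@croplandTargets >= maxFrac))
    stop("cropland target exceeds the non-PA share of the landscape")
  slope <- cov$stack[["slope"]]@values
  dRiv <- cov$stack[["dist_rivers"]]@values
  nrm <- function(x) (x - min(x)) / max(1e-12, diff(range(x)))
  .withSeed(.substream(cfg@seed, "cropland"), {
    pref <- 1 + 99 * nrm(2 * nrm(slope) + 0.3 * nrm(dRiv) +
                           0.8 * matrix(runif(n), nr, nc))
    pseudoRes <- new("ResistanceSurface",
                     grid = rasterGrid(pref, cellsize = cfg@cellsize,
                                       origin = cov$stack[[1L]]@origin),
                     c = 0.25)
    spread <- costWeightedDistance(pseudoRes, cov$masks$nuclei)@values
    spread[paAny] <- Inf
    ord <- order(spread)
    evi <- cov$stack[["evi"]]@values
    river <- cov$masks$rivers@values != 0
    lapply(seq_along(cfg@timeSteps), function(t) {
      k <- round(cfg@croplandTargets[t] * n)
      crop <- matrix(FALSE, nr, nc)
      crop[ord[seq_len(k)]] <- TRUE
      lc <- matrix(2, nr, nc)              # open woodland
      rest <- !crop & !river
      qs <- quantile(evi[rest], c(0.2, 0.67))
      lc[evi <= qs[1]] <- 3                # burned
      lc[evi > qs[2]] <- 1                 # dense woodland
      lc[river] <- 5                       # water
      lc[crop] <- 4                        # cropland
      rasterGrid(lc, cellsize = cfg@cellsize,
                 origin = cov$stack[[1L]]@origin)
    })
  })
}

#' Covariate stack for one time step
#'
#' Adds the distance-to-cropland surface of the step's land cover to
#' the base covariate stack.
#'
#' @param cov output of [simulateCovariates()].
#' @param landcoverStep classified [RasterGrid-class] of the step.
#' @param croplandCode cropland class code (default 4).
#' @return a [CovariateStack-class].
#' @export
stackForStep <- function(cov, landcoverStep, croplandCode = 4) {
  cropMask <- rasterGrid((landcoverStep@values == croplandCode) + 0,
                         cellsize = landcoverStep@cellsize,
                         origin = landcoverStep@origin)
  grids <- cov$stack@grids
  grids$dist_cropland <- euclideanDistanceSurface(cropMask)
  covariateStack(grids)
}

#' True suitability surface of the generator
#'
#' Logistic function of the standardized covariates under the
#' configured effect weights; the dominant positive weight on distance
#' to cropland makes suitability monotone non-decreasing in that
#' distance, the ground truth the recovery tests check against. The
#' linear predictor is standardized over the landscape and passed
#' through a sharpened, offset logistic, so high suitability is
#' confined to a minority of the window (~18% of cells above 0.5, the
#' share a compressed wildlife distribution shows) with strong contrast
#' between good and poor habitat.
#'
#' @param cfg a `SimulationConfig`.
#' @param stack full per-step [CovariateStack-class] (with
#'   dist_cropland).
#' @param sharpness logistic slope on the standardized predictor
#'   (default 4).
#' @param offset standardized-predictor value mapped to suitability 0.5
#'   (default 0.9, i.e. roughly the upper fifth of cells).
#' @return a [SuitabilitySurface-class].
#' @export
trueSuitability <- function(cfg, stack, sharpness = 4, offset = 0.9) {
  w <- cfg@effectWeights
  vals <- stackValues(stack)
  eta <- 0
  for (v in names(w)) {
    x <- vals[, v]
    z <- (x - mean(x, na.rm = TRUE)) / max(1e-12, sd(x, na.rm = TRUE))
    eta <- eta + w[[v]] * z
  }
  eta <- (eta - mean(eta, na.rm = TRUE)) / max(1e-12, sd(eta, na.rm = TRUE))
  g <- stack@grids[[1L]]
  suit <- 1 / (1 + exp(-sharpness * (eta - offset)))
  new("SuitabilitySurface",
      grid = rasterGrid(matrix(suit, nrows(g), ncols(g)),
                        cellsize = g@cellsize, origin = g@origin))
}

#' Sample presence points from a true suitability surface
#'
#' `n` cells drawn without replacement with probability proportional to
#' suitability; points sit at cell centers.
#'
#' @param suit a [SuitabilitySurface-class].
#' @param n number of points.
#' @param seed RNG seed.
#' @return data.frame with `x`, `y`.
#' @export
samplePresences <- function(suit, n, seed = 1) {
  stopifnot(n >= 1)
  v <- suit@grid@values
  pos <- which(!is.na(v) & v > 0)
  if (length(pos) < n)
    stop(sprintf("only %d cells with positive suitability for n = %d",
                 length(pos), n))
  idx <- .withSeed(seed, sample(pos, n, prob = v[pos]))
  nr <- nrow(v)
  cellCenters(suit@grid, (idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
}

#' Simulate validation transects and interview reports
#'
#' Transect centroids sit on a 5 km grid over the window, each with a
#' Bernoulli presence flag with success probability equal to the true
#' suitability at the centroid. The report table draws, per link and
#' respondent, Poisson sighting counts whose mean is proportional to
#' the link's mean corridor current density (uniform when no current
#' maps are filled), scaled so the least-used active corridor still
#' yields clearly nonzero counts; one configurable link is forced to
#' zero reports, emulating a corridor abandoned before the study
#' period.
#'
#' @param suit true [SuitabilitySurface-class].
#' @param links list of [CorridorLink-class].
#' @param cfg a `SimulationConfig`.
#' @param inactiveLink index of the link forced silent (default: the
#'   last reachable link).
#' @param respondentsPerSite respondents interviewed per site (default 10).
#' @param meanSightings Poisson mean for a link of average current
#'   density (default 12).
#' @param transectSpacing transect grid spacing in km (default 5).
#' @return list with `transects` (x, y, presence), `reports` (site,
#'   sightings, season) and `siteLinks` (site, from, to).
#' @export
simulateValidationData <- function(suit, links, cfg,
                                   inactiveLink = NULL,
                                   respondentsPerSite = 10,
                                   meanSightings = 12,
                                   transectSpacing = 5) {
  g <- suit@grid
  .withSeed(.substream(cfg@seed, "validation"), {
    xs <- seq(transectSpacing / 2, ncols(g) * g@cellsize, by = transectSpacing)
    ys <- seq(transectSpacing / 2, nrows(g) * g@cellsize, by = transectSpacing)
    ctr <- expand.grid(x = xs, y = ys)
    rc <- cellFromXY(g, ctr$x, ctr$y)
    p <- g@values[cbind(rc$row, rc$col)]
    p[is.na(p)] <- 0
    transects <- data.frame(x = ctr$x, y = ctr$y,
                            presence = rbinom(nrow(ctr), 1, p))
    use <- which(vapply(links, function(l) l@reachable, logical(1)))
    if (is.null(inactiveLink)) inactiveLink <- use[length(use)]
    dens <- vapply(links[use], function(l) {
      if (!is.null(l@currentMap))
        mean(l@currentMap@values, na.rm = TRUE) else 1
    }, numeric(1))
    lam <- meanSightings * pmax(dens / mean(dens), 0.25)
    rows <- lapply(seq_along(use), function(k) {
      l <- links[[use[k]]]
      site <- paste0("site_", l@paFrom, "_", l@paTo)
      cnt <- if (use[k] == inactiveLink) rep(0L, respondentsPerSite)
             else rpois(respondentsPerSite, lam[k]) + 1L
      data.frame(site = site, sightings = cnt,
                 season = sample(c("Wet", "Dry"), respondentsPerSite,
                                 replace = TRUE, prob = c(0.6, 0.4)))
    })
    reports <- do.call(rbind, rows)
    siteLinks <- do.call(rbind, lapply(links[use], function(l)
      data.frame(site = paste0("site_", l@paFrom, "_", l@paTo),
                 from = l@paFrom, to = l@paTo)))
    list(transects = transects, reports = reports, siteLinks = siteLinks)
  })
}

#' Simulate a complete synthetic study landscape
#'
#' Orchestrates PA placement, covariates, cropland series, per-step
#' stacks, true suitability and presence samples, all reproducible from
#' the config's seed.
#'
#' @param cfg a `SimulationConfig` (default [simulationConfig()]).
#' @return list with `cfg`, `pas`, `cov`, `landcover`, `stacks`,
#'   `truth` (per-step [SuitabilitySurface-class]) and `presences`
#'   (per-step point data.frames), the last three named by time step.
#' @export
simulateLandscape <- function(cfg = simulationConfig()) {
  pas <- simulatePAs(cfg)
  cov <- simulateCovariates(cfg, pas)
  landcover <- simulateCroplandSeries(cfg, cov, pas)
  lbl <- as.character(cfg@timeSteps)
  stacks <- lapply(landcover, function(lc) stackForStep(cov, lc))
  truth <- lapply(stacks, function(s) trueSuitability(cfg, s))
  presences <- lapply(seq_along(stacks), function(t)
    samplePresences(truth[[t]], cfg@nPresence,
                    .substream(cfg@seed, paste0("presence", t))))
  names(landcover) <- names(stacks) <- names(truth) <-
    names(presences) <- lbl
  list(cfg = cfg, pas = pas, cov = cov, landcover = landcover,
       stacks = stacks, truth = truth, presences = presences)
}
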