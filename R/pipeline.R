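#' Assemble a pipeline configuration
#'
#' A plain nested list (class `pipelineConfig`) collecting the settings
#' of every stage; it round-trips losslessly through YAML via
#' [readPipelineConfig()]/[writePipelineConfig()]. All randomness flows
#' from the single `seed` through named substreams.
#'
#' @param sim list of [simulationConfig()] arguments (less the seed).
#' @param nAbsences pseudo-absences per time step (default 1000).
#' @param replications ensemble train/test rounds (default 10).
#' @param trainFraction training share per class (default 0.75).
#' @param jackknife run jackknife importance per step (default FALSE;
#'   it refits the ensemble once per covariate).
#' @param shapeFactor resistance shape factor c (default 0.25).
#' @param cutoff corridor truncation in cw-km (default 200).
#' @param pairs optional data.frame(from, to) restricting PA pairs.
#' @param croplandCode land-cover code for cropland (default 4).
#' @param seed master seed.
#' @param outDir optional directory for artifacts (CSV, ASCII rasters).
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(sim = list(), nAbsences = 1000,
                           replications = 10, trainFraction = 0.75,
                           jackknife = FALSE, shapeFactor = 0.25,
                           cutoff = 200, pairs = NULL, croplandCode = 4,
                           seed = 1, outDir = NULL) {
  structure(list(sim = sim, nAbsences = nAbsences,
                 replications = replications,
                 trainFraction = trainFraction, jackknife = jackknife,
                 shapeFactor = shapeFactor, cutoff = cutoff,
                 pairs = pairs, croplandCode = croplandCode, seed = seed,
                 outDir = outDir),
            class = "pipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipelineConfig, raw[setdiff(names(raw), "pairs")])
  if (!is.null(raw$pairs))
    cfg$pairs <- data.frame(from = vapply(raw$pairs, `[[`, "", 1L),
                            to = vapply(raw$pairs, `[[`, "", 2L))
  cfg
}

#' @rdname pipelineConfig
#' @param cfg a `pipelineConfig`.
#' @export
writePipelineConfig <- function(cfg, path) {
  out <- unclass(cfg)
  if (!is.null(out$pairs))
    out$pairs <- lapply(seq_len(nrow(out$pairs)), function(i)
      c(out$pairs$from[i], out$pairs$to[i]))
  out <- Filter(Negate(is.null), out)
  yaml::write_yaml(out, path)
  invisible(path)
}

.logStage <- function(log, stage, ...) {
  msg <- sprintf("[%s] %s", stage, sprintf(...))
  message(msg)
  c(log, msg)
}

#' Run the full per-time-step connectivity analysis
#'
#' simulate -> collinearity screen -> ensemble SDM -> suitability ->
#' resistance -> least-cost corridors -> circuit (pinch points,
#' centrality) -> change accounting -> validation, per time step, plus
#' the cross-step link table sorted by descending final-step
#' centrality. With `cfg$outDir` set, CSV tables and ASCII rasters are
#' written there.
#'
#' @param cfg a [pipelineConfig()].
#' @return list with `steps` (per-step results), `changeTable`,
#'   `encroachment`, `activity`, `validation`, `linksWide` (Table-style
#'   cross-step link table) and `log`.
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  log <- character(0)
  simArgs <- cfg$sim; simArgs$seed <- cfg$seed
  scfg <- do.call(simulationConfig, simArgs)
  log <- .logStage(log, "simulate", "seed %d, %d x %d cells, %d PAs",
                   cfg$seed, scfg@nrows, scfg@ncols, scfg@nPas)
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  scn <- simulateLandscape(scfg)
  log <- .logStage(log, "simulate", "done in %.2f s", tic() - t0)
  lbl <- as.character(scfg@timeSteps)
  background <- rasterGrid(
    matrix(1, scfg@nrows, scfg@ncols), cellsize = scfg@cellsize,
    origin = scn$cov$stack[[1L]]@origin)
  steps <- list()
  for (t in seq_along(lbl)) {
    stack <- scn$stacks[[t]]
    filt <- collinearityFilter(stack)
    log <- .logStage(log, paste0("sdm-", lbl[t]),
                     "dropped collinear: %s",
                     if (length(filt$dropped)) paste(filt$dropped,
                                                     collapse = ", ")
                     else "(none)")
    pres <- scn$presences[[t]]
    abs_ <- samplePseudoAbsences(background, pres, cfg$nAbsences,
                                 .substream(cfg$seed, paste0("abs", t)))
    t0 <- tic()
    model <- fitEnsemble(pres, abs_, filt$stack,
                         replications = cfg$replications,
                         trainFraction = cfg$trainFraction,
                         seed = .substream(cfg$seed, paste0("fit", t)))
    log <- .logStage(log, paste0("sdm-", lbl[t]),
                     "%d presences, %d absences, %d replications, train %g%%: weighted AUC %.3f in %.2f s",
                     nrow(pres), nrow(abs_), cfg$replications,
                     100 * cfg$trainFraction, weightedAuc(model), tic() - t0)
    suit <- classifySuitability(predictSuitability(model, filt$stack))
    imp <- NULL
    if (isTRUE(cfg$jackknife))
      imp <- jackknifeImportance(pres, abs_, filt$stack,
                                 replications = cfg$replications,
                                 trainFraction = cfg$trainFraction,
                                 seed = .substream(cfg$seed,
                                                   paste0("fit", t)),
                                 fullModel = model)
    t0 <- tic()
    res <- suitabilityToResistance(suit, cfg$shapeFactor)
    links <- buildLinkTable(scn$pas, res, pairs = cfg$pairs,
                            cutoff = cfg$cutoff)
    links <- pinchpointMaps(links, res, scn$pas)
    links <- linkCentrality(links)
    log <- .logStage(log, paste0("corridors-", lbl[t]),
                     "%d links (%d reachable), c = %g, cutoff = %g cw-km, %.2f s",
                     length(links),
                     sum(vapply(links, function(l) l@reachable,
                                logical(1))),
                     cfg$shapeFactor, cfg$cutoff, tic() - t0)
    steps[[lbl[t]]] <- list(model = model, suitability = suit,
                            importance = imp, resistance = res,
                            links = links, collinearity = filt)
  }
  changeTable <- composeChangeTable(
    scn$landcover, scfg@timeSteps,
    classNames = c(`1` = "dense_woodland", `2` = "open_woodland",
                   `3` = "burned", `4` = "cropland", `5` = "water"))
  lastLinks <- steps[[length(steps)]]$links
  enc <- corridorEncroachment(lastLinks, scn$landcover, scfg@timeSteps,
                              cfg$croplandCode)
  val <- simulateValidationData(scn$truth[[length(steps)]], lastLinks, scfg)
  act <- corridorActivity(lastLinks, val$reports, val$siteLinks)
  ## binary-map validation of the last step against the transects
  lastSuit <- steps[[length(steps)]]$suitability
  pres <- scn$presences[[length(steps)]]
  abs_ <- samplePseudoAbsences(background, pres, cfg$nAbsences,
                               .substream(cfg$seed,
                                          paste0("abs", length(steps))))
  rcAll <- rbind(pres, abs_)
  rc <- cellFromXY(lastSuit@grid, rcAll$x, rcAll$y)
  scores <- lastSuit@grid@values[cbind(rc$row, rc$col)]
  labels <- c(rep(1L, nrow(pres)), rep(0L, nrow(abs_)))
  okp <- !is.na(scores)
  thr <- maxSensSpecThreshold(scores[okp], labels[okp])
  bm <- binaryMap(lastSuit, thr)
  acc <- binaryMapAccuracy(bm, val$transects)
  log <- .logStage(log, "validate",
                   "threshold %.3f, transect map accuracy %.1f%%",
                   thr, acc)
  linksWide <- .linksWide(steps, act)
  out <- list(steps = steps, scenario = scn, changeTable = changeTable,
              encroachment = enc, activity = act,
              validation = list(threshold = thr, accuracy = acc,
                                transects = val$transects,
                                reports = val$reports),
              linksWide = linksWide, log = log)
  if (!is.null(cfg$outDir)) .writeArtifacts(out, cfg)
  out
}

## cross-step Table-style link summary: CWD:EUD, CWD:LCP and centrality
## per step, plus sightings and status; sorted by last-step centrality
.linksWide <- function(steps, activity) {
  lbl <- names(steps)
  base <- linkTable(steps[[1L]]$links)[, c("from", "to")]
  wide <- base
  for (t in lbl) {
    lt <- linkTable(steps[[t]]$links)
    m <- match(paste(base$from, base$to), paste(lt$from, lt$to))
    wide[[paste0("cwd_eud_", t)]] <- lt$cwd_eud[m]
    wide[[paste0("cwd_lcp_", t)]] <- lt$cwd_lcp[m]
    wide[[paste0("centrality_", t)]] <- lt$centrality[m]
  }
  m <- match(paste(base$from, base$to),
             paste(activity$from, activity$to))
  wide$sightings_mean <- activity$mean[m]
  wide$sightings_sd <- activity$sd[m]
  wide$seasons <- activity$seasons[m]
  wide$n_respondents <- activity$n[m]
  wide$status <- activity$status[m]
  cent <- wide[[paste0("centrality_", lbl[length(lbl)])]]
  wide <- wide[order(-cent), , drop = FALSE]
  rownames(wide) <- NULL
  wide
}

.writeArtifacts <- function(out, cfg) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    write.csv(df, file.path(cfg$outDir, name), row.names = FALSE)
  wcsv(out$changeTable, "change_table.csv")
  wcsv(out$encroachment, "encroachment.csv")
  wcsv(out$activity, "corridor_status.csv")
  wcsv(out$linksWide, "links.csv")
  wcsv(out$validation$transects, "transects.csv")
  wcsv(out$validation$reports, "reports.csv")
  for (t in names(out$steps)) {
    s <- out$steps[[t]]
    writeRaster(s$suitability@grid,
                file.path(cfg$outDir, paste0("suitability_", t, ".asc")))
    writeRaster(s$resistance@grid,
                file.path(cfg$outDir, paste0("resistance_", t, ".asc")))
    auc <- as.data.frame(aucTable(s$model))
    auc <- cbind(learner = rownames(auc), auc)
    wcsv(auc, paste0("auc_table_", t, ".csv"))
    if (!is.null(s$importance))
      wcsv(data.frame(covariate = names(s$importance),
                      contribution_pct = as.numeric(s$importance)),
           paste0("importance_", t, ".csv"))
  }
  writeLines(out$log, file.path(cfg$outDir, "run.log"))
  invisible(cfg$outDir)
}

#' Sensitivity of corridor extraction to c and the cutoff
#'
#' For every combination of shape factor and truncation cutoff, counts
#' the non-empty corridors and the total corridor area -- the evidence
#' base behind choosing an approximately linear transformation and a
#' wide cutoff.
#'
#' @param suit a [SuitabilitySurface-class].
#' @param pas named list of binary PA masks.
#' @param cValues shape factors (default `c(2, 1, 0.5, 0.25)`).
#' @param cutoffs truncation cutoffs in cw-km (default
#'   `c(200, 150, 100, 50)`).
#' @param pairs optional pair restriction as in [buildLinkTable()].
#' @return data.frame with c, cutoff, n_corridors, corridor_area_km2.
#' @export
sensitivityScan <- function(suit, pas, cValues = c(2, 1, 0.5, 0.25),
                            cutoffs = c(200, 150, 100, 50),
                            pairs = NULL) {
  rows <- list()
  for (cc in cValues) {
    res <- suitabilityToResistance(suit, cc)
    cwds <- lapply(pas, function(m) costWeightedDistance(res, m))
    if (is.null(pairs)) {
      cmb <- utils::combn(names(pas), 2L)
      pairs_ <- data.frame(from = cmb[1L, ], to = cmb[2L, ])
    } else pairs_ <- pairs
    vals <- list()
    for (i in seq_len(nrow(pairs_))) {
      a <- pairs_$from[i]; b <- pairs_$to[i]
      lcp <- leastCostPath(res, pas[[a]], pas[[b]], cwd = cwds[[a]])
      if (!lcp$reachable) { vals[[i]] <- NULL; next }
      vals[[i]] <- cwds[[a]]@values + cwds[[b]]@values - lcp$lcpCost
    }
    cellA <- (res@grid@cellsize)^2
    for (cut in cutoffs) {
      nc_ <- 0L; area <- 0
      for (v in vals) {
        if (is.null(v)) next
        m <- sum(is.finite(v) & v <= cut + 1e-9)
        if (m > 0) { nc_ <- nc_ + 1L; area <- area + m * cellA }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(c = cc, cutoff = cut, n_corridors = nc_,
                   corridor_area_km2 = area)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
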