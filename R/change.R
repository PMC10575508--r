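#' Land-cover change statistics from per-step cover percentages
#'
#' Core arithmetic of the change table, usable directly on printed cover
#' figures: per class, interval changes in percent points and the
#' average annual rates over the full span, in % per year and km^2 per
#' year (span = last year label minus first).
#'
#' @param cover numeric matrix, classes x time steps, percent cover.
#' @param years numeric time-step labels (e.g. c(2000, 2010, 2019)).
#' @param totalAreaKm2 total landscape area in km^2.
#' @return data.frame with cover percentages, areas, interval changes,
#'   span change, and annual rates (`rate_pct_yr`, `rate_km2_yr`).
#' @export
changeStatistics <- function(cover, years, totalAreaKm2) {
  stopifnot(is.matrix(cover), ncol(cover) == length(years),
            length(years) >= 2L)
  span <- years[length(years)] - years[1L]
  out <- data.frame(class = rownames(cover), check.names = FALSE)
  for (t in seq_along(years))
    out[[paste0("pct_", years[t])]] <- cover[, t]
  for (t in seq_along(years))
    out[[paste0("area_km2_", years[t])]] <- cover[, t] / 100 * totalAreaKm2
  for (t in seq_len(length(years) - 1L))
    out[[paste0("change_", years[t], "_", years[t + 1L])]] <-
      cover[, t + 1L] - cover[, t]
  out[[paste0("change_", years[1L], "_", years[length(years)])]] <-
    cover[, length(years)] - cover[, 1L]
  out$rate_pct_yr <- (cover[, length(years)] - cover[, 1L]) / span
  out$rate_km2_yr <- (cover[, length(years)] - cover[, 1L]) / 100 *
    totalAreaKm2 / span
  out
}

#' Compose the land-cover change table from classified rasters
#'
#' Computes per-class percent cover over the non-nodata cells of each
#' time step (a class absent from a step covers 0%), then delegates to
#' [changeStatistics()]. Per step the class percentages sum to 100 over
#' the non-nodata domain.
#'
#' @param landcover list of classified [RasterGrid-class]s, one per step.
#' @param years numeric time-step labels.
#' @param totalAreaKm2 total landscape area in km^2 (default: non-nodata
#'   cell count x cell area of the first grid).
#' @param classNames optional named character vector mapping class codes
#'   to labels.
#' @return as [changeStatistics()].
#' @export
composeChangeTable <- function(landcover, years, totalAreaKm2 = NULL,
                               classNames = NULL) {
  stopifnot(length(landcover) == length(years))
  g1 <- landcover[[1L]]
  if (is.null(totalAreaKm2))
    totalAreaKm2 <- sum(!is.na(g1@values)) * g1@cellsize^2
  codes <- sort(unique(unlist(lapply(landcover, function(g)
    unique(g@values[!is.na(g@values)])))))
  cover <- vapply(landcover, function(g) {
    v <- g@values[!is.na(g@values)]
    vapply(codes, function(k) 100 * mean(v == k), numeric(1))
  }, numeric(length(codes)))
  cover <- matrix(cover, nrow = length(codes))
  rownames(cover) <- if (!is.null(classNames))
    unname(classNames[as.character(codes)]) else as.character(codes)
  changeStatistics(cover, years, totalAreaKm2)
}

#' Confusion matrix, overall accuracy and Cohen's kappa
#'
#' Looks up the predicted class under each reference point and
#' cross-tabulates reference against prediction. Overall accuracy is the
#' trace over the total; kappa is `(p_o - p_e) / (1 - p_e)` with the
#' chance agreement `p_e` from the row/column marginals. Points on
#' nodata or outside the grid are excluded and counted.
#'
#' @param reference data.frame with `x`, `y` and a `class` column.
#' @param predicted classified [RasterGrid-class].
#' @return list with `confusion` (reference rows x predicted columns),
#'   `overallAccuracy` (percent), `kappa`, and `nExcluded`.
#' @export
confusionAndKappa <- function(reference, predicted) {
  stopifnot(is(predicted, "RasterGrid"))
  rc <- cellFromXY(predicted, reference$x, reference$y)
  pred <- rep(NA_real_, nrow(reference))
  ok <- !is.na(rc$row)
  pred[ok] <- predicted@values[cbind(rc$row[ok], rc$col[ok])]
  use <- !is.na(pred)
  ref <- reference$class[use]; prd <- pred[use]
  if (length(unique(ref)) < 2L)
    stop("need at least two reference classes")
  lev <- sort(unique(c(ref, prd)))
  cm <- table(factor(ref, levels = lev), factor(prd, levels = lev))
  kappaFromConfusion(cm, nExcluded = sum(!use))
}

#' Accuracy statistics of a confusion matrix
#'
#' @param cm confusion matrix (reference rows x predicted columns).
#' @param nExcluded count of excluded points to carry through.
#' @return list with `confusion`, `overallAccuracy` (percent), `kappa`
#'   and `nExcluded`.
#' @export
kappaFromConfusion <- function(cm, nExcluded = 0L) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe >= 1) 1 else (po - pe) / (1 - pe)
  list(confusion = cm, overallAccuracy = 100 * po, kappa = kappa,
       nExcluded = nExcluded)
}

#' Cropland encroachment of corridors over time
#'
#' Per link and time step, the percent of corridor-mask cells classed as
#' cropland; a link is flagged encroached when the percent exceeds the
#' threshold in any step.
#'
#' @param links list of [CorridorLink-class] with corridor masks.
#' @param landcover list of classified [RasterGrid-class]s per step.
#' @param years time-step labels.
#' @param croplandCode land-cover code for cropland.
#' @param threshold encroachment flag threshold in percent (default 0:
#'   any cropland cell flags the link).
#' @return data.frame with from, to, one percent column per step, and
#'   `encroached`.
#' @export
corridorEncroachment <- function(links, landcover, years, croplandCode,
                                 threshold = 0) {
  rows <- lapply(links, function(l) {
    if (!l@reachable || is.null(l@corridorMask)) return(NULL)
    m <- l@corridorMask@values
    sel <- !is.na(m) & m != 0
    if (!any(sel)) return(NULL)
    pct <- vapply(landcover, function(g)
      100 * mean(g@values[sel] == croplandCode, na.rm = TRUE), numeric(1))
    out <- data.frame(from = l@paFrom, to = l@paTo)
    for (t in seq_along(years)) out[[paste0("pct_", years[t])]] <- pct[t]
    out$encroached <- any(pct > threshold)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Corridor activity status from interview reports
#'
#' Summarizes per-link sighting reports: mean and sample (n-1) SD of the
#' reported counts, the number of respondents, the union of reported
#' seasons, and the status: "active" if any respondent reported at
#' least one sighting in the last year, otherwise "inactive".
#'
#' @param links list of [CorridorLink-class].
#' @param reports data.frame with columns `site`, `sightings` and
#'   optionally `season`.
#' @param siteLinks data.frame mapping `site` to `from`, `to` link ends.
#' @return data.frame with from, to, n, mean, sd, seasons, status.
#' @export
corridorActivity <- function(links, reports, siteLinks) {
  key <- function(a, b) paste(a, b, sep = "|")
  mapKey <- key(siteLinks$from, siteLinks$to)
  reports$linkKey <- mapKey[match(reports$site, siteLinks$site)]
  unmapped <- is.na(reports$linkKey)
  if (any(unmapped)) {
    warning(sum(unmapped), " report(s) at unmapped sites excluded")
    reports <- reports[!unmapped, , drop = FALSE]
  }
  rows <- lapply(links, function(l) {
    sub <- reports[reports$linkKey == key(l@paFrom, l@paTo), , drop = FALSE]
    n <- nrow(sub)
    cnt <- sub$sightings
    seas <- if (!is.null(sub$season) && any(cnt > 0))
      paste(sort(unique(sub$season[cnt > 0])), collapse = " and ") else "-"
    data.frame(from = l@paFrom, to = l@paTo, n = n,
               mean = if (n) mean(cnt) else NA_real_,
               sd = if (n > 1) sd(cnt) else if (n == 1) 0 else NA_real_,
               seasons = seas,
               status = if (n && any(cnt >= 1)) "active" else "inactive")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
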