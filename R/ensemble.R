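#' Sample pseudo-absence points from a background mask
#'
#' Draws `n` cells uniformly without replacement from the background
#' (non-nodata, mask-true) cells, excluding any cell that contains a
#' presence point. Returns cell-center coordinates.
#'
#' @param background [RasterGrid-class]; cells with value 0 or `NA` are
#'   ineligible.
#' @param presences data.frame with columns `x`, `y`.
#' @param n number of pseudo-absences (default 1000).
#' @param seed RNG seed.
#' @return data.frame with columns `x`, `y`.
#' @export
samplePseudoAbsences <- function(background, presences, n = 1000, seed = 1) {
  stopifnot(is(background, "RasterGrid"))
  m <- background@values
  elig <- which(!is.na(m) & m != 0)
  if (nrow(presences) > 0L) {
    rc <- cellFromXY(background, presences$x, presences$y)
    pres <- (rc$col - 1L) * nrow(m) + rc$row
    elig <- setdiff(elig, pres[!is.na(pres)])
  }
  if (length(elig) < n)
    stop(sprintf("only %d eligible background cells for %d pseudo-absences",
                 length(elig), n))
  idx <- .withSeed(seed, sort(sample(elig, n)))
  row <- (idx - 1L) %% nrow(m) + 1L
  col <- (idx - 1L) %/% nrow(m) + 1L
  cellCenters(background, row, col)
}

#' Area under the ROC curve
#'
#' Rank-statistic formulation: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, ties counted 1/2
#' (equivalent to the Mann-Whitney U statistic).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
aucRoc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

.stratifiedSplit <- function(labels, trainFraction) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    ntr <- round(length(idx) * trainFraction)
    train[sample(idx, ntr)] <- TRUE
  }
  train
}

#' Fit the accuracy-weighted suitability ensemble
#'
#' For each of `replications` rounds, the labelled points are split into
#' a training and a test set by a stratified draw that preserves the
#' presence:absence ratio (`trainFraction` of each class trains). Every
#' learner is fitted on the training rows and scored by held-out AUC.
#' Ensemble weights are the per-learner mean AUCs normalized to sum to
#' one. A learner that errors on a replication is logged and excluded
#' from its own mean.
#'
#' @param presences,absences data.frames with `x`, `y`.
#' @param stack [CovariateStack-class] of model covariates.
#' @param learners list of [LearnerSpec-class] (default [defaultLearners()]).
#' @param replications train/test rounds (default 10).
#' @param trainFraction training share per class (default 0.75).
#' @param seed master seed; split and learner seeds are derived from it.
#' @param keepFits retain the fitted learner objects (default TRUE; the
#'   jackknife refits drop them, since only the AUCs are used).
#' @return an [EnsembleModel-class].
#' @export
fitEnsemble <- function(presences, absences, stack,
                        learners = defaultLearners(),
                        replications = 10, trainFraction = 0.75, seed = 1,
                        keepFits = TRUE) {
  if (length(learners) < 2L) stop("need at least two learners")
  x <- rbind(extractCovariates(stack, presences),
             extractCovariates(stack, absences))
  y <- c(rep(1L, nrow(presences)), rep(0L, nrow(absences)))
  ok <- complete.cases(x)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  if (length(y) < 20L) stop("need at least 20 labelled points")
  lnames <- vapply(learners, function(l) l@name, character(1))
  auc <- matrix(NA_real_, length(learners), replications,
                dimnames = list(lnames, NULL))
  fits <- lapply(learners, function(l) vector("list", replications))
  names(fits) <- lnames
  for (rep_ in seq_len(replications)) {
    train <- .withSeed(.substream(seed, paste0("split", rep_)),
                       .stratifiedSplit(y, trainFraction))
    for (li in seq_along(learners)) {
      l <- learners[[li]]
      lseed <- .substream(seed, paste0("learner", l@name, rep_))
      res <- tryCatch({
        fit <- .withSeed(lseed, l@fitFun(x[train, , drop = FALSE],
                                         y[train], lseed))
        p <- l@predictFun(fit, x[!train, , drop = FALSE])
        list(fit = fit, auc = aucRoc(p, y[!train]))
      }, error = function(e) {
        warning(sprintf("learner %s failed on replication %d: %s",
                        l@name, rep_, conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) {
        if (keepFits) fits[[li]][[rep_]] <- res$fit
        auc[li, rep_] <- res$auc
      }
    }
  }
  meanAuc <- rowMeans(auc, na.rm = TRUE)
  if (all(!is.finite(meanAuc))) stop("all learners failed on all replications")
  w <- meanAuc / sum(meanAuc)
  new("EnsembleModel", learners = learners, fits = fits, aucTable = auc,
      weights = setNames(as.numeric(w), lnames),
      replications = replications, trainFraction = trainFraction,
      covariates = colnames(x))
}

#' Accessors for EnsembleModel objects
#'
#' @param x an [EnsembleModel-class].
#' @name ensemble-accessors
#' @aliases ensembleWeights aucTable
NULL

#' @rdname ensemble-accessors
#' @export
setMethod("ensembleWeights", "EnsembleModel", function(x) x@weights)

#' @rdname ensemble-accessors
#' @export
setMethod("aucTable", "EnsembleModel", function(x) x@aucTable)

#' Weighted mean held-out AUC of an ensemble
#'
#' @param model an [EnsembleModel-class].
#' @return weighted average of per-learner mean AUCs, the ensemble's
#'   headline accuracy figure.
#' @export
weightedAuc <- function(model) {
  m <- rowMeans(model@aucTable, na.rm = TRUE)
  sum(model@weights * m, na.rm = TRUE)
}

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: %d learners x %d replications (train %g%%)\n",
              length(object@learners), object@replications,
              100 * object@trainFraction))
  m <- rowMeans(object@aucTable, na.rm = TRUE)
  for (n in names(object@weights))
    cat(sprintf("  %-4s mean AUC %.3f  weight %.3f\n",
                n, m[n], object@weights[n]))
  cat(sprintf("  weighted average AUC: %.3f\n", weightedAuc(object)))
})

#' Predict habitat suitability over a landscape
#'
#' Per cell, each learner's predictions are averaged over its
#' replication fits, then combined by the ensemble weights. Nodata cells
#' propagate.
#'
#' @param model an [EnsembleModel-class].
#' @param stack [CovariateStack-class] containing every model covariate.
#' @return a [SuitabilitySurface-class].
#' @export
predictSuitability <- function(model, stack) {
  missing <- setdiff(model@covariates, layerNames(stack))
  if (length(missing))
    stop("stack is missing model covariate(s): ",
         paste(missing, collapse = ", "))
  vals <- stackValues(stack)[, model@covariates, drop = FALSE]
  ok <- complete.cases(vals)
  out <- rep(NA_real_, nrow(vals))
  if (any(ok)) {
    xo <- vals[ok, , drop = FALSE]
    acc <- numeric(sum(ok))
    for (li in seq_along(model@learners)) {
      l <- model@learners[[li]]
      reps <- Filter(Negate(is.null), model@fits[[li]])
      if (length(reps) == 0L) next
      pl <- rowMeans(vapply(reps, function(f) l@predictFun(f, xo),
                            numeric(sum(ok))))
      acc <- acc + model@weights[li] * pl
    }
    out[ok] <- .clamp01(acc)
  }
  g <- stack@grids[[1L]]
  suit <- rasterGrid(matrix(out, nrows(g), ncols(g)),
                     cellsize = g@cellsize, origin = g@origin,
                     nodata = g@nodata)
  new("SuitabilitySurface", grid = suit)
}

#' Jackknife variable importance
#'
#' For each covariate the ensemble is refitted without it; the raw
#' importance is `max(0, AUC_full - AUC_without)` on the weighted mean
#' held-out AUC, and contributions are normalized to sum to 100%. If
#' every raw importance is zero the contributions are uniform, with a
#' warning.
#'
#' @param presences,absences data.frames with `x`, `y`.
#' @param stack [CovariateStack-class] (>= 2 covariates).
#' @param learners list of [LearnerSpec-class].
#' @param replications,trainFraction,seed as in [fitEnsemble()].
#' @param fullModel optionally a pre-fitted full [EnsembleModel-class]
#'   (with the same settings) to avoid refitting it.
#' @return named numeric vector of percent contributions (sums to 100).
#' @export
jackknifeImportance <- function(presences, absences, stack,
                                learners = defaultLearners(),
                                replications = 10, trainFraction = 0.75,
                                seed = 1, fullModel = NULL) {
  nm <- layerNames(stack)
  if (length(nm) < 2L) stop("need at least two covariates")
  if (is.null(fullModel))
    fullModel <- fitEnsemble(presences, absences, stack, learners,
                             replications, trainFraction, seed)
  aucFull <- weightedAuc(fullModel)
  raw <- setNames(numeric(length(nm)), nm)
  for (v in nm) {
    sub <- covariateStack(stack@grids[setdiff(nm, v)])
    m <- fitEnsemble(presences, absences, sub, learners,
                     replications, trainFraction, seed, keepFits = FALSE)
    raw[v] <- max(0, aucFull - weightedAuc(m))
    gc(FALSE)
  }
  if (sum(raw) == 0) {
    warning("all raw importances are zero; returning uniform contributions")
    return(setNames(rep(100 / length(nm), length(nm)), nm))
  }
  100 * raw / sum(raw)
}
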