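#' Jenks natural breaks
#'
#' Exact dynamic program minimizing the total within-class sum of
#' squared deviations from class means over all partitions of the sorted
#' values into `k` contiguous classes (Fisher's optimal 1-D
#' partitioning). Returns the k-1 upper class boundaries; class j is
#' (b_{j-1}, b_j\] with b_0 = -Inf and b_k = +Inf.
#'
#' @param values numeric vector with at least `k` distinct finite values.
#' @param k number of classes (>= 2).
#' @return numeric vector of k-1 strictly ascending break values.
#' @export
jenksBreaks <- function(values, k = 3) {
  x <- sort(values[is.finite(values)])
  if (k < 2) stop("k must be at least 2")
  ux <- unique(x)
  if (length(ux) < k)
    stop(sprintf("need at least %d distinct values for %d classes",
                 k, k))
  ## weighted DP on unique values
  w <- as.numeric(table(match(x, ux)))
  n <- length(ux)
  cw <- c(0, cumsum(w))
  cs <- c(0, cumsum(w * ux))
  cs2 <- c(0, cumsum(w * ux * ux))
  sse <- function(i, j) {  # i may be a vector, j scalar
    m <- cw[j + 1L] - cw[i]
    s <- cs[j + 1L] - cs[i]
    (cs2[j + 1L] - cs2[i]) - s * s / m
  }
  D <- matrix(Inf, k, n)
  A <- matrix(1L, k, n)  # argmin start index of last class
  D[1L, ] <- sse(1L, seq_len(n))
  for (kk in 2:k) {
    for (j in kk:n) {
      i <- kk:j
      cand <- D[kk - 1L, i - 1L] + sse(i, j)
      best <- which.min(cand)
      D[kk, j] <- cand[best]
      A[kk, j] <- i[best]
    }
  }
  ## backtrack class boundaries
  breaks <- numeric(k - 1L)
  j <- n
  for (kk in k:2) {
    i <- A[kk, j]
    breaks[kk - 1L] <- ux[i - 1L]
    j <- i - 1L
  }
  breaks
}

#' Classify a suitability surface into natural-breaks classes
#'
#' Default three classes following the usual suitability legend:
#' 1 = marginal (lowest), 2 = moderate, 3 = high.
#'
#' @param suit a [SuitabilitySurface-class].
#' @param k number of classes (default 3).
#' @return `suit` with `classes` and `breaks` filled.
#' @export
classifySuitability <- function(suit, k = 3) {
  stopifnot(is(suit, "SuitabilitySurface"))
  v <- suit@grid@values
  breaks <- jenksBreaks(as.vector(v), k)
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  ## class j is (b_{j-1}, b_j]: values equal to a break fall below it
  cls[ok] <- 1 + rowSums(outer(v[ok], breaks, ">"))
  suit@classes <- rasterGrid(cls, cellsize = suit@grid@cellsize,
                             origin = suit@grid@origin,
                             nodata = suit@grid@nodata)
  suit@breaks <- breaks
  validObject(suit)
  suit
}

#' Threshold maximizing sensitivity + specificity
#'
#' Scans the midpoints between adjacent sorted unique scores and returns
#' the one maximizing sensitivity + specificity under the rule
#' score >= threshold -> positive; ties broken toward the lowest
#' threshold.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @return the selected threshold.
#' @export
maxSensSpecThreshold <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("threshold undefined: both classes must be present")
  u <- sort(unique(scores))
  if (length(u) == 1L) return(u)
  cand <- (u[-length(u)] + u[-1L]) / 2
  j <- vapply(cand, function(t) {
    sens <- sum(scores >= t & labels == 1L) / np
    spec <- sum(scores < t & labels == 0L) / nn
    sens + spec
  }, numeric(1))
  cand[which.max(j)]  # which.max takes the first (lowest) maximizer
}

#' Binarize a suitability surface at a threshold
#'
#' @param suit a [SuitabilitySurface-class].
#' @param threshold cut value; cells with suitability >= threshold are 1
#'   (suitable), others 0 (marginal).
#' @return a 0/1 [RasterGrid-class].
#' @export
binaryMap <- function(suit, threshold) {
  stopifnot(is(suit, "SuitabilitySurface"))
  v <- suit@grid@values
  rasterGrid((v >= threshold) + 0, cellsize = suit@grid@cellsize,
             origin = suit@grid@origin, nodata = suit@grid@nodata)
}

#' Agreement of a binary suitability map with presence/absence points
#'
#' Percent of observation points whose presence flag matches the binary
#' class at their cell (presence <-> suitable = 1, absence <-> marginal
#' = 0). Points falling outside the grid or on nodata cells are excluded
#' with a warning.
#'
#' @param binary 0/1 [RasterGrid-class].
#' @param observations data.frame with `x`, `y` and a 0/1 `presence`
#'   column.
#' @return percent agreement in \[0, 100\].
#' @export
binaryMapAccuracy <- function(binary, observations) {
  stopifnot(is(binary, "RasterGrid"))
  rc <- cellFromXY(binary, observations$x, observations$y)
  val <- rep(NA_real_, nrow(observations))
  ok <- !is.na(rc$row)
  val[ok] <- binary@values[cbind(rc$row[ok], rc$col[ok])]
  use <- !is.na(val)
  if (any(!use))
    warning(sum(!use), " point(s) outside the grid or on nodata excluded")
  if (!any(use)) stop("no usable observation points")
  100 * mean((val[use] != 0) == (observations$presence[use] != 0))
}
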