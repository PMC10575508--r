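## small labelled dataset with a clean signal for learner checks
sdmFixture <- function(seed = 1, n = 300) {
  set.seed(seed)
  x <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  p <- plogis(2 * x[, "a"] - 1.2 * x[, "b"])
  y <- rbinom(n, 1, p)
  list(x = x, y = y)
}

test_that("AUC matches brute-force pair counting on random sets", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(aucRoc(scores, labels),
                 oracleAucPairs(scores, labels), tolerance = 1e-12)
  }
  expect_error(aucRoc(1:3, c(1, 1, 1)), "both classes")
})

test_that("every default learner fits, predicts in [0,1] and beats chance", {
  d <- sdmFixture(2)
  for (l in defaultLearners()) {
    fit <- l@fitFun(d$x, d$y, seed = 42)
    p <- l@predictFun(fit, d$x)
    expect_length(p, nrow(d$x))
    expect_true(all(p >= 0 & p <= 1), info = l@name)
    expect_gt(aucRoc(p, d$y), 0.7)
  }
})

test_that("ensemble weights are normalized means of held-out AUCs", {
  d <- sdmFixture(3, n = 200)
  grids <- lapply(c("a", "b", "c"), function(nm)
    rasterGrid(matrix(d$x[1:100, nm], 10, 10), cellsize = 1,
               origin = c(0, 10)))
  names(grids) <- c("a", "b", "c")
  stack <- covariateStack(grids)
  ctr <- cellCenters(grids[[1]], rep(1:10, 10), rep(1:10, each = 10))
  pres <- data.frame(x = ctr$x[d$y[1:100] == 1], y = ctr$y[d$y[1:100] == 1])
  abs_ <- data.frame(x = ctr$x[d$y[1:100] == 0], y = ctr$y[d$y[1:100] == 0])
  m <- fitEnsemble(pres, abs_, stack, replications = 3, seed = 5)
  expect_equal(sum(ensembleWeights(m)), 1, tolerance = 1e-12)
  means <- rowMeans(aucTable(m), na.rm = TRUE)
  expect_equal(as.numeric(ensembleWeights(m)),
               as.numeric(means / sum(means)), tolerance = 1e-12)
  expect_equal(dim(aucTable(m)), c(4L, 3L))
  ## prediction stays in [0, 1] and covers the grid
  suit <- predictSuitability(m, stack)
  sv <- gridValues(suit@grid)
  expect_true(all(sv >= 0 & sv <= 1))
  expect_error(predictSuitability(m, covariateStack(grids[1:2])),
               "missing model covariate")
})

test_that("pseudo-absences avoid presence cells and respect the mask", {
  bg <- rasterGrid(matrix(1, 20, 20), cellsize = 1, origin = c(0, 20))
  pres <- cellCenters(bg, 1:5, 1:5)
  ab <- samplePseudoAbsences(bg, as.data.frame(pres), n = 50, seed = 3)
  expect_equal(nrow(ab), 50)
  rcP <- cellFromXY(bg, pres$x, pres$y)
  rcA <- cellFromXY(bg, ab$x, ab$y)
  expect_length(intersect(paste(rcP$row, rcP$col),
                          paste(rcA$row, rcA$col)), 0)
  expect_error(samplePseudoAbsences(bg, as.data.frame(pres), n = 1000),
               "eligible background")
})

test_that("stratified split preserves the class ratio", {
  d <- sdmFixture(4, n = 400)
  grids <- list(a = rasterGrid(matrix(rnorm(400), 20, 20),
                               cellsize = 1, origin = c(0, 20)),
                b = rasterGrid(matrix(rnorm(400), 20, 20),
                               cellsize = 1, origin = c(0, 20)))
  stack <- covariateStack(grids)
  ## spot-check through the AUC table shape instead of internals:
  ## 10 replications yield 10 held-out scores per learner
  ctr <- cellCenters(grids$a, rep(1:20, 20), rep(1:20, each = 20))
  pres <- data.frame(x = ctr$x[1:120], y = ctr$y[1:120])
  abs_ <- data.frame(x = ctr$x[121:400], y = ctr$y[121:400])
  m <- fitEnsemble(pres, abs_, stack, replications = 2, seed = 1)
  expect_equal(ncol(aucTable(m)), 2L)
})

test_that("jackknife importance sums to 100 and finds a dominant covariate", {
  set.seed(9)
  n <- 400
  a <- rnorm(n); b <- rnorm(n); c_ <- rnorm(n)
  y <- rbinom(n, 1, plogis(3 * a))
  grids <- list(a = rasterGrid(matrix(a, 20, 20), cellsize = 1,
                               origin = c(0, 20)),
                b = rasterGrid(matrix(b, 20, 20), cellsize = 1,
                               origin = c(0, 20)),
                c = rasterGrid(matrix(c_, 20, 20), cellsize = 1,
                               origin = c(0, 20)))
  stack <- covariateStack(grids)
  ctr <- cellCenters(grids$a, rep(1:20, 20), rep(1:20, each = 20))
  pres <- data.frame(x = ctr$x[y == 1], y = ctr$y[y == 1])
  abs_ <- data.frame(x = ctr$x[y == 0], y = ctr$y[y == 0])
  imp <- jackknifeImportance(pres, abs_, stack, replications = 3, seed = 2)
  expect_equal(sum(imp), 100, tolerance = 1e-9)
  expect_equal(names(which.max(imp)), "a")
  expect_true(all(imp >= 0))
})

test_that("Jenks breaks match the exhaustive-partition oracle", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(6:12, 1)
    v <- round(runif(n, 0, 10), 2)
    if (length(unique(v)) < 3) next
    br <- jenksBreaks(v, 3)
    oracle <- oracleJenksAll(v, 3)
    expect_equal(jenksScore(v, br), oracle$score, tolerance = 1e-9)
  }
  expect_equal(jenksBreaks(c(1, 2, 101, 102), 2), 2)
  expect_error(jenksBreaks(c(1, 1, 1), 2), "distinct")
})

test_that("classification legend and break semantics are honoured", {
  v <- matrix(c(0.05, 0.1, 0.45, 0.5, 0.9, 0.95), 2, 3)
  suit <- new("SuitabilitySurface",
              grid = rasterGrid(v, cellsize = 1, origin = c(0, 2)))
  cls <- classifySuitability(suit, 3)
  expect_equal(sort(unique(as.vector(gridValues(cls@classes)))), 1:3)
  ## values at a break fall in the lower class: (b_{j-1}, b_j]
  onBreak <- gridValues(cls@classes)[v == cls@breaks[1]]
  if (length(onBreak)) expect_true(all(onBreak == 1))
})

test_that("max sens+spec threshold agrees with direct maximization", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(8:40, 1)
    scores <- round(runif(n), 2)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    thr <- maxSensSpecThreshold(scores, labels)
    j <- function(t) {
      sum(scores >= t & labels == 1) / sum(labels == 1) +
        sum(scores < t & labels == 0) / sum(labels == 0)
    }
    u <- sort(unique(scores))
    if (length(u) < 2) next
    cands <- (u[-length(u)] + u[-1]) / 2   # candidate cuts between scores
    js <- vapply(cands, j, numeric(1))
    expect_equal(j(thr), max(js), tolerance = 1e-12)
    ## ties resolve to the lowest cut
    expect_equal(thr, cands[which(js >= max(js) - 1e-12)][1])
  }
  expect_equal(maxSensSpecThreshold(c(0.1, 0.2, 0.8, 0.9),
                                    c(0, 0, 1, 1)), 0.5)
})
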