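test_that("resistance transform endpoints, monotonicity and errors", {
  for (cc in c(2, 1, 0.5, 0.25)) {
    g <- rasterGrid(matrix(c(1, 0, 0.5, NA), 2, 2), cellsize = 1,
                    origin = c(0, 2))
    r <- suitabilityToResistance(g, cc)
    expect_identical(gridValues(r@grid)[1, 1], 1)    # h = 1 -> 1
    expect_identical(gridValues(r@grid)[2, 1], 100)  # h = 0 -> 100
    expect_true(is.na(gridValues(r@grid)[2, 2]))     # nodata propagates
    h <- seq(0, 1, by = 0.01)
    rr <- 100 - 99 * (1 - exp(-cc * h)) / (1 - exp(-cc))
    expect_true(all(diff(rr) < 0))                   # monotone decreasing
  }
  expect_error(suitabilityToResistance(
    rasterGrid(matrix(c(0.5, 1.2), 1, 2), cellsize = 1, origin = c(0, 1))),
    "outside")
  expect_error(suitabilityToResistance(
    rasterGrid(matrix(0.5, 1, 1), cellsize = 1, origin = c(0, 1)), c = 0),
    "positive")
})

test_that("cost-weighted distance equals both oracles on random grids", {
  set.seed(17)
  for (rep in 1:25) {
    R <- matrix(runif(16, 1, 100), 4, 4)
    if (rep %% 3 == 0) R[sample(16, 2)] <- NA  # nodata obstacles
    srcIdx <- sample(which(!is.na(R)), 1)
    src <- matrix(FALSE, 4, 4); src[srcIdx] <- TRUE
    cs <- sample(c(0.5, 1), 1)
    res <- resistanceFixture(ifelse(is.na(R), NA, R), cs)
    got <- gridValues(costWeightedDistance(res, src))
    expect_equal(got, oracleCwdEnum(R, src, cs), tolerance = 1e-9)
  }
})

test_that("cost-weighted distance matches igraph Dijkstra on a larger grid", {
  set.seed(23)
  R <- matrix(runif(30 * 30, 1, 100), 30, 30)
  R[sample(900, 40)] <- NA
  src <- matrix(FALSE, 30, 30); src[c(1, 450, 900)] <- TRUE
  src[is.na(R)] <- FALSE
  res <- resistanceFixture(R, 1)
  got <- gridValues(costWeightedDistance(res, src))
  ora <- oracleCwdIgraph(R, src, 1)
  ## igraph leaves isolated nodata vertices at distance Inf as we do
  expect_equal(got[!is.na(R)], ora[!is.na(R)], tolerance = 1e-8)
})

test_that("uniform resistance gives geometric distances", {
  res <- resistanceFixture(matrix(2, 5, 5), 1)
  src <- matrix(FALSE, 5, 5); src[1, 1] <- TRUE
  D <- gridValues(costWeightedDistance(res, src))
  expect_equal(D[1, 2], 2)              # one cardinal step, cost 1*2
  expect_equal(D[2, 2], 2 * sqrt(2))    # one diagonal step
  expect_equal(D[5, 5], 8 * sqrt(2))    # pure diagonal run
  expect_equal(D[1, 1], 0)
})

test_that("least-cost path is optimal, connected and reproducible", {
  set.seed(29)
  R <- matrix(runif(100, 1, 50), 10, 10)
  res <- resistanceFixture(R, 1)
  srcM <- maskFixture(10, 10, cbind(1, 1))
  dstM <- maskFixture(10, 10, cbind(10, 10))
  lcp <- leastCostPath(res, srcM, dstM)
  expect_true(lcp$reachable)
  ## path endpoints and 8-connectivity
  expect_equal(unname(lcp$path[1, ]), c(1, 1))
  expect_equal(unname(lcp$path[nrow(lcp$path), ]), c(10, 10))
  steps <- diff(lcp$path)
  expect_true(all(abs(steps) <= 1) && all(rowSums(abs(steps)) > 0))
  ## cost along the path reproduces the reported cost
  cost <- 0
  for (i in seq_len(nrow(lcp$path) - 1)) {
    a <- lcp$path[i, ]; b <- lcp$path[i + 1, ]
    d <- sqrt(sum((b - a)^2))
    cost <- cost + d * (R[a[1], a[2]] + R[b[1], b[2]]) / 2
  }
  expect_equal(cost, lcp$lcpCost, tolerance = 1e-9)
  expect_equal(lcp$lcpCost, min(gridValues(lcp$cwd)[10, 10]))
  ## geometric length consistent with the step count
  expect_equal(lcp$lcpLength,
               sum(sqrt(rowSums(diff(lcp$path)^2))), tolerance = 1e-9)
})

test_that("touching or overlapping masks yield a degenerate zero path", {
  res <- resistanceFixture(matrix(10, 4, 4), 1)
  a <- maskFixture(4, 4, cbind(1, 1))
  b <- maskFixture(4, 4, cbind(2, 2))  # diagonal neighbour
  lcp <- leastCostPath(res, a, b)
  expect_true(lcp$reachable)
  expect_equal(lcp$lcpCost, 0)
  expect_equal(lcp$lcpLength, 0)
})

test_that("unreachable destinations are reported, not invented", {
  R <- matrix(5, 3, 3); R[, 2] <- NA   # wall of nodata
  res <- resistanceFixture(R, 1)
  lcp <- leastCostPath(res, maskFixture(3, 3, cbind(2, 1)),
                       maskFixture(3, 3, cbind(2, 3)))
  expect_false(lcp$reachable)
  expect_equal(lcp$lcpCost, Inf)
})

test_that("normalized corridor is zero on the path and nested in cutoff", {
  set.seed(37)
  R <- matrix(runif(144, 1, 30), 12, 12)
  res <- resistanceFixture(R, 1)
  a <- maskFixture(12, 12, cbind(2, 2))
  b <- maskFixture(12, 12, cbind(11, 11))
  cwdA <- costWeightedDistance(res, a)
  cwdB <- costWeightedDistance(res, b)
  lcp <- leastCostPath(res, a, b, cwd = cwdA)
  corr <- normalizedCorridor(cwdA, cwdB, lcp$lcpCost, cutoff = 100)
  v <- gridValues(corr$values)
  ## corridor value along the least-cost path is ~0
  onPath <- v[lcp$path]
  expect_true(all(onPath <= 1e-6))
  expect_true(min(v) >= -1e-9)
  ## masks nested across cutoffs
  masks <- lapply(c(50, 100, 150, 200), function(cut)
    gridValues(normalizedCorridor(cwdA, cwdB, lcp$lcpCost, cut)$mask))
  for (i in 1:3)
    expect_true(all(masks[[i + 1]][masks[[i]] == 1] == 1))
})

test_that("PA Euclidean distance is the brute-force minimum", {
  a <- maskFixture(10, 10, rbind(c(1, 1), c(2, 2)))
  b <- maskFixture(10, 10, rbind(c(8, 9), c(10, 10)))
  d <- paEuclideanDistance(a, b, cellsize = 2)
  expect_equal(d, 2 * sqrt((8 - 2)^2 + (9 - 2)^2))
  expect_warning(paEuclideanDistance(a, a), "overlap")
})

test_that("link table carries costs, ratios and sane ordering", {
  scn <- simulateLandscape(simulationConfig(nrows = 40, ncols = 40,
                                            nPas = 4, nPresence = 80,
                                            seed = 13))
  res <- suitabilityToResistance(scn$truth[[1]], 0.25)
  links <- buildLinkTable(scn$pas, res)
  expect_length(links, choose(4, 2))
  lt <- linkTable(links)
  reach <- lt[lt$reachable, ]
  ## CWD:LCP is the mean resistance along the path, bounded by [1, 100]
  expect_true(all(reach$cwd_lcp >= 1 - 1e-9 & reach$cwd_lcp <= 100 + 1e-9))
  ## cost-weighted distance can never beat resistance-1 travel over EUD
  expect_true(all(reach$cwd_eud >= 1 - 1e-9))
  expect_true(all(reach$lcp_length + 1e-9 >= reach$euclid_dist))
  ## restricting pairs restricts rows
  two <- buildLinkTable(scn$pas, res,
                        pairs = data.frame(from = c("PA1", "PA2"),
                                           to = c("PA2", "PA3")))
  expect_length(two, 2L)
})
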