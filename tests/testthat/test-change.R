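test_that("change statistics recover rates from printed cover figures", {
  cover <- matrix(c(6.71, 8.79, 13.14), 1, 3,
                  dimnames = list("cropland", NULL))
  out <- changeStatistics(cover, c(2000, 2010, 2019), 187308)
  expect_equal(out$change_2000_2010, 2.08)
  expect_equal(out$change_2010_2019, 4.35)
  expect_equal(out$change_2000_2019, 6.43)
  expect_equal(out$rate_pct_yr, 6.43 / 19, tolerance = 1e-12)
  expect_equal(out$rate_km2_yr, 6.43 / 100 * 187308 / 19, tolerance = 1e-9)
  expect_equal(out$area_km2_2000, 6.71 / 100 * 187308, tolerance = 1e-9)
})

test_that("composed change table sums to 100% per step", {
  scn <- simulateLandscape(simulationConfig(nrows = 40, ncols = 40,
                                            nPas = 4, nPresence = 80,
                                            seed = 21))
  tab <- composeChangeTable(scn$landcover, c(2000, 2010, 2019),
                            classNames = c(`1` = "dense", `2` = "open",
                                           `3` = "burned", `4` = "cropland",
                                           `5` = "water"))
  for (col in c("pct_2000", "pct_2010", "pct_2019"))
    expect_equal(sum(tab[[col]]), 100, tolerance = 1e-9)
  expect_true("cropland" %in% tab$class)
  crop <- tab[tab$class == "cropland", ]
  expect_true(crop$rate_pct_yr > 0)
  ## default area: cell count times cell area
  expect_equal(sum(tab$area_km2_2019), 40 * 40 * 1, tolerance = 1e-9)
})

test_that("kappa and overall accuracy follow the marginal formulas", {
  cm <- matrix(c(50, 5, 3, 42), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  out <- kappaFromConfusion(cm)
  n <- sum(cm)
  po <- (50 + 42) / n
  pe <- (53 * 55 + 47 * 45) / n^2
  expect_equal(out$overallAccuracy, 100 * po)
  expect_equal(out$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
  ## perfect agreement
  expect_equal(kappaFromConfusion(diag(c(10, 20)))$kappa, 1)
})

test_that("confusionAndKappa looks up classes and excludes bad points", {
  pred <- rasterGrid(matrix(c(1, 1, 2, 2), 2, 2), cellsize = 1,
                     origin = c(0, 2))
  ref <- data.frame(x = c(0.5, 0.5, 1.5, 1.5, 9.0),
                    y = c(1.5, 0.5, 1.5, 0.5, 9.0),
                    class = c(1, 1, 2, 1, 2))
  out <- confusionAndKappa(ref, pred)
  expect_equal(out$nExcluded, 1L)
  expect_equal(sum(out$confusion), 4)
  expect_equal(out$overallAccuracy, 75)
})

test_that("corridor encroachment tracks nested cropland growth", {
  scn <- simulateLandscape(simulationConfig(nrows = 40, ncols = 40,
                                            nPas = 4, nPresence = 80,
                                            seed = 23))
  res <- suitabilityToResistance(scn$truth[[3]], 0.25)
  links <- buildLinkTable(scn$pas, res)
  enc <- corridorEncroachment(links, scn$landcover, c(2000, 2010, 2019),
                              croplandCode = 4)
  expect_true(all(enc$pct_2010 >= enc$pct_2000 - 1e-9))
  expect_true(all(enc$pct_2019 >= enc$pct_2010 - 1e-9))
  expect_true(all(enc$encroached == (enc$pct_2000 > 0 | enc$pct_2010 > 0 |
                                       enc$pct_2019 > 0)))
})

test_that("corridor activity summarizes reports and flags silence", {
  mkLink <- function(a, b) new("CorridorLink", paFrom = a, paTo = b,
                               lcpCost = 1, lcpLength = 1, euclidDist = 1,
                               cwdEudRatio = 1, cwdLcpRatio = 1,
                               corridorMask = NULL,
                               path = matrix(integer(0), 0, 2),
                               reachable = TRUE)
  links <- list(mkLink("A", "B"), mkLink("B", "C"))
  siteLinks <- data.frame(site = c("s1", "s2"),
                          from = c("A", "B"), to = c("B", "C"))
  reports <- data.frame(site = c("s1", "s1", "s1", "s2", "s2"),
                        sightings = c(4, 6, 5, 0, 0),
                        season = c("Wet", "Dry", "Wet", "Wet", "Wet"))
  act <- corridorActivity(links, reports, siteLinks)
  expect_equal(act$status, c("active", "inactive"))
  expect_equal(act$mean[1], 5)
  expect_equal(act$sd[1], sd(c(4, 6, 5)))
  expect_equal(act$seasons[1], "Dry and Wet")
  expect_equal(act$seasons[2], "-")
  expect_warning(
    corridorActivity(links, rbind(reports,
                                  data.frame(site = "ghost", sightings = 1,
                                             season = "Wet")),
                     siteLinks),
    "unmapped")
})
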