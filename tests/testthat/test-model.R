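test_that("free-parameter count enumerates the model structure", {
  expect_identical(countFreeParameters(defaultControlSpec()), 23L)
  expect_identical(length(paramNames(defaultControlSpec())), 23L)

  # one single-factor control, no maximum-cover or zero-inflation terms:
  # x0, k, sigma
  single <- methods::new("ControlSpec",
    controls = list(Z = list(factors = "map", sign = 1,
                             powered = FALSE)),
    hasTcMax = FALSE, hasP0 = FALSE)
  expect_identical(countFreeParameters(single), 3L)

  # dropping the wind stress factor loses one weight and one exponent
  noWind <- defaultControlSpec()
  noWind@controls$S$factors <- c("burnt_area", "seasonality", "heat")
  expect_identical(countFreeParameters(noWind), 21L)
})

test_that("the precipitation transform is log(MAP + 1/ncells) and monotone", {
  expect_equal(transformMAP(0, 100), log(0.01), tolerance = 1e-12)
  expect_equal(transformMAP(0, 100), -4.60517, tolerance = 1e-5)
  expect_equal(transformMAP(999.99, 100), 6.90776, tolerance = 1e-5)
  x <- sort(runif(50, 0, 3000))
  expect_true(all(diff(transformMAP(x, 2000)) > 0))
  expect_error(transformMAP(10, 0), "positive")
})

test_that("min-max scaling clips to the unit interval", {
  expect_equal(scaleFactor(10, c(10, 45)), 0)
  expect_equal(scaleFactor(45, c(10, 45)), 1)
  expect_equal(scaleFactor(35, c(10, 45)), 0.71429, tolerance = 1e-5)
  ba <- runif(20)
  expect_equal(scaleFactor(ba, c(0, 1)), ba)  # identity for fractions
  expect_equal(scaleFactor(60, c(10, 45)), 1)  # clipped
  expect_error(scaleFactor(1, c(2, 2)), "max > min")
})

test_that("the control index is a normalized weighted power combination", {
  expect_equal(controlIndex(0.3, 1, 1), 0.3)
  expect_equal(controlIndex(c(0.2, 0.5), c(1, 1), c(1, 2)),
               (0.2 + 0.25) / 2, tolerance = 1e-12)
  expect_equal(controlIndex(c(0, 0, 0), c(1, 2, 3)), 0)
  m <- cbind(runif(5), runif(5))
  ci <- controlIndex(m, c(1, 0.5), c(1, 2))
  expect_true(all(ci >= 0 & ci <= 1))
  expect_error(controlIndex(c(0.1, 0.2), 1), "length")
  expect_error(controlIndex(0.5, 1, -1), "positive")
})

test_that("the limitation curve is a logistic in k(X - x0)", {
  expect_equal(limitationCurve(2, 2, 5), 0.5)
  expect_equal(limitationCurve(1, 0, 2), 0.88080, tolerance = 1e-5)
  expect_equal(limitationCurve(1, 0, -1e6), 0)
  x <- seq(-3, 3, 0.5)
  expect_true(all(diff(limitationCurve(x, 0, 2)) > 0))
  expect_true(all(diff(limitationCurve(x, 0, -2)) < 0))
})

test_that("the energy factor multiplies the MAT and SW curves", {
  p <- randomParams(3)
  expect_equal(energyFactor(p@x0[["MAT"]], p@x0[["SW"]], p), 0.25)
  # either curve saturated at 1 leaves the other unchanged
  expect_equal(energyFactor(p@x0[["MAT"]] + 1e6, 200, p),
               limitationCurve(200, p@x0[["SW"]], p@k[["SW"]]))
  # worked pair: f values 0.88080 and 0.5
  p2 <- p
  p2@x0[c("MAT", "SW")] <- c(20, 210)
  p2@k[c("MAT", "SW")] <- c(2, 1)
  expect_equal(energyFactor(21, 210, p2), 0.44040, tolerance = 1e-4)
})

test_that("tree cover is the product of control limitations times the maximum", {
  # drivers engineered so the five factors are (0.9, 0.8, 1, 0.7, 1)
  d <- oneCellDrivers(list(map_mm = 1000, mat_c = 25, sw_wm2 = 220,
                           burnt_area = 0.4, seasonality = 0.2,
                           mtwm_c = 27.5, wind_ms = 1.2,
                           pop_density = 100, urban = 0.1,
                           cropland = 0.2, pasture = 0.3))
  mapStar <- log(1000 + 1)  # one unmasked cell
  p <- modelParams(
    x0 = c(MAP = mapStar - log(0.9 / 0.1) / 1.5,
           MAT = 25 - log(0.8 / 0.2) / 0.4,
           SW = -1e6,                       # f_SW saturates at 1
           S = NA, LU = 1e6),               # f_LU saturates at 1
    k = c(MAP = 1.5, MAT = 0.4, SW = 0.1, S = 4, LU = 5),
    weights = list(S = c(1, 1, 1, 1), LU = c(1, 1, 1, 1)),
    powers = list(S = c(1, 1, 1, 1)),
    tcMax = 0.8, sigma = 0.5, p0 = 0.9)
  # stress index = mean(0.4, 0.2, 0.5, 0.1) = 0.3; pick x0 so f_S = 0.7
  p@x0[["S"]] <- 0.3 + log(0.7 / 0.3) / 4
  tc <- treeCover(d, p)
  expect_equal(tc@values[1, 1], 0.8 * 0.9 * 0.8 * 1 * 0.7 * 1,
               tolerance = 1e-6)

  # all factors saturated: upper bound tc_max
  psat <- p
  psat@x0[c("MAP", "MAT")] <- c(-1e6, -1e6)
  psat@x0[c("S", "LU")] <- c(1e6, 1e6)
  expect_equal(treeCover(d, psat)@values[1, 1], 0.8, tolerance = 1e-9)

  # an absorbing zero factor drives cover to zero
  pzero <- p
  pzero@x0[["MAP"]] <- 1e6
  expect_equal(treeCover(d, pzero)@values[1, 1], 0)
})

test_that("removal drops a factor's term while keeping the normalization", {
  d <- oneCellDrivers()
  p <- randomParams(11)
  # factor with zero weight: removal is a no-op
  p0w <- p
  p0w@weights$S[3] <- 0
  expect_equal(treeCoverWithout(d, p0w, removed = "heat")@values[1, 1],
               treeCover(d, p0w)@values[1, 1], tolerance = 1e-12)

  # whole-control removal divides the product by that control's factor
  tc <- treeCover(d, p)@values[1, 1]
  tcs <- treeCoverWithout(d, p, removed = "S")@values[1, 1]
  fS <- tc / tcs
  expect_true(fS > 0 && fS < 1)
  expect_equal(tcs, tc / fS, tolerance = 1e-12)

  # two-factor stress control with v = (1, 1), x = (0.4, 0.2): index
  # 0.3 -> 0.1 when burnt area is removed (numerator term dropped, the
  # fitted normalization sum(v) = 2 kept, so no burning means no fire
  # contribution and removal is monotone)
  spec2 <- methods::new("ControlSpec",
    controls = list(
      MAP = list(factors = "map", sign = 1, powered = FALSE),
      S = list(factors = c("burnt_area", "seasonality"), sign = -1,
               powered = TRUE)),
    hasTcMax = TRUE, hasP0 = TRUE)
  d2 <- oneCellDrivers(list(burnt_area = 0.4, seasonality = 0.2))
  p2 <- modelParams(x0 = c(MAP = 5, S = 0.5), k = c(MAP = 1, S = 3),
                    weights = list(S = c(1, 1)),
                    powers = list(S = c(1, 1)),
                    tcMax = 0.9, sigma = 0.5, p0 = 0.9)
  mapStar <- log(1500 + 1)
  fMAP <- plogis(1 * (mapStar - 5))
  fS03 <- plogis(-3 * (0.3 - 0.5))
  fS02 <- plogis(-3 * (0.1 - 0.5))
  expect_equal(treeCover(d2, p2, spec2)@values[1, 1],
               0.9 * fMAP * fS03, tolerance = 1e-12)
  expect_equal(treeCoverWithout(d2, p2, spec2,
                                removed = "burnt_area")@values[1, 1],
               0.9 * fMAP * fS02, tolerance = 1e-12)
  expect_error(treeCoverWithout(d2, p2, spec2, removed = "nope"),
               "unknown")
})

test_that("vectorized tree cover matches the per-cell scalar oracle", {
  for (seed in 1:10) {
    d <- randomDrivers(10, 10, seed = seed)
    p <- randomParams(seed + 100)
    tc <- treeCover(d, p)
    expect_equal(tc@values[tc@mask], oracleTreeCover(d, p),
                 tolerance = 1e-12)
    tgt <- c("S", "LU", "MAP", "burnt_area", "cropland")[seed %% 5 + 1]
    tcw <- treeCoverWithout(d, p, removed = tgt)
    expect_equal(tcw@values[tcw@mask], oracleTreeCover(d, p, tgt),
                 tolerance = 1e-12)
  }
})

test_that("cover is monotone in drivers with the expected signs", {
  p <- randomParams(5)
  base <- makeDrivers(3, 3)
  tc0 <- treeCover(base, p)@values[1, 1]
  up <- function(nm, v) treeCover(makeDrivers(3, 3,
    values = stats::setNames(list(v), nm)), p)@values[1, 1]
  expect_gte(up("map_mm", 2500), tc0)      # wetter: more cover
  expect_gte(up("mat_c", 30), tc0)         # warmer: more cover
  expect_lte(up("burnt_area", 0.6), tc0)   # more fire: less cover
  expect_lte(up("cropland", 0.7), tc0)     # more cropland: less cover
  expect_lte(up("mtwm_c", 44), tc0)        # more heat stress: less cover
  # cover vanishes with rainfall
  expect_lt(up("map_mm", 0), 1e-3)
})

test_that("parameter vector round trip is exact", {
  spec <- defaultControlSpec()
  p <- randomParams(9)
  v <- paramsToVector(p, spec)
  expect_identical(names(v), paramNames(spec))
  p2 <- vectorToParams(v, spec)
  expect_equal(paramsToVector(p2, spec), v, tolerance = 0)
})
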