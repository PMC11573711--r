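.mkObsField <- function(nlat, nlon, seed = 1) {
  set.seed(seed)
  lat <- (seq_len(nlat) - (nlat + 1) / 2) * 0.5
  lon <- (seq_len(nlon) - (nlon + 1) / 2) * 0.5
  observationSet(griddedField("tc", matrix(runif(nlat * nlon), nlat),
                              lat, lon))
}

.mkEnsemble <- function(members, logLik,
                        provenance = rep("a", nrow(members))) {
  methods::new("PosteriorEnsemble", members = members, logLik = logLik,
               provenance = provenance, weights = NULL,
               chains = array(numeric(), c(0, 0, 0)),
               acceptance = numeric())
}

test_that("train/validation split is exact, disjoint and seed-deterministic", {
  obs <- .mkObsField(110, 110)  # 12100 cells
  # mask 60 cells so n = 12040, the size whose 20% split is 2408
  f <- obs@field
  f@mask[1, 1:60] <- FALSE
  f@values[1, 1:60] <- NA
  obs <- observationSet(f)
  sp <- splitTrain(obs, 0.20, seed = 4)
  expect_identical(nObs(sp$train), 2408L)
  expect_identical(nObs(sp$validation), 12040L - 2408L)
  expect_false(any(sp$train@field@mask & sp$validation@field@mask))

  small <- .mkObsField(2, 5)
  sp2 <- splitTrain(small, 0.5, seed = 1)
  expect_identical(nObs(sp2$train), 5L)
  expect_identical(nObs(sp2$validation), 5L)

  spA <- splitTrain(obs, 0.20, seed = 9)
  spB <- splitTrain(obs, 0.20, seed = 9)
  expect_identical(spA$train@field@mask, spB$train@field@mask)
  expect_error(splitTrain(small, 1.2), "fraction")
})

test_that("log prior scores supports and known densities", {
  d <- makeDrivers(4, 4)
  spec <- defaultControlSpec()
  priors <- defaultPriors(d, spec)
  p <- randomParams(17)
  expect_true(is.finite(logPrior(p, priors, spec)))

  # outside [0,1] support for the maximum cover
  pBad <- p; pBad@tcMax <- 1.2
  expect_identical(logPrior(pBad, priors, spec), -Inf)
  pNeg <- p; pNeg@k[["S"]] <- -0.5
  expect_identical(logPrior(pNeg, priors, spec), -Inf)

  # a rate-1 exponential weight contributes -v
  p2 <- p; p2@weights$S[2] <- 2
  p3 <- p; p3@weights$S[2] <- 0.5
  expect_equal(logPrior(p2, priors, spec) - logPrior(p3, priors, spec),
               -2 + 0.5, tolerance = 1e-12)

  # midpoint at its prior mean scores -log(sd * sqrt(2*pi)); one prior
  # s.d. away drops by exactly 1/2
  mu <- priors@x0Mean[["MAT"]]; sd_ <- priors@x0Sd[["MAT"]]
  pMu <- p; pMu@x0[["MAT"]] <- mu
  pSd <- p; pSd@x0[["MAT"]] <- mu + sd_
  expect_equal(logPrior(pMu, priors, spec) - logPrior(pSd, priors, spec),
               0.5, tolerance = 1e-12)
})

test_that("split-Rhat flags divergent chains and passes white noise", {
  n <- 1000
  set.seed(8)
  white <- array(rnorm(n * 4 * 2), c(n, 4, 2),
                 dimnames = list(NULL, NULL, c("a", "b")))
  rh <- rhat(white)
  expect_true(all(rh < 1.05))

  # constant identical chains: exactly 1; identical stationary chains:
  # indistinguishable from 1
  const <- array(2.5, c(n, 4, 1), dimnames = list(NULL, NULL, "a"))
  expect_identical(unname(rhat(const)["a"]), 1)
  ident <- array(rep(rnorm(n), 4), c(n, 4, 1),
                 dimnames = list(NULL, NULL, "a"))
  expect_lt(abs(unname(rhat(ident)["a"]) - 1), 0.01)

  diverged <- white
  diverged[, 1, 1] <- diverged[, 1, 1] + 50
  expect_gt(rhat(diverged)["a"], 2)
  expect_error(rhat(array(0, c(10, 1, 2))), "2 chains")
})

test_that("likelihood-weighted bootstrap respects softmax odds and size", {
  m <- matrix(c(1, 2), 2, 1, dimnames = list(NULL, "x"))
  eq <- .mkEnsemble(m, c(-5, -5))
  idx <- combinePosteriors(list(eq), nOut = 2e4, seed = 2)@members[, "x"]
  expect_equal(mean(idx == 1), 0.5, tolerance = 0.02)

  odds3 <- .mkEnsemble(m, c(-5 + log(3), -5))
  draw <- combinePosteriors(list(odds3), nOut = 1e5,
                            seed = 3)@members[, "x"]
  expect_equal(mean(draw == 1), 0.75, tolerance = 0.01)

  two <- combinePosteriors(list(eq, odds3), nOut = 1000, seed = 4)
  expect_identical(nMembers(two), 1000L)
  expect_true(all(two@provenance == "a"))
  expect_error(combinePosteriors(list()), "no ensembles")
})

test_that("the sampler is reproducible and tunes into the target window", {
  d <- generateDrivers(syntheticConfig(nlat = 12, nlon = 12, seed = 5))
  obs <- simulateObservations(d, defaultTrueParams(), seed = 6)
  cfg <- chainConfig(nChains = 2, nIter = 1000, seed = 42)
  e1 <- samplePosterior(obs, d, config = cfg)
  e2 <- samplePosterior(obs, d, config = cfg)
  expect_identical(e1@members, e2@members)
  expect_identical(e1@logLik, e2@logLik)
  np <- countFreeParameters(defaultControlSpec())
  acc <- e1@acceptance[seq_len(np)]
  expect_true(all(acc > 0.02))  # tuned into a workable window
  expect_identical(nMembers(e1), 20L)  # 10 per chain
  expect_true(all(is.finite(e1@logLik)))
})

test_that("with a constant likelihood the sampler recovers its priors", {
  d <- generateDrivers(syntheticConfig(nlat = 6, nlon = 6, seed = 2,
                                       landFraction = 1))
  obs <- simulateObservations(d, defaultTrueParams(), seed = 3)
  ens <- samplePosterior(obs, d,
                         config = chainConfig(nChains = 2, nIter = 2500,
                                              seed = 77),
                         likelihoodConstant = TRUE)
  draws <- apply(ens@chains, 3, c)
  ksDist <- function(x, cdf) {
    x <- sort(x)
    n <- length(x)
    max(abs(cdf(x) - seq_len(n) / n))
  }
  expect_lt(ksDist(draws[, "tc_max"], punif), 0.1)
  expect_lt(ksDist(draws[, "p0"], punif), 0.1)
  expect_lt(ksDist(draws[, "sigma"], pexp), 0.1)
  expect_lt(ksDist(draws[, "v_wind"], pexp), 0.1)
})

test_that("larger training sets tighten the maximum-cover posterior", {
  d <- generateDrivers(syntheticConfig(seed = 4))
  obs <- simulateObservations(d, defaultTrueParams(), seed = 4)
  sds <- vapply(c(0.1, 0.25, 1), function(fr) {
    train <- if (fr < 1) splitTrain(obs, fr, seed = 10)$train else obs
    ens <- samplePosterior(train, d,
                           config = chainConfig(nChains = 2, nIter = 800,
                                                seed = 50))
    stats::sd(ens@chains[, , "tc_max"])
  }, 0)
  # 200 -> 2000 cells must tighten; the middle size may wobble with
  # sampling noise at this scaled-down chain length
  expect_lt(sds[3], sds[1])
  expect_lt(sds[3], sds[2])
  expect_lt(sds[2], sds[1] * 1.4)
})
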