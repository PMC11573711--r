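# Shared fixtures, built in code at test time.

# constant-valued driver set on a tiny grid; individual fields can be
# overridden with matrices or scalars
makeDrivers <- function(nlat = 4, nlon = 4, values = list(),
                        maskOut = NULL) {
  lat <- (seq_len(nlat) - (nlat + 1) / 2) * 0.5
  lon <- (seq_len(nlon) - (nlon + 1) / 2) * 0.5
  defaults <- list(map_mm = 1500, mat_c = 25, sw_wm2 = 220,
                   burnt_area = 0.1, seasonality = 0.3, mtwm_c = 32,
                   wind_ms = 3, urban = 0.02, cropland = 0.1,
                   pasture = 0.1, pop_density = 50)
  mask <- matrix(TRUE, nlat, nlon)
  if (!is.null(maskOut)) mask[maskOut] <- FALSE
  fields <- lapply(driverNames(), function(nm) {
    v <- values[[nm]]
    if (is.null(v)) v <- defaults[[nm]]
    m <- matrix(v, nlat, nlon)
    m[!mask] <- NA_real_
    griddedField(nm, m, lat = lat, lon = lon, mask = mask)
  })
  names(fields) <- driverNames()
  driverSet(fields)
}

# uniformly random driver fields (no spatial structure); used by the
# scalar-oracle equivalence checks
randomDrivers <- function(nlat = 10, nlon = 10, seed = 1,
                          maskFrac = 0.15) {
  set.seed(seed)
  n <- nlat * nlon
  vals <- list(
    map_mm = runif(n, 0, 3500), mat_c = runif(n, 5, 32),
    sw_wm2 = runif(n, 150, 280), burnt_area = runif(n),
    seasonality = runif(n), mtwm_c = runif(n, 20, 45),
    wind_ms = runif(n, 0, 12), urban = runif(n), cropland = runif(n),
    pasture = runif(n), pop_density = runif(n, 0, 1000)
  )
  mask <- matrix(runif(n) > maskFrac, nlat, nlon)
  if (sum(mask) < 2) mask[1:2] <- TRUE
  makeDrivers(nlat, nlon, values = lapply(vals, matrix, nlat, nlon),
              maskOut = !mask)
}

# random but plausible parameter set
randomParams <- function(seed = 1) {
  set.seed(seed)
  modelParams(
    x0 = c(MAP = runif(1, 4, 7), MAT = runif(1, 8, 20),
           SW = runif(1, 150, 220), S = runif(1, 0.2, 0.7),
           LU = runif(1, 0.2, 0.7)),
    k = c(MAP = runif(1, 0.5, 2), MAT = runif(1, 0.1, 0.6),
          SW = runif(1, 0.02, 0.2), S = runif(1, 1, 6),
          LU = runif(1, 1, 6)),
    weights = list(S = c(1, runif(3, 0.2, 1.5)),
                   LU = c(1, runif(3, 0.2, 1.5))),
    powers = list(S = runif(4, 0.5, 2.5)),
    tcMax = runif(1, 0.6, 0.95), sigma = runif(1, 0.3, 0.8),
    p0 = runif(1, 0.5, 0.95)
  )
}

# single-cell driver set whose control indices/limitation factors are
# easy to compute by hand
oneCellDrivers <- function(values = list()) {
  makeDrivers(2, 2, values = values, maskOut = cbind(c(1, 2, 2),
                                                     c(2, 1, 2)))
}

# fits shared by the parameter-recovery and predictive-calibration
# acceptance checks: computed once, cached for the session
.acceptanceCache <- new.env(parent = emptyenv())
acceptanceRecoveryFits <- function(nRep = 10) {
  if (!is.null(.acceptanceCache$fits)) return(.acceptanceCache$fits)
  truth <- defaultTrueParams()
  spec <- defaultControlSpec()
  drivers <- generateDrivers(syntheticConfig(seed = 1))
  out <- vector("list", nRep)
  for (r in seq_len(nRep)) {
    obs <- simulateObservations(drivers, truth, spec, seed = 100 + r)
    split <- splitTrain(obs, fraction = 0.25, seed = 100 + r)  # 500 cells
    ens <- samplePosterior(split$train, drivers, spec,
                           config = chainConfig(nChains = 4,
                                                nIter = 2000,
                                                seed = 200 + r))
    q <- apply(ens@chains, 3, stats::quantile, c(0.05, 0.95))
    pc <- predictiveInterval(drivers, ens, spec,
                             obs = split$validation, nDraws = 10,
                             seed = 300 + r)
    out[[r]] <- list(ci = q, rhat = rhat(ens),
                     acceptance = ens@acceptance,
                     pitCoverage = pc$pitCoverage,
                     rawCoverage = pc$coverage)
  }
  .acceptanceCache$fits <- out
  out
}
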