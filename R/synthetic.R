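# Synthetic study conditions. Spatially correlated driver fields are
# built from Gaussian white noise smoothed by a separable Gaussian kernel
# and rank-mapped onto per-driver marginal distributions; burnt area and
# rainfall seasonality share a configured cross-correlation (fire
# co-varies with seasonal drought in the real drivers). Observations are
# forward-simulated from known parameters through the zero-inflated
# logit-normal observation model, so every downstream stage can be tested
# against a known truth without external downloads.

#' Default generating parameters for the synthetic study
#'
#' Chosen so every control is partially limiting somewhere on the default
#' fixture (no control saturates everywhere): midpoints sit inside each
#' control index's occupied range and steepness values are moderate.
#'
#' @return a [ModelParams-class].
#' @export
defaultTrueParams <- function() {
  modelParams(
    x0 = c(MAP = 6.2, MAT = 12, SW = 170, S = 0.4, LU = 0.35),
    k = c(MAP = 1.5, MAT = 0.4, SW = 0.1, S = 4, LU = 5),
    weights = list(S = c(1, 0.8, 0.6, 0.4), LU = c(1, 0.9, 0.7, 0.5)),
    powers = list(S = c(1, 1.5, 2, 1.2)),
    tcMax = 0.85, sigma = 0.5, p0 = 0.8
  )
}

#' Configure the synthetic study
#'
#' Defaults define the study conditions: a 50 x 50 cell grid at 0.5
#' degree spacing (~2,000 land cells, comparable to the training sample of
#' a 20% split of a real tropical land grid), correlation length 5 cells,
#' burnt-area/seasonality cross-correlation 0.6, and driver marginals
#' spanning realistic tropical ranges (MAP 0-3500 mm/yr, MAT 5-32 C,
#' SW 150-280 W/m2, MTWM 20-45 C, wind 0-12 m/s, fractions on [0, 1]).
#'
#' @param nlat,nlon grid size in cells.
#' @param seed RNG seed fixing every draw.
#' @param corLength spatial correlation length in cells (0 = white noise).
#' @param trueParams generating [ModelParams-class].
#' @param baSeasCor burnt-area/seasonality cross-correlation.
#' @param landFraction fraction of cells left unmasked.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nlat = 50, nlon = 50, seed = 1, corLength = 5,
                            trueParams = defaultTrueParams(),
                            baSeasCor = 0.6, landFraction = 0.8) {
  ranges <- list(
    map_mm = c(0, 3500), mat_c = c(5, 32), sw_wm2 = c(150, 280),
    mtwm_c = c(20, 45), wind_ms = c(0, 12), pop_density = c(0, 1000)
  )
  new("SyntheticConfig", nlat = nlat, nlon = nlon, seed = seed,
      corLength = corLength, trueParams = trueParams, ranges = ranges,
      baSeasCor = baSeasCor, landFraction = landFraction)
}

# smoothed standard-normal field: white noise convolved with a separable
# Gaussian kernel (reflective padding), then re-standardized
.smoothField <- function(nlat, nlon, corLength) {
  z <- matrix(stats::rnorm(nlat * nlon), nlat, nlon)
  if (corLength <= 0) return(z)
  half <- max(1L, ceiling(2 * corLength))
  kern <- stats::dnorm(seq(-half, half), sd = corLength)
  kern <- kern / sum(kern)
  # mirrored index for reflective padding, valid for any pad width
  fold <- function(i, n) {
    if (n == 1L) return(rep(1L, length(i)))
    j <- (i - 1L) %% (2L * (n - 1L))
    ifelse(j < n, j + 1L, 2L * n - 1L - j)
  }
  conv1 <- function(m) {
    n <- nrow(m)
    p <- m[fold(seq(1L - half, n + half), n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(kern)) {
      out <- out + kern[i] * p[seq_len(n) + i - 1L, , drop = FALSE]
    }
    out
  }
  z <- conv1(z)            # latitude direction
  z <- t(conv1(t(z)))      # longitude direction
  (z - mean(z)) / stats::sd(z)
}

# rank-map a latent standard-normal field onto a marginal quantile fn
.rankMap <- function(z, qfun) qfun(stats::pnorm(z))

#' Generate the eleven synthetic driver fields
#'
#' Spatially correlated latent fields rank-mapped onto per-driver
#' marginals: uniform over the configured ranges for the climate drivers,
#' and right-skewed Beta marginals for the sparse fraction drivers (burnt
#' area, urban, cropland, pasture). Burnt area and seasonality share the
#' configured cross-correlation at the latent level. The land mask is a
#' thresholded smooth field (contiguous "ocean"). Deterministic for a
#' fixed seed.
#'
#' @param config a [SyntheticConfig-class].
#' @return a [DriverSet-class] on a 0.5-degree grid centred on the
#'   equator.
#' @export
generateDrivers <- function(config) {
  nlat <- config@nlat; nlon <- config@nlon
  lat <- (seq_len(nlat) - (nlat + 1) / 2) * 0.5
  lon <- (seq_len(nlon) - (nlon + 1) / 2) * 0.5
  rng <- config@ranges
  qunif2 <- function(lo, hi) function(p) lo + p * (hi - lo)
  marg <- list(
    map_mm = qunif2(rng$map_mm[1], rng$map_mm[2]),
    mat_c = qunif2(rng$mat_c[1], rng$mat_c[2]),
    sw_wm2 = qunif2(rng$sw_wm2[1], rng$sw_wm2[2]),
    mtwm_c = qunif2(rng$mtwm_c[1], rng$mtwm_c[2]),
    wind_ms = qunif2(rng$wind_ms[1], rng$wind_ms[2]),
    pop_density = function(p) stats::qbeta(p, 0.8, 4) *
      rng$pop_density[2],
    burnt_area = function(p) stats::qbeta(p, 0.8, 4),
    seasonality = function(p) stats::qbeta(p, 2, 2),
    urban = function(p) stats::qbeta(p, 0.5, 8),
    cropland = function(p) stats::qbeta(p, 0.8, 4),
    pasture = function(p) stats::qbeta(p, 0.8, 4)
  )
  fields <- .withSeed(config@seed, {
    maskLatent <- .smoothField(nlat, nlon, max(config@corLength, 2))
    mask <- maskLatent <= stats::quantile(maskLatent,
                                          config@landFraction)
    zsea <- .smoothField(nlat, nlon, config@corLength)
    zba0 <- .smoothField(nlat, nlon, config@corLength)
    rho <- config@baSeasCor
    zba <- rho * zsea + sqrt(1 - rho^2) * zba0
    latents <- list(seasonality = zsea, burnt_area = zba)
    for (nm in setdiff(.DRIVER_NAMES, names(latents))) {
      latents[[nm]] <- .smoothField(nlat, nlon, config@corLength)
    }
    out <- list()
    for (nm in .DRIVER_NAMES) {
      vals <- .rankMap(latents[[nm]], marg[[nm]])
      vals[!mask] <- NA_real_
      units <- switch(nm, map_mm = "mm/yr", mat_c = "degC",
                      sw_wm2 = "W/m2", mtwm_c = "degC", wind_ms = "m/s",
                      pop_density = "persons/km2", "1")
      out[[nm]] <- griddedField(nm, vals, lat = lat, lon = lon,
                                units = units, mask = mask)
    }
    out
  })
  driverSet(fields,
            scaling = list(mtwm_c = rng$mtwm_c, wind_ms = rng$wind_ms,
                           pop_density = rng$pop_density))
}

#' Forward-simulate tree-cover observations
#'
#' Computes model cover from the drivers and parameters, then draws each
#' cell from the zero-inflated logit-normal observation model: zero with
#' probability `(1 - TC^2)(1 - p0)`, otherwise logit-normal around
#' `logit(TC)` with s.d. `sigma`, clipped to [0, 1]. In the noiseless
#' limit (`sigma -> 0`, `p0 = 1`) observations equal model cover.
#'
#' @param drivers a [DriverSet-class].
#' @param params generating [ModelParams-class].
#' @param spec a [ControlSpec-class].
#' @param seed RNG seed.
#' @return an [ObservationSet-class] on the driver grid.
#' @export
simulateObservations <- function(drivers, params,
                                 spec = defaultControlSpec(), seed = 1) {
  prep <- .prepareDrivers(drivers, spec)
  tc <- .treeCoverVec(prep, params, spec)
  obs <- .withSeed(seed, {
    pz <- zeroProb(pmin(tc, 1), params@p0)
    z <- stats::runif(length(tc)) < pz
    y <- if (params@sigma > 0) {
      stats::plogis(stats::rnorm(length(tc), .logit(tc), params@sigma))
    } else tc
    y[z] <- 0
    y
  })
  observationSet(.vecToField(obs, prep, "tree_cover_obs"))
}

#' Rule-based synthetic biome map
#'
#' Groups cells from MAP and seasonality: desert below 300 mm/yr; savanna
#' (seasonal) or mediterranean (aseasonal) at 300-1200 mm/yr; dry forest
#' at 1200-1800 mm/yr; above 1800 mm/yr, wet forest where seasonality is
#' low and summergreen forest/woodland where it is high. Deterministic
#' given the drivers; on the default fixture every group is non-empty.
#'
#' @param drivers a [DriverSet-class].
#' @param thresholds named list overriding the rule thresholds
#'   (`desertMAP`, `savannaMAP`, `forestMAP`, `seasonalSplit`,
#'   `wetSeason`).
#' @return a [BiomeMap-class] using [defaultBiomeGroups()] codes.
#' @export
generateBiomeMap <- function(drivers,
                             thresholds = list(desertMAP = 300,
                                               savannaMAP = 1200,
                                               forestMAP = 1800,
                                               seasonalSplit = 0.5,
                                               wetSeason = 0.5)) {
  map <- drivers@fields[["map_mm"]]@values
  sea <- drivers@fields[["seasonality"]]@values
  mask <- drivers@fields[[1L]]@mask
  th <- thresholds
  code <- matrix(NA_real_, nrow(map), ncol(map))
  code[mask & map < th$desertMAP] <- 6                       # desert
  code[mask & map >= th$desertMAP & map < th$savannaMAP &
         sea >= th$seasonalSplit] <- 3                       # savanna
  code[mask & map >= th$desertMAP & map < th$savannaMAP &
         sea < th$seasonalSplit] <- 4                        # mediterranean
  code[mask & map >= th$savannaMAP & map < th$forestMAP] <- 2 # dry forest
  code[mask & map >= th$forestMAP & sea < th$wetSeason] <- 1  # wet forest
  code[mask & map >= th$forestMAP & sea >= th$wetSeason] <- 5 # summergreen
  f <- drivers@fields[[1L]]
  biomeMap(griddedField("biome_code", code, lat = f@lat, lon = f@lon,
                        units = "1", mask = mask))
}

#' Counterfactual burnt-area ensemble without human suppression
#'
#' Humans mostly suppress fire at landscape scale, so a counterfactual
#' burnt area without human influence scales the observed field up by a
#' spatially varying factor >= 1 (1 + a smooth random field times
#' `inflation - 1`), clipped to [0, 1]. Reproducible for a fixed seed.
#'
#' @param drivers a [DriverSet-class] carrying the observed burnt area.
#' @param nMembers ensemble size (>= 1).
#' @param inflation maximum multiplicative increase (default 1.5; 1.0
#'   reproduces the observed field exactly).
#' @param seed RNG seed.
#' @param corLength correlation length of the scaling field in cells.
#' @return list of `nMembers` burnt-area [GriddedField-class]s.
#' @export
generateCounterfactualBurntArea <- function(drivers, nMembers = 10,
                                            inflation = 1.5, seed = 1,
                                            corLength = 5) {
  if (nMembers < 1) .stopf("nMembers must be >= 1")
  ba <- drivers@fields[["burnt_area"]]
  .withSeed(seed, {
    lapply(seq_len(nMembers), function(m) {
      u <- stats::pnorm(.smoothField(length(ba@lat), length(ba@lon),
                                     corLength))
      fac <- 1 + (inflation - 1) * u
      out <- ba
      out@values <- pmin(ba@values * fac, 1)
      out@values[!ba@mask] <- NA_real_
      out@name <- sprintf("burnt_area_counterfactual_%03d", m)
      out
    })
  })
}
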