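#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' A single gridded variable on a regular latitude-longitude grid
#'
#' `GriddedField` is the basic raster container of the package: one named
#' variable on a regular lat-lon grid of cell centres, with a per-cell
#' validity mask and a units string. Values are stored as a matrix with rows
#' indexed by latitude (strictly increasing) and columns by longitude.
#' Masked cells hold `NA` and take no part in any computation.
#'
#' @slot name variable identifier.
#' @slot values numeric matrix, `length(lat)` rows by `length(lon)` columns;
#'   `NA` on masked cells.
#' @slot mask logical matrix of the same shape; `TRUE` marks valid cells.
#' @slot lat,lon cell-centre coordinates in degrees, strictly increasing,
#'   uniformly spaced.
#' @slot units units string (CF style, e.g. `"mm/yr"`).
#'
#' @aliases GriddedField-class
#' @exportClass GriddedField
setClass("GriddedField",
  representation(
    name = "character", values = "matrix", mask = "matrix",
    lat = "numeric", lon = "numeric", units = "character"
  )
)

.checkRegular <- function(x, what) {
  if (length(x) > 1) {
    d <- diff(x)
    if (any(d <= 0)) return(sprintf("%s must be strictly increasing", what))
    if (max(d) - min(d) > 1e-6) {
      return(sprintf("%s spacing must be uniform", what))
    }
  }
  NULL
}

setValidity("GriddedField", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), dim(object@mask))) {
    msgs <- c(msgs, "values and mask must have identical dimensions")
  }
  if (nrow(object@values) != length(object@lat) ||
      ncol(object@values) != length(object@lon)) {
    msgs <- c(msgs, "values must be length(lat) x length(lon)")
  }
  msgs <- c(msgs, .checkRegular(object@lat, "lat"),
            .checkRegular(object@lon, "lon"))
  if (any(!is.na(object@values[!object@mask]))) {
    msgs <- c(msgs, "masked cells must carry NA values")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GriddedField
#'
#' @param name variable identifier.
#' @param values numeric matrix (`lat` rows by `lon` columns).
#' @param lat,lon cell-centre coordinates (degrees), strictly increasing.
#' @param units units string.
#' @param mask optional logical matrix; defaults to `!is.na(values)`.
#' @return a [GriddedField-class] object.
#' @examples
#' g <- griddedField("x", matrix(1, 2, 2), lat = c(-0.25, 0.25),
#'                   lon = c(0.25, 0.75), units = "1")
#' @export
griddedField <- function(name, values, lat, lon, units = "1", mask = NULL) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- !is.na(values)
  values[!mask] <- NA_real_
  storage.mode(values) <- "double"
  new("GriddedField", name = name, values = values, mask = mask,
      lat = as.numeric(lat), lon = as.numeric(lon), units = units)
}

#' The eleven predictor fields driving the limitation model
#'
#' `DriverSet` bundles the eleven gridded predictors (mean annual
#' precipitation, mean annual temperature, shortwave radiation, burnt-area
#' fraction, a rainfall-seasonality metric, maximum temperature of the
#' warmest month, mean wind speed, urban/cropland/pasture fractions and
#' population density) on one shared grid and mask, together with the
#' min-max scaling constants used to map unbounded drivers onto [0, 1].
#' Storing the scaling constants with the data keeps fitted parameters
#' interpretable.
#'
#' @slot fields named list of [GriddedField-class] objects; see
#'   [driverNames()] for the required names.
#' @slot scaling named list of `c(min, max)` pairs for the drivers that are
#'   min-max scaled (`mtwm_c`, `wind_ms`, `pop_density`); fraction-valued
#'   drivers pass through unscaled.
#'
#' @aliases DriverSet-class
#' @exportClass DriverSet
setClass("DriverSet",
  representation(fields = "list", scaling = "list")
)

.DRIVER_NAMES <- c("map_mm", "mat_c", "sw_wm2", "burnt_area", "seasonality",
                   "mtwm_c", "wind_ms", "urban", "cropland", "pasture",
                   "pop_density")
.FRACTION_DRIVERS <- c("burnt_area", "seasonality", "urban", "cropland",
                       "pasture")
.SCALED_DRIVERS <- c("mtwm_c", "wind_ms", "pop_density")

#' Names of the eleven predictor fields
#' @return character vector of the driver field names in canonical order.
#' @export
driverNames <- function() .DRIVER_NAMES

setValidity("DriverSet", function(object) {
  msgs <- character()
  if (!setequal(names(object@fields), .DRIVER_NAMES)) {
    msgs <- c(msgs, sprintf("fields must be named exactly: %s",
                            paste(.DRIVER_NAMES, collapse = ", ")))
  } else {
    ref <- object@fields[[1L]]
    for (nm in names(object@fields)) {
      f <- object@fields[[nm]]
      if (!is(f, "GriddedField")) {
        msgs <- c(msgs, sprintf("field '%s' is not a GriddedField", nm))
        next
      }
      if (!isTRUE(all.equal(f@lat, ref@lat)) ||
          !isTRUE(all.equal(f@lon, ref@lon)) ||
          !identical(f@mask, ref@mask)) {
        msgs <- c(msgs, sprintf("field '%s' not on the shared grid/mask", nm))
      }
      if (nm %in% .FRACTION_DRIVERS) {
        v <- f@values[f@mask]
        if (any(v < 0 | v > 1, na.rm = TRUE)) {
          msgs <- c(msgs, sprintf("fraction field '%s' outside [0,1]", nm))
        }
      }
    }
    for (nm in .SCALED_DRIVERS) {
      b <- object@scaling[[nm]]
      if (is.null(b) || length(b) != 2 || b[2] <= b[1]) {
        msgs <- c(msgs, sprintf("scaling for '%s' must be c(min, max)", nm))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DriverSet
#'
#' @param fields named list of [GriddedField-class] objects covering
#'   [driverNames()].
#' @param scaling named list of `c(min, max)` bounds for `mtwm_c`,
#'   `wind_ms` and `pop_density`; defaults cover typical tropical ranges.
#' @return a [DriverSet-class] object.
#' @export
driverSet <- function(fields,
                      scaling = list(mtwm_c = c(10, 45), wind_ms = c(0, 12),
                                     pop_density = c(0, 1000))) {
  new("DriverSet", fields = fields[.DRIVER_NAMES], scaling = scaling)
}

#' Control structure of the limitation model
#'
#' A `ControlSpec` records the model's controls (by default the five axes:
#' mean annual precipitation MAP, mean annual temperature MAT, shortwave
#' radiation SW, environmental stress S and human pressure LU), the factors
#' entering each composite control, each control's sign (+1 where tree
#' cover increases with the control, -1 for the suppressive S and LU), and
#' whether the control's factors are raised to fitted powers (stress only).
#' The first factor of every multi-factor control is the reference: its
#' weight is fixed at 1.
#'
#' @slot controls named list; each element is `list(factors =, sign =,
#'   powered =)`.
#' @slot hasTcMax,hasP0 logical; whether the maximum-cover and
#'   zero-inflation parameters are part of the free parameter set.
#'
#' @aliases ControlSpec-class
#' @exportClass ControlSpec
setClass("ControlSpec",
  representation(controls = "list", hasTcMax = "logical", hasP0 = "logical")
)

setValidity("ControlSpec", function(object) {
  msgs <- character()
  for (nm in names(object@controls)) {
    ct <- object@controls[[nm]]
    if (!all(c("factors", "sign", "powered") %in% names(ct))) {
      msgs <- c(msgs, sprintf("control '%s' needs factors/sign/powered", nm))
    } else if (!ct$sign %in% c(-1, 1)) {
      msgs <- c(msgs, sprintf("control '%s' sign must be +1 or -1", nm))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' The default five-control specification
#'
#' MAP (log-transformed precipitation), MAT and SW are single-factor
#' positive controls; stress S combines burnt area, rainfall seasonality,
#' heat (scaled MTWM) and wind with fitted weights and powers; human
#' pressure LU combines population density, urban, cropland and pasture
#' fractions with fitted weights and unit powers.
#'
#' @param hasTcMax,hasP0 include the maximum-cover / zero-inflation
#'   parameters in the free set (default `TRUE`).
#' @return a [ControlSpec-class] object.
#' @examples
#' countFreeParameters(defaultControlSpec())  # 23
#' @export
defaultControlSpec <- function(hasTcMax = TRUE, hasP0 = TRUE) {
  new("ControlSpec",
    controls = list(
      MAP = list(factors = "map", sign = 1, powered = FALSE),
      MAT = list(factors = "mat", sign = 1, powered = FALSE),
      SW  = list(factors = "sw", sign = 1, powered = FALSE),
      S   = list(factors = c("burnt_area", "seasonality", "heat", "wind"),
                 sign = -1, powered = TRUE),
      LU  = list(factors = c("pop_density", "urban", "cropland", "pasture"),
                 sign = -1, powered = FALSE)
    ),
    hasTcMax = hasTcMax, hasP0 = hasP0
  )
}

#' One realization of the model parameter vector
#'
#' Holds logistic midpoints and steepness magnitudes per control, factor
#' weights and powers for the composite controls, the maximum cover, the
#' logit-scale observation noise and the zero-inflation parameter. Steepness
#' is stored as a positive magnitude; the sign is applied from the
#' [ControlSpec-class]. Under the default specification the free-parameter
#' count is 23.
#'
#' @slot x0 named numeric, midpoint per control (control-index units).
#' @slot k named numeric, steepness magnitude per control (>= 0).
#' @slot weights named list, per multi-factor control a numeric vector of
#'   factor weights with the first entry fixed at 1.
#' @slot powers named list, per powered control a vector of positive
#'   exponents (one per factor).
#' @slot tcMax maximum attainable cover in [0, 1].
#' @slot sigma logit-scale observation s.d. (> 0).
#' @slot p0 zero-inflation parameter in [0, 1].
#'
#' @aliases ModelParams-class
#' @exportClass ModelParams
setClass("ModelParams",
  representation(
    x0 = "numeric", k = "numeric", weights = "list", powers = "list",
    tcMax = "numeric", sigma = "numeric", p0 = "numeric"
  )
)

#' Construct a ModelParams object
#'
#' @param x0,k named numeric vectors over the controls of the spec.
#' @param weights,powers named lists (see [ModelParams-class]).
#' @param tcMax,sigma,p0 scalars.
#' @return a [ModelParams-class] object.
#' @export
modelParams <- function(x0, k, weights = list(), powers = list(),
                        tcMax = 1, sigma = 0.5, p0 = 1) {
  new("ModelParams", x0 = x0, k = k, weights = weights, powers = powers,
      tcMax = tcMax, sigma = sigma, p0 = p0)
}

#' Fractional tree-cover observations on a grid
#'
#' @slot field [GriddedField-class] of fractional cover in [0, 1]; the mask
#'   selects the cells that enter the likelihood.
#'
#' @aliases ObservationSet-class
#' @exportClass ObservationSet
setClass("ObservationSet", representation(field = "GriddedField"))

setValidity("ObservationSet", function(object) {
  v <- object@field@values[object@field@mask]
  if (any(v < 0 | v > 1, na.rm = TRUE)) "observations outside [0,1]" else TRUE
})

#' Construct an ObservationSet
#' @param field [GriddedField-class] of fractional cover in [0, 1].
#' @return an [ObservationSet-class] object.
#' @export
observationSet <- function(field) new("ObservationSet", field = field)

#' Number of valid observation cells
#' @param obs an [ObservationSet-class].
#' @return integer count of unmasked cells.
#' @export
nObs <- function(obs) sum(obs@field@mask)

#' Priors over the free parameters
#'
#' Generously wide priors: uniform [0, 1] for the maximum cover and the
#' zero-inflation parameter, rate-1 exponentials for weights, powers,
#' steepness magnitudes and the observation s.d., and normal priors for the
#' midpoints with mean and s.d. equal to half the range of the
#' corresponding control index (0.5 for the fraction-valued composite
#' controls).
#'
#' @slot x0Mean,x0Sd named numeric, normal prior location/scale per control.
#' @slot rate exponential rate for k, weights, powers and sigma.
#'
#' @aliases PriorSpec-class
#' @exportClass PriorSpec
setClass("PriorSpec",
  representation(x0Mean = "numeric", x0Sd = "numeric", rate = "numeric")
)

#' MCMC run configuration
#'
#' @slot nChains number of chains (>= 2 for convergence diagnostics).
#' @slot nIter total iterations per chain.
#' @slot warmupFraction fraction of iterations discarded as warmup.
#' @slot trainFraction fraction of cells used for fitting (default 0.20).
#' @slot nKeepPerChain posterior members retained per chain.
#' @slot seed RNG seed.
#'
#' @aliases ChainConfig-class
#' @exportClass ChainConfig
setClass("ChainConfig",
  representation(
    nChains = "numeric", nIter = "numeric", warmupFraction = "numeric",
    trainFraction = "numeric", nKeepPerChain = "numeric", seed = "numeric"
  )
)

#' Construct a ChainConfig
#'
#' Defaults follow the scaled-down test profile (4 chains of 2,000
#' iterations, half discarded as warmup, 10 retained members per chain);
#' the full-scale protocol (10 chains of 10,000) is obtained by overriding
#' `nChains` and `nIter`.
#'
#' @param nChains,nIter,warmupFraction,trainFraction,nKeepPerChain,seed see
#'   [ChainConfig-class].
#' @return a [ChainConfig-class] object.
#' @export
chainConfig <- function(nChains = 4, nIter = 2000, warmupFraction = 0.5,
                        trainFraction = 0.2, nKeepPerChain = 10, seed = 1) {
  stopifnot(nChains >= 1, nIter >= 20, warmupFraction > 0, warmupFraction < 1)
  new("ChainConfig", nChains = nChains, nIter = nIter,
      warmupFraction = warmupFraction, trainFraction = trainFraction,
      nKeepPerChain = nKeepPerChain, seed = seed)
}

#' A sampled posterior ensemble
#'
#' @slot members numeric matrix, retained members by free parameter
#'   (columns named as in [paramNames()]).
#' @slot logLik per-member log-likelihood.
#' @slot provenance per-member label (dataset/metric combination).
#' @slot weights optional per-member weights.
#' @slot chains post-warmup draws as an array (iteration, chain, parameter)
#'   for convergence diagnostics; may be empty for combined ensembles.
#' @slot acceptance named per-parameter post-warmup acceptance rates.
#'
#' @aliases PosteriorEnsemble-class
#' @exportClass PosteriorEnsemble
setClass("PosteriorEnsemble",
  representation(
    members = "matrix", logLik = "numeric", provenance = "character",
    weights = "numericOrNULL", chains = "array", acceptance = "numeric"
  )
)

setValidity("PosteriorEnsemble", function(object) {
  msgs <- character()
  if (nrow(object@members) < 1) msgs <- c(msgs, "ensemble is empty")
  if (length(object@logLik) != nrow(object@members)) {
    msgs <- c(msgs, "logLik must have one entry per member")
  }
  if (any(!is.finite(object@logLik))) {
    msgs <- c(msgs, "member log-likelihoods must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' Number of ensemble members
#' @param ensemble a [PosteriorEnsemble-class].
#' @return integer member count.
#' @export
nMembers <- function(ensemble) nrow(ensemble@members)

#' Per-cell impact values across posterior members
#'
#' Rows are unmasked grid cells (in the order of `cellIndex` within the
#' template grid), columns are posterior members; paired experiments always
#' share member order so differences are taken member-by-member.
#'
#' @slot values numeric matrix, cells by members.
#' @slot kind `"absolute"` or `"relative"`.
#' @slot cellIndex integer positions of the rows within the template grid.
#' @slot template [GriddedField-class] supplying grid and mask for writing
#'   results back onto the map.
#'
#' @aliases ImpactDistribution-class
#' @exportClass ImpactDistribution
setClass("ImpactDistribution",
  representation(values = "matrix", kind = "character",
                 cellIndex = "integer", template = "GriddedField")
)

#' Per-cell biome codes with a grouping table
#'
#' @slot codes [GriddedField-class] of integer biome codes.
#' @slot groups data.frame with columns `code` and `group` mapping codes to
#'   the aggregated biome groups (wet forest, dry forest, savanna/grassland,
#'   mediterranean, summergreen forest/woodland, desert, other).
#'
#' @aliases BiomeMap-class
#' @exportClass BiomeMap
setClass("BiomeMap",
  representation(codes = "GriddedField", groups = "data.frame")
)

#' Monthly precipitation climatology on a grid
#'
#' @slot pr array (lat, lon, 12) of monthly totals (mm/month).
#' @slot lat,lon cell-centre coordinates (degrees).
#' @slot mask logical validity matrix.
#'
#' @aliases MonthlyClimatology-class
#' @exportClass MonthlyClimatology
setClass("MonthlyClimatology",
  representation(pr = "array", lat = "numeric", lon = "numeric",
                 mask = "matrix")
)

#' Construct a MonthlyClimatology
#' @param pr array (lat, lon, 12) of monthly precipitation totals
#'   (mm/month), non-negative.
#' @param lat,lon cell-centre coordinates.
#' @param mask optional validity matrix.
#' @return a [MonthlyClimatology-class] object.
#' @export
monthlyClimatology <- function(pr, lat, lon, mask = NULL) {
  if (dim(pr)[3] != 12) .stopf("monthly climatology needs 12 months")
  if (any(pr < 0, na.rm = TRUE)) .stopf("negative precipitation")
  if (is.null(mask)) {
    mask <- matrix(!is.na(pr[, , 1]), dim(pr)[1], dim(pr)[2])
  }
  new("MonthlyClimatology", pr = pr, lat = as.numeric(lat),
      lon = as.numeric(lon), mask = mask)
}

#' Daily precipitation series on a grid
#'
#' @slot pr array (lat, lon, days) of daily precipitation (mm/day).
#' @slot lat,lon cell-centre coordinates.
#' @slot mask logical validity matrix.
#' @slot wetDayThreshold mm/day below which a day counts as dry
#'   (default 0.1).
#' @slot monthIndex integer month (1-12) of each day.
#'
#' @aliases DailySeries-class
#' @exportClass DailySeries
setClass("DailySeries",
  representation(pr = "array", lat = "numeric", lon = "numeric",
                 mask = "matrix", wetDayThreshold = "numeric",
                 monthIndex = "integer")
)

# month-of-year for each day of a 365-day calendar
.monthIndex365 <- function(ndays = 365L) {
  lens <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  idx <- rep.int(seq_len(12), lens)
  if (ndays != length(idx)) idx <- rep_len(idx, ndays)
  as.integer(idx)
}

#' Construct a DailySeries
#' @param pr array (lat, lon, days) of daily precipitation (mm/day),
#'   non-negative.
#' @param lat,lon cell-centre coordinates.
#' @param wetDayThreshold mm/day threshold for a dry day (default 0.1).
#' @param monthIndex integer month of each day; defaults to a 365-day
#'   calendar.
#' @param mask optional validity matrix.
#' @return a [DailySeries-class] object.
#' @export
dailySeries <- function(pr, lat, lon, wetDayThreshold = 0.1,
                        monthIndex = NULL, mask = NULL) {
  if (any(pr < 0, na.rm = TRUE)) .stopf("negative precipitation")
  if (is.null(monthIndex)) monthIndex <- .monthIndex365(dim(pr)[3])
  if (is.null(mask)) {
    mask <- matrix(!is.na(pr[, , 1]), dim(pr)[1], dim(pr)[2])
  }
  new("DailySeries", pr = pr, lat = as.numeric(lat), lon = as.numeric(lon),
      mask = mask, wetDayThreshold = wetDayThreshold,
      monthIndex = as.integer(monthIndex))
}

#' Synthetic study configuration
#'
#' Defines the synthetic study conditions: grid size, spatial correlation
#' length of the driver fields, the true generating parameters, marginal
#' ranges for each driver, the burnt-area/seasonality cross-correlation and
#' the land fraction.
#'
#' @slot nlat,nlon grid size in cells (0.5 degree spacing).
#' @slot seed RNG seed fixing every random draw.
#' @slot corLength spatial correlation length in cells.
#' @slot trueParams generating [ModelParams-class].
#' @slot ranges named list of marginal ranges per driver.
#' @slot baSeasCor cross-correlation between burnt area and seasonality.
#' @slot landFraction fraction of cells left unmasked.
#'
#' @aliases SyntheticConfig-class
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    nlat = "numeric", nlon = "numeric", seed = "numeric",
    corLength = "numeric", trueParams = "ModelParams", ranges = "list",
    baSeasCor = "numeric", landFraction = "numeric"
  )
)

setMethod("show", "GriddedField", function(object) {
  cat(sprintf("GriddedField '%s' [%s]: %d x %d cells (%d valid)\n",
              object@name, object@units, length(object@lat),
              length(object@lon), sum(object@mask)))
  cat(sprintf("  lat %.2f..%.2f, lon %.2f..%.2f\n",
              min(object@lat), max(object@lat),
              min(object@lon), max(object@lon)))
})

setMethod("show", "DriverSet", function(object) {
  f <- object@fields[[1L]]
  cat(sprintf("DriverSet: %d predictors on %d x %d grid (%d valid cells)\n",
              length(object@fields), length(f@lat), length(f@lon),
              sum(f@mask)))
})

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams\n")
  cat("  x0:   ", paste(sprintf("%s=%.3g", names(object@x0), object@x0),
                        collapse = " "), "\n")
  cat("  |k|:  ", paste(sprintf("%s=%.3g", names(object@k), object@k),
                        collapse = " "), "\n")
  cat(sprintf("  tcMax=%.3g sigma=%.3g p0=%.3g\n", object@tcMax,
              object@sigma, object@p0))
})

setMethod("show", "PosteriorEnsemble", function(object) {
  cat(sprintf("PosteriorEnsemble: %d members x %d parameters\n",
              nrow(object@members), ncol(object@members)))
  cat(sprintf("  logLik range %.1f..%.1f\n", min(object@logLik),
              max(object@logLik)))
  if (length(object@acceptance)) {
    cat(sprintf("  mean acceptance %.2f\n", mean(object@acceptance)))
  }
})

setMethod("show", "ImpactDistribution", function(object) {
  cat(sprintf("ImpactDistribution (%s): %d cells x %d members\n",
              object@kind, nrow(object@values), ncol(object@values)))
})
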