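# The forward model. Fractional tree cover is a maximum cover times the
# product over controls of logistic limitation factors,
#   TC = tcMax * prod_c f(sign_c * k_c * (X_c - x0_c)),  f(x) = 1/(1+e^-x),
# where X_c is the control index: the driver itself for the single-factor
# climate controls (log-transformed precipitation, temperature, shortwave)
# and a normalized weighted power combination
#   X_c = sum_i v_i x_i^p_i / sum_i v_i
# for the composite stress and human-pressure controls (powers are fitted
# for stress only; the first factor of each composite is the reference
# with weight fixed at 1). All composite factors are scaled to [0, 1].

.FACTOR_DRIVER <- c(
  map = "map_mm", mat = "mat_c", sw = "sw_wm2",
  burnt_area = "burnt_area", seasonality = "seasonality",
  heat = "mtwm_c", wind = "wind_ms",
  pop_density = "pop_density", urban = "urban", cropland = "cropland",
  pasture = "pasture"
)

#' Number of free parameters implied by a control specification
#'
#' Counts the logistic midpoint and steepness per control, the
#' non-reference weights and free exponents of the composite controls, the
#' observation s.d., and (if present) the maximum-cover and zero-inflation
#' parameters. The default five-control specification yields 23.
#'
#' @param spec a [ControlSpec-class].
#' @return integer free-parameter count.
#' @examples
#' countFreeParameters(defaultControlSpec())  # 23
#' @export
countFreeParameters <- function(spec) {
  n <- 0L
  for (ct in spec@controls) {
    nf <- length(ct$factors)
    n <- n + 2L + max(0L, nf - 1L) + if (isTRUE(ct$powered)) nf else 0L
  }
  n + 1L + as.integer(spec@hasTcMax) + as.integer(spec@hasP0)
}

#' Names of the free parameters in vector order
#' @param spec a [ControlSpec-class].
#' @return character vector of free-parameter names.
#' @export
paramNames <- function(spec) {
  cn <- names(spec@controls)
  nms <- c(paste0("x0_", cn), paste0("k_", cn))
  for (nm in cn) {
    ct <- spec@controls[[nm]]
    if (length(ct$factors) > 1) {
      nms <- c(nms, paste0("v_", ct$factors[-1]))
    }
  }
  for (nm in cn) {
    ct <- spec@controls[[nm]]
    if (isTRUE(ct$powered)) nms <- c(nms, paste0("p_", ct$factors))
  }
  if (spec@hasTcMax) nms <- c(nms, "tc_max")
  nms <- c(nms, "sigma")
  if (spec@hasP0) nms <- c(nms, "p0")
  nms
}

#' Log transform of mean annual precipitation
#'
#' `log(MAP + 1/ncells)` with `ncells` the number of unmasked analysis
#' cells; strictly increasing in MAP and tending to a large negative value
#' as MAP tends to zero, so the precipitation control drives tree cover to
#' zero in rainless cells.
#'
#' @param map numeric vector/matrix or [GriddedField-class] of MAP (mm/yr).
#' @param ncells number of unmasked analysis cells (> 0).
#' @return transformed values, same shape/class as `map`.
#' @export
transformMAP <- function(map, ncells) {
  if (ncells <= 0) .stopf("ncells must be positive")
  if (is(map, "GriddedField")) {
    out <- map
    out@values <- log(map@values + 1 / ncells)
    out@name <- "map_star"
    out@units <- "log(mm/yr)"
    return(out)
  }
  log(map + 1 / ncells)
}

#' Min-max scaling of a driver to [0, 1]
#'
#' `(x - min)/(max - min)`, clipped to [0, 1]. With bounds `c(0, 1)` this
#' is the identity for already-fractional drivers.
#'
#' @param x numeric vector/matrix or [GriddedField-class].
#' @param bounds `c(min, max)` with `max > min`.
#' @return scaled values, same shape/class as `x`.
#' @export
scaleFactor <- function(x, bounds) {
  if (length(bounds) != 2 || bounds[2] <= bounds[1]) {
    .stopf("bounds must be c(min, max) with max > min")
  }
  sc <- function(v) pmin(pmax((v - bounds[1]) / (bounds[2] - bounds[1]), 0), 1)
  if (is(x, "GriddedField")) {
    out <- x
    out@values <- sc(x@values)
    out@units <- "1"
    return(out)
  }
  sc(x)
}

#' Weighted power combination of scaled factors
#'
#' The composite control index `sum_i v_i x_i^p_i / sum_i v_i`, in [0, 1]
#' for factors in [0, 1].
#'
#' @param x numeric vector with one value per factor, or a matrix with one
#'   column per factor.
#' @param weights factor weights (first entry is the reference, fixed 1).
#' @param exponents positive exponents, one per factor (default all 1).
#' @return the combined index (scalar or vector over rows).
#' @export
controlIndex <- function(x, weights, exponents = rep(1, length(weights))) {
  if (is.matrix(x)) {
    if (ncol(x) != length(weights)) .stopf("weights length != factor count")
  } else if (length(x) != length(weights)) {
    .stopf("weights length != factor count")
  }
  if (length(exponents) != length(weights)) {
    .stopf("exponents length != factor count")
  }
  if (any(exponents <= 0)) .stopf("exponents must be positive")
  if (any(weights < 0)) .stopf("weights must be non-negative")
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  num <- 0
  for (i in seq_along(weights)) {
    num <- num + weights[i] * xm[, i]^exponents[i]
  }
  out <- num / sum(weights)
  if (is.matrix(x)) out else as.numeric(out)
}

#' Logistic limitation curve
#'
#' `f(k * (X - x0))` with `f` the standard logistic; 0.5 at `X = x0`,
#' increasing in `X` for `k > 0` and decreasing for `k < 0`.
#'
#' @param X control index (numeric or [GriddedField-class]).
#' @param x0 midpoint.
#' @param k signed steepness.
#' @return limitation factor in (0, 1), same shape/class as `X`.
#' @export
limitationCurve <- function(X, x0, k) {
  if (is(X, "GriddedField")) {
    out <- X
    out@values <- stats::plogis(k * (X@values - x0))
    out@units <- "1"
    return(out)
  }
  stats::plogis(k * (X - x0))
}

#' Combined energy limitation factor
#'
#' The product of the temperature and shortwave limitation factors,
#' reported as a single energy control.
#'
#' @param mat,sw control indices (numeric or [GriddedField-class]).
#' @param params a [ModelParams-class] with `MAT` and `SW` entries.
#' @return the combined factor, same shape/class as `mat`.
#' @export
energyFactor <- function(mat, sw, params) {
  fm <- limitationCurve(mat, params@x0[["MAT"]], params@k[["MAT"]])
  fs <- limitationCurve(sw, params@x0[["SW"]], params@k[["SW"]])
  if (is(fm, "GriddedField")) {
    fm@values <- fm@values * (if (is(fs, "GriddedField")) fs@values else fs)
    fm@name <- "energy_factor"
    return(fm)
  }
  fm * fs
}

# ---- internal prepared representation -------------------------------------

# Scaled/transformed factor matrix over unmasked cells. ncells for the
# precipitation transform is the count of unmasked analysis cells.
.prepareDrivers <- function(drivers, spec) {
  ref <- drivers@fields[[1L]]
  cellIndex <- which(ref@mask)
  ncells <- length(cellIndex)
  fac <- unique(unlist(lapply(spec@controls, `[[`, "factors")))
  X <- matrix(NA_real_, length(cellIndex), length(fac),
              dimnames = list(NULL, fac))
  for (f in fac) {
    dn <- .FACTOR_DRIVER[[f]]
    v <- drivers@fields[[dn]]@values[cellIndex]
    if (f == "map") {
      v <- transformMAP(v, ncells)
    } else if (dn %in% .SCALED_DRIVERS) {
      v <- scaleFactor(v, drivers@scaling[[dn]])
    }
    X[, f] <- v
  }
  list(X = X, cellIndex = cellIndex, template = ref, ncells = ncells)
}

# index column for one control from the prepared factor matrix.
# zeroFactors removes factors' terms from the numerator while keeping
# the fitted normalization sum(v): a removed factor simply stops
# contributing stress, so a zero-valued factor is a no-op and removal
# never increases the index.
.ctrlIndexVec <- function(prep, params, spec, nm, zeroFactors = NULL) {
  ct <- spec@controls[[nm]]
  if (length(ct$factors) == 1L) return(prep$X[, ct$factors])
  w <- params@weights[[nm]]
  p <- if (isTRUE(ct$powered)) params@powers[[nm]] else
    rep(1, length(ct$factors))
  den <- sum(w)
  if (!is.null(zeroFactors)) w[match(zeroFactors, ct$factors)] <- 0
  num <- 0
  for (i in seq_along(w)) {
    if (w[i] > 0) num <- num + w[i] * prep$X[, ct$factors[i]]^p[i]
  }
  num / den
}

# matrix of limitation factors (cells x controls); dropControls excludes
# whole controls, zeroFactors removes factors inside their composites
.limitFactorMatrix <- function(prep, params, spec,
                               dropControls = character(),
                               zeroFactors = NULL) {
  keep <- setdiff(names(spec@controls), dropControls)
  F <- matrix(NA_real_, nrow(prep$X), length(keep),
              dimnames = list(NULL, keep))
  for (nm in keep) {
    ct <- spec@controls[[nm]]
    zf <- intersect(zeroFactors, ct$factors)
    Xc <- .ctrlIndexVec(prep, params, spec, nm,
                        zeroFactors = if (length(zf)) zf else NULL)
    F[, nm] <- stats::plogis(ct$sign * params@k[[nm]] *
                             (Xc - params@x0[[nm]]))
  }
  F
}

.treeCoverVec <- function(prep, params, spec, dropControls = character(),
                          zeroFactors = NULL) {
  F <- .limitFactorMatrix(prep, params, spec, dropControls, zeroFactors)
  tcm <- if (spec@hasTcMax) params@tcMax else 1
  tcm * .rowProds(F)
}

.vecToField <- function(v, prep, name, units = "1") {
  vals <- prep$template@values
  vals[] <- NA_real_
  vals[prep$cellIndex] <- v
  griddedField(name, vals, lat = prep$template@lat, lon = prep$template@lon,
               units = units, mask = prep$template@mask)
}

# ---- exported forward model ------------------------------------------------

#' Predicted fractional tree cover
#'
#' Evaluates the full forward model: per-cell maximum cover times the
#' product of all control limitation factors.
#'
#' @param drivers a [DriverSet-class].
#' @param params a [ModelParams-class].
#' @param spec a [ControlSpec-class] (default [defaultControlSpec()]).
#' @return a [GriddedField-class] of fractional cover in (0, tcMax).
#' @export
treeCover <- function(drivers, params, spec = defaultControlSpec()) {
  prep <- .prepareDrivers(drivers, spec)
  .vecToField(.treeCoverVec(prep, params, spec), prep, "tree_cover")
}

#' Tree cover with one control or factor removed
#'
#' For a whole control the product simply excludes that control's
#' limitation factor. For a factor inside a composite control the control
#' index is recomputed with that factor's contribution removed from the
#' numerator while the fitted normalization `sum(v)` is kept, so a
#' zero-valued factor is a no-op and removing a suppressive factor never
#' decreases cover.
#'
#' @param drivers a [DriverSet-class].
#' @param params a [ModelParams-class].
#' @param spec a [ControlSpec-class].
#' @param removed a control name (e.g. `"S"`) or factor name (e.g.
#'   `"burnt_area"`); a character vector removes several jointly.
#' @return a [GriddedField-class] of fractional cover.
#' @export
treeCoverWithout <- function(drivers, params, spec = defaultControlSpec(),
                             removed) {
  prep <- .prepareDrivers(drivers, spec)
  .vecToField(.treeCoverWithoutVec(prep, params, spec, removed), prep,
              paste0("tree_cover_without_", paste(removed, collapse = "_")))
}

# resolve a removal id to (dropControls, zeroFactor); single-factor
# controls are removed whole when named by their factor
.resolveRemoval <- function(spec, removed) {
  dropControls <- character()
  zeroFactors <- character()
  for (id in removed) {
    if (id %in% names(spec@controls)) {
      dropControls <- c(dropControls, id)
      next
    }
    owner <- NULL
    for (nm in names(spec@controls)) {
      if (id %in% spec@controls[[nm]]$factors) owner <- nm
    }
    if (is.null(owner)) .stopf("unknown control or factor '%s'", id)
    if (length(spec@controls[[owner]]$factors) == 1L) {
      dropControls <- c(dropControls, owner)
    } else {
      zeroFactors <- c(zeroFactors, id)
    }
  }
  list(dropControls = dropControls, zeroFactors = zeroFactors)
}

.treeCoverWithoutVec <- function(prep, params, spec, removed) {
  r <- .resolveRemoval(spec, removed)
  .treeCoverVec(prep, params, spec, dropControls = r$dropControls,
                zeroFactors = if (length(r$zeroFactors)) r$zeroFactors
                              else NULL)
}
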