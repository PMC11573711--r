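# Independent per-cell scalar oracles: plain-R re-derivations of the
# model quantities from raw driver values, written without reference to
# the package internals.

.oLogistic <- function(x) 1 / (1 + exp(-x))

# per-cell factor values (scaled/transformed) for the default spec
.oCellFactors <- function(drivers, cell, ncells) {
  g <- function(nm) drivers@fields[[nm]]@values[cell]
  sc <- function(nm) {
    b <- drivers@scaling[[nm]]
    min(max((g(nm) - b[1]) / (b[2] - b[1]), 0), 1)
  }
  list(map = log(g("map_mm") + 1 / ncells), mat = g("mat_c"),
       sw = g("sw_wm2"),
       s = c(g("burnt_area"), g("seasonality"), sc("mtwm_c"),
             sc("wind_ms")),
       lu = c(sc("pop_density"), g("urban"), g("cropland"),
              g("pasture")))
}

# limitation factors of the five controls at one cell; dropS / dropLU
# remove one factor's term from the composite numerator (by position),
# keeping the fitted normalization
.oCellControlFactors <- function(fv, p, dropS = NULL, dropLU = NULL) {
  wS <- p@weights$S
  denS <- sum(wS)
  if (!is.null(dropS)) wS[dropS] <- 0
  wLU <- p@weights$LU
  denLU <- sum(wLU)
  if (!is.null(dropLU)) wLU[dropLU] <- 0
  xS <- sum(wS * fv$s^p@powers$S) / denS
  xLU <- sum(wLU * fv$lu) / denLU
  c(MAP = .oLogistic(p@k[["MAP"]] * (fv$map - p@x0[["MAP"]])),
    MAT = .oLogistic(p@k[["MAT"]] * (fv$mat - p@x0[["MAT"]])),
    SW = .oLogistic(p@k[["SW"]] * (fv$sw - p@x0[["SW"]])),
    S = .oLogistic(-p@k[["S"]] * (xS - p@x0[["S"]])),
    LU = .oLogistic(-p@k[["LU"]] * (xLU - p@x0[["LU"]])))
}

# scalar-loop tree cover over all unmasked cells; removed may name a
# control or one of the composite factors
oracleTreeCover <- function(drivers, p, removed = NULL) {
  mask <- drivers@fields[[1]]@mask
  cells <- which(mask)
  ncells <- length(cells)
  sFac <- c("burnt_area", "seasonality", "heat", "wind")
  luFac <- c("pop_density", "urban", "cropland", "pasture")
  vapply(cells, function(cell) {
    fv <- .oCellFactors(drivers, cell, ncells)
    dropS <- if (!is.null(removed) && removed %in% sFac) {
      match(removed, sFac)
    }
    dropLU <- if (!is.null(removed) && removed %in% luFac) {
      match(removed, luFac)
    }
    f <- .oCellControlFactors(fv, p, dropS, dropLU)
    keep <- setdiff(names(f),
                    if (!is.null(removed)) removed else character())
    p@tcMax * prod(f[keep])
  }, 0)
}

# scalar-loop zero-inflated logit-normal log-likelihood
oracleLogLik <- function(obsVec, tcVec, sigma, p0) {
  lg <- function(x) {
    x <- min(max(x, 1e-6), 1 - 1e-6)
    log(x / (1 - x))
  }
  total <- 0
  for (i in seq_along(obsVec)) {
    pz <- (1 - tcVec[i]^2) * (1 - p0)
    total <- total + if (obsVec[i] == 0) {
      log(pz)
    } else {
      z <- (lg(obsVec[i]) - lg(tcVec[i])) / sigma
      log(1 - pz) - 0.5 * z^2 - log(sigma * sqrt(2 * pi))
    }
  }
  total
}

# scalar sensitivity R = 4 f (1-f) * TC_without(control)
oracleSensitivity <- function(drivers, p, control) {
  mask <- drivers@fields[[1]]@mask
  cells <- which(mask)
  ncells <- length(cells)
  tcs <- oracleTreeCover(drivers, p, removed = control)
  vapply(seq_along(cells), function(i) {
    fv <- .oCellFactors(drivers, cells[i], ncells)
    f <- .oCellControlFactors(fv, p)[[control]]
    4 * f * (1 - f) * tcs[i]
  }, 0)
}
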