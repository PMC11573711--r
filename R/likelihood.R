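# Zero-inflated logit-normal observation model. A cell observes exactly
# zero cover with probability (1 - TC^2) * (1 - p0); positive observations
# follow a normal on the logit scale centred at logit(TC) with s.d. sigma.
# The logit Jacobian 1/(obs*(1-obs)) is constant in the parameters and is
# omitted, leaving the posterior shape unchanged. Observed and predicted
# cover are clipped to [1e-6, 1 - 1e-6] before the logit so satellite-like
# data containing exact 0/1 stay finite.

#' Probability of observing exactly zero cover
#'
#' `(1 - tc^2) * (1 - p0)`: decreasing in both predicted cover and the
#' zero-inflation parameter; as `p0` approaches 1 the model predicts no
#' exact zeros.
#'
#' @param tc predicted cover in [0, 1] (vectorized).
#' @param p0 zero-inflation parameter in [0, 1].
#' @return probability in [0, 1].
#' @export
zeroProb <- function(tc, p0) {
  if (any(tc < 0 | tc > 1, na.rm = TRUE)) .stopf("tc outside [0,1]")
  if (any(p0 < 0 | p0 > 1)) .stopf("p0 outside [0,1]")
  (1 - tc^2) * (1 - p0)
}

# vectorized core used by the sampler: obsVec in [0,1], tcVec in [0,1]
.logLikVec <- function(obsVec, tcVec, sigma, p0) {
  pz <- (1 - pmin(tcVec, 1)^2) * (1 - p0)
  iszero <- obsVec <= 0
  ll <- numeric(length(obsVec))
  ll[iszero] <- log(pz[iszero])
  if (any(!iszero)) {
    lt <- .logit(tcVec[!iszero])
    lo <- .logit(obsVec[!iszero])
    ll[!iszero] <- log1p(-pz[!iszero]) +
      stats::dnorm(lo, mean = lt, sd = sigma, log = TRUE)
  }
  ll
}

#' Zero-inflated logit-normal log-likelihood
#'
#' Sums per-cell contributions: `log zeroProb(tc, p0)` where the observed
#' cover is zero, and `log(1 - zeroProb(tc, p0))` plus the logit-scale
#' normal log-density where it is positive.
#'
#' @param obs an [ObservationSet-class] or numeric vector in [0, 1].
#' @param tc predicted cover: a [GriddedField-class] on the same grid, or a
#'   numeric vector aligned with `obs`.
#' @param sigma logit-scale s.d. (> 0).
#' @param p0 zero-inflation parameter in [0, 1].
#' @return the summed log-likelihood (scalar).
#' @export
logLikelihood <- function(obs, tc, sigma, p0) {
  if (sigma <= 0) .stopf("sigma must be positive")
  if (p0 < 0 || p0 > 1) .stopf("p0 outside [0,1]")
  if (is(obs, "ObservationSet")) {
    m <- obs@field@mask
    obsVec <- obs@field@values[m]
    tcVec <- if (is(tc, "GriddedField")) tc@values[m] else tc
  } else {
    obsVec <- obs
    tcVec <- if (is(tc, "GriddedField")) tc@values[tc@mask] else tc
  }
  if (length(obsVec) != length(tcVec)) {
    .stopf("obs and tc must align cell-by-cell")
  }
  if (any(obsVec < 0 | obsVec > 1, na.rm = TRUE)) .stopf("obs outside [0,1]")
  sum(.logLikVec(obsVec, tcVec, sigma, p0))
}
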