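# Priors and the flat parameter-vector representation used by the
# sampler. Priors are deliberately wide: uniform [0,1] for the maximum
# cover and zero-inflation parameter, rate-1 exponentials for weights,
# powers, steepness magnitudes and the observation s.d. (bounding
# steepness at zero; the sign comes from the control spec), and normal
# priors for midpoints with mean and s.d. equal to half the range of the
# corresponding control index (0.5 for the fraction-valued composites).

# per-parameter metadata: role, transform for proposals, owning control
.paramMeta <- function(spec) {
  nms <- paramNames(spec)
  role <- sub("_.*$", "", nms)
  role[nms == "tc_max"] <- "tcmax"
  role[nms == "sigma"] <- "sigma"
  role[nms == "p0"] <- "p0"
  control <- rep(NA_character_, length(nms))
  factor_ <- rep(NA_character_, length(nms))
  cn <- names(spec@controls)
  for (i in seq_along(nms)) {
    nm <- nms[i]
    if (role[i] %in% c("x0", "k")) {
      control[i] <- sub("^(x0|k)_", "", nm)
    } else if (role[i] %in% c("v", "p")) {
      f <- sub("^(v|p)_", "", nm)
      factor_[i] <- f
      for (cc in cn) if (f %in% spec@controls[[cc]]$factors) control[i] <- cc
    }
  }
  transform <- ifelse(role == "x0", "identity",
               ifelse(role %in% c("tcmax", "p0"), "logit", "log"))
  data.frame(name = nms, role = role, control = control, factor = factor_,
             transform = transform, stringsAsFactors = FALSE)
}

#' Default priors derived from the driver ranges
#'
#' Midpoint priors are normal with mean and s.d. equal to half the range
#' of each control index over the unmasked cells (0.5 for the
#' fraction-valued stress and human-pressure composites); all positive
#' parameters get rate-1 exponential priors; the maximum cover and the
#' zero-inflation parameter get uniform [0, 1] priors.
#'
#' @param drivers a [DriverSet-class] (supplies the control ranges).
#' @param spec a [ControlSpec-class].
#' @return a [PriorSpec-class].
#' @export
defaultPriors <- function(drivers, spec = defaultControlSpec()) {
  prep <- .prepareDrivers(drivers, spec)
  cn <- names(spec@controls)
  halfRange <- vapply(cn, function(nm) {
    ct <- spec@controls[[nm]]
    if (length(ct$factors) == 1L) {
      r <- range(prep$X[, ct$factors], finite = TRUE)
      (r[2] - r[1]) / 2
    } else 0.5  # composite indices live on [0, 1]
  }, 0)
  new("PriorSpec", x0Mean = halfRange, x0Sd = pmax(halfRange, 1e-3),
      rate = 1)
}

#' Flatten ModelParams to the free-parameter vector
#' @param params a [ModelParams-class].
#' @param spec a [ControlSpec-class].
#' @return named numeric vector in [paramNames()] order.
#' @export
paramsToVector <- function(params, spec) {
  meta <- .paramMeta(spec)
  out <- numeric(nrow(meta))
  names(out) <- meta$name
  for (i in seq_len(nrow(meta))) {
    out[i] <- switch(meta$role[i],
      x0 = params@x0[[meta$control[i]]],
      k = params@k[[meta$control[i]]],
      v = {
        ct <- spec@controls[[meta$control[i]]]
        params@weights[[meta$control[i]]][match(meta$factor[i], ct$factors)]
      },
      p = {
        ct <- spec@controls[[meta$control[i]]]
        params@powers[[meta$control[i]]][match(meta$factor[i], ct$factors)]
      },
      tcmax = params@tcMax,
      sigma = params@sigma,
      p0 = params@p0
    )
  }
  out
}

#' Rebuild ModelParams from a free-parameter vector
#' @param vec named numeric vector in [paramNames()] order.
#' @param spec a [ControlSpec-class].
#' @return a [ModelParams-class].
#' @export
vectorToParams <- function(vec, spec) {
  cn <- names(spec@controls)
  x0 <- vec[paste0("x0_", cn)]
  k <- vec[paste0("k_", cn)]
  names(x0) <- names(k) <- cn
  weights <- list()
  powers <- list()
  for (nm in cn) {
    ct <- spec@controls[[nm]]
    nf <- length(ct$factors)
    if (nf > 1) {
      weights[[nm]] <- c(1, unname(vec[paste0("v_", ct$factors[-1])]))
    }
    if (isTRUE(ct$powered)) {
      powers[[nm]] <- unname(vec[paste0("p_", ct$factors)])
    }
  }
  modelParams(x0 = x0, k = k, weights = weights, powers = powers,
              tcMax = if (spec@hasTcMax) unname(vec[["tc_max"]]) else 1,
              sigma = unname(vec[["sigma"]]),
              p0 = if (spec@hasP0) unname(vec[["p0"]]) else 1)
}

# vectorized log prior over the natural-scale parameter vector
.logPriorVec <- function(vec, priors, spec, meta = .paramMeta(spec)) {
  lp <- 0
  for (i in seq_len(nrow(meta))) {
    x <- vec[[i]]
    lp <- lp + switch(meta$role[i],
      x0 = stats::dnorm(x, priors@x0Mean[[meta$control[i]]],
                        priors@x0Sd[[meta$control[i]]], log = TRUE),
      tcmax = ,
      p0 = if (x >= 0 && x <= 1) 0 else -Inf,
      # k, v, p, sigma: rate-1 exponential bounded at zero
      if (x >= 0) stats::dexp(x, priors@rate, log = TRUE) else -Inf
    )
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}

#' Log prior density of a parameter set
#'
#' Sum of independent log prior densities; `-Inf` outside the support.
#'
#' @param params a [ModelParams-class].
#' @param priors a [PriorSpec-class].
#' @param spec a [ControlSpec-class].
#' @return scalar log prior density.
#' @export
logPrior <- function(params, priors, spec = defaultControlSpec()) {
  .logPriorVec(paramsToVector(params, spec), priors, spec)
}
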