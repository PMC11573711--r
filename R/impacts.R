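# The impact calculus. A factor or control's impact is measured by
# removing it and comparing: the absolute impact is |TC_*(i) - TC| and the
# relative impact is (TC_*(i) - TC)/TC_*(i), where TC_*(i) is tree cover
# recomputed with i removed (whole controls drop out of the product;
# factors inside a composite lose their numerator term while the fitted
# normalization is kept). For a whole control the relative impact
# equals 1 - f_c, one minus that control's limitation factor. Experiments
# across posterior members are always paired member-by-member to respect
# parameter co-variation.

.impactDist <- function(values, kind, prep) {
  new("ImpactDistribution", values = values, kind = kind,
      cellIndex = prep$cellIndex, template = prep$template)
}

#' Absolute impact of a control or factor
#'
#' `|TC_*(target) - TC|` per cell for one parameter set.
#'
#' @param drivers a [DriverSet-class].
#' @param params a [ModelParams-class].
#' @param spec a [ControlSpec-class].
#' @param target control or factor name.
#' @return a [GriddedField-class] of absolute cover differences.
#' @export
absoluteImpact <- function(drivers, params, spec = defaultControlSpec(),
                           target) {
  prep <- .prepareDrivers(drivers, spec)
  tc <- .treeCoverVec(prep, params, spec)
  tcs <- .treeCoverWithoutVec(prep, params, spec, target)
  .vecToField(abs(tcs - tc), prep, paste0("impact_", target))
}

#' Relative impact of a control or factor
#'
#' The fractional increase in cover were the target removed,
#' `(TC_*(target) - TC)/TC_*(target)`; for a whole control this equals one
#' minus the control's limitation factor. `form = "printed"` evaluates the
#' alternative form `TC * (1 - f)` kept for comparison.
#'
#' @inheritParams absoluteImpact
#' @param form `"ratio"` (the definition) or `"printed"`.
#' @return a [GriddedField-class]; cells with `TC_* = 0` are masked.
#' @export
relativeImpact <- function(drivers, params, spec = defaultControlSpec(),
                           target, form = c("ratio", "printed")) {
  form <- match.arg(form)
  prep <- .prepareDrivers(drivers, spec)
  tc <- .treeCoverVec(prep, params, spec)
  tcs <- .treeCoverWithoutVec(prep, params, spec, target)
  v <- if (form == "ratio") {
    ifelse(tcs > 0, (tcs - tc) / tcs, NA_real_)
  } else {
    tc * (1 - ifelse(tcs > 0, tc / tcs, NA_real_))
  }
  .vecToField(v, prep, paste0("relative_impact_", target))
}

#' Impact distribution across a posterior ensemble
#'
#' Per-cell impacts for every ensemble member (paired columns).
#'
#' @inheritParams absoluteImpact
#' @param ensemble a [PosteriorEnsemble-class].
#' @param kind `"relative"` or `"absolute"`.
#' @return an [ImpactDistribution-class].
#' @export
impactDistribution <- function(drivers, ensemble,
                               spec = defaultControlSpec(), target,
                               kind = c("relative", "absolute")) {
  kind <- match.arg(kind)
  prep <- .prepareDrivers(drivers, spec)
  M <- nMembers(ensemble)
  out <- matrix(NA_real_, nrow(prep$X), M)
  for (m in seq_len(M)) {
    pm <- memberParams(ensemble, m, spec)
    tc <- .treeCoverVec(prep, pm, spec)
    tcs <- .treeCoverWithoutVec(prep, pm, spec, target)
    out[, m] <- if (kind == "absolute") abs(tcs - tc) else {
      ifelse(tcs > 0, (tcs - tc) / tcs, NA_real_)
    }
  }
  .impactDist(out, kind, prep)
}

# per-member area-weighted aggregate of an impact distribution
.memberAggregate <- function(dist) {
  w <- cellAreaWeights(dist@template)@values[dist@cellIndex]
  colSums(dist@values * w, na.rm = TRUE) / sum(w)
}

#' Overlap probability between two impact distributions
#'
#' The Bhattacharyya coefficient `sum_b sqrt(P_i(b) P_j(b))` over a shared
#' histogram binning of the two samples: 1 for identical distributions, 0
#' for disjoint supports. `convention = "pvalue"` returns one minus the
#' coefficient, the null-test reporting convention. Symmetric in its
#' arguments.
#'
#' @param x,y numeric samples on a common support (e.g. per-member
#'   aggregate impacts), or [ImpactDistribution-class] objects (reduced to
#'   per-member area-weighted means).
#' @param nbins number of shared histogram bins (default 100).
#' @param support common support (default [0, 1]).
#' @param convention `"overlap"` (the coefficient) or `"pvalue"`.
#' @return scalar in [0, 1].
#' @export
pairwiseDifferenceProbability <- function(x, y, nbins = 100,
                                          support = c(0, 1),
                                          convention = c("overlap",
                                                         "pvalue")) {
  convention <- match.arg(convention)
  if (is(x, "ImpactDistribution")) x <- .memberAggregate(x)
  if (is(y, "ImpactDistribution")) y <- .memberAggregate(y)
  if (!length(x) || !length(y)) .stopf("empty impact samples")
  breaks <- seq(support[1], support[2], length.out = nbins + 1)
  hx <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins)
  hy <- tabulate(findInterval(y, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins)
  bc <- sum(sqrt((hx / sum(hx)) * (hy / sum(hy))))
  if (convention == "overlap") bc else 1 - bc
}

#' Limitation imposed by a control
#'
#' One minus the maximum cover the control allows. For the suppressive
#' stress and human-pressure controls the factor is first normalized by
#' its value at zero stress, so zero stress means zero limitation.
#'
#' @inheritParams absoluteImpact
#' @param control control name.
#' @return a [GriddedField-class] of limitation in [0, 1].
#' @export
limitation <- function(drivers, params, spec = defaultControlSpec(),
                       control) {
  if (!control %in% names(spec@controls)) {
    .stopf("unknown control '%s'", control)
  }
  prep <- .prepareDrivers(drivers, spec)
  ct <- spec@controls[[control]]
  Xc <- .ctrlIndexVec(prep, params, spec, control)
  f <- stats::plogis(ct$sign * params@k[[control]] *
                     (Xc - params@x0[[control]]))
  v <- if (ct$sign > 0) {
    1 - f
  } else {
    f0 <- stats::plogis(ct$sign * params@k[[control]] *
                        (0 - params@x0[[control]]))
    1 - f / f0
  }
  .vecToField(pmin(pmax(v, 0), 1), prep, paste0("limitation_", control))
}

#' Sensitivity of tree cover to a control
#'
#' The local responsiveness `R = G * TC_*(target)` with
#' `G = f'(k(X - x0)) / f'(0) = 4 f (1 - f)`: the logistic gradient
#' normalized to its midpoint maximum, times the cover unconstrained by
#' the target. Maximal exactly where the control index crosses its
#' midpoint.
#'
#' @inheritParams absoluteImpact
#' @param target control name.
#' @return a [GriddedField-class]; values in [0, TC_*].
#' @export
sensitivity <- function(drivers, params, spec = defaultControlSpec(),
                        target) {
  if (!target %in% names(spec@controls)) .stopf("unknown control '%s'",
                                                target)
  prep <- .prepareDrivers(drivers, spec)
  F <- .limitFactorMatrix(prep, params, spec)
  f <- F[, target]
  G <- 4 * f * (1 - f)
  tcs <- .treeCoverVec(prep, params, spec, dropControls = target)
  .vecToField(G * tcs, prep, paste0("sensitivity_", target))
}

# drivers with the burnt-area field replaced
.withBurntArea <- function(drivers, baValues) {
  f <- drivers@fields[["burnt_area"]]
  f@values[f@mask] <- baValues
  drivers@fields[["burnt_area"]] <- f
  drivers
}

#' Tree-cover loss from a uniform burnt-area increase
#'
#' Recomputes cover with burnt area increased by `delta` everywhere
#' (clipped to [0, 1]) and returns the per-cell, per-member loss
#' `TC(ba) - TC(ba + delta)`, paired by member with the standard run.
#'
#' @inheritParams impactDistribution
#' @param delta burnt-area increment (default 0.01, i.e. +1%).
#' @return an [ImpactDistribution-class] of cover losses (>= 0).
#' @export
fireIncrementExperiment <- function(drivers, ensemble,
                                    spec = defaultControlSpec(),
                                    delta = 0.01) {
  prep <- .prepareDrivers(drivers, spec)
  ba <- drivers@fields[["burnt_area"]]
  prepUp <- .prepareDrivers(
    .withBurntArea(drivers, pmin(ba@values[ba@mask] + delta, 1)), spec)
  M <- nMembers(ensemble)
  out <- matrix(NA_real_, nrow(prep$X), M)
  for (m in seq_len(M)) {
    pm <- memberParams(ensemble, m, spec)
    out[, m] <- .treeCoverVec(prep, pm, spec) -
                .treeCoverVec(prepUp, pm, spec)
  }
  .impactDist(out, "absolute", prep)
}

# core of the fire-without-humans comparison for one parameter set:
# cover with human pressure removed, with and without burnt area
.fireNoHumansVecs <- function(prep, pm, spec) {
  noLU <- .treeCoverWithoutVec(prep, pm, spec, "LU")
  noLUnoBA <- .treeCoverVec(prep, pm, spec, dropControls = "LU",
                            zeroFactors = "burnt_area")
  list(noLU = noLU, noLUnoBA = noLUnoBA)
}

#' Fire impact without direct human influence on tree cover
#'
#' Compares cover with human pressure removed against cover with human
#' pressure and burnt area removed:
#' relative `(TC_*(ba, LU) - TC_*(LU)) / TC_*(ba, LU)` and the absolute
#' analogue, per cell and member.
#'
#' @inheritParams impactDistribution
#' @return list of two [ImpactDistribution-class]s, `relative` and
#'   `absolute`.
#' @export
fireWithoutHumans <- function(drivers, ensemble,
                              spec = defaultControlSpec()) {
  prep <- .prepareDrivers(drivers, spec)
  M <- nMembers(ensemble)
  rel <- abs_ <- matrix(NA_real_, nrow(prep$X), M)
  for (m in seq_len(M)) {
    pm <- memberParams(ensemble, m, spec)
    v <- .fireNoHumansVecs(prep, pm, spec)
    abs_[, m] <- v$noLUnoBA - v$noLU
    rel[, m] <- ifelse(v$noLUnoBA > 0, (v$noLUnoBA - v$noLU) / v$noLUnoBA,
                       NA_real_)
  }
  list(relative = .impactDist(rel, "relative", prep),
       absolute = .impactDist(abs_, "absolute", prep))
}

#' Fire impact without human influence on tree cover or burnt area
#'
#' As [fireWithoutHumans()], but with the observed burnt area replaced,
#' member by member, by a randomly sampled field from a counterfactual
#' burnt-area ensemble (burnt area reconstructed without human
#' suppression).
#'
#' @inheritParams fireWithoutHumans
#' @param baCounterfactual list of [GriddedField-class] burnt-area fields
#'   on the driver grid.
#' @param seed RNG seed for the member-to-field pairing.
#' @return list of two [ImpactDistribution-class]s, `relative` and
#'   `absolute`.
#' @export
fireWithoutHumansAndBA <- function(drivers, ensemble,
                                   spec = defaultControlSpec(),
                                   baCounterfactual, seed = 1) {
  if (!length(baCounterfactual)) .stopf("empty counterfactual ensemble")
  ref <- drivers@fields[["burnt_area"]]
  for (f in baCounterfactual) {
    if (!isTRUE(all.equal(f@lat, ref@lat)) ||
        !isTRUE(all.equal(f@lon, ref@lon))) {
      .stopf("counterfactual burnt area not on the driver grid")
    }
  }
  M <- nMembers(ensemble)
  pick <- .withSeed(seed, sample.int(length(baCounterfactual), M,
                                     replace = TRUE))
  rel <- abs_ <- NULL
  for (m in seq_len(M)) {
    cf <- baCounterfactual[[pick[m]]]
    prep <- .prepareDrivers(.withBurntArea(drivers,
                                           cf@values[ref@mask]), spec)
    if (is.null(rel)) {
      rel <- abs_ <- matrix(NA_real_, nrow(prep$X), M)
      prep0 <- prep
    }
    pm <- memberParams(ensemble, m, spec)
    v <- .fireNoHumansVecs(prep, pm, spec)
    abs_[, m] <- v$noLUnoBA - v$noLU
    rel[, m] <- ifelse(v$noLUnoBA > 0, (v$noLUnoBA - v$noLU) / v$noLUnoBA,
                       NA_real_)
  }
  list(relative = .impactDist(rel, "relative", prep0),
       absolute = .impactDist(abs_, "absolute", prep0))
}

#' Per-unit response curve of relative impact versus factor level
#'
#' Groups cells into bins of the (area-fraction valued) factor and, per
#' posterior member and bin, evaluates the area-weighted mean of
#' `(TC_*(i) - TC) / (A_bin * TC_*(i))` with `A_bin` the bin's factor
#' level: a value of 1 means the factor excludes tree cover over exactly
#' its own area.
#'
#' @inheritParams impactDistribution
#' @param factor factor name (must be area-fraction valued, e.g.
#'   `"burnt_area"`, `"cropland"`).
#' @param binWidth bin width in fraction units (default 0.01).
#' @param levels member quantiles to report (default 10-90%).
#' @return data.frame with columns `bin` (midpoint level), `n` (cells),
#'   `median`, and one column per requested quantile.
#' @export
responseCurve <- function(drivers, ensemble, spec = defaultControlSpec(),
                          factor, binWidth = 0.01,
                          levels = c(0.1, 0.9)) {
  prep <- .prepareDrivers(drivers, spec)
  dn <- .FACTOR_DRIVER[factor]
  if (is.na(dn) || !dn %in% .FRACTION_DRIVERS) {
    .stopf("'%s' is not an area-fraction factor", factor)
  }
  x <- drivers@fields[[dn]]@values[prep$cellIndex]
  bin <- pmin(floor(x / binWidth), floor(1 / binWidth) - 1L)
  ub <- sort(unique(bin))
  mids <- (ub + 0.5) * binWidth
  w <- cellAreaWeights(prep$template)@values[prep$cellIndex]
  M <- nMembers(ensemble)
  res <- matrix(NA_real_, length(mids), M)
  occ <- integer(length(mids))
  for (m in seq_len(M)) {
    pm <- memberParams(ensemble, m, spec)
    tc <- .treeCoverVec(prep, pm, spec)
    tcs <- .treeCoverWithoutVec(prep, pm, spec, factor)
    pe <- ifelse(tcs > 0, (tcs - tc) / tcs, NA_real_)
    for (b in seq_along(mids)) {
      sel <- bin == ub[b]
      occ[b] <- sum(sel)
      res[b, m] <- sum(w[sel] * pe[sel], na.rm = TRUE) /
                   sum(w[sel]) / mids[b]
    }
  }
  out <- data.frame(bin = mids, n = occ,
                    median = apply(res, 1, stats::median))
  for (lv in levels) {
    out[[sprintf("q%02d", round(lv * 100))]] <-
      apply(res, 1, stats::quantile, probs = lv, names = FALSE)
  }
  out
}

#' Quantile bounds of an impact distribution
#'
#' Empirical per-cell quantiles across members using linear interpolation
#' of order statistics. Supports the asymmetric 65/35% convention used for
#' dominant-control maps by passing those levels.
#'
#' @param dist an [ImpactDistribution-class].
#' @param levels probabilities (default `c(0.10, 0.90)`).
#' @return numeric matrix, cells by levels (columns `q10`, `q90`, ...).
#' @export
quantileSummary <- function(dist, levels = c(0.1, 0.9)) {
  if (ncol(dist@values) < 2) .stopf("need at least 2 members")
  out <- matrix(NA_real_, nrow(dist@values), length(levels),
                dimnames = list(NULL,
                                sprintf("q%02d", round(levels * 100))))
  for (i in seq_along(levels)) {
    out[, i] <- apply(dist@values, 1, stats::quantile,
                      probs = levels[i], names = FALSE, na.rm = TRUE)
  }
  out
}

#' Put one quantile of an impact distribution back on the map
#' @param dist an [ImpactDistribution-class].
#' @param level quantile probability.
#' @return a [GriddedField-class].
#' @export
impactQuantileField <- function(dist, level = 0.9) {
  q <- apply(dist@values, 1, stats::quantile, probs = level, names = FALSE,
             na.rm = TRUE)
  prep <- list(template = dist@template, cellIndex = dist@cellIndex)
  .vecToField(q, prep, sprintf("%s_q%02d", dist@kind, round(level * 100)))
}
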