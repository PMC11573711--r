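# Area-weighted biome summaries. Impacts are aggregated per posterior
# member within each biome group (grid-cell area weighted, optionally
# weighted additionally by a deciduous-vegetation fraction), and the
# member-level aggregates are then quantiled: the reported bounds reflect
# framework (parameter) uncertainty, not cell-to-cell spread.

.BIOME_GROUPS <- c("wet forest", "dry forest", "savanna/grassland",
                   "mediterranean", "summergreen forest/woodland",
                   "desert", "other")

#' Default biome grouping table
#'
#' Integer codes 1-7 mapped to the aggregated groups: wet forest, dry
#' forest, savanna/grassland, mediterranean, summergreen forest/woodland,
#' desert, other. Editable: pass a modified table to [biomeMap()].
#'
#' @return data.frame with columns `code` and `group`.
#' @export
defaultBiomeGroups <- function() {
  data.frame(code = seq_along(.BIOME_GROUPS), group = .BIOME_GROUPS,
             stringsAsFactors = FALSE)
}

#' Construct a BiomeMap
#' @param codes [GriddedField-class] of integer biome codes.
#' @param groups grouping table (default [defaultBiomeGroups()]).
#' @return a [BiomeMap-class].
#' @export
biomeMap <- function(codes, groups = defaultBiomeGroups()) {
  new("BiomeMap", codes = codes, groups = groups)
}

# group label per unmasked cell (NA for unmapped codes)
.cellGroups <- function(biomes, cellIndex) {
  code <- biomes@codes@values[cellIndex]
  biomes@groups$group[match(code, biomes@groups$code)]
}

#' Per-member biome aggregates of a target's impact
#'
#' For each posterior member and biome group: the area-weighted sum of the
#' absolute impact (in cell-area units) and the area-weighted relative
#' impact in percent (impact area relative to the cover unconstrained by
#' the target). Optionally weights cells additionally by a deciduous
#' fraction field.
#'
#' @param drivers a [DriverSet-class].
#' @param ensemble a [PosteriorEnsemble-class].
#' @param spec a [ControlSpec-class].
#' @param target control or factor name.
#' @param biomes a [BiomeMap-class].
#' @param deciduous optional [GriddedField-class] of deciduous fraction.
#' @return list of two matrices (`area`, `relative`), biome group by
#'   member; unmapped codes are dropped with a warning.
#' @export
memberBiomeAggregates <- function(drivers, ensemble,
                                  spec = defaultControlSpec(), target,
                                  biomes, deciduous = NULL) {
  prep <- .prepareDrivers(drivers, spec)
  grp <- .cellGroups(biomes, prep$cellIndex)
  if (anyNA(grp)) {
    warning(sprintf("%d cells with unmapped biome codes excluded",
                    sum(is.na(grp))))
  }
  w <- cellAreaWeights(prep$template)@values[prep$cellIndex]
  if (!is.null(deciduous)) w <- w * deciduous@values[prep$cellIndex]
  groups <- unique(stats::na.omit(grp))
  M <- nMembers(ensemble)
  area <- rel <- den <- matrix(NA_real_, length(groups), M,
                               dimnames = list(groups, NULL))
  for (m in seq_len(M)) {
    pm <- memberParams(ensemble, m, spec)
    tc <- .treeCoverVec(prep, pm, spec)
    tcs <- .treeCoverWithoutVec(prep, pm, spec, target)
    dv <- abs(tcs - tc)
    for (g in groups) {
      sel <- !is.na(grp) & grp == g
      area[g, m] <- sum(w[sel] * dv[sel])
      den[g, m] <- sum(w[sel] * tcs[sel])
      rel[g, m] <- 100 * sum(w[sel] * (tcs[sel] - tc[sel])) / den[g, m]
    }
  }
  list(area = area, relative = rel, unconstrained = den)
}

#' Biome-by-target impact table with percentile bounds
#'
#' One row per biome group and target: area impact (cell-area units) and
#' relative impact (%), each with the requested member quantiles
#' (default 10% and 90%). Aggregation is per member first, quantiles
#' second, so bounds express framework uncertainty.
#'
#' @inheritParams memberBiomeAggregates
#' @param targets character vector of controls/factors to tabulate.
#' @param levels quantile probabilities (default `c(0.1, 0.9)`).
#' @param includeTotal also report an `"(all)"` row over every mapped cell.
#' @return data.frame with columns `biome`, `target`, `area_qXX...`,
#'   `rel_qXX...`.
#' @export
aggregateByBiome <- function(drivers, ensemble,
                             spec = defaultControlSpec(), targets,
                             biomes, deciduous = NULL,
                             levels = c(0.1, 0.9), includeTotal = TRUE) {
  rows <- list()
  for (tg in targets) {
    agg <- memberBiomeAggregates(drivers, ensemble, spec, tg, biomes,
                                 deciduous)
    if (includeTotal) {
      totRel <- 100 * colSums(agg$area) / colSums(agg$unconstrained)
      agg$area <- rbind(agg$area, "(all)" = colSums(agg$area))
      agg$relative <- rbind(agg$relative, "(all)" = totRel)
    }
    for (g in rownames(agg$area)) {
      row <- data.frame(biome = g, target = tg, stringsAsFactors = FALSE)
      for (lv in levels) {
        row[[sprintf("area_q%02d", round(lv * 100))]] <-
          stats::quantile(agg$area[g, ], lv, names = FALSE)
        row[[sprintf("rel_q%02d", round(lv * 100))]] <-
          stats::quantile(agg$relative[g, ], lv, names = FALSE)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tree-cover frequency histogram in 1% bins
#'
#' Counts of cells per cover bin; with a biome map, counts are stacked by
#' group. For an ensemble (cells-by-members matrix or
#' [ImpactDistribution-class]) the per-member histograms are summarized by
#' their median and 10-90% envelope.
#'
#' @param tc a [GriddedField-class] of cover in [0, 1], a cells-by-members
#'   matrix, or an [ImpactDistribution-class].
#' @param binWidth bin width (default 0.01).
#' @param by optional [BiomeMap-class] (single-field input only).
#' @return data.frame with `bin` (midpoint) and `count` (plus `group`
#'   when stacked, or `q10`/`median`/`q90` for ensembles).
#' @export
treeCoverHistogram <- function(tc, binWidth = 0.01, by = NULL) {
  nb <- round(1 / binWidth)
  mids <- (seq_len(nb) - 0.5) * binWidth
  binOf <- function(v) pmin(floor(v / binWidth), nb - 1L) + 1L
  if (is(tc, "ImpactDistribution")) {
    vals <- tc@values
  } else if (is.matrix(tc) && !is(tc, "GriddedField")) {
    vals <- tc
  } else {
    v <- tc@values[tc@mask]
    if (any(v < 0 | v > 1, na.rm = TRUE)) .stopf("cover outside [0,1]")
    if (is.null(by)) {
      return(data.frame(bin = mids, count = tabulate(binOf(v), nb)))
    }
    grp <- .cellGroups(by, which(tc@mask))
    groups <- unique(stats::na.omit(grp))
    out <- do.call(rbind, lapply(groups, function(g) {
      data.frame(bin = mids, group = g,
                 count = tabulate(binOf(v[!is.na(grp) & grp == g]), nb))
    }))
    return(out)
  }
  counts <- apply(vals, 2, function(v) tabulate(binOf(v[!is.na(v)]), nb))
  data.frame(bin = mids,
             q10 = apply(counts, 1, stats::quantile, 0.1, names = FALSE),
             median = apply(counts, 1, stats::median),
             q90 = apply(counts, 1, stats::quantile, 0.9, names = FALSE))
}
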