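# Rainfall seasonality metrics. Four proxies for the seasonal
# distribution of rainfall, all mapped to [0, 1]:
#   MADD  - fractional mean annual dry days (daily series)
#   MDDM  - dry-day fraction of the driest month (daily series)
#   MADM  - driest-month precipitation normalized by the monthly mean
#           (monthly climatology); note 1 = perfectly uniform, so the
#           suppressive seasonality driver is typically 1 - MADM
#   MConc - seasonal concentration: length of the vector sum of monthly
#           rainfall placed around the annual cycle, over total rainfall
# Month direction angles sit at month mid-points, 2*pi*(m - 0.5)/12; any
# fixed convention leaves MConc invariant to cyclic rotation.

.seasonField <- function(name, vals, x)
  griddedField(name, vals, lat = x@lat, lon = x@lon, units = "1",
               mask = x@mask & !is.na(vals))

#' Fractional mean annual dry days (MADD)
#'
#' Fraction of days with precipitation below the wet-day threshold
#' (default 0.1 mm/day).
#'
#' @param series a [DailySeries-class].
#' @return a [GriddedField-class] in [0, 1].
#' @export
madd <- function(series) {
  dry <- series@pr < series@wetDayThreshold
  vals <- apply(dry, c(1, 2), mean)
  .seasonField("madd", vals, series)
}

#' Dry-day fraction of the driest month (MDDM)
#'
#' The dry-day fraction of the month with the largest dry-day fraction,
#' i.e. the month with the fewest wet days. Setting `driest = FALSE`
#' selects the month with the smallest dry-day fraction instead (kept for
#' comparison; not a dryness metric).
#'
#' @param series a [DailySeries-class].
#' @param driest use the driest month (default `TRUE`).
#' @return a [GriddedField-class] in [0, 1].
#' @export
mddm <- function(series, driest = TRUE) {
  dry <- series@pr < series@wetDayThreshold
  months <- sort(unique(series@monthIndex))
  fracs <- vapply(months, function(m) {
    sel <- series@monthIndex == m
    apply(dry[, , sel, drop = FALSE], c(1, 2), mean)
  }, matrix(0, dim(dry)[1], dim(dry)[2]))
  pick <- if (driest) function(x) max(x) else function(x) min(x)
  vals <- apply(fracs, c(1, 2), pick)
  .seasonField("mddm", vals, series)
}

#' Normalized driest-month precipitation (MADM)
#'
#' Minimum monthly precipitation times 12 over mean annual precipitation;
#' 1 for perfectly uniform months, 0 when any month is completely dry.
#' Cells with zero annual precipitation return 0 by convention (such cells
#' are already driven to zero cover by the precipitation control).
#'
#' @param clim a [MonthlyClimatology-class].
#' @return a [GriddedField-class] in [0, 1].
#' @export
madm <- function(clim) {
  mapv <- apply(clim@pr, c(1, 2), sum)
  minv <- apply(clim@pr, c(1, 2), min)
  vals <- ifelse(mapv > 0, minv * 12 / mapv, 0)
  .seasonField("madm", vals, clim)
}

#' Seasonal precipitation concentration (MConc)
#'
#' Each month's rainfall is placed as a vector at the month's direction
#' around the annual cycle; the metric is the length of the vector sum
#' divided by total rainfall. 0 for uniform rainfall, 1 when all rain
#' falls in a single month. Zero-rainfall cells return 0 by convention.
#'
#' @param clim a [MonthlyClimatology-class].
#' @return a [GriddedField-class] in [0, 1].
#' @export
mconc <- function(clim) {
  theta <- 2 * pi * (seq_len(12) - 0.5) / 12
  cw <- cos(theta); sw <- sin(theta)
  lx <- 0; ly <- 0; tot <- 0
  for (m in seq_len(12)) {
    lx <- lx + clim@pr[, , m] * cw[m]
    ly <- ly + clim@pr[, , m] * sw[m]
    tot <- tot + clim@pr[, , m]
  }
  vals <- ifelse(tot > 0, sqrt(lx^2 + ly^2) / tot, 0)
  vals <- pmin(vals, 1)
  .seasonField("mconc", vals, clim)
}

#' Collapse a daily series to a monthly climatology
#' @param series a [DailySeries-class].
#' @return a [MonthlyClimatology-class] of monthly totals (mm/month).
#' @export
toMonthlyClimatology <- function(series) {
  pr <- vapply(seq_len(12), function(m) {
    sel <- series@monthIndex == m
    apply(series@pr[, , sel, drop = FALSE], c(1, 2), sum)
  }, matrix(0, dim(series@pr)[1], dim(series@pr)[2]))
  monthlyClimatology(pr, lat = series@lat, lon = series@lon,
                     mask = series@mask)
}
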