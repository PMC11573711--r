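# Gridded NetCDF I/O, tropics clipping, bilinear regridding and
# cell-area weighting. All fields live on regular lat-lon grids of cell
# centres; the analysis grid is 0.5 degree with centres at -29.75..29.75
# latitude within the tropical band.

.LAT_NAMES <- c("lat", "latitude", "y")
.LON_NAMES <- c("lon", "longitude", "x")

#' Read one gridded variable from a NetCDF file
#'
#' Reads a 2-D variable (or a 3-D variable with a time axis, which is
#' averaged over time) on a regular lat-lon grid. The mask is taken from
#' the file's missing-value convention (`_FillValue` / `NaN`).
#'
#' @param path NetCDF file path.
#' @param varname variable name in the file.
#' @return a [GriddedField-class].
#' @seealso [writeGridNetCDF()]
#' @export
readGridNetCDF <- function(path, varname) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!varname %in% names(nc$var)) {
    .stopf("variable '%s' not found in %s", varname, path)
  }
  v <- nc$var[[varname]]
  dimnames_ <- vapply(v$dim, function(d) d$name, "")
  ilat <- which(tolower(dimnames_) %in% .LAT_NAMES)
  ilon <- which(tolower(dimnames_) %in% .LON_NAMES)
  if (length(ilat) != 1 || length(ilon) != 1) {
    .stopf("variable '%s' lacks recognizable lat/lon dimensions", varname)
  }
  lat <- v$dim[[ilat]]$vals
  lon <- v$dim[[ilon]]$vals
  for (cc in list(lat, lon)) {
    if (length(cc) > 1) {
      d <- diff(cc)
      if (any(d <= 0) || max(d) - min(d) > 1e-5) {
        .stopf("grid of '%s' is not regular", varname)
      }
    }
  }
  arr <- ncdf4::ncvar_get(nc, varname, collapse_degen = FALSE)
  nd <- length(dim(arr))
  if (nd == 3) {
    itime <- setdiff(seq_len(3), c(ilat, ilon))
    arr <- apply(arr, c(ilat, ilon), mean)
    # apply() orders result dims as requested: (lat, lon)
    vals <- arr
  } else if (nd == 2) {
    vals <- if (ilat < ilon) arr else t(arr)
  } else {
    .stopf("variable '%s' must be 2-D or 3-D", varname)
  }
  units <- if (nzchar(v$units)) v$units else "1"
  griddedField(varname, vals, lat = lat, lon = lon, units = units)
}

#' Write a GriddedField to NetCDF
#'
#' Writes a CF-style file with `lat`/`lon` coordinate variables, the units
#' attribute and a `NaN` `_FillValue` for masked cells. Optional global
#' attributes (e.g. seed, config hash) are attached for provenance.
#'
#' @param field a [GriddedField-class].
#' @param path output file path.
#' @param attributes optional named list of global attributes.
#' @return `path`, invisibly.
#' @export
writeGridNetCDF <- function(field, path, attributes = list()) {
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", field@lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", field@lat)
  var <- ncdf4::ncvar_def(field@name, field@units, list(dlon, dlat),
                          missval = NaN, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  vals <- field@values
  vals[!field@mask] <- NaN
  ncdf4::ncvar_put(nc, var, t(vals))
  for (nm in names(attributes)) {
    ncdf4::ncatt_put(nc, 0, nm, as.character(attributes[[nm]]))
  }
  invisible(path)
}

#' Restrict a field to the tropical band
#'
#' Keeps the latitude rows whose cell centres fall inside the band
#' (default 30 degrees North to 30 degrees South).
#'
#' @param field a [GriddedField-class].
#' @param latBounds inclusive latitude bounds in degrees.
#' @return the clipped [GriddedField-class].
#' @export
clipToTropics <- function(field, latBounds = c(-30, 30)) {
  keep <- field@lat >= latBounds[1] & field@lat <= latBounds[2]
  if (!any(keep)) .stopf("no grid cells inside [%g, %g] latitude",
                         latBounds[1], latBounds[2])
  griddedField(field@name, field@values[keep, , drop = FALSE],
               lat = field@lat[keep], lon = field@lon,
               units = field@units,
               mask = field@mask[keep, , drop = FALSE])
}

# fractional position of targets within source centres; outside = NA
.interpIndex <- function(target, source) {
  ns <- length(source)
  j <- findInterval(target, source)
  j0 <- pmin(pmax(j, 1L), ns - 1L)
  frac <- (target - source[j0]) / (source[j0 + 1L] - source[j0])
  frac <- pmin(pmax(frac, 0), 1)
  outside <- target < source[1] - 1e-9 | target > source[ns] + 1e-9
  list(j0 = j0, frac = frac, outside = outside)
}

#' Bilinear regridding between regular lat-lon grids
#'
#' Interpolates bilinearly between source cell centres. Masked source
#' neighbours are dropped and the remaining weights renormalized; a target
#' cell is masked only when all four neighbours are masked or when it lies
#' outside the source grid.
#'
#' @param field a [GriddedField-class].
#' @param lat,lon target cell-centre coordinates (strictly increasing).
#' @return the regridded [GriddedField-class].
#' @export
regridBilinear <- function(field, lat, lon) {
  if (length(field@lat) < 2 || length(field@lon) < 2) {
    .stopf("source grid must be at least 2 x 2")
  }
  ia <- .interpIndex(lat, field@lat)
  ib <- .interpIndex(lon, field@lon)
  if (all(ia$outside) || all(ib$outside)) {
    .stopf("target grid does not overlap the source grid")
  }
  V <- field@values
  M <- field@mask * 1
  V[!field@mask] <- 0
  num <- 0; den <- 0
  for (da in 0:1) {
    wa <- if (da == 0) 1 - ia$frac else ia$frac
    ra <- ia$j0 + da
    for (db in 0:1) {
      wb <- if (db == 0) 1 - ib$frac else ib$frac
      cb <- ib$j0 + db
      w <- outer(wa, wb)
      num <- num + w * V[ra, cb, drop = FALSE] * M[ra, cb, drop = FALSE]
      den <- den + w * M[ra, cb, drop = FALSE]
    }
  }
  out <- num / den
  out[den <= 1e-12] <- NA_real_
  out[ia$outside, ] <- NA_real_
  out[, ib$outside] <- NA_real_
  griddedField(field@name, out, lat = lat, lon = lon, units = field@units)
}

#' Cell-area weights for a regular lat-lon grid
#'
#' Cell area on a regular lat-lon grid is proportional to the cosine of
#' the centre latitude; weights are normalized so an equatorial cell has
#' weight 1. The normalization cancels in any weighted mean.
#'
#' @param lat,lon cell-centre coordinates, or a [GriddedField-class] passed
#'   as `lat` to take its grid (and mask).
#' @return a [GriddedField-class] of weights.
#' @export
cellAreaWeights <- function(lat, lon = NULL) {
  mask <- NULL
  if (is(lat, "GriddedField")) {
    mask <- lat@mask
    lon <- lat@lon
    lat <- lat@lat
  }
  w <- matrix(cos(lat * pi / 180), nrow = length(lat), ncol = length(lon))
  if (!is.null(mask)) w[!mask] <- NA_real_
  griddedField("cell_area_weight", w, lat = lat, lon = lon, units = "1",
               mask = if (is.null(mask)) NULL else mask)
}

#' Area-weighted mean of a field
#' @param field a [GriddedField-class].
#' @return scalar area-weighted mean over unmasked cells.
#' @export
areaWeightedMean <- function(field) {
  w <- cellAreaWeights(field)@values
  ok <- field@mask & !is.na(field@values)
  sum(w[ok] * field@values[ok]) / sum(w[ok])
}

#' The default 0.5-degree tropical analysis grid
#' @param latBounds latitude band (default 30N-30S).
#' @param lonBounds longitude extent (default global).
#' @return list with `lat` and `lon` cell centres at 0.5-degree spacing.
#' @export
tropicsGrid <- function(latBounds = c(-30, 30), lonBounds = c(-180, 180)) {
  list(lat = seq(latBounds[1] + 0.25, latBounds[2] - 0.25, by = 0.5),
       lon = seq(lonBounds[1] + 0.25, lonBounds[2] - 0.25, by = 0.5))
}
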