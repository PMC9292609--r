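#' Read an ESRI ASCII grid raster
#'
#' Plain-text single-band raster format (\code{ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value} header followed by north-to-south rows of values),
#' as distributed for monthly climate surfaces. Values can be rescaled on read
#' (e.g. \code{scale = 0.1} for datasets stored as integer tenths of a degree).
#'
#' @param path File path.
#' @param scale Multiplicative scale factor applied to non-nodata values.
#' @return A \code{grid_raster}: list with \code{values} (matrix, row 1 =
#'   northernmost), \code{xmin,xmax,ymin,ymax,cellsize,nodata}.
#' @export
read_ascii_grid <- function(path, scale = 1) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    tgp_abort(sprintf("%s: ASCII grid header incomplete", basename(path)),
              "tgp_raster_error")
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    tgp_abort(sprintf("%s: expected %d values, found %d", basename(path),
                      hdr$ncols * hdr$nrows, length(vals)), "tgp_raster_error")
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  is_nd <- m == nodata
  m <- m * scale
  m[is_nd] <- NA_real_
  grid_raster(m,
              xmin = hdr$xllcorner,
              ymin = hdr$yllcorner,
              cellsize = hdr$cellsize)
}

#' Construct an in-memory grid raster
#'
#' @param values Matrix of cell values; row 1 is the northernmost row.
#' @param xmin,ymin Coordinates of the lower-left corner.
#' @param cellsize Cell edge length in coordinate units.
#' @return A \code{grid_raster} object.
#' @export
grid_raster <- function(values, xmin, ymin, cellsize) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         xmax = xmin + ncol(values) * cellsize,
         ymax = ymin + nrow(values) * cellsize,
         cellsize = cellsize),
    class = "grid_raster"
  )
}

#' Extract the nearest-cell value of a raster at a coordinate
#'
#' @param raster A \code{\link{grid_raster}}.
#' @param lat,lon Decimal degrees (lat in [-90, 90], lon in [-180, 180]).
#' @return The value of the cell containing the point.
#' @export
extract_value <- function(raster, lat, lon) {
  stopifnot(inherits(raster, "grid_raster"))
  if (!is_scalar_number(lat) || !is_scalar_number(lon) ||
      lat < -90 || lat > 90 || lon < -180 || lon > 180) {
    tgp_abort("lat must be in [-90, 90] and lon in [-180, 180] decimal degrees",
              "tgp_extent_error")
  }
  if (lon < raster$xmin || lon > raster$xmax ||
      lat < raster$ymin || lat > raster$ymax) {
    tgp_abort(sprintf("point (%g, %g) outside raster extent [%g, %g] x [%g, %g]",
                      lat, lon, raster$ymin, raster$ymax, raster$xmin,
                      raster$xmax), "tgp_extent_error")
  }
  col <- min(ncol(raster$values),
             max(1L, 1L + floor((lon - raster$xmin) / raster$cellsize)))
  row <- min(nrow(raster$values),
             max(1L, 1L + floor((raster$ymax - lat) / raster$cellsize)))
  v <- raster$values[row, col]
  if (is.na(v)) {
    tgp_abort(sprintf(
      "nodata at point (%g, %g); try the nearest valid cell (e.g. shift by one cellsize = %g)",
      lat, lon, raster$cellsize), "tgp_nodata_error")
  }
  v
}

#' Extract a 12-month climate series from monthly raster files
#'
#' @param tmax_paths,tmin_paths Character vectors of 12 ASCII-grid file paths
#'   (January to December) for monthly tmax and tmin.
#' @param lat,lon Query coordinate, decimal degrees.
#' @param scenario Scenario label for the resulting series.
#' @param model Source model id.
#' @param scale Scale factor passed to \code{\link{read_ascii_grid}}.
#' @return A \code{\link{climate_series}}.
#' @export
extract_point <- function(tmax_paths, tmin_paths, lat, lon,
                          scenario = "current", model = "unknown", scale = 1) {
  if (length(tmax_paths) != 12L || length(tmin_paths) != 12L) {
    tgp_abort("need exactly 12 monthly rasters per variable", "tgp_raster_error")
  }
  tmax <- vapply(tmax_paths, function(p)
    extract_value(read_ascii_grid(p, scale = scale), lat, lon), numeric(1))
  tmin <- vapply(tmin_paths, function(p)
    extract_value(read_ascii_grid(p, scale = scale), lat, lon), numeric(1))
  climate_series(data.frame(month = 1:12, tmax = unname(tmax),
                            tmin = unname(tmin)),
                 scenario = scenario, model = model)
}
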