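#' Construct a Tmax raster grid
#'
#' A `tmax_raster` is a regular geographic (WGS84 lat/lon) grid of maximum
#' summer temperatures stored in the WorldClim v1.4 dialect: integer tenths of
#' a degree Celsius, with `NA` marking nodata cells. Rows run north to south
#' from the grid's north-west corner; columns run west to east.
#'
#' Conversion from stored tenths to degrees Celsius happens exactly once, in
#' [value_at()]; everything downstream of extraction works in plain Celsius.
#'
#' @param values numeric matrix of cell values in tenths of a degree C
#'   (`NA` = nodata); `nrow(values)` rows north to south.
#' @param lat_nw,lon_nw latitude/longitude of the grid's north-west *corner*
#'   (not cell center), decimal degrees WGS84.
#' @param cell_size cell edge length in decimal degrees (> 0).
#' @return an object of class `tmax_raster`.
#' @seealso [read_ascii_grid()], [value_at()], [in_range_mask()],
#'   [distance_to_range()]
#' @export
tmax_raster <- function(values, lat_nw, lon_nw, cell_size) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("'cell_size' must be a single positive number", call. = FALSE)
  if (lat_nw > 90 || lat_nw - nrow(values) * cell_size < -90)
    stop("grid latitude extent outside [-90, 90]", call. = FALSE)
  structure(
    list(values = values, lat_nw = lat_nw, lon_nw = lon_nw,
         cell_size = cell_size),
    class = "tmax_raster")
}

#' @export
print.tmax_raster <- function(x, ...) {
  cat(sprintf("<tmax_raster> %d x %d cells, %.6g deg resolution\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  NW corner: (%.4f, %.4f); %d nodata cells\n",
              x$lat_nw, x$lon_nw, sum(is.na(x$values))))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  stored values (tenths of degC): %g .. %g\n", rng[1], rng[2]))
  invisible(x)
}

# cell-center coordinates for 1-based row/col indices
cell_center_lat <- function(grid, row) grid$lat_nw - (row - 0.5) * grid$cell_size
cell_center_lon <- function(grid, col) grid$lon_nw + (col - 0.5) * grid$cell_size

#' Locate the raster cell containing a point
#'
#' Implements the half-open membership convention: a point on a cell boundary
#' belongs to the cell south (for a latitude boundary) or east (for a
#' longitude boundary) of the line, so every interior point belongs to exactly
#' one cell. Points on the grid's outer southern/eastern edge fall outside.
#'
#' @param grid a [tmax_raster()].
#' @param lat,lon point coordinates, decimal degrees WGS84.
#' @return list with integer `row`, `col` (1-based).
#' @export
cell_index <- function(grid, lat, lon) {
  row <- floor((grid$lat_nw - lat) / grid$cell_size) + 1L
  col <- floor((lon - grid$lon_nw) / grid$cell_size) + 1L
  if (row < 1L || row > nrow(grid$values) || col < 1L || col > ncol(grid$values))
    stop(sprintf("point (%.4f, %.4f) is outside the raster extent", lat, lon),
         call. = FALSE)
  list(row = as.integer(row), col = as.integer(col))
}

#' Extract Tmax at a point from a single pixel
#'
#' Returns the value of the unique cell containing the point, converted from
#' stored tenths of a degree to degrees Celsius. No interpolation is done:
#' the analysis deliberately uses single-pixel extraction at the raster's
#' native resolution.
#'
#' @inheritParams cell_index
#' @return Tmax in degrees C, or `NA_real_` if the cell is nodata.
#' @export
value_at <- function(grid, lat, lon) {
  idx <- cell_index(grid, lat, lon)
  v <- grid$values[idx$row, idx$col]
  if (is.na(v)) NA_real_ else v / 10
}

#' Boolean mask of cells inside a temperature interval
#'
#' @param grid a [tmax_raster()].
#' @param interval numeric length-2 `c(T_lo, T_hi)` in degrees C, closed.
#' @return logical matrix, `TRUE` where `T_lo <= value <= T_hi`; `FALSE` for
#'   nodata cells.
#' @export
in_range_mask <- function(grid, interval) {
  stopifnot(is.numeric(interval), length(interval) == 2L)
  if (interval[1] > interval[2])
    stop("'interval' must satisfy T_lo <= T_hi", call. = FALSE)
  v <- grid$values / 10
  m <- !is.na(v) & v >= interval[1] & v <= interval[2]
  m
}

# IUGG mean Earth radius, km; pinned so distances are bit-reproducible
.EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between points
#'
#' Haversine distance on a sphere with the IUGG mean radius 6371.0088 km,
#' computed via [geosphere::distHaversine()]. Vectorised over the second
#' point.
#'
#' @param lat1,lon1 first point (scalars), decimal degrees.
#' @param lat2,lon2 second point(s), decimal degrees.
#' @return distance(s) in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(c(lon1, lat1), cbind(lon2, lat2),
                           r = .EARTH_RADIUS_KM)
}

#' Distance from a point to the nearest in-range raster cell
#'
#' Zero when the point's own cell lies inside the interval; otherwise the
#' minimum great-circle distance from the point to the *center* of any
#' in-range cell. Distances to cell centers (not edges) match the native
#' resolution of the data and keep the convention explicit.
#'
#' @inheritParams cell_index
#' @param interval numeric `c(T_lo, T_hi)` degrees C.
#' @param mask optional precomputed [in_range_mask()] for `grid` and
#'   `interval`, to amortise repeated queries.
#' @return distance in kilometres (0 if in range).
#' @export
distance_to_range <- function(grid, interval, lat, lon, mask = NULL) {
  if (is.null(mask)) mask <- in_range_mask(grid, interval)
  if (!any(mask))
    stop("no raster cell lies inside the interval", call. = FALSE)
  idx <- cell_index(grid, lat, lon)
  if (mask[idx$row, idx$col]) return(0)
  w <- which(mask, arr.ind = TRUE)
  d <- haversine_km(lat, lon,
                    cell_center_lat(grid, w[, "row"]),
                    cell_center_lon(grid, w[, "col"]))
  min(d)
}

#' Read an ESRI ASCII grid as a Tmax raster
#'
#' Reads the plain-text ASCII grid dialect (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by rows of values,
#' north to south). Values are taken as stored tenths of a degree C, the
#' WorldClim v1.4 convention; nodata cells become `NA`.
#'
#' @param path file path.
#' @return a [tmax_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L) stop("not an ASCII grid: too few lines", call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed ASCII grid header at line ", i, call. = FALSE)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing: ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has wrong number of values", call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  tmax_raster(m,
              lat_nw = hdr$yllcorner + hdr$nrows * hdr$cellsize,
              lon_nw = hdr$xllcorner,
              cell_size = hdr$cellsize)
}

#' Write a Tmax raster as an ESRI ASCII grid
#'
#' @param grid a [tmax_raster()].
#' @param path output path.
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "tmax_raster"))
  v <- grid$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$lon_nw),
    sprintf("yllcorner %.10g", grid$lat_nw - nrow(v) * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %g", nodata))
  body <- apply(v, 1L, function(r) paste(format(r, scientific = FALSE,
                                                trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
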