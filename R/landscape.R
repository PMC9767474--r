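#' Great-circle distance between two points
#'
#' Haversine distance on a spherical Earth. All grid geometry in the package
#' (cell widths, cell areas, dispersal distances) is derived from this metric.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees. Vectorized.
#' @param radius_km Sphere radius in km (default 6371).
#' @return Distance(s) in kilometers.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Construct the discrete geographic domain
#'
#' Builds a plate-carree latitude/longitude grid over a bounding box, marks
#' cells as land or water from a topography raster (negative elevation =
#' water), and precomputes per-cell metric geometry (east-west width, north-
#' south height, and area in km, via haversine distances at the cell center).
#'
#' Cells are indexed row-major from the south-west corner: row 1 is the
#' southernmost latitude band, column 1 the westernmost. Cells are half-open:
#' a point on a shared edge belongs to the cell to its north-east.
#'
#' @param bbox Numeric vector `c(lat_min, lat_max, lon_min, lon_max)` degrees.
#' @param resolution Cell size in degrees (same in both axes). The bbox spans
#'   must be integer multiples of it.
#' @param topography A topography object from [read_topography_asc()] or
#'   [synthetic_topography()], covering `bbox`; elevation in meters, negative
#'   below sea level. `NULL` makes every cell land.
#' @param land_bridges Optional list of `c(lat, lon)` points (or a 2-column
#'   matrix); the cells containing them are forced to land regardless of
#'   topography (e.g. to connect islands to the mainland so the allele can
#'   reach them).
#' @param radius_km Earth radius for the haversine metric.
#' @return An object of class `aw_landscape`.
#' @export
build_landscape <- function(bbox, resolution = 1, topography = NULL,
                            land_bridges = NULL, radius_km = 6371) {
  stopifnot(length(bbox) == 4, is.numeric(bbox), resolution > 0)
  lat_min <- bbox[1]; lat_max <- bbox[2]; lon_min <- bbox[3]; lon_max <- bbox[4]
  if (!(lat_max > lat_min) || !(lon_max > lon_min))
    stop("degenerate bounding box: bbox must span > 0 degrees in both axes")
  nr <- (lat_max - lat_min) / resolution
  nc <- (lon_max - lon_min) / resolution
  if (abs(nr - round(nr)) > 1e-9 || abs(nc - round(nc)) > 1e-9)
    stop("bbox spans are not integer multiples of the resolution")
  n_rows <- as.integer(round(nr)); n_cols <- as.integer(round(nc))

  cell_lat <- lat_min + (seq_len(n_rows) - 0.5) * resolution
  cell_lon <- lon_min + (seq_len(n_cols) - 0.5) * resolution

  # metric geometry at each cell's center latitude; constant across longitude
  dx_km <- haversine_km(cell_lat, 0, cell_lat, resolution, radius_km)
  dy_km <- haversine_km(cell_lat - resolution / 2, 0,
                        cell_lat + resolution / 2, 0, radius_km)
  area_km2 <- dx_km * dy_km

  if (is.null(topography)) {
    land <- matrix(TRUE, n_rows, n_cols)
  } else {
    land <- resample_land_mask(topography, lat_min, lon_min, resolution,
                               n_rows, n_cols)
  }

  if (!is.null(land_bridges)) {
    if (is.matrix(land_bridges)) {
      land_bridges <- lapply(seq_len(nrow(land_bridges)),
                             function(i) land_bridges[i, ])
    }
    for (pt in land_bridges) {
      rc <- point_to_cell(pt[1], pt[2], lat_min, lon_min, resolution,
                          n_rows, n_cols)
      if (is.null(rc))
        stop(sprintf("land bridge point (%g, %g) outside bbox", pt[1], pt[2]))
      land[rc[1], rc[2]] <- TRUE
    }
  }

  structure(list(
    lat_min = lat_min, lat_max = lat_max,
    lon_min = lon_min, lon_max = lon_max,
    resolution = resolution, n_rows = n_rows, n_cols = n_cols,
    cell_lat = cell_lat, cell_lon = cell_lon,
    land = land, dx_km = dx_km, dy_km = dy_km, area_km2 = area_km2,
    radius_km = radius_km
  ), class = "aw_landscape")
}

# half-open cell lookup; returns c(row, col) or NULL when outside the bbox
point_to_cell <- function(lat, lon, lat_min, lon_min, resolution,
                          n_rows, n_cols) {
  row <- floor((lat - lat_min) / resolution) + 1
  col <- floor((lon - lon_min) / resolution) + 1
  # points on the very top/right edge belong to the outermost cell
  if (row == n_rows + 1 && (lat - lat_min) / resolution == n_rows) row <- n_rows
  if (col == n_cols + 1 && (lon - lon_min) / resolution == n_cols) col <- n_cols
  if (row < 1 || row > n_rows || col < 1 || col > n_cols) return(NULL)
  c(as.integer(row), as.integer(col))
}

#' Metric geometry of one grid cell
#'
#' @param landscape An `aw_landscape`.
#' @param row,col Cell indices (row 1 = southernmost).
#' @return Named numeric vector `c(dx_km, dy_km, area_km2)`.
#' @export
cell_geometry <- function(landscape, row, col) {
  stopifnot(inherits(landscape, "aw_landscape"))
  if (row < 1 || row > landscape$n_rows || col < 1 || col > landscape$n_cols)
    stop("cell index out of range")
  c(dx_km = landscape$dx_km[row], dy_km = landscape$dy_km[row],
    area_km2 = landscape$area_km2[row])
}

#' Locate a geographic point on the grid
#'
#' Returns the (row, col) of the cell containing a point. If that cell is
#' water, the point is snapped to the nearest land cell (by haversine distance
#' from the point to candidate cell centers) within `snap_radius` cells.
#'
#' @param landscape An `aw_landscape`.
#' @param lat,lon Point in decimal degrees.
#' @param snap_radius Chebyshev search radius, in cells, for snapping a
#'   water-cell point to land (default 1).
#' @return Named integer vector `c(row, col)`.
#' @export
locate <- function(landscape, lat, lon, snap_radius = 1) {
  stopifnot(inherits(landscape, "aw_landscape"))
  rc <- point_to_cell(lat, lon, landscape$lat_min, landscape$lon_min,
                      landscape$resolution, landscape$n_rows, landscape$n_cols)
  if (is.null(rc))
    stop(sprintf("point (%g, %g) outside the landscape bounding box", lat, lon))
  if (landscape$land[rc[1], rc[2]]) return(c(row = rc[1], col = rc[2]))
  best <- NULL; best_d <- Inf
  for (dr in -snap_radius:snap_radius) {
    for (dc in -snap_radius:snap_radius) {
      r <- rc[1] + dr; c <- rc[2] + dc
      if (r < 1 || r > landscape$n_rows || c < 1 || c > landscape$n_cols) next
      if (!landscape$land[r, c]) next
      d <- haversine_km(lat, lon, landscape$cell_lat[r], landscape$cell_lon[c],
                        landscape$radius_km)
      if (d < best_d) { best_d <- d; best <- c(r, c) }
    }
  }
  if (is.null(best))
    stop(sprintf(
      "point (%g, %g) falls on water with no land cell within %d cell(s)",
      lat, lon, snap_radius))
  c(row = best[1], col = best[2])
}

#' Cell center coordinates
#' @param landscape An `aw_landscape`.
#' @param row,col Cell indices.
#' @return Named numeric vector `c(lat, lon)`.
#' @export
cell_center <- function(landscape, row, col) {
  c(lat = landscape$cell_lat[row], lon = landscape$cell_lon[col])
}

#' Default land bridges for the Western Eurasia study map
#'
#' Cells connecting Great Britain (across the Dover strait) and Sardinia
#' (via Corsica to the Italian mainland) to continental Europe, so the allele
#' frequency can diffuse onto those islands. Override or extend via the
#' `land_bridges` argument of [build_landscape()] or the run config.
#'
#' @return A matrix of (lat, lon) points, one bridge cell per row.
#' @export
default_land_bridges <- function() {
  rbind(
    c(51.5, 1.5),  # Dover strait: Great Britain <-> mainland
    c(42.5, 9.5),  # Corsica
    c(41.5, 9.5)   # Corsica <-> Sardinia
  )
}

#' @export
print.aw_landscape <- function(x, ...) {
  cat(sprintf(
    "aw_landscape: %d x %d cells at %g deg (%g..%gN, %g..%gE), %d land / %d water\n",
    x$n_rows, x$n_cols, x$resolution, x$lat_min, x$lat_max, x$lon_min,
    x$lon_max, sum(x$land), sum(!x$land)))
  invisible(x)
}

# --- internal: land-cell indexing used by the PDE solver --------------------

# Returns list(idx): matrix of land-cell linear ids (0 where water),
# ids (n_land x 2 row/col), and 0-based neighbor table for the stencil with
# codes: >=0 land neighbor id, -1 water neighbor (reflect), -2 outside map
# (absorbing ghost cell at p = 0).
land_index <- function(landscape) {
  land <- landscape$land
  nr <- landscape$n_rows; nc <- landscape$n_cols
  idx <- matrix(0L, nr, nc)
  which_land <- which(land)
  idx[which_land] <- seq_along(which_land)
  ids <- arrayInd(which_land, c(nr, nc))
  neighbor_code <- function(r, c) {
    if (r < 1 || r > nr || c < 1 || c > nc) return(-2L)
    if (!land[r, c]) return(-1L)
    idx[r, c] - 1L
  }
  n_land <- length(which_land)
  nb <- matrix(0L, n_land, 4)  # W, E, S, N
  for (k in seq_len(n_land)) {
    r <- ids[k, 1]; c <- ids[k, 2]
    nb[k, 1] <- neighbor_code(r, c - 1)
    nb[k, 2] <- neighbor_code(r, c + 1)
    nb[k, 3] <- neighbor_code(r - 1, c)
    nb[k, 4] <- neighbor_code(r + 1, c)
  }
  # contiguous land runs along rows (x sweeps) and columns (y sweeps),
  # as 0-based land indices — consumed by the ADI solver
  runs_along <- function(outer_n, inner_n, cell_idx) {
    runs <- list(); lens <- integer(0)
    for (o in seq_len(outer_n)) {
      cur <- integer(0)
      for (i in seq_len(inner_n)) {
        id <- cell_idx(o, i)
        if (id > 0) cur <- c(cur, id - 1L)
        else if (length(cur)) { runs[[length(runs) + 1]] <- cur
                                lens <- c(lens, length(cur)); cur <- integer(0) }
      }
      if (length(cur)) { runs[[length(runs) + 1]] <- cur
                         lens <- c(lens, length(cur)) }
    }
    list(cells = as.integer(unlist(runs)), lens = lens)
  }
  row_runs <- runs_along(nr, nc, function(r, c) idx[r, c])
  col_runs <- runs_along(nc, nr, function(c, r) idx[r, c])

  # flux-form face weights for the north/south faces: the shared face width
  # relative to the cell's own width (finite-volume discretization, so that
  # area-weighted mass is conserved exactly on the spherical metric)
  dxr <- landscape$dx_km
  w_between <- function(r1, r2) {
    r2 <- pmin(pmax(r2, 1), nr)
    (dxr[r1] + dxr[r2]) / (2 * dxr[r1])
  }
  wN <- w_between(ids[, 1], ids[, 1] + 1)
  wS <- w_between(ids[, 1], ids[, 1] - 1)

  list(idx = idx, ids = ids, nb = nb,
       dx = landscape$dx_km[ids[, 1]], dy = landscape$dy_km[ids[, 1]],
       area = landscape$area_km2[ids[, 1]], wN = wN, wS = wS,
       row_runs = row_runs, col_runs = col_runs)
}
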