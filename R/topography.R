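#' Read an ESRI ASCII grid (.asc) topography raster
#'
#' Parses the plain-text ESRI ASCII grid format: a 6-line header (ncols,
#' nrows, xllcorner/xllcenter, yllcorner/yllcenter, cellsize, NODATA_value)
#' followed by rows of elevation values, north first. Elevations are in
#' meters; negative values are below sea level and become water in
#' [build_landscape()]. NODATA cells are treated as water.
#'
#' @param path Path to the `.asc` file.
#' @return A topography object: list with `elev` (matrix, row 1 = southern-
#'   most), `lat_min`, `lon_min`, `cellsize`, `n_rows`, `n_cols`.
#' @export
read_topography_asc <- function(path) {
  if (!file.exists(path)) stop("topography file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("malformed ESRI ASCII header: need ncols, nrows, cellsize")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) {
    lon_min <- hdr$xllcorner
  } else if (!is.null(hdr$xllcenter)) {
    lon_min <- hdr$xllcenter - cs / 2
  } else stop("ESRI ASCII header lacks xllcorner/xllcenter")
  if (!is.null(hdr$yllcorner)) {
    lat_min <- hdr$yllcorner
  } else if (!is.null(hdr$yllcenter)) {
    lat_min <- hdr$yllcenter - cs / 2
  } else stop("ESRI ASCII header lacks yllcorner/yllcenter")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999

  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)))
  # file rows run north->south; store south row first
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]
  m[m == nodata] <- -1  # NODATA -> water
  structure(list(elev = m, lat_min = lat_min, lon_min = lon_min,
                 cellsize = cs, n_rows = nr, n_cols = nc),
            class = "aw_topography")
}

#' Write a topography object as an ESRI ASCII grid
#' @param topography An `aw_topography`.
#' @param path Output path.
#' @export
write_topography_asc <- function(topography, path) {
  t <- topography
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", t$n_cols),
    sprintf("nrows %d", t$n_rows),
    sprintf("xllcorner %.10g", t$lon_min),
    sprintf("yllcorner %.10g", t$lat_min),
    sprintf("cellsize %.10g", t$cellsize),
    "NODATA_value -9999"
  ), con)
  for (r in t$n_rows:1)
    writeLines(paste(format(t$elev[r, ], trim = TRUE), collapse = " "), con)
  invisible(path)
}

#' Build a synthetic topography raster
#'
#' Convenience constructor for tests and simulated worlds: wraps an elevation
#' matrix (row 1 = southernmost) in the same object [read_topography_asc()]
#' returns. Purely synthetic; it stands in for real bathymetry rasters such
#' as ETOPO, which are not shipped.
#'
#' @param elev Elevation matrix in meters, row 1 = southernmost row.
#' @param lat_min,lon_min South-west corner of the raster, degrees.
#' @param cellsize Raster cell size in degrees.
#' @return An `aw_topography`.
#' @export
synthetic_topography <- function(elev, lat_min, lon_min, cellsize) {
  stopifnot(is.matrix(elev))
  structure(list(elev = elev, lat_min = lat_min, lon_min = lon_min,
                 cellsize = cellsize, n_rows = nrow(elev),
                 n_cols = ncol(elev)),
            class = "aw_topography")
}

# Aggregate a topography raster onto the model grid by majority vote of the
# covered raster cells: a model cell is land iff more covered raster cells
# have elevation >= 0 than < 0 (ties -> water, the conservative choice for a
# dispersal barrier).
resample_land_mask <- function(topography, lat_min, lon_min, resolution,
                               n_rows, n_cols) {
  t <- topography
  t_lat_max <- t$lat_min + t$n_rows * t$cellsize
  t_lon_max <- t$lon_min + t$n_cols * t$cellsize
  eps <- 1e-9
  if (t$lat_min > lat_min + eps || t$lon_min > lon_min + eps ||
      t_lat_max < lat_min + n_rows * resolution - eps ||
      t_lon_max < lon_min + n_cols * resolution - eps)
    stop("topography raster does not cover the requested bounding box")

  # raster cell centers
  rc_lat <- t$lat_min + (seq_len(t$n_rows) - 0.5) * t$cellsize
  rc_lon <- t$lon_min + (seq_len(t$n_cols) - 0.5) * t$cellsize
  row_of <- pmin(pmax(floor((rc_lat - lat_min) / resolution) + 1, 0), n_rows + 1)
  col_of <- pmin(pmax(floor((rc_lon - lon_min) / resolution) + 1, 0), n_cols + 1)
  in_r <- row_of >= 1 & row_of <= n_rows
  in_c <- col_of >= 1 & col_of <= n_cols

  land_votes <- matrix(0L, n_rows, n_cols)
  total_votes <- matrix(0L, n_rows, n_cols)
  for (ri in which(in_r)) {
    cols <- col_of[in_c]
    elev_row <- t$elev[ri, in_c]
    mr <- row_of[ri]
    tab_all <- tabulate(cols, nbins = n_cols)
    tab_land <- tabulate(cols[elev_row >= 0], nbins = n_cols)
    total_votes[mr, ] <- total_votes[mr, ] + tab_all
    land_votes[mr, ] <- land_votes[mr, ] + tab_land
  }
  if (any(total_votes == 0))
    stop("topography raster leaves model cells uncovered")
  land_votes > total_votes - land_votes
}
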