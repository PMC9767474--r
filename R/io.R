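#' Read a sample table
#'
#' Parses a TSV/CSV sample table with header columns
#' `id lat lon age_bp kind` plus a per-kind payload: `gl0 gl1 gl2`
#' (beagle order: ascending derived-allele count) for
#' `kind = genotype_likelihood`, `genotype` for `diploid_genotype`, `allele`
#' for `pseudohaploid`. Validation failures report 1-based data line numbers.
#'
#' @param path File path. Delimiter inferred from the extension (`.csv` =
#'   comma, otherwise tab).
#' @param locus Locus label for the resulting dataset.
#' @return An `aw_dataset`.
#' @export
read_samples <- function(path, locus = "locus") {
  if (!file.exists(path)) stop("sample table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  req <- c("id", "lat", "lon", "age_bp", "kind")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("sample table lacks required column(s): ", paste(miss, collapse = ", "))
  bad_line <- function(i, msg)
    stop(sprintf("%s (line %d of %s)", msg, i + 1, basename(path)))
  obs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!is.finite(row$lat) || row$lat < -90 || row$lat > 90)
      bad_line(i, "latitude out of range")
    if (!is.finite(row$lon) || row$lon < -180 || row$lon > 360)
      bad_line(i, "longitude out of range")
    if (!is.finite(row$age_bp) || row$age_bp < 0)
      bad_line(i, "negative or non-numeric age_bp")
    obs[[i]] <- switch(as.character(row$kind),
      genotype_likelihood = {
        if (!all(c("gl0", "gl1", "gl2") %in% names(df)))
          bad_line(i, "kind genotype_likelihood needs columns gl0 gl1 gl2")
        gl <- c(row$gl0, row$gl1, row$gl2)
        if (any(!is.finite(gl)) || any(gl < 0))
          bad_line(i, "non-numeric or negative genotype likelihood")
        if (sum(gl) == 0) bad_line(i, "degenerate likelihood (all zero)")
        observation(row$id, row$lat, row$lon, row$age_bp,
                    kind = "genotype_likelihood", gl = gl)
      },
      diploid_genotype = {
        if (!"genotype" %in% names(df))
          bad_line(i, "kind diploid_genotype needs column genotype")
        if (!isTRUE(row$genotype %in% 0:2))
          bad_line(i, "genotype must be 0, 1, or 2")
        observation(row$id, row$lat, row$lon, row$age_bp,
                    kind = "diploid_genotype", genotype = row$genotype)
      },
      pseudohaploid = {
        if (!"allele" %in% names(df))
          bad_line(i, "kind pseudohaploid needs column allele")
        if (!isTRUE(row$allele %in% 0:1))
          bad_line(i, "allele must be 0 or 1")
        observation(row$id, row$lat, row$lon, row$age_bp,
                    kind = "pseudohaploid", allele = row$allele)
      },
      bad_line(i, sprintf("unknown observation kind '%s'", row$kind)))
  }
  dataset(obs, locus = locus)
}

#' Write a sample table
#' @param data An `aw_dataset`.
#' @param path Output path (`.csv` writes comma-separated, else TSV).
#' @return `path`, invisibly.
#' @export
write_samples <- function(data, path) {
  df <- as.data.frame(data)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Extract one site's genotype-likelihood triplets from a beagle file
#'
#' Beagle GL format: header `marker allele1 allele2` then three columns per
#' individual; one row per site. Triplets need not be normalized (rescaling a
#' triplet only shifts the log-likelihood by a constant).
#'
#' @param path Beagle file (plain text, whitespace-separated).
#' @param target_site Marker name of the site to extract.
#' @return data.frame with columns `id`, `gl0`, `gl1`, `gl2`.
#' @export
read_beagle <- function(path, target_site) {
  if (!file.exists(path)) stop("beagle file not found: ", path)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 6 || (ncol(df) - 3) %% 3 != 0)
    stop("beagle file: individual column count not divisible by 3")
  hit <- which(df[[1]] == target_site)
  if (length(hit) == 0)
    stop(sprintf("site '%s' not found in %s", target_site, basename(path)))
  row <- as.numeric(df[hit[1], -(1:3)])
  n_ind <- length(row) / 3
  ids <- names(df)[seq(4, ncol(df), by = 3)]
  out <- data.frame(id = ids,
                    gl0 = row[seq(1, length(row), by = 3)],
                    gl1 = row[seq(2, length(row), by = 3)],
                    gl2 = row[seq(3, length(row), by = 3)],
                    stringsAsFactors = FALSE)
  tot <- out$gl0 + out$gl1 + out$gl2
  if (any(abs(tot - 1) > 1e-6))
    message(sprintf("read_beagle: %d unnormalized triplet(s) accepted",
                    sum(abs(tot - 1) > 1e-6)))
  out
}

#' Serialize a fit result to JSON
#'
#' Writes per-epoch estimates with confidence intervals, the origin (lat,
#' lon, cell), the log-likelihood, and optimizer trace metadata; lossless
#' round trip via [read_fit()].
#'
#' @param result An `aw_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(result, path) {
  stopifnot(inherits(result, "aw_fit"))
  ci <- result$ci
  per_param <- lapply(seq_along(result$theta), function(i) {
    x <- list(estimate = unname(result$theta[i]))
    if (!is.null(ci)) {
      x$lower <- unname(ci[i, "lower"])
      x$upper <- unname(ci[i, "upper"])
    }
    x
  })
  names(per_param) <- names(result$theta)
  obj <- list(
    variant = result$variant, n_epochs = result$n_epochs,
    parameters = per_param,
    origin = result$origin,
    loglik = result$loglik,
    at_boundary = as.list(result$at_boundary),
    trace = result$trace[c("n_starts", "seed", "sa_loglik", "sa_evals",
                           "refine_failed", "convergence")],
    spec = list(variant = result$spec$variant,
                allele_age_years_bp = result$spec$allele_age_years_bp,
                generation_time = result$spec$generation_time,
                epoch_boundary_years_bp = result$spec$epoch_boundary_years_bp,
                founder_density_D = result$spec$founder_density_D),
    bounds = unclass(result$bounds))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fit result written by [write_fit()]
#' @param path JSON path.
#' @return A list mirroring the serialized fields.
#' @export
read_fit <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export a frequency surface as a gridded time series
#'
#' Writes one ESRI ASCII grid per stored time slice (water = NODATA) plus a
#' JSON sidecar (`<prefix>.json`) carrying the time axis in generations, the
#' grid registration, and the slice file names. A plain-text stand-in for
#' multi-band raster formats; [import_surface()] reads it back losslessly at
#' the written precision.
#'
#' @param surface An `aw_surface`.
#' @param prefix Output path prefix; files are `<prefix>_t<k>.asc`.
#' @param digits Significant digits written (default 8).
#' @return The sidecar path, invisibly.
#' @export
export_surface <- function(surface, prefix, digits = 8) {
  ls <- surface$landscape
  files <- character(length(surface$times))
  for (k in seq_along(surface$times)) {
    m <- surface_slice(surface, k)
    f <- sprintf("%s_t%03d.asc", prefix, k)
    con <- file(f, "w")
    writeLines(c(sprintf("ncols %d", ls$n_cols),
                 sprintf("nrows %d", ls$n_rows),
                 sprintf("xllcorner %.10g", ls$lon_min),
                 sprintf("yllcorner %.10g", ls$lat_min),
                 sprintf("cellsize %.10g", ls$resolution),
                 "NODATA_value -9999"), con)
    for (r in ls$n_rows:1) {
      v <- m[r, ]
      v_str <- ifelse(is.na(v), "-9999", formatC(v, digits = digits,
                                                 format = "g"))
      writeLines(paste(v_str, collapse = " "), con)
    }
    close(con)
    files[k] <- basename(f)
  }
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(list(times_generations = surface$times,
                            files = files,
                            bbox = c(ls$lat_min, ls$lat_max, ls$lon_min,
                                     ls$lon_max),
                            resolution = ls$resolution,
                            allele_age_years_bp =
                              surface$spec$allele_age_years_bp,
                            generation_time = surface$spec$generation_time),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Import a surface written by [export_surface()]
#' @param sidecar Path to the `<prefix>.json` sidecar.
#' @return List: `times` (generations), `p` (list of matrices, NA = water),
#'   `bbox`, `resolution`.
#' @export
import_surface <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  slices <- lapply(meta$files, function(f) {
    t <- read_topography_asc(file.path(dir, f))
    m <- t$elev
    m[m == -1] <- NA  # NODATA mapped to -1 by the .asc reader
    m
  })
  list(times = meta$times_generations, p = slices, bbox = meta$bbox,
       resolution = meta$resolution)
}

#' Read a run configuration file
#'
#' JSON config with blocks `map` (bbox, resolution, topography path,
#' land_bridges, snap_radius), `model` (variant, allele_age_years_bp,
#' generation_time, epoch_boundary_years_bp, founder_density_D), `bounds`
#' (s, sigma2, v ranges), and `optimizer` (n_starts, sa, refine, output_dt).
#' Referenced paths are checked at load.
#'
#' @param path JSON config path.
#' @return Named list with validated fields and an `aw_bounds` in `$bounds`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$map$topography) &&
      !file.exists(file.path(dirname(path), cfg$map$topography)) &&
      !file.exists(cfg$map$topography))
    stop("config references a missing topography file: ", cfg$map$topography)
  if (!is.null(cfg$bounds)) {
    b <- cfg$bounds
    cfg$bounds <- parameter_bounds(
      s = if (!is.null(b$s)) as.numeric(b$s) else c(0.001, 0.1),
      sigma2 = if (!is.null(b$sigma2)) as.numeric(b$sigma2) else c(1, 100),
      v = if (!is.null(b$v)) as.numeric(b$v) else c(-2.5, 2.5))
  } else cfg$bounds <- parameter_bounds()
  cfg
}
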