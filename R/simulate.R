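#' Sampling design for deterministic-surface simulations
#'
#' Describes how validation samples are placed in space and time: spatial
#' scheme (`homogeneous` = uniform over land; `intermediate` / `extreme` =
#' uniform over progressively restricted sub-regions), the split of samples
#' across the epoch boundary, the age distribution, and the genotype calling
#' mode.
#'
#' @param n_samples Number of samples (default 1040, matching the size of the
#'   combined ancient + present-day panel used in the real-data analyses).
#' @param spatial_scheme `"homogeneous"`, `"intermediate"`, `"extreme"`, or a
#'   length-4 bbox `c(lat_min, lat_max, lon_min, lon_max)` for an explicit
#'   region.
#' @param temporal_split Length-2 fractions (older, younger than the epoch
#'   boundary), summing to 1. E.g. `c(0.75, 0.25)` oversamples the ancient
#'   period.
#' @param age_distribution `"log-uniform"` (more samples toward the present)
#'   or `"uniform"`.
#' @param mode `"pseudohaploid"` or `"diploid"`.
#' @param seed Integer seed.
#' @return An `aw_design`.
#' @export
sampling_design <- function(n_samples = 1040,
                            spatial_scheme = "homogeneous",
                            temporal_split = c(0.5, 0.5),
                            age_distribution = c("log-uniform", "uniform"),
                            mode = c("pseudohaploid", "diploid"),
                            seed = 1) {
  stopifnot(n_samples >= 1, length(temporal_split) == 2)
  if (abs(sum(temporal_split) - 1) > 1e-9)
    stop("temporal_split fractions must sum to 1")
  if (is.character(spatial_scheme))
    spatial_scheme <- match.arg(spatial_scheme,
                                c("homogeneous", "intermediate", "extreme"))
  else stopifnot(length(spatial_scheme) == 4)
  structure(list(n_samples = as.integer(n_samples),
                 spatial_scheme = spatial_scheme,
                 temporal_split = temporal_split,
                 age_distribution = match.arg(age_distribution),
                 mode = match.arg(mode), seed = as.integer(seed)),
            class = "aw_design")
}

# restricted sub-bboxes for the clustering schemes: central fractions of the
# landscape bbox (configurable by passing an explicit bbox instead)
scheme_bbox <- function(design, landscape) {
  ss <- design$spatial_scheme
  if (is.numeric(ss)) return(ss)
  frac <- switch(ss, homogeneous = 1, intermediate = 0.5, extreme = 0.2)
  clat <- (landscape$lat_min + landscape$lat_max) / 2
  clon <- (landscape$lon_min + landscape$lon_max) / 2
  hlat <- (landscape$lat_max - landscape$lat_min) * frac / 2
  hlon <- (landscape$lon_max - landscape$lon_min) * frac / 2
  c(clat - hlat, clat + hlat, clon - hlon, clon + hlon)
}

#' Sample locations and ages from a design
#'
#' Places samples uniformly over the land cells of the scheme's region
#' (uniform within the chosen cell) and draws ages on each side of the epoch
#' boundary according to the temporal split quota, log-uniformly (denser
#' toward the present) or uniformly within each side.
#'
#' @param design An `aw_design`.
#' @param landscape An `aw_landscape`.
#' @param allele_age_years_bp Oldest possible age (samples stay younger).
#' @param epoch_boundary_years_bp Epoch boundary in years BP.
#' @return data.frame with columns `lat`, `lon`, `age_bp`.
#' @export
design_locations <- function(design, landscape, allele_age_years_bp,
                             epoch_boundary_years_bp = 5000) {
  r <- local_rng(design$seed)
  bbox <- scheme_bbox(design, landscape)
  in_box <- outer(landscape$cell_lat >= bbox[1] &
                  landscape$cell_lat <= bbox[2],
                  landscape$cell_lon >= bbox[3] &
                  landscape$cell_lon <= bbox[4], "&")
  cells <- which(landscape$land & in_box)
  if (length(cells) == 0)
    stop("the restricted sampling region contains no land cells")
  ids <- arrayInd(cells, c(landscape$n_rows, landscape$n_cols))

  n <- design$n_samples
  n_old <- round(design$temporal_split[1] * n)
  n_young <- n - n_old
  draw_ages <- function(k, lo, hi) {
    if (k == 0) return(numeric(0))
    if (design$age_distribution == "log-uniform") {
      # log-uniform on [lo + 1, hi + 1] years BP: density increasing toward
      # the present
      exp(r$runif(k, log(lo + 1), log(hi + 1))) - 1
    } else {
      r$runif(k, lo, hi)
    }
  }
  ages <- c(draw_ages(n_old, epoch_boundary_years_bp,
                      allele_age_years_bp * 0.999),
            draw_ages(n_young, 0, epoch_boundary_years_bp))

  pick <- ceiling(r$runif(n) * length(cells))
  row <- ids[pick, 1]; col <- ids[pick, 2]
  res <- landscape$resolution
  lat <- landscape$lat_min + (row - 1 + r$runif(n)) * res
  lon <- landscape$lon_min + (col - 1 + r$runif(n)) * res
  data.frame(lat = lat, lon = lon, age_bp = ages)
}

#' Collapse a diploid genotype to a pseudohaploid call
#'
#' Random single-allele sampling: homozygotes map deterministically, a
#' heterozygote carries the derived allele with probability 1/2.
#'
#' @param genotype Integer vector with values in 0:2.
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @return Integer vector of 0/1 derived-allele calls.
#' @export
pseudohaploidize <- function(genotype, seed = NULL) {
  if (any(!genotype %in% 0:2)) stop("genotypes must be 0, 1, or 2")
  u <- if (is.null(seed)) stats::runif(length(genotype))
       else local_rng(seed)$runif(length(genotype))
  as.integer(ifelse(genotype == 1, u < 0.5, genotype / 2))
}

#' Draw genotype samples from a solved frequency surface
#'
#' For each sample in the design, the genotype is drawn Binomial(2, p) at the
#' surface frequency for that location and age; pseudohaploid mode then
#' applies [pseudohaploidize()]. The result is a dataset ready for [fit()].
#'
#' @param surface An `aw_surface`.
#' @param design An `aw_design`.
#' @param locations Optional data.frame (`lat`, `lon`, `age_bp`) overriding
#'   [design_locations()]; e.g. to match a real sample table.
#' @return An `aw_dataset`.
#' @export
sample_from_surface <- function(surface, design, locations = NULL) {
  spec <- surface$spec
  if (is.null(locations))
    locations <- design_locations(design, surface$landscape,
                                  spec$allele_age_years_bp,
                                  spec$epoch_boundary_years_bp)
  n <- nrow(locations)
  r <- local_rng(design$seed + 1L)
  u1 <- r$runif(n); u2 <- r$runif(n); u3 <- r$runif(n)
  obs <- vector("list", n)
  for (i in seq_len(n)) {
    p <- frequency_at(surface, locations$lat[i], locations$lon[i],
                      locations$age_bp[i])
    g <- (u1[i] < p) + (u2[i] < p)
    if (design$mode == "pseudohaploid") {
      allele <- if (g == 1) as.integer(u3[i] < 0.5) else as.integer(g / 2)
      obs[[i]] <- observation(sprintf("sim_%04d", i), locations$lat[i],
                              locations$lon[i], locations$age_bp[i],
                              kind = "pseudohaploid", allele = allele)
    } else {
      obs[[i]] <- observation(sprintf("sim_%04d", i), locations$lat[i],
                              locations$lon[i], locations$age_bp[i],
                              kind = "diploid_genotype", genotype = g)
    }
  }
  dataset(obs, locus = "simulated")
}

#' Parameters of the individual-based forward simulator
#'
#' Defaults follow the validation experiment the package emulates: 20,000
#' individuals, an additive beneficial allele with s = 0.03 arising in a
#' single individual in Central Europe 15,000 years BP, mate choice and
#' spatial competition within 250 km, offspring displaced from the mother by
#' an isotropic Gaussian with SD 25 km, 29 years per generation.
#'
#' @param n_individuals Constant population size.
#' @param s Selection coefficient (additive fitness 1, 1+s, 1+2s).
#' @param origin_lat,origin_lon Where the mutation arises (Central Europe).
#' @param start_years_bp When the mutation arises.
#' @param competition_mating_radius_km Interaction radius.
#' @param offspring_dispersal_sd_km Dispersal SD.
#' @param generation_time Years per generation.
#' @param seed Integer seed.
#' @return An `aw_forward_params`.
#' @export
forward_sim_params <- function(n_individuals = 20000, s = 0.03,
                               origin_lat = 50, origin_lon = 10,
                               start_years_bp = 15000,
                               competition_mating_radius_km = 250,
                               offspring_dispersal_sd_km = 25,
                               generation_time = 29, seed = 1) {
  stopifnot(n_individuals >= 2, s >= 0, competition_mating_radius_km > 0,
            offspring_dispersal_sd_km > 0)
  structure(list(n_individuals = as.integer(n_individuals), s = s,
                 origin_lat = origin_lat, origin_lon = origin_lon,
                 start_years_bp = start_years_bp,
                 competition_mating_radius_km = competition_mating_radius_km,
                 offspring_dispersal_sd_km = offspring_dispersal_sd_km,
                 generation_time = generation_time, seed = as.integer(seed)),
            class = "aw_forward_params")
}

#' Spatially explicit individual-based forward simulation
#'
#' Discrete non-overlapping generations at fixed population size on the
#' landscape's land mask. Mothers are sampled with weight
#' fitness / local crowding (local density within roughly the interaction
#' radius), mates uniformly within the mating radius, offspring placed by
#' Gaussian dispersal rejected off water and map edges. The derived allele
#' starts as a single copy in one individual at the origin.
#'
#' If the allele is lost, the run stops and the result has `lost = TRUE`;
#' callers conditioning on establishment (as the validation experiments do)
#' should retry with a fresh seed — see `retries`.
#'
#' @param params An `aw_forward_params`.
#' @param landscape An `aw_landscape`.
#' @param end_years_bp Stop time (default 0 = present).
#' @param record_every Record all individuals every this many generations.
#' @param retries Re-run with derived seeds up to this many times if the
#'   allele is lost (0 = report the loss instead).
#' @param init_at Optional `c(lat, lon)`: release every founder at one point
#'   instead of uniformly over land (useful for dispersal checks and
#'   range-expansion scenarios).
#' @return An `aw_forward_sim`: data.frame `records` (id, generation, lat,
#'   lon, genotype, age_bp), flags `lost`, `n_generations`, `params`, and
#'   `attempts`.
#' @export
forward_simulate <- function(params, landscape, end_years_bp = 0,
                             record_every = 1, retries = 0, init_at = NULL) {
  stopifnot(inherits(params, "aw_forward_params"),
            inherits(landscape, "aw_landscape"))
  n_gens <- round((params$start_years_bp - end_years_bp) /
                  params$generation_time)
  if (n_gens < 1) stop("simulation span shorter than one generation")
  rc <- locate(landscape, params$origin_lat, params$origin_lon)
  origin <- cell_center(landscape, rc[1], rc[2])

  land_int <- matrix(as.integer(landscape$land), landscape$n_rows,
                     landscape$n_cols)
  attempt <- 0
  repeat {
    attempt <- attempt + 1
    seed <- params$seed + (attempt - 1L) * 7919L
    res <- local_rng(seed)$with_state(function()
      forward_sim_cpp(params$n_individuals, params$s, n_gens,
                      origin["lat"], origin["lon"], land_int,
                      landscape$lat_min, landscape$lon_min,
                      landscape$resolution, landscape$area_km2,
                      params$competition_mating_radius_km,
                      params$offspring_dispersal_sd_km,
                      as.integer(record_every), 0L,
                      if (is.null(init_at)) numeric(0) else
                        as.numeric(init_at)))
    if (!res$lost || attempt > retries) break
  }

  records <- data.frame(
    id = sprintf("ind_g%d_%d", res$generation,
                 stats::ave(res$generation, res$generation,
                            FUN = seq_along)),
    generation = res$generation, lat = res$lat, lon = res$lon,
    genotype = res$genotype,
    age_bp = params$start_years_bp - res$generation * params$generation_time,
    stringsAsFactors = FALSE)
  structure(list(records = records, lost = res$lost,
                 n_generations = n_gens, params = params,
                 attempts = attempt),
            class = "aw_forward_sim")
}

#' @export
print.aw_forward_sim <- function(x, ...) {
  final <- x$records[x$records$generation == max(x$records$generation), ]
  cat(sprintf(
    "aw_forward_sim: %d generations, N = %d, %s; final frequency %.3f\n",
    x$n_generations, x$params$n_individuals,
    if (x$lost) "allele LOST" else "allele segregating",
    mean(final$genotype) / 2))
  invisible(x)
}

#' Subsample individuals from a forward simulation into a dataset
#'
#' Draws `n` individuals with ages distributed log-uniformly between the
#' simulation start and the present (denser toward the present, as in real
#' ancient-DNA compilations), pseudohaploidizes their genotypes, and returns
#' an [dataset()] ready for [fit()].
#'
#' @param sim An `aw_forward_sim` (or its `records` data.frame plus
#'   `generation_time`/`start_years_bp` attributes).
#' @param n Number of individuals to draw (default 1040).
#' @param age_distribution `"log-uniform"` or `"uniform"`.
#' @param mode `"pseudohaploid"` (default) or `"diploid"`.
#' @param seed Integer seed.
#' @return An `aw_dataset`.
#' @export
subsample_individuals <- function(sim, n = 1040,
                                  age_distribution = c("log-uniform",
                                                       "uniform"),
                                  mode = c("pseudohaploid", "diploid"),
                                  seed = 1) {
  age_distribution <- match.arg(age_distribution)
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "aw_forward_sim"))
  rec <- sim$records
  gens <- sort(unique(rec$generation))
  gen_time <- sim$params$generation_time
  start_bp <- sim$params$start_years_bp
  r <- local_rng(seed)

  # target ages, then snap each to the nearest recorded generation
  ages <- if (age_distribution == "log-uniform")
    exp(r$runif(n, log(1), log(start_bp))) - 1
  else r$runif(n, 0, start_bp - 1)
  target_gen <- (start_bp - ages) / gen_time
  snapped <- gens[pmax(1, pmin(length(gens),
                               findInterval(target_gen, gens) +
                                 (r$runif(n) < 0.5)))]

  obs <- vector("list", n)
  u_pick <- r$runif(n); u_ph <- r$runif(n)
  split_idx <- split(seq_len(nrow(rec)), rec$generation)
  for (i in seq_len(n)) {
    pool <- split_idx[[as.character(snapped[i])]]
    if (length(pool) == 0) stop("no individuals recorded at a requested age")
    k <- pool[ceiling(u_pick[i] * length(pool))]
    g <- rec$genotype[k]
    age <- start_bp - snapped[i] * gen_time
    if (mode == "pseudohaploid") {
      allele <- if (g == 1) as.integer(u_ph[i] < 0.5) else as.integer(g / 2)
      obs[[i]] <- observation(sprintf("fsim_%04d", i), rec$lat[k], rec$lon[k],
                              age, kind = "pseudohaploid", allele = allele)
    } else {
      obs[[i]] <- observation(sprintf("fsim_%04d", i), rec$lat[k], rec$lon[k],
                              age, kind = "diploid_genotype", genotype = g)
    }
  }
  dataset(obs, locus = "forward_sim")
}
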