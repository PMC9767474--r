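# Fixtures are built in code; nothing binary ships with the package.

# all-land grid, mid-latitudes
tiny_landscape <- function(n = 10, lat0 = 40, lon0 = 0, res = 1) {
  build_landscape(c(lat0, lat0 + n * res, lon0, lon0 + n * res), res)
}

# land island surrounded by water: the zero-flux test configuration
# (no land touches the absorbing outer frame)
island_landscape <- function(core = 10, lat0 = 39, lon0 = -1) {
  n <- core + 2
  elev <- matrix(-10, n, n)
  elev[2:(n - 1), 2:(n - 1)] <- 100
  topo <- synthetic_topography(elev, lat0, lon0, 1)
  build_landscape(c(lat0, lat0 + n, lon0, lon0 + n), 1, topo)
}

# landscape with a metrically flat grid (constant cell size), for oracles
# that assume a uniform stencil; geometry fields are overridden in place
flat_landscape <- function(n = 11, h_km = 100) {
  ls <- tiny_landscape(n)
  ls$dx_km[] <- h_km
  ls$dy_km[] <- h_km
  ls$area_km2[] <- h_km^2
  ls
}

# spatially uniform surface with constant frequency p at all land cells and
# all times; handy for likelihood tests with known p
constant_surface <- function(landscape, p, times = c(0, 100),
                             allele_age = 100 * 29) {
  spec <- model_spec("B", allele_age_years_bp = allele_age,
                     origin_cell = first_land_cell(landscape),
                     epoch_boundary_years_bp = 0)
  epochs <- list(epoch_params(s = 0, sigma_x2 = 0, sigma_y2 = 0,
                              t_start = 0, t_end = max(times)))
  init <- matrix(p, landscape$n_rows, landscape$n_cols)
  solve_surface(landscape, spec, epochs, output_times = times, init = init)
}

first_land_cell <- function(landscape) {
  k <- which(landscape$land)[1]
  rc <- arrayInd(k, c(landscape$n_rows, landscape$n_cols))
  c(rc[1], rc[2])
}

# random observation of a random kind at a given location/age
random_observation <- function(id, lat, lon, age) {
  kind <- sample(c("genotype_likelihood", "diploid_genotype",
                   "pseudohaploid"), 1)
  switch(kind,
    genotype_likelihood = observation(id, lat, lon, age, kind,
                                      gl = stats::runif(3, 0.01, 1)),
    diploid_genotype = observation(id, lat, lon, age, kind,
                                   genotype = sample(0:2, 1)),
    pseudohaploid = observation(id, lat, lon, age, kind,
                                allele = sample(0:1, 1)))
}

random_dataset <- function(landscape, n, allele_age, seed = 1) {
  set.seed(seed)
  ids <- which(landscape$land)
  rc <- arrayInd(sample(ids, n, replace = TRUE),
                 c(landscape$n_rows, landscape$n_cols))
  obs <- lapply(seq_len(n), function(i) {
    random_observation(paste0("o", i),
                       landscape$cell_lat[rc[i, 1]],
                       landscape$cell_lon[rc[i, 2]],
                       stats::runif(1, 0, allele_age * 0.9))
  })
  dataset(obs)
}

# build a model spec from the shipped example config (mirrors the CLI path)
spec_from_config_example <- function(cfg, landscape) {
  model_spec(cfg$model$variant, cfg$model$allele_age_years_bp,
             origin_cell = locate(landscape, cfg$model$origin[1],
                                  cfg$model$origin[2]),
             generation_time = cfg$model$generation_time,
             epoch_boundary_years_bp = cfg$model$epoch_boundary_years_bp,
             founder_density_D = cfg$model$founder_density_D)
}
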