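test_that("design locations honor quotas and restricted regions", {
  ls <- tiny_landscape(10)
  d1 <- sampling_design(1000, "homogeneous", c(0.5, 0.5), seed = 1)
  locs <- design_locations(d1, ls, 15000, 5000)
  expect_equal(nrow(locs), 1000L)
  expect_equal(sum(locs$age_bp >= 5000), 500L)

  d2 <- sampling_design(1040, "intermediate", c(0.75, 0.25), seed = 2)
  locs2 <- design_locations(d2, ls, 15000, 5000)
  expect_equal(sum(locs2$age_bp >= 5000), 780L)
  expect_equal(sum(locs2$age_bp < 5000), 260L)

  d3 <- sampling_design(200, "extreme", c(0.5, 0.5), seed = 3)
  locs3 <- design_locations(d3, ls, 15000, 5000)
  bb <- allelewave:::scheme_bbox(d3, ls)
  expect_true(all(locs3$lat >= bb[1] & locs3$lat <= bb[2]))
  expect_true(all(locs3$lon >= bb[3] & locs3$lon <= bb[4]))
  # the extreme region is a strict subset of the intermediate one
  bb2 <- allelewave:::scheme_bbox(d2, ls)
  expect_true(bb[1] > bb2[1] && bb[2] < bb2[2])

  # explicit region with no land errors
  elev <- matrix(-5, 10, 10); elev[1, 1] <- 50
  lsw <- build_landscape(c(40, 50, 0, 10), 1,
                         synthetic_topography(elev, 40, 0, 1))
  d4 <- sampling_design(10, c(45, 48, 5, 8), c(0.5, 0.5), seed = 4)
  expect_error(design_locations(d4, lsw, 15000, 5000), "no land")

  expect_error(sampling_design(10, temporal_split = c(0.6, 0.5)), "sum to 1")
})

test_that("pseudohaploidization maps homozygotes deterministically and is fair", {
  expect_equal(pseudohaploidize(c(0, 0, 2, 2), seed = 1), c(0L, 0L, 1L, 1L))
  draws <- pseudohaploidize(rep(1L, 10000), seed = 7)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
  # expectation of the derived call equals g/2 for every genotype
  for (g in 0:2) {
    m <- mean(pseudohaploidize(rep(g, 4000), seed = g + 1))
    expect_lt(abs(m - g / 2), 3 * sqrt(0.25 / 4000) + 1e-12)
  }
  expect_error(pseudohaploidize(3), "0, 1, or 2")
  expect_identical(pseudohaploidize(rep(1L, 50), seed = 3),
                   pseudohaploidize(rep(1L, 50), seed = 3))
})

test_that("surface sampling draws Binomial(2, p) genotypes", {
  ls <- tiny_landscape(6)
  # p = 1 everywhere: every diploid draw is homozygous derived
  surf1 <- constant_surface(ls, 1)
  d <- sampling_design(50, "homogeneous", c(0.5, 0.5), mode = "diploid",
                       seed = 5)
  locs <- design_locations(d, ls, 100 * 29, 50 * 29)
  ds <- sample_from_surface(surf1, d, locations = locs)
  expect_true(all(vapply(ds$observations, `[[`, 0L, "genotype") == 2L))

  # p = 0.5: mean genotype within 3 SE of 1
  surf5 <- constant_surface(ls, 0.5)
  d2 <- sampling_design(10000, "homogeneous", c(0.5, 0.5), mode = "diploid",
                        seed = 6)
  locs2 <- design_locations(d2, ls, 100 * 29, 50 * 29)
  ds2 <- sample_from_surface(surf5, d2, locations = locs2)
  g <- vapply(ds2$observations, `[[`, 0L, "genotype")
  expect_lt(abs(mean(g) - 1), 3 * sqrt(0.5 / 10000))

  # determinism and pseudohaploid payload
  d3 <- sampling_design(40, "homogeneous", c(0.5, 0.5), seed = 9)
  a <- sample_from_surface(surf5, d3)
  b <- sample_from_surface(surf5, d3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(vapply(a$observations, `[[`, "", "kind") ==
                    "pseudohaploid"))
})

test_that("neutral forward simulation keeps allele frequency a martingale", {
  ls <- tiny_landscape(6)
  # large radius relative to the map, short neutral runs
  n_rep <- 200; N <- 60; gens <- 5
  finals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    p <- forward_sim_params(n_individuals = N, s = 0,
                            origin_lat = 43, origin_lon = 3,
                            start_years_bp = gens * 29,
                            competition_mating_radius_km = 5000,
                            offspring_dispersal_sd_km = 25, seed = r)
    sim <- forward_simulate(p, ls)
    rec <- sim$records
    finals[r] <- mean(rec$genotype[rec$generation ==
                                     max(rec$generation)]) / 2
  }
  init <- 1 / (2 * N)
  se <- stats::sd(finals) / sqrt(n_rep)
  expect_lt(abs(mean(finals) - init), 3 * se)
})

test_that("selection raises conditional final frequency above the neutral run", {
  ls <- tiny_landscape(6)
  n_rep <- 60; N <- 120; gens <- 60
  run <- function(s) {
    vapply(seq_len(n_rep), function(r) {
      p <- forward_sim_params(n_individuals = N, s = s,
                              origin_lat = 43, origin_lon = 3,
                              start_years_bp = gens * 29,
                              competition_mating_radius_km = 5000,
                              offspring_dispersal_sd_km = 25, seed = 1000 + r)
      sim <- forward_simulate(p, ls)
      rec <- sim$records
      if (sim$lost) 0 else
        mean(rec$genotype[rec$generation == max(rec$generation)]) / 2
    }, 0)
  }
  neutral <- run(0)
  selected <- run(0.03)
  # among replicates where the allele establishes, selection pushes frequency
  # above the neutral conditional mean (paired seeds)
  expect_gt(mean(selected[selected > 0]), mean(neutral[neutral > 0]))
})

test_that("offspring dispersal follows the stated Gaussian contract", {
  # release all founders at one point on a big all-land map; after one
  # generation every individual's displacement from that point is one
  # dispersal draw
  ls <- build_landscape(c(30, 60, -15, 15), 1)
  p <- forward_sim_params(n_individuals = 4000, s = 0,
                          origin_lat = 45, origin_lon = 0,
                          start_years_bp = 29,
                          competition_mating_radius_km = 1e5,
                          offspring_dispersal_sd_km = 25, seed = 12)
  sim <- forward_simulate(p, ls, init_at = c(45, 0))
  rec <- sim$records
  off <- rec[rec$generation == 1, ]
  dy <- (off$lat - 45) * 111.1949
  sd_y <- stats::sd(dy)
  expect_lt(abs(sd_y - 25) / 25, 0.05)
  # x displacements (scaled by cos(lat) at the release point)
  dx <- (off$lon - 0) * 111.1949 * cos(45 * pi / 180)
  expect_lt(abs(stats::sd(dx) - 25) / 25, 0.06)
})

test_that("population size is exactly constant and runs are reproducible", {
  ls <- tiny_landscape(8)
  p <- forward_sim_params(n_individuals = 300, s = 0.1, origin_lat = 44,
                          origin_lon = 4, start_years_bp = 40 * 29,
                          seed = 2)
  sim1 <- forward_simulate(p, ls, retries = 20)
  sim2 <- forward_simulate(p, ls, retries = 20)
  expect_identical(sim1$records, sim2$records)
  counts <- table(sim1$records$generation)
  expect_true(all(counts == 300))
  expect_error(forward_simulate(
    forward_sim_params(n_individuals = 10, origin_lat = 0, origin_lon = 0),
    ls), "outside|not on land")
})

test_that("lost alleles are reported and retried with derived seeds", {
  ls <- tiny_landscape(6)
  p <- forward_sim_params(n_individuals = 500, s = 0, origin_lat = 43,
                          origin_lon = 3, start_years_bp = 100 * 29, seed = 1)
  sim <- forward_simulate(p, ls, retries = 0)
  # neutral single copy in N = 500 is almost surely lost in 100 generations
  expect_true(sim$lost)
  sim2 <- forward_simulate(p, ls, retries = 40)
  expect_true(sim2$attempts > 1)
})

test_that("subsampling produces a present-biased pseudohaploid dataset", {
  ls <- tiny_landscape(8)
  p <- forward_sim_params(n_individuals = 400, s = 0.15, origin_lat = 44,
                          origin_lon = 4, start_years_bp = 150 * 29, seed = 5)
  sim <- forward_simulate(p, ls, retries = 40)
  ds <- subsample_individuals(sim, n = 1040, seed = 3)
  expect_equal(length(ds), 1040L)
  expect_true(all(vapply(ds$observations, `[[`, "", "kind") ==
                    "pseudohaploid"))
  ages <- vapply(ds$observations, `[[`, 0, "age_years_bp")
  # log-uniform ages pile up near the present
  expect_gt(sum(ages < max(ages) / 2), sum(ages >= max(ages) / 2))
  ds2 <- subsample_individuals(sim, n = 1040, seed = 3)
  expect_identical(as.data.frame(ds), as.data.frame(ds2))
})

test_that("panmictic limit realizes the nominal selection coefficient", {
  # huge mating radius + huge dispersal = well-mixed population, so the
  # global frequency trajectory must be logistic at rate ~s (guards against
  # selection leaking through only one parental pathway, which would halve
  # the realized rate)
  ls <- build_landscape(c(30, 75, -10, 80), 1)
  p <- forward_sim_params(n_individuals = 4000, s = 0.05, seed = 5,
                          start_years_bp = 200 * 29,
                          competition_mating_radius_km = 1e5,
                          offspring_dispersal_sd_km = 4000)
  sim <- forward_simulate(p, ls, retries = 200)
  expect_false(sim$lost)
  rec <- sim$records
  freq <- tapply(rec$genotype, rec$generation, mean) / 2
  gens <- as.numeric(names(freq))
  sel <- freq > 0.02 & freq < 0.9
  expect_gt(sum(sel), 10)
  rate <- unname(coef(stats::lm(log(freq[sel] / (1 - freq[sel])) ~
                                  gens[sel]))[2])
  expect_lt(abs(rate - 0.05) / 0.05, 0.25)
})
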