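test_that("Latin hypercube starts stratify every dimension", {
  lower <- c(s = 0.001, sig = 1)
  upper <- c(s = 0.1, sig = 100)
  x <- lhs_starts(lower, upper, 50, seed = 3)
  expect_equal(dim(x), c(50L, 2L))
  for (j in 1:2) {
    strata <- floor((x[, j] - lower[j]) / (upper[j] - lower[j]) * 50)
    expect_setequal(strata, 0:49)  # exactly one point per stratum
  }
  expect_identical(x, lhs_starts(lower, upper, 50, seed = 3))
  x1 <- lhs_starts(lower, upper, 1, seed = 1)
  expect_true(all(x1 >= lower & x1 <= upper))
  expect_error(lhs_starts(c(1, 2), c(1, 3), 5), "invalid bounds")
})

# small fitting problem reused below: single-epoch model A on a tiny map
toy_problem <- function(s_true = 0.04, n = 150, seed = 9) {
  ls <- tiny_landscape(6)
  spec <- model_spec("A", allele_age_years_bp = 250 * 29,
                     origin_cell = c(3, 3), epoch_boundary_years_bp = 0)
  epochs <- list(epoch_params(s = s_true, sigma_x2 = 25, sigma_y2 = 25,
                              t_start = 0, t_end = 250))
  surf <- solve_surface(ls, spec, epochs, output_times = seq(0, 250, 5))
  design <- sampling_design(n_samples = n, temporal_split = c(0.5, 0.5),
                            seed = seed)
  # keep samples younger than the allele so every age is valid; boundary 0
  locs <- design_locations(design, ls, 250 * 29, 120 * 29)
  data <- sample_from_surface(surf, design, locations = locs)
  list(ls = ls, spec = spec, data = data, s_true = s_true)
}

test_that("annealing layer beats a brute-force grid scan on a 1-D problem", {
  tp <- toy_problem()
  # effectively 1-D: pin the dispersal rate by a near-degenerate bound
  b <- parameter_bounds(sigma2 = c(25, 25.0001))
  llfn <- allelewave:::make_loglik_fn(tp$data, tp$ls, tp$spec)
  grid_s <- seq(0.001, 0.1, length.out = 120)
  grid_ll <- vapply(grid_s, function(s) llfn(c(s, 25), c(3, 3)), 0)
  s_grid_opt <- grid_s[which.max(grid_ll)]

  tb <- allelewave:::theta_bounds("A", 1, b)
  starts <- lhs_starts(tb$lower, tb$upper, 8, seed = 2)
  inc <- anneal_fit(tp$data, tp$ls, tp$spec, starts,
                    origin_candidates = rbind(c(3L, 3L)), b, seed = 4)
  expect_lt(abs(inc$theta[1] - s_grid_opt) / s_grid_opt, 0.10)
  expect_equal(unname(inc$origin), c(3L, 3L))  # single candidate is returned
  # the incumbent is never worse than the best start
  start_best <- max(vapply(seq_len(nrow(starts)),
                           function(i) llfn(starts[i, ], c(3, 3)), 0))
  expect_gte(inc$loglik, start_best)
})

test_that("annealing accepts a start already at the optimum and never regresses", {
  tp <- toy_problem(n = 60)
  b <- parameter_bounds()
  tb <- allelewave:::theta_bounds("A", 1, b)
  llfn <- allelewave:::make_loglik_fn(tp$data, tp$ls, tp$spec)
  ref <- refine_fit(tp$data, tp$ls, tp$spec,
                    list(theta = c(0.04, 25), origin = c(3L, 3L),
                         loglik = llfn(c(0.04, 25), c(3, 3))), b)
  starts <- rbind(ref$theta, lhs_starts(tb$lower, tb$upper, 3, seed = 5))
  inc <- anneal_fit(tp$data, tp$ls, tp$spec, starts, rbind(c(3L, 3L)), b,
                    seed = 6, control = list(iters = 40))
  expect_gte(inc$loglik, ref$loglik)
})

test_that("anneal_fit validates its candidate set and detects impossible data", {
  tp <- toy_problem(n = 20)
  b <- parameter_bounds()
  tb <- allelewave:::theta_bounds("A", 1, b)
  starts <- lhs_starts(tb$lower, tb$upper, 2, seed = 1)
  expect_error(anneal_fit(tp$data, tp$ls, tp$spec, starts,
                          matrix(integer(0), 0, 2), b), "empty")
  lsw <- tp$ls; lsw$land[1, 1] <- FALSE
  expect_error(anneal_fit(tp$data, lsw, tp$spec, starts, rbind(c(1L, 1L)), b),
               "land")
})

test_that("refinement solves a smooth toy problem to high precision", {
  tp <- toy_problem(n = 30)
  b <- parameter_bounds(s = c(0.001, 1), sigma2 = c(1, 100))
  # analytic quadratic: maximum at (0.3, 40)
  quad <- function(th, origin) -(th[1] - 0.3)^2 - 1e-4 * (th[2] - 40)^2
  res <- refine_fit(tp$data, tp$ls, tp$spec,
                    list(theta = c(0.1, 10), origin = c(3L, 3L),
                         loglik = quad(c(0.1, 10))),
                    b, loglik_fn = quad)
  expect_false(res$refine_failed)
  expect_equal(unname(res$theta), c(0.3, 40), tolerance = 1e-6)
  expect_false(any(res$at_boundary))

  # re-refining from the optimum yields no further improvement
  res2 <- refine_fit(tp$data, tp$ls, tp$spec, res, b, loglik_fn = quad)
  expect_lt(abs(res2$loglik - res$loglik), 1e-10)

  # gradient pointing outside the box: estimate pinned at the bound, flagged
  mono <- function(th, origin) th[1]
  res3 <- refine_fit(tp$data, tp$ls, tp$spec,
                     list(theta = c(0.5, 40), origin = c(3L, 3L),
                          loglik = 0.5), b, loglik_fn = mono)
  expect_equal(unname(res3$theta[1]), 1)
  expect_true(res3$at_boundary[1])
})

test_that("Fisher intervals reproduce the binomial closed form", {
  n <- 400; k <- 123
  loglik <- function(th) k * log(th) + (n - k) * log(1 - th)
  p_hat <- k / n
  ci <- allelewave:::fisher_ci_from_loglik(loglik, p_hat)
  se_exact <- sqrt(p_hat * (1 - p_hat) / n)
  expect_equal(unname(ci[1, "lower"]), p_hat - 1.96 * se_exact,
               tolerance = 1e-4)
  expect_equal(unname(ci[1, "upper"]), p_hat + 1.96 * se_exact,
               tolerance = 1e-4)
  expect_true(ci[1, "lower"] <= p_hat && p_hat <= ci[1, "upper"])

  # flat direction: NaN interval with a warning, not an invented one
  flat <- function(th) k * log(th[1]) + (n - k) * log(1 - th[1]) + 0 * th[2]
  expect_warning(ci2 <- allelewave:::fisher_ci_from_loglik(flat,
                                                           c(p_hat, 1)),
                 "positive definite")
  expect_true(all(is.nan(ci2[, "se"])))
})

test_that("full fit recovers s on zero-dispersal data and is deterministic", {
  # zero-dispersal world: every cell follows the same logistic curve, so the
  # MLE of s is recoverable by a 1-D grid scan oracle
  ls <- tiny_landscape(5)
  s_true <- 0.05
  spec <- model_spec("A", allele_age_years_bp = 200 * 29,
                     origin_cell = c(3, 3), epoch_boundary_years_bp = 0)
  spec_sim <- spec
  spec_sim$founder_density_D <- 1 / (2 * 1e-3 * ls$area_km2[3])  # p0 = 1e-3
  surf <- solve_surface(ls, spec_sim,
                        list(epoch_params(s_true, sigma_x2 = 0, sigma_y2 = 0,
                                          t_start = 0, t_end = 200)),
                        output_times = seq(0, 200, 5))
  # with zero dispersal only the origin cell ever carries the allele, so all
  # samples sit there, making this a pure logistic-growth problem in s
  design <- sampling_design(n_samples = 120, temporal_split = c(0.5, 0.5),
                            seed = 21)
  oc <- cell_center(ls, 3, 3)
  locs <- design_locations(design, ls, 200 * 29, 100 * 29)
  locs$lat <- oc["lat"]; locs$lon <- oc["lon"]
  data <- sample_from_surface(surf, design, locations = locs)

  # oracle: logistic-growth MLE by grid search (dispersal pinned near zero)
  b <- parameter_bounds(s = c(0.005, 0.2), sigma2 = c(1e-6, 2e-6))
  spec_fit <- spec
  spec_fit$founder_density_D <- 1 / (2 * 1e-3 * ls$area_km2[3])  # p0 = 1e-3
  llfn <- allelewave:::make_loglik_fn(data, ls, spec_fit)
  grid_s <- seq(0.005, 0.2, length.out = 300)
  gll <- vapply(grid_s, function(s) llfn(c(s, 1.5e-6), c(3, 3)), 0)
  s_oracle <- grid_s[which.max(gll)]

  cfg <- list(n_starts = 5, seed = 2, origin_candidates = rbind(c(3L, 3L)),
              sa = list(iters = 50), refine = list(maxit = 50))
  res <- fit(data, ls, spec_fit, b, cfg)
  expect_lt(abs(res$theta[1] - s_oracle), 0.002)
  expect_lt(abs(res$theta[1] - s_true) / s_true, 0.25)
  expect_true(all(res$theta >= allelewave:::theta_bounds("A", 1, b)$lower -
                    1e-12))
  # loglik never decreases across pipeline stages
  expect_gte(res$loglik, res$trace$sa_loglik)
  expect_gte(res$trace$sa_loglik, max(res$trace$start_loglik))

  res_again <- fit(data, ls, spec_fit, b, cfg)
  expect_identical(res$theta, res_again$theta)
  expect_identical(res$loglik, res_again$loglik)
  expect_identical(res$origin, res_again$origin)

  expect_error(fit(dataset(list()), ls, spec_fit, b, cfg))
})

test_that("fitting model C to model-B data yields a near-equivalent surface", {
  ls <- tiny_landscape(8)
  spec <- model_spec("B", allele_age_years_bp = 250 * 29,
                     origin_cell = c(4, 4), epoch_boundary_years_bp = 0)
  epochs_true <- list(epoch_params(s = 0.05, sigma_x2 = 40, sigma_y2 = 15,
                                   t_start = 0, t_end = 250))
  times <- seq(0, 250, 10)
  surf_true <- solve_surface(ls, spec, epochs_true, times)
  design <- sampling_design(n_samples = 400, temporal_split = c(0.5, 0.5),
                            seed = 33)
  locs <- design_locations(design, ls, 250 * 29, 120 * 29)
  data <- sample_from_surface(surf_true, design, locations = locs)

  specC <- spec; specC$variant <- "C"
  cfg <- list(n_starts = 6, seed = 5, origin_candidates = rbind(c(4L, 4L)),
              sa = list(iters = 60), refine = list(maxit = 60), ci = FALSE)
  resC <- fit(data, ls, specC, parameter_bounds(), cfg)
  surf_C <- solve_surface(ls, specC, resC$epochs, times)
  rms <- sqrt(mean((surf_C$p - surf_true$p)^2))
  expect_lt(rms, 0.05)
})

test_that("allele-age profiling returns one maximized log-likelihood per age", {
  tp <- toy_problem(n = 60)
  cfg <- list(n_starts = 3, seed = 8,
              origin_candidates = rbind(c(3L, 3L)),
              sa = list(iters = 25), refine = list(maxit = 25), ci = FALSE)
  b <- parameter_bounds()
  single <- profile_allele_age(tp$data, tp$ls, tp$spec,
                               ages = tp$spec$allele_age_years_bp, b, cfg)
  direct <- fit(tp$data, tp$ls, tp$spec, b, cfg)
  expect_equal(single$loglik, direct$loglik)

  # an age younger than the oldest observation is flagged, others returned
  oldest <- max(vapply(tp$data$observations, `[[`, 0, "age_years_bp"))
  prof <- profile_allele_age(tp$data, tp$ls, tp$spec,
                             ages = c(oldest * 0.5,
                                      tp$spec$allele_age_years_bp), b, cfg)
  expect_true(is.na(prof$loglik[1]) && !is.na(prof$error[1]))
  expect_false(is.na(prof$loglik[2]))
  expect_error(profile_allele_age(tp$data, tp$ls, tp$spec, ages = -1))
})
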