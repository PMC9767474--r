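test_that("reaction term matches the closed form and its fixed points", {
  for (s in c(0, 0.01, 0.1)) {
    expect_equal(reaction_term(0, s), 0)
    expect_equal(reaction_term(1, s), 0)
    expect_equal(reaction_term(0, s, d = 0.07), 0)
  }
  # additive case reduces to logistic growth
  expect_equal(reaction_term(0.5, 0.03, d = 0.06), 0.0075)
  expect_equal(reaction_term(0.5, s = 0.03), 0.03 * 0.5 * 0.5)
  # general dominance: p(1-p)(pd + s(1-2p))
  expect_equal(reaction_term(0.5, s = 0.01, d = 0.05), 0.00625)
  p <- seq(0, 1, by = 0.1)
  expect_equal(reaction_term(p, 0.02, d = 0.03),
               p * (1 - p) * (p * 0.03 + 0.02 * (1 - 2 * p)))
  expect_error(reaction_term(1.2, 0.01), "outside")
})

test_that("spatial operator reproduces hand-computed stencils", {
  ls <- flat_landscape(11, h_km = 100)
  h2 <- 100^2

  # uniform field: Laplacian and gradient vanish, only the reaction remains
  st <- matrix(0.4, 11, 11)
  d <- spatial_operator(st, epoch_params(s = 0.05, sigma_x2 = 30, v_x = 1,
                                         v_y = -2), ls)
  expect_equal(max(abs(d[2:10, 2:10] - reaction_term(0.4, 0.05))), 0,
               tolerance = 1e-12)

  # unit spike: 5-point stencil with Dx = sigma_x^2/2, Dy = sigma_y^2/2
  st2 <- matrix(0, 11, 11); st2[6, 6] <- 1
  d2 <- spatial_operator(st2, epoch_params(s = 0, sigma_x2 = 50,
                                           sigma_y2 = 20, d = 0), ls)
  expect_equal(d2[6, 6], -2 * (25 + 10) / h2)
  expect_equal(d2[6, 5], 25 / h2)   # west neighbor
  expect_equal(d2[6, 7], 25 / h2)   # east neighbor
  expect_equal(d2[5, 6], 10 / h2)   # south neighbor
  expect_equal(d2[7, 6], 10 / h2)   # north neighbor
  expect_equal(d2[5, 5], 0)         # diagonal untouched

  # uniform east-west gradient with pure advection: d/dt = vx * grad
  grad <- matrix(rep(seq(0, 1, length.out = 11), each = 11), 11, 11)
  for (vx in c(1.5, -1.5)) {
    d3 <- spatial_operator(grad, epoch_params(s = 0, sigma_x2 = 0, v_x = vx,
                                              d = 0), ls)
    expect_equal(max(abs(d3[2:10, 2:10] - vx * 0.1 / 100)), 0,
                 tolerance = 1e-12)
  }

  expect_error(spatial_operator(matrix(NaN, 11, 11),
                                epoch_params(0.01, 10), ls), "non-finite")
})

test_that("water cells act as no-flux boundaries in the operator", {
  # single land cell flanked by water: nothing diffuses anywhere
  elev <- matrix(-10, 5, 5); elev[3, 3] <- 10
  ls <- build_landscape(c(40, 45, 0, 5), 1,
                        synthetic_topography(elev, 40, 0, 1))
  st <- matrix(NA_real_, 5, 5); st[3, 3] <- 0.7
  d <- spatial_operator(st, epoch_params(s = 0, sigma_x2 = 80, sigma_y2 = 80,
                                         v_x = 2, d = 0), ls)
  expect_equal(d[3, 3], 0)
})

test_that("initial surface encodes p0 = 1/(2 D A)", {
  # cell centered on the equator: A approx 111.19^2 km^2
  ls <- build_landscape(c(-0.5, 0.5, 0, 1), 1)
  spec <- model_spec("B", 1000, origin_cell = c(1, 1),
                     epoch_boundary_years_bp = 0, founder_density_D = 2.5)
  p0 <- initial_surface(ls, spec)[1, 1]
  expect_equal(p0, 1 / (2 * 2.5 * ls$area_km2[1]))
  expect_equal(p0, 1.618e-5, tolerance = 1e-3)

  ls2 <- tiny_landscape(6)
  spec2 <- model_spec("B", 1000, origin_cell = c(3, 4),
                      epoch_boundary_years_bp = 0)
  m <- initial_surface(ls2, spec2)
  expect_equal(sum(m), m[3, 4])  # mass only at the origin
  spec3 <- spec2; spec3$founder_density_D <- 5
  expect_equal(initial_surface(ls2, spec3)[3, 4], m[3, 4] / 2)
})

test_that("zero-dispersal solve matches the logistic closed form everywhere", {
  ls <- tiny_landscape(8)
  s <- 0.025; p0 <- 1e-4
  spec <- model_spec("B", allele_age_years_bp = 500 * 29,
                     origin_cell = c(4, 4), epoch_boundary_years_bp = 0)
  epochs <- list(epoch_params(s = s, sigma_x2 = 0, sigma_y2 = 0,
                              t_start = 0, t_end = 500))
  times <- c(0, 50, 200, 350, 500)
  surf <- solve_surface(ls, spec, epochs, output_times = times,
                        init = matrix(p0, 8, 8))
  exact <- p0 * exp(s * times) / (1 + p0 * (exp(s * times) - 1))
  for (k in seq_len(nrow(surf$p)))
    expect_lt(max(abs(surf$p[k, ] - exact) / exact), 1e-4)
})

test_that("area-weighted mass is conserved (s = 0) and non-decreasing (s > 0) on an island", {
  ls <- island_landscape(10)
  spec <- model_spec("B", 200 * 29, origin_cell = c(7, 7),
                     epoch_boundary_years_bp = 0)
  epochs <- list(epoch_params(s = 0, sigma_x2 = 40, sigma_y2 = 40,
                              t_start = 0, t_end = 200))
  surf <- solve_surface(ls, spec, epochs, output_times = seq(0, 200, 50),
                        rtol = 1e-9, atol = 1e-12)
  mass <- colSums(surf$p * surf$land_index$area)
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-6)

  epochs2 <- list(epoch_params(s = 0.04, sigma_x2 = 40, sigma_y2 = 40,
                               t_start = 0, t_end = 200))
  surf2 <- solve_surface(ls, spec, epochs2, output_times = seq(0, 200, 25))
  mass2 <- colSums(surf2$p * surf2$land_index$area)
  expect_true(all(diff(mass2) > -1e-9))
})

test_that("solution stays in [0, 1] and the surface is symmetric when the problem is", {
  # 90-degree rotation symmetry on a metrically flat all-land square
  ls <- flat_landscape(11, 100)
  spec <- model_spec("B", 150 * 29, origin_cell = c(6, 6),
                     epoch_boundary_years_bp = 0)
  epochs <- list(epoch_params(s = 0.05, sigma_x2 = 60, sigma_y2 = 60,
                              t_start = 0, t_end = 150))
  surf <- solve_surface(ls, spec, epochs, output_times = c(0, 75, 150))
  expect_lte(surf$overshoot, 1e-3)
  expect_true(all(surf$p >= 0 & surf$p <= 1))
  m <- surface_slice(surf, 3)
  for (rot in 1:3) {
    mr <- m
    for (i in seq_len(rot)) mr <- t(mr[nrow(mr):1, ])
    expect_lt(max(abs(m - mr)), 1e-6)
  }
})

test_that("models A, B, C nest at degenerate parameter values", {
  ls <- tiny_landscape(9)
  mk_spec <- function(v) model_spec(v, 120 * 29, origin_cell = c(5, 5),
                                    epoch_boundary_years_bp = 0)
  times <- c(0, 60, 120)
  sA <- solve_surface(ls, mk_spec("A"), list(epoch_params(
    0.04, sigma_x2 = 35, sigma_y2 = 35, t_start = 0, t_end = 120)), times)
  sB <- solve_surface(ls, mk_spec("B"), list(epoch_params(
    0.04, sigma_x2 = 35, sigma_y2 = 35, t_start = 0, t_end = 120)), times)
  sC <- solve_surface(ls, mk_spec("C"), list(epoch_params(
    0.04, sigma_x2 = 35, sigma_y2 = 35, v_x = 0, v_y = 0,
    t_start = 0, t_end = 120)), times)
  expect_lt(max(abs(sA$p - sB$p)), 1e-8)
  expect_lt(max(abs(sB$p - sC$p)), 1e-8)
})

test_that("the x10 time/parameter rescaling leaves the solution invariant", {
  ls <- tiny_landscape(9)
  spec <- model_spec("C", 200 * 29, origin_cell = c(5, 5),
                     epoch_boundary_years_bp = 100 * 29)
  epochs <- two_epochs(spec, list(s = 0.05, sigma_x2 = 30, sigma_y2 = 20,
                                  v_x = 1, v_y = -1),
                       list(s = 0.02, sigma_x2 = 50, sigma_y2 = 40,
                            v_x = -0.5, v_y = 0.5))
  s1 <- solve_surface(ls, spec, epochs, output_times = c(0, 100, 200))
  s10 <- solve_surface(ls, spec, epochs, output_times = c(0, 100, 200),
                       time_scale = 10)
  expect_lt(max(abs(s1$p - s10$p)), 1e-5)
})

test_that("ADI stepping agrees with the adaptive integrator", {
  ls <- island_landscape(10)
  spec <- model_spec("C", 150 * 29, origin_cell = c(7, 7),
                     epoch_boundary_years_bp = 75 * 29)
  epochs <- two_epochs(spec, list(s = 0.05, sigma_x2 = 60, sigma_y2 = 30,
                                  v_x = 1.5, v_y = -1),
                       list(s = 0.02, sigma_x2 = 20, sigma_y2 = 80,
                            v_x = -2, v_y = 0.5))
  times <- seq(0, 150, by = 25)
  ref <- solve_surface(ls, spec, epochs, times, rtol = 1e-9, atol = 1e-12)
  adi <- solve_surface(ls, spec, epochs, times, method = "adi", adi_dt = 0.5)
  expect_lt(max(abs(ref$p - adi$p)), 5e-4)
})

test_that("epoch tiling is validated and state is continuous across the boundary", {
  ls <- tiny_landscape(6)
  spec <- model_spec("B", 100 * 29, origin_cell = c(3, 3),
                     epoch_boundary_years_bp = 50 * 29)
  gap <- list(epoch_params(0.02, 10, t_start = 0, t_end = 40),
              epoch_params(0.02, 10, t_start = 50, t_end = 100))
  expect_error(solve_surface(ls, spec, gap, c(0, 100)), "gaps")
  late <- list(epoch_params(0.02, 10, t_start = 10, t_end = 100))
  expect_error(solve_surface(ls, spec, late, c(0, 100)), "start at 0")
  short <- list(epoch_params(0.02, 10, t_start = 0, t_end = 60))
  expect_error(solve_surface(ls, spec, short, c(0, 100)), "cover")

  # a no-op epoch split must not perturb the solution
  one <- solve_surface(ls, spec, list(epoch_params(0.03, 25, t_start = 0,
                                                   t_end = 100)), c(0, 100))
  split <- solve_surface(ls, spec, two_epochs(spec,
      list(s = 0.03, sigma_x2 = 25, sigma_y2 = 25),
      list(s = 0.03, sigma_x2 = 25, sigma_y2 = 25)), c(0, 100))
  expect_lt(max(abs(one$p - split$p)), 1e-7)
})

test_that("frequency_at interpolates in time and enforces the age precondition", {
  ls <- tiny_landscape(8)
  spec <- model_spec("B", 400 * 29, origin_cell = c(4, 4),
                     epoch_boundary_years_bp = 0)
  epochs <- list(epoch_params(0.03, 30, t_start = 0, t_end = 400))
  surf <- solve_surface(ls, spec, epochs, output_times = seq(0, 400, 20))
  oc <- cell_center(ls, 4, 4)

  p0 <- initial_surface(ls, spec)[4, 4]
  expect_equal(frequency_at(surf, oc["lat"], oc["lon"], 400 * 29), p0)
  expect_equal(frequency_at(surf, oc["lat"], oc["lon"], 0),
               surf$p[surf$land_index$idx[4, 4], ncol(surf$p)])
  expect_error(frequency_at(surf, oc["lat"], oc["lon"], 400 * 29 + 1),
               "predates")
  expect_equal(frequency_at(surf, oc["lat"], oc["lon"], 400 * 29 + 1,
                            clamp_old = TRUE), p0)

  # refining the stored time grid only moves values by interpolation error,
  # which shrinks quadratically with the storage step
  mid <- solve_surface(ls, spec, epochs, output_times = seq(0, 400, 10))
  fine <- solve_surface(ls, spec, epochs, output_times = seq(0, 400, 2))
  ages <- c(29 * 33, 29 * 150.5, 29 * 399)
  for (a in ages) {
    f_fine <- frequency_at(fine, oc["lat"], oc["lon"], a)
    err_coarse <- abs(frequency_at(surf, oc["lat"], oc["lon"], a) - f_fine)
    err_mid <- abs(frequency_at(mid, oc["lat"], oc["lon"], a) - f_fine)
    expect_lt(err_coarse, 5e-3)
    expect_lte(err_mid, err_coarse + 1e-12)
  }
})
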