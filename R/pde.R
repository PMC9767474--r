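#' Epoch-wise spread parameters
#'
#' One set of spread parameters, valid over an interval of generations since
#' the allele's origin. Dispersal is parameterized by sigma_x^2 and sigma_y^2
#' in km^2 per generation (the quantity entering the PDE as
#' \eqn{\tfrac12\sigma^2 \partial^2 p/\partial x^2}); advection velocities are
#' in km per generation.
#'
#' @param s Selection coefficient per generation.
#' @param sigma_x2,sigma_y2 Longitudinal / latitudinal dispersal rates,
#'   km^2 per generation.
#' @param v_x,v_y Advection velocities, km per generation.
#' @param t_start,t_end Validity interval in generations since origin.
#' @param d Dominance coefficient; `NULL` (default) applies the additive rule
#'   d = 2s at every evaluation of the reaction term.
#' @return An `aw_epoch_params`.
#' @export
epoch_params <- function(s, sigma_x2, sigma_y2 = sigma_x2, v_x = 0, v_y = 0,
                         t_start = 0, t_end = Inf, d = NULL) {
  stopifnot(t_start < t_end, sigma_x2 >= 0, sigma_y2 >= 0)
  structure(list(s = s, d = if (is.null(d)) 2 * s else d,
                 sigma_x2 = sigma_x2, sigma_y2 = sigma_y2,
                 v_x = v_x, v_y = v_y, t_start = t_start, t_end = t_end),
            class = "aw_epoch_params")
}

#' Model specification for one allele
#'
#' Fixed, non-fitted quantities of the spread model: the variant (A, B, or C),
#' the allele age used to anchor the time axis, the generation time, the
#' origin cell, the epoch boundary at which spread parameters may change, and
#' the founder population density used to set the initial frequency
#' p0 = 1 / (2 D A) (one chromosome among 2 D A in the origin cell of area A).
#'
#' @param variant `"A"` (isotropic diffusion), `"B"` (anisotropic diffusion),
#'   or `"C"` (anisotropic diffusion + advection).
#' @param allele_age_years_bp Age of the allele in years before present.
#' @param origin_cell Integer `c(row, col)` of the origin cell (must be land).
#' @param generation_time Years per generation (default 29).
#' @param epoch_boundary_years_bp Time at which spread parameters may change
#'   (default 5000 years BP); must lie within `[0, allele_age_years_bp]`.
#' @param founder_density_D Population density, individuals per km^2
#'   (default 2.5).
#' @return An `aw_model_spec`.
#' @export
model_spec <- function(variant = c("B", "A", "C"), allele_age_years_bp,
                       origin_cell, generation_time = 29,
                       epoch_boundary_years_bp = 5000,
                       founder_density_D = 2.5) {
  variant <- match.arg(variant)
  stopifnot(allele_age_years_bp > 0, founder_density_D > 0,
            generation_time > 0)
  if (epoch_boundary_years_bp < 0 ||
      epoch_boundary_years_bp > allele_age_years_bp)
    stop("epoch boundary must lie within [0, allele age]")
  structure(list(variant = variant,
                 allele_age_years_bp = allele_age_years_bp,
                 origin_cell = as.integer(origin_cell),
                 generation_time = generation_time,
                 epoch_boundary_years_bp = epoch_boundary_years_bp,
                 founder_density_D = founder_density_D),
            class = "aw_model_spec")
}

#' Local allele-frequency growth rate
#'
#' The reaction term gamma(p, s, d) = p (1 - p) (p d + s (1 - 2 p)). With the
#' additive rule d = 2s this reduces to logistic growth s p (1 - p).
#'
#' @param p Allele frequency in `[0, 1]` (vectorized).
#' @param s Selection coefficient.
#' @param d Dominance coefficient (default `2 * s`, additive).
#' @param tol Tolerance on the `[0, 1]` precondition.
#' @return Growth rate per generation.
#' @export
reaction_term <- function(p, s, d = 2 * s, tol = 1e-8) {
  if (any(p < -tol | p > 1 + tol))
    stop("frequency outside [0, 1] beyond tolerance")
  p * (1 - p) * (p * d + s * (1 - 2 * p))
}

#' Evaluate the spatial operator once
#'
#' Single evaluation of the semi-discrete right-hand side
#' \eqn{\tfrac12\sigma_x^2 p_{xx} + \tfrac12\sigma_y^2 p_{yy}
#'      + v_x p_x + v_y p_y + \gamma(p, s, d)}
#' on the land cells of a landscape (second-order central diffusion,
#' first-order upwind advection; no flux across land-water interfaces,
#' absorbing ghost cells beyond the map edge). Mainly useful for testing the
#' discretization against stencil oracles.
#'
#' @param state Numeric matrix (`n_rows x n_cols`) of frequencies; water
#'   entries are ignored. Or a vector over land cells in land-index order.
#' @param params An `aw_epoch_params`.
#' @param landscape An `aw_landscape`.
#' @return Matrix of time derivatives (NA on water), same shape as the
#'   landscape grid.
#' @export
spatial_operator <- function(state, params, landscape) {
  li <- land_index(landscape)
  if (is.matrix(state)) {
    v <- state[landscape$land]
  } else {
    v <- state
  }
  if (any(!is.finite(v))) stop("non-finite values in state")
  dv <- pde_rhs_cpp(v, li$nb, li$dx, li$dy, li$wS, li$wN, params$s,
                    params$d, params$sigma_x2, params$sigma_y2, params$v_x,
                    params$v_y)
  out <- matrix(NA_real_, landscape$n_rows, landscape$n_cols)
  out[landscape$land] <- dv
  out
}

#' Initial frequency field
#'
#' Places the founder frequency p0 = 1 / (2 D A) in the origin cell (A = that
#' cell's area in km^2, D the founder density) and 0 elsewhere.
#'
#' @param landscape An `aw_landscape`.
#' @param spec An `aw_model_spec`.
#' @return Matrix (`n_rows x n_cols`): p0 at the origin, 0 on other land
#'   cells, NA on water.
#' @export
initial_surface <- function(landscape, spec) {
  oc <- spec$origin_cell
  if (!landscape$land[oc[1], oc[2]])
    stop("origin cell is water")
  p0 <- 1 / (2 * spec$founder_density_D * landscape$area_km2[oc[1]])
  out <- matrix(NA_real_, landscape$n_rows, landscape$n_cols)
  out[landscape$land] <- 0
  out[oc[1], oc[2]] <- p0
  out
}

#' Solve the allele-frequency surface
#'
#' Method-of-lines integration of the diffusion-advection-reaction PDE from
#' the allele's origin (time 0, initial field from [initial_surface()] unless
#' overridden) to the last requested output time, with epoch-wise parameters.
#' The state is continuous across epoch boundaries. Values are clipped to
#' `[0, 1]` post hoc (the pre-clip overshoot is retained as a diagnostic);
#' water cells are NA in the output.
#'
#' @param landscape An `aw_landscape`.
#' @param spec An `aw_model_spec`.
#' @param epochs List of `aw_epoch_params` tiling `[0, T]` (T = allele age in
#'   generations) without gaps or overlaps, in order.
#' @param output_times Generations since origin at which to store the surface
#'   (ascending). Default: ~every 5 generations plus the endpoint.
#' @param init Optional initial field (matrix or land-cell vector) replacing
#'   the point initial condition — used by validation tests.
#' @param rtol,atol Integrator relative/absolute tolerances.
#' @param time_scale Internal non-dimensionalization factor: time is divided
#'   and rates multiplied by this factor before integration. Results are
#'   invariant to it (up to integrator tolerance); exposed for testing.
#' @param max_steps Step budget for the integrator.
#' @param method `"dopri"` (default): adaptive Dormand-Prince 5(4) honoring
#'   `rtol`/`atol`. `"adi"`: unconditionally stable alternating-direction
#'   implicit stepping with Strang-split reaction — much faster when
#'   dispersal rates are large enough to make the explicit stability step
#'   tiny, at fixed O(dt^2) accuracy.
#' @param adi_dt Time step in generations for `method = "adi"` (default 0.5;
#'   the first `init_refine` generations are substepped 8x to resolve the
#'   point-mass initial condition).
#' @param init_refine See `adi_dt`.
#' @return An `aw_surface`: list with `landscape`, `times` (generations),
#'   `p` (matrix `n_land x n_times`), `land_index`, `spec`, and diagnostics
#'   `overshoot` (max excursion outside `[0, 1]` pre-clip) and `steps`.
#' @export
solve_surface <- function(landscape, spec, epochs, output_times = NULL,
                          init = NULL, rtol = 1e-6, atol = 1e-8,
                          time_scale = 1, max_steps = 1e6,
                          method = c("dopri", "adi"), adi_dt = 0.5,
                          init_refine = 20) {
  method <- match.arg(method)
  t_total <- spec$allele_age_years_bp / spec$generation_time
  if (is.null(output_times))
    output_times <- unique(c(seq(0, t_total, by = 5), t_total))
  output_times <- sort(output_times)
  if (min(output_times) < 0 || max(output_times) > t_total + 1e-9)
    stop("output times outside [0, allele age] in generations")

  # epochs must tile [0, t_last]
  t_last <- max(output_times)
  ep <- epochs[order(vapply(epochs, `[[`, 0, "t_start"))]
  starts <- vapply(ep, `[[`, 0, "t_start")
  ends <- pmin(vapply(ep, `[[`, 0, "t_end"), t_last)
  if (abs(starts[1]) > 1e-9) stop("first epoch must start at 0")
  if (length(ep) > 1 &&
      any(abs(starts[-1] - ends[-length(ends)]) > 1e-9))
    stop("epochs have gaps or overlaps")
  if (ends[length(ends)] < t_last - 1e-9)
    stop("epochs do not cover the requested time span")

  li <- land_index(landscape)
  if (is.null(init)) {
    p0m <- initial_surface(landscape, spec)
    p0 <- p0m[landscape$land]
  } else if (is.matrix(init)) {
    p0 <- init[landscape$land]
  } else {
    p0 <- init
  }

  emat <- do.call(rbind, lapply(seq_along(ep), function(i) {
    e <- ep[[i]]
    c(e$s, e$d, e$sigma_x2, e$sigma_y2, e$v_x, e$v_y, starts[i], ends[i])
  }))
  # non-dimensionalization: t' = t / k, rates scale by k
  k <- time_scale
  emat_s <- emat
  emat_s[, 1:6] <- emat_s[, 1:6] * k
  emat_s[, 7:8] <- emat_s[, 7:8] / k

  res <- if (method == "dopri") {
    pde_solve_cpp(p0, li$nb, li$dx, li$dy, li$wS, li$wN, emat_s,
                  output_times / k, rtol, atol, max_steps)
  } else {
    pde_solve_adi_cpp(p0, li$nb, li$dx, li$dy, li$wS, li$wN,
                      li$row_runs$cells, li$row_runs$lens,
                      li$col_runs$cells, li$col_runs$lens,
                      emat_s, output_times / k, adi_dt / k, init_refine / k)
  }
  if (!isTRUE(res$success))
    stop("PDE integration failed: ", res$message,
         sprintf(" (steps = %g)", res$steps))
  p <- res$p
  overshoot <- max(0, max(p) - 1, -min(p))
  if (overshoot > 1e-3)
    warning(sprintf("solution left [0,1] by %.3g before clipping", overshoot))
  p[p < 0] <- 0
  p[p > 1] <- 1
  structure(list(landscape = landscape, times = output_times, p = p,
                 land_index = li, spec = spec, epochs = ep,
                 overshoot = overshoot, steps = res$steps),
            class = "aw_surface")
}

#' @export
print.aw_surface <- function(x, ...) {
  cat(sprintf(
    "aw_surface: %d land cells x %d times (0..%.1f generations), max p = %.4g\n",
    nrow(x$p), length(x$times), max(x$times), max(x$p)))
  invisible(x)
}

#' Surface as a frequency matrix at one stored time
#' @param surface An `aw_surface`.
#' @param time_index Column index into the stored time axis.
#' @return Matrix (`n_rows x n_cols`), NA on water.
#' @export
surface_slice <- function(surface, time_index) {
  ls <- surface$landscape
  out <- matrix(NA_real_, ls$n_rows, ls$n_cols)
  out[ls$land] <- surface$p[, time_index]
  out
}

#' Frequency at a dated, geolocated sample
#'
#' Looks up (with water-to-land snapping) the cell containing the point and
#' interpolates the stored surface linearly in time at
#' t = (allele_age - age) / generation_time generations since origin.
#'
#' @param surface An `aw_surface`.
#' @param lat,lon Sample location, degrees.
#' @param age_years_bp Sample age in years before present.
#' @param snap_radius Passed to [locate()].
#' @param clamp_old If `TRUE`, samples older than the allele are clamped to
#'   the origin time instead of erroring.
#' @return Frequency in `[0, 1]`.
#' @export
frequency_at <- function(surface, lat, lon, age_years_bp, snap_radius = 1,
                         clamp_old = FALSE) {
  spec <- surface$spec
  t <- (spec$allele_age_years_bp - age_years_bp) / spec$generation_time
  if (t < -1e-9) {
    if (clamp_old) t <- 0
    else stop(sprintf("sample age %g years BP predates the allele (%g years BP)",
                      age_years_bp, spec$allele_age_years_bp))
  }
  t <- max(t, 0)
  rc <- locate(surface$landscape, lat, lon, snap_radius)
  k <- surface$land_index$idx[rc[1], rc[2]]
  interp_time(surface$p[k, ], surface$times, t)
}

# linear interpolation on the stored time axis; constant extrapolation at ends
interp_time <- function(v, times, t) {
  if (t <= times[1]) return(v[1])
  n <- length(times)
  if (t >= times[n]) return(v[n])
  i <- findInterval(t, times)
  w <- (t - times[i]) / (times[i + 1] - times[i])
  (1 - w) * v[i] + w * v[i + 1]
}

# Epochs for a two-epoch scheme from a spec and per-epoch parameter list.
# boundary is converted to generations since origin.
two_epochs <- function(spec, params1, params2) {
  t_total <- spec$allele_age_years_bp / spec$generation_time
  t_b <- (spec$allele_age_years_bp - spec$epoch_boundary_years_bp) /
    spec$generation_time
  if (t_b <= 0 || t_b >= t_total) {
    # boundary coincides with an endpoint: single epoch
    return(list(do.call(epoch_params,
                        c(params1, list(t_start = 0, t_end = t_total)))))
  }
  list(do.call(epoch_params, c(params1, list(t_start = 0, t_end = t_b))),
       do.call(epoch_params, c(params2, list(t_start = t_b, t_end = t_total))))
}
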