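#' Box constraints for the fitted parameters
#'
#' Default search ranges: selection coefficient 0.001-0.1 per generation,
#' dispersal rates 1-100 km^2 per generation per axis, and advection
#' velocities -2.5 to 2.5 km per generation per axis (a narrow range around
#' zero acting as regularization).
#'
#' @param s Length-2 range for the selection coefficient.
#' @param sigma2 Length-2 range for sigma_x^2 / sigma_y^2 (km^2/generation).
#' @param v Length-2 range for v_x / v_y (km/generation).
#' @return An `aw_bounds`.
#' @export
parameter_bounds <- function(s = c(0.001, 0.1), sigma2 = c(1, 100),
                             v = c(-2.5, 2.5)) {
  for (b in list(s, sigma2, v))
    if (length(b) != 2 || b[1] >= b[2]) stop("each bound must be (lower < upper)")
  structure(list(s = s, sigma2 = sigma2, v = v), class = "aw_bounds")
}

# free parameters per epoch for each model variant
param_layout <- function(variant) {
  switch(variant,
         A = c("s", "sigma2"),
         B = c("s", "sigma_x2", "sigma_y2"),
         C = c("s", "sigma_x2", "sigma_y2", "v_x", "v_y"))
}

# lower/upper vectors for a full theta (all epochs), with epoch-prefixed names
theta_bounds <- function(variant, n_epochs, bounds) {
  per <- param_layout(variant)
  lower <- upper <- numeric(0)
  nms <- character(0)
  for (e in seq_len(n_epochs)) {
    for (p in per) {
      rng <- if (p == "s") bounds$s else if (startsWith(p, "sigma"))
        bounds$sigma2 else bounds$v
      lower <- c(lower, rng[1]); upper <- c(upper, rng[2])
      nms <- c(nms, sprintf("e%d_%s", e, p))
    }
  }
  names(lower) <- names(upper) <- nms
  list(lower = lower, upper = upper, names = nms, per_epoch = per)
}

# theta vector -> list of aw_epoch_params tiling [0, T]
theta_to_epochs <- function(theta, variant, spec) {
  per <- param_layout(variant)
  k <- length(per)
  n_epochs <- length(theta) / k
  stopifnot(n_epochs == round(n_epochs))
  mk <- function(v) {
    p <- as.list(v); names(p) <- per
    if (variant == "A")
      list(s = p$s, sigma_x2 = p$sigma2, sigma_y2 = p$sigma2)
    else if (variant == "B")
      list(s = p$s, sigma_x2 = p$sigma_x2, sigma_y2 = p$sigma_y2)
    else
      list(s = p$s, sigma_x2 = p$sigma_x2, sigma_y2 = p$sigma_y2,
           v_x = p$v_x, v_y = p$v_y)
  }
  plist <- lapply(seq_len(n_epochs), function(e) mk(theta[((e - 1) * k + 1):(e * k)]))
  if (n_epochs == 1) {
    t_total <- spec$allele_age_years_bp / spec$generation_time
    list(do.call(epoch_params, c(plist[[1]], list(t_start = 0, t_end = t_total))))
  } else if (n_epochs == 2) {
    two_epochs(spec, plist[[1]], plist[[2]])
  } else stop("only one- or two-epoch parameterizations are supported")
}

#' Latin hypercube starting points
#'
#' Stratified multistart draws: in every dimension the n points occupy the n
#' equal-width strata exactly once, in a randomly permuted order, uniformly
#' within each stratum. Reproducible given a seed.
#'
#' @param lower,upper Named bound vectors (see [parameter_bounds()] /
#'   internal layout), or an `aw_bounds` plus `variant`/`n_epochs` via
#'   [fit()].
#' @param n Number of starting points.
#' @param seed Integer seed.
#' @return An `n x d` matrix, one start per row.
#' @export
lhs_starts <- function(lower, upper, n, seed = 1) {
  stopifnot(n >= 1, length(lower) == length(upper))
  if (any(lower >= upper)) stop("invalid bounds: lower must be < upper")
  d <- length(lower)
  out <- matrix(0, n, d)
  r <- local_rng(seed)
  for (j in seq_len(d)) {
    strata <- r$sample_int(n)
    u <- r$runif(n)
    out[, j] <- lower[j] + (strata - 1 + u) / n * (upper[j] - lower[j])
  }
  colnames(out) <- names(lower)
  out
}

# self-contained RNG stream (does not disturb the global .Random.seed)
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    sample_int = function(n, size = n) with_state(function() sample.int(n, size)),
    with_state = with_state
  )
}

# Default origin candidate set: a coarse lattice over land cells (every
# `stride`-th row and column), mirroring the paper's fixed set of candidate
# origin points, whose exact locations are not published.
#' Origin candidate lattice
#' @param landscape An `aw_landscape`.
#' @param stride Keep every `stride`-th row/column (default 5).
#' @return Integer matrix of candidate (row, col) land cells.
#' @export
origin_lattice <- function(landscape, stride = 5) {
  rows <- seq(ceiling(stride / 2), landscape$n_rows, by = stride)
  cols <- seq(ceiling(stride / 2), landscape$n_cols, by = stride)
  cand <- as.matrix(expand.grid(row = rows, col = cols))
  cand <- cand[landscape$land[cand], , drop = FALSE]
  if (nrow(cand) == 0) stop("no land cells in the candidate lattice")
  storage.mode(cand) <- "integer"
  cand
}

# Cells holding the oldest observations that carry the derived allele:
# natural extra origin candidates, since the inferred origin tends to track
# the earliest appearance of the derived allele in the data.
oldest_derived_cells <- function(data, landscape, snap_radius = 1, k = 5) {
  obs <- data$observations
  derived <- vapply(obs, function(o) switch(o$kind,
    pseudohaploid = o$allele == 1L,
    diploid_genotype = o$genotype >= 1L,
    genotype_likelihood = which.max(o$gl) > 1), TRUE)
  cand <- obs[derived]
  if (length(cand) == 0) return(matrix(integer(0), 0, 2))
  ages <- vapply(cand, `[[`, 0, "age_years_bp")
  cand <- cand[order(ages, decreasing = TRUE)]
  cells <- lapply(utils::head(cand, k), function(o)
    tryCatch(locate(landscape, o$lat, o$lon, snap_radius),
             error = function(e) NULL))
  cells <- cells[!vapply(cells, is.null, TRUE)]
  if (length(cells) == 0) return(matrix(integer(0), 0, 2))
  m <- do.call(rbind, cells)
  storage.mode(m) <- "integer"
  unique(m)
}

# Build the likelihood closure used by all optimizer layers: returns
# function(theta, origin_rc) -> log-likelihood. Observation contexts and the
# land index are computed once.
make_loglik_fn <- function(data, landscape, spec, output_dt = 5,
                           snap_radius = 1, clamp_old = FALSE,
                           rtol = 1e-6, atol = 1e-8,
                           method = "dopri", adi_dt = 0.5) {
  ctx <- make_contexts(data, landscape, spec, snap_radius, clamp_old)
  t_total <- spec$allele_age_years_bp / spec$generation_time
  times <- unique(c(seq(0, t_total, by = output_dt), t_total))
  function(theta, origin_rc) {
    sp <- spec
    sp$origin_cell <- as.integer(origin_rc)
    epochs <- theta_to_epochs(theta, spec$variant, sp)
    surf <- tryCatch(
      suppressWarnings(solve_surface(landscape, sp, epochs,
                                     output_times = times,
                                     rtol = rtol, atol = atol,
                                     method = method, adi_dt = adi_dt)),
      error = function(e) NULL)
    if (is.null(surf)) return(-Inf)
    contexts_loglik(ctx, surf)
  }
}

#' Simulated-annealing search layer
#'
#' First optimization layer: from each multistart point (with a random origin
#' from the candidate set), a simulated-annealing chain with geometric cooling
#' explores the continuous parameters (Gaussian proposals scaled to a fraction
#' of each bound range, reflected into the box) and the discrete origin
#' (jumps within the candidate set). The returned incumbent is the best
#' (origin, parameters) pair ever evaluated, so it is never worse than the
#' best start.
#'
#' @param data An `aw_dataset`.
#' @param landscape An `aw_landscape`.
#' @param spec An `aw_model_spec` (its `origin_cell` is ignored; the origin is
#'   searched over `origin_candidates`).
#' @param starts Matrix of starting parameter vectors (rows), e.g. from
#'   [lhs_starts()].
#' @param origin_candidates Integer matrix of candidate (row, col) cells, all
#'   land; e.g. [origin_lattice()].
#' @param bounds An `aw_bounds`.
#' @param seed Integer seed.
#' @param control List: `iters` SA iterations per start (default 200); `cool`
#'   geometric cooling ratio (default `NA` = derived so the temperature
#'   reaches `t_end_frac` (1e-3) of its initial value by the last iteration);
#'   `prop_frac` proposal SD as a fraction of each bound range (0.05);
#'   `origin_prob` probability of proposing an origin jump (0.2); plus
#'   `output_dt`, `snap_radius`, `clamp_old`, `method`, `adi_dt` for the
#'   likelihood.
#' @param loglik_fn Optional precomputed closure from `make_loglik_fn`
#'   (internal use).
#' @return List: `theta`, `origin` (row, col), `loglik`, `n_eval`, `trace`.
#' @export
anneal_fit <- function(data, landscape, spec, starts, origin_candidates,
                       bounds = parameter_bounds(), seed = 1,
                       control = list(), loglik_fn = NULL) {
  ctl <- utils::modifyList(list(iters = 200, cool = NA, t_end_frac = 1e-3,
                                prop_frac = 0.05,
                                origin_prob = 0.2, output_dt = 5,
                                snap_radius = 1, clamp_old = FALSE,
                                method = "dopri", adi_dt = 0.5), control)
  if (nrow(origin_candidates) == 0) stop("empty origin candidate set")
  if (!all(landscape$land[origin_candidates]))
    stop("origin candidates must all be land cells")
  n_epochs <- n_epochs_of(spec)
  tb <- theta_bounds(spec$variant, n_epochs, bounds)
  if (ncol(starts) != length(tb$lower))
    stop(sprintf("starts have %d columns; variant %s with %d epoch(s) needs %d",
                 ncol(starts), spec$variant, n_epochs, length(tb$lower)))
  if (is.null(loglik_fn))
    loglik_fn <- make_loglik_fn(data, landscape, spec,
                                output_dt = ctl$output_dt,
                                snap_radius = ctl$snap_radius,
                                clamp_old = ctl$clamp_old,
                                method = ctl$method, adi_dt = ctl$adi_dt)
  r <- local_rng(seed)
  n_cand <- nrow(origin_candidates)
  n_start <- nrow(starts)

  start_origin <- origin_candidates[
    ceiling(r$runif(n_start) * n_cand), , drop = FALSE]
  start_ll <- vapply(seq_len(n_start), function(i)
    loglik_fn(starts[i, ], start_origin[i, ]), 0)
  n_eval <- n_start
  if (all(!is.finite(start_ll)))
    stop("all starting points have zero likelihood; data incompatible ",
         "with every candidate origin at this allele age")

  # initial temperature from the spread of finite start log-likelihoods;
  # geometric cooling reaches t_end_frac * T0 by the end of each chain, so
  # short chains still anneal fully
  spread <- stats::sd(start_ll[is.finite(start_ll)])
  T0 <- if (is.finite(spread) && spread > 0) spread else 1
  cool <- if (is.na(ctl$cool)) ctl$t_end_frac^(1 / ctl$iters) else ctl$cool

  best_i <- which.max(start_ll)
  best <- list(theta = starts[best_i, ], origin = start_origin[best_i, ],
               loglik = start_ll[best_i])
  rng_width <- tb$upper - tb$lower
  trace <- numeric(n_start)

  for (i in seq_len(n_start)) {
    cur_theta <- starts[i, ]
    cur_origin <- start_origin[i, ]
    cur_ll <- start_ll[i]
    temp <- T0
    for (it in seq_len(ctl$iters)) {
      prop_theta <- cur_theta + r$rnorm(length(cur_theta)) *
        ctl$prop_frac * rng_width
      prop_theta <- reflect_into(prop_theta, tb$lower, tb$upper)
      prop_origin <- cur_origin
      if (r$runif(1) < ctl$origin_prob)
        prop_origin <- origin_candidates[ceiling(r$runif(1) * n_cand), ]
      prop_ll <- loglik_fn(prop_theta, prop_origin)
      n_eval <- n_eval + 1
      accept <- is.finite(prop_ll) &&
        (prop_ll >= cur_ll || r$runif(1) < exp((prop_ll - cur_ll) / temp))
      if (accept) {
        cur_theta <- prop_theta; cur_origin <- prop_origin; cur_ll <- prop_ll
        if (cur_ll > best$loglik)
          best <- list(theta = cur_theta, origin = cur_origin, loglik = cur_ll)
      }
      temp <- temp * cool
    }
    trace[i] <- cur_ll
  }
  names(best$theta) <- tb$names
  best$n_eval <- n_eval
  best$trace <- trace
  best$start_loglik <- start_ll
  best
}

reflect_into <- function(x, lower, upper) {
  w <- upper - lower
  y <- (x - lower) %% (2 * w)
  lower + ifelse(y > w, 2 * w - y, y)
}

n_epochs_of <- function(spec) {
  b <- spec$epoch_boundary_years_bp
  if (b <= 0 || b >= spec$allele_age_years_bp) 1L else 2L
}

#' Bounded quasi-Newton refinement layer
#'
#' Second optimization layer: L-BFGS-B over the continuous parameters with the
#' origin fixed at the incumbent's origin (the origin lives on a discrete
#' grid, so it is not explored here). If the line search fails or returns a
#' worse point, the incumbent is returned with a `refine_failed` flag.
#'
#' @param data,landscape,spec,bounds As in [anneal_fit()].
#' @param incumbent List with `theta`, `origin`, `loglik` (from
#'   [anneal_fit()]).
#' @param control List: `maxit` (default 100), `factr` (1e8), plus likelihood
#'   options as in [anneal_fit()].
#' @param loglik_fn Optional precomputed closure (internal use).
#' @return List: `theta`, `origin`, `loglik`, `convergence`, `at_boundary`
#'   (logical per parameter), `refine_failed`.
#' @export
refine_fit <- function(data, landscape, spec, incumbent,
                       bounds = parameter_bounds(), control = list(),
                       loglik_fn = NULL) {
  ctl <- utils::modifyList(list(maxit = 100, factr = 1e8, output_dt = 5,
                                snap_radius = 1, clamp_old = FALSE,
                                method = "dopri", adi_dt = 0.5), control)
  if (!is.finite(incumbent$loglik))
    stop("incumbent has non-finite log-likelihood")
  n_epochs <- n_epochs_of(spec)
  tb <- theta_bounds(spec$variant, n_epochs, bounds)
  if (is.null(loglik_fn))
    loglik_fn <- make_loglik_fn(data, landscape, spec,
                                output_dt = ctl$output_dt,
                                snap_radius = ctl$snap_radius,
                                clamp_old = ctl$clamp_old,
                                method = ctl$method, adi_dt = ctl$adi_dt)
  origin <- incumbent$origin
  neg <- function(th) {
    v <- loglik_fn(th, origin)
    if (!is.finite(v)) 1e12 else -v
  }
  res <- tryCatch(
    stats::optim(incumbent$theta, neg, method = "L-BFGS-B",
                 lower = tb$lower, upper = tb$upper,
                 control = list(maxit = ctl$maxit, factr = ctl$factr,
                                parscale = tb$upper - tb$lower)),
    error = function(e) NULL)
  failed <- is.null(res) || -res$value < incumbent$loglik
  theta <- if (failed) incumbent$theta else res$par
  ll <- if (failed) incumbent$loglik else -res$value
  names(theta) <- tb$names
  at_b <- theta <= tb$lower + 1e-10 | theta >= tb$upper - 1e-10
  names(at_b) <- tb$names
  list(theta = theta, origin = origin, loglik = ll,
       convergence = if (is.null(res)) NA_integer_ else res$convergence,
       at_boundary = at_b, refine_failed = failed)
}

# Generic Fisher-information CIs from any log-likelihood function:
# numerical Hessian by symmetrized central differences with per-parameter
# relative step, F = -H, CI = theta +- z sqrt(diag(F^-1)).
fisher_ci_from_loglik <- function(loglik, theta, rel_step = 1e-3,
                                  level = 0.95) {
  d <- length(theta)
  h <- pmax(abs(theta) * rel_step, 1e-8)
  H <- matrix(NA_real_, d, d)
  f0 <- loglik(theta)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h[i])
    H[i, i] <- (loglik(theta + ei) - 2 * f0 + loglik(theta - ei)) / h[i]^2
    if (i < d) for (j in (i + 1):d) {
      ej <- replace(numeric(d), j, h[j])
      H[i, j] <- H[j, i] <-
        (loglik(theta + ei + ej) - loglik(theta + ei - ej) -
         loglik(theta - ei + ej) + loglik(theta - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H <- (H + t(H)) / 2
  z <- stats::qnorm(1 - (1 - level) / 2)
  Finfo <- -H
  inv <- tryCatch(solve(Finfo), error = function(e) NULL)
  se <- rep(NaN, d)
  ok <- FALSE
  if (!is.null(inv)) {
    dg <- diag(inv)
    if (all(is.finite(dg)) && all(dg > 0)) { se <- sqrt(dg); ok <- TRUE }
  }
  if (!ok)
    warning("observed Fisher information not positive definite; ",
            "confidence intervals reported as NaN")
  cbind(estimate = theta, lower = theta - z * se, upper = theta + z * se,
        se = se)
}

#' Asymptotic confidence intervals from the observed Fisher information
#'
#' 95% (by default) Wald intervals
#' \eqn{\hat\theta_j \pm z \sqrt{(F(\hat\theta)^{-1})_{jj}}} where F is the
#' negative numerical Hessian of the log-likelihood at the estimate
#' (symmetrized central differences, relative step `rel_step`). A
#' non-positive-definite F yields NaN intervals with a warning rather than
#' fabricated bounds.
#'
#' @param data,landscape,spec As in [anneal_fit()]; the spec's `origin_cell`
#'   is used (fix it to the fitted origin).
#' @param theta_hat Named parameter vector at the maximum.
#' @param rel_step Relative step for the numerical Hessian (default 1e-3).
#' @param level Confidence level (default 0.95).
#' @param control Likelihood options (`output_dt`, `snap_radius`,
#'   `clamp_old`).
#' @return Matrix with columns estimate, lower, upper, se; one row per
#'   parameter.
#' @export
fisher_confints <- function(data, landscape, spec, theta_hat,
                            rel_step = 1e-3, level = 0.95, control = list()) {
  ctl <- utils::modifyList(list(output_dt = 5, snap_radius = 1,
                                clamp_old = FALSE,
                                method = "dopri", adi_dt = 0.5), control)
  loglik_fn <- make_loglik_fn(data, landscape, spec,
                              output_dt = ctl$output_dt,
                              snap_radius = ctl$snap_radius,
                              clamp_old = ctl$clamp_old,
                              method = ctl$method, adi_dt = ctl$adi_dt)
  origin <- spec$origin_cell
  fisher_ci_from_loglik(function(th) loglik_fn(th, origin), theta_hat,
                        rel_step = rel_step, level = level)
}

#' Fit the spread model by maximum likelihood
#'
#' Full two-layer pipeline: Latin hypercube starting points, simulated
#' annealing over parameters and the discrete allele origin, L-BFGS-B
#' refinement with the origin fixed, and Fisher-information confidence
#' intervals. With a two-epoch spec the fit is joint: a single likelihood
#' over all data with epoch-wise parameters and one PDE solve per evaluation.
#'
#' @param data An `aw_dataset`.
#' @param landscape An `aw_landscape`.
#' @param spec An `aw_model_spec`; its `origin_cell` is the fallback if
#'   `origin_candidates` has a single row, otherwise the origin is estimated.
#' @param bounds An `aw_bounds`.
#' @param config List of optimizer settings: `n_starts` (default 50), `seed`,
#'   `origin_candidates` (matrix; default [origin_lattice()]),
#'   `sa` (control list for [anneal_fit()]), `refine` (control list for
#'   [refine_fit()]), `ci` (`TRUE`/`FALSE`, default TRUE), `output_dt`,
#'   `snap_radius`, `clamp_old`, `method`/`adi_dt` (PDE solver, see
#'   [solve_surface()]), `augment_origins` (default TRUE: add the cells
#'   of the oldest derived-allele observations to the origin candidates),
#'   `origin_polish`/`polish_rounds`/`polish_maxit` (default TRUE/4/NULL:
#'   after refinement, walk the origin over nearby land cells, re-refining
#'   after each move, optionally at reduced `maxit`), and
#'   `screen_origins`/`screen_keep` (default TRUE/8: pre-rank all candidate
#'   origins by a single mid-bounds likelihood sweep and anneal only over
#'   the best few).
#' @return An `aw_fit`: per-epoch estimates, origin, log-likelihood, CI
#'   table, and optimizer trace metadata.
#' @export
fit <- function(data, landscape, spec, bounds = parameter_bounds(),
                config = list()) {
  stopifnot(inherits(data, "aw_dataset"), length(data) >= 1)
  cfg <- utils::modifyList(
    list(n_starts = 50, seed = 1, origin_candidates = NULL,
         sa = list(), refine = list(), ci = TRUE, output_dt = 5,
         snap_radius = 1, clamp_old = FALSE, augment_origins = TRUE,
         origin_polish = TRUE, polish_rounds = 4, polish_maxit = NULL,
         screen_origins = TRUE, screen_keep = 8,
         method = "dopri", adi_dt = 0.5), config)
  if (is.null(cfg$origin_candidates))
    cfg$origin_candidates <- origin_lattice(landscape)
  if (isTRUE(cfg$augment_origins)) {
    extra <- oldest_derived_cells(data, landscape, cfg$snap_radius)
    cfg$origin_candidates <- unique(rbind(cfg$origin_candidates, extra))
  }
  n_epochs <- n_epochs_of(spec)
  tb <- theta_bounds(spec$variant, n_epochs, bounds)

  loglik_fn <- make_loglik_fn(data, landscape, spec,
                              output_dt = cfg$output_dt,
                              snap_radius = cfg$snap_radius,
                              clamp_old = cfg$clamp_old,
                              method = cfg$method, adi_dt = cfg$adi_dt)

  # origin screening: one cheap likelihood sweep over all candidate origins
  # at a mid-bounds parameter vector, keeping the best few (plus the
  # data-derived candidates) for the annealing layer — concentrates the
  # discrete search where the spatial pattern of the data supports an origin
  if (isTRUE(cfg$screen_origins) &&
      nrow(cfg$origin_candidates) > cfg$screen_keep) {
    theta_mid <- (tb$lower + tb$upper) / 2
    screen_ll <- vapply(seq_len(nrow(cfg$origin_candidates)), function(i)
      loglik_fn(theta_mid, cfg$origin_candidates[i, ]), 0)
    keep <- order(screen_ll, decreasing = TRUE)[seq_len(cfg$screen_keep)]
    kept <- cfg$origin_candidates[keep, , drop = FALSE]
    if (isTRUE(cfg$augment_origins)) {
      extra <- oldest_derived_cells(data, landscape, cfg$snap_radius)
      kept <- unique(rbind(kept, extra))
    }
    cfg$origin_candidates <- kept
  }

  starts <- lhs_starts(tb$lower, tb$upper, cfg$n_starts, seed = cfg$seed)
  sa_ctl <- utils::modifyList(list(output_dt = cfg$output_dt,
                                   snap_radius = cfg$snap_radius,
                                   clamp_old = cfg$clamp_old), cfg$sa)
  incumbent <- anneal_fit(data, landscape, spec, starts,
                          cfg$origin_candidates, bounds,
                          seed = cfg$seed + 1L, control = sa_ctl,
                          loglik_fn = loglik_fn)
  ref_ctl <- utils::modifyList(list(output_dt = cfg$output_dt,
                                    snap_radius = cfg$snap_radius,
                                    clamp_old = cfg$clamp_old), cfg$refine)
  refined <- refine_fit(data, landscape, spec, incumbent, bounds,
                        control = ref_ctl, loglik_fn = loglik_fn)

  # discrete origin polish: the quasi-Newton layer cannot move the origin, so
  # walk it over nearby land cells at the refined parameters, re-refining
  # after each accepted move
  if (isTRUE(cfg$origin_polish)) {
    offs <- as.matrix(expand.grid(dr = -2:2, dc = -2:2))
    offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
    polish_ctl <- ref_ctl
    if (!is.null(cfg$polish_maxit)) polish_ctl$maxit <- cfg$polish_maxit
    origin_before_polish <- refined$origin
    for (round in seq_len(cfg$polish_rounds)) {
      cand <- cbind(refined$origin[1] + offs[, 1],
                    refined$origin[2] + offs[, 2])
      keep <- cand[, 1] >= 1 & cand[, 1] <= landscape$n_rows &
              cand[, 2] >= 1 & cand[, 2] <= landscape$n_cols
      cand <- cand[keep, , drop = FALSE]
      cand <- cand[landscape$land[cand], , drop = FALSE]
      if (nrow(cand) == 0) break
      ll <- vapply(seq_len(nrow(cand)), function(i)
        loglik_fn(refined$theta, cand[i, ]), 0)
      if (max(ll) <= refined$loglik + 1e-9) break
      best <- cand[which.max(ll), ]
      moved <- list(theta = refined$theta, origin = as.integer(best),
                    loglik = max(ll))
      refined <- refine_fit(data, landscape, spec, moved, bounds,
                            control = polish_ctl, loglik_fn = loglik_fn)
    }
    # a moved origin was only lightly re-refined; finish at full effort
    if (any(refined$origin != origin_before_polish))
      refined <- refine_fit(data, landscape, spec, refined, bounds,
                            control = ref_ctl, loglik_fn = loglik_fn)
  }

  ci <- NULL
  if (isTRUE(cfg$ci)) {
    sp <- spec
    sp$origin_cell <- as.integer(refined$origin)
    ci <- suppressWarnings(
      fisher_ci_from_loglik(function(th) loglik_fn(th, refined$origin),
                            refined$theta))
  }

  origin_ll <- cell_center(landscape, refined$origin[1], refined$origin[2])
  structure(list(
    variant = spec$variant, n_epochs = n_epochs,
    theta = refined$theta,
    epochs = theta_to_epochs(refined$theta, spec$variant, {
      sp <- spec; sp$origin_cell <- as.integer(refined$origin); sp
    }),
    origin = list(row = refined$origin[1], col = refined$origin[2],
                  lat = unname(origin_ll["lat"]),
                  lon = unname(origin_ll["lon"])),
    loglik = refined$loglik, ci = ci,
    at_boundary = refined$at_boundary,
    trace = list(n_starts = cfg$n_starts, seed = cfg$seed,
                 sa_loglik = incumbent$loglik,
                 sa_evals = incumbent$n_eval,
                 start_loglik = incumbent$start_loglik,
                 refine_failed = refined$refine_failed,
                 convergence = refined$convergence),
    spec = spec, bounds = bounds
  ), class = "aw_fit")
}

#' @export
print.aw_fit <- function(x, ...) {
  cat(sprintf("aw_fit (model %s, %d epoch(s)): loglik = %.3f\n", x$variant,
              x$n_epochs, x$loglik))
  cat(sprintf("origin: (%.1f, %.1f) [cell %d, %d]\n", x$origin$lat,
              x$origin$lon, x$origin$row, x$origin$col))
  tab <- if (!is.null(x$ci)) x$ci else cbind(estimate = x$theta)
  print(round(tab, 5))
  if (any(x$at_boundary))
    cat("at boundary:", paste(names(x$theta)[x$at_boundary], collapse = ", "),
        "\n")
  invisible(x)
}

#' Profile the log-likelihood over candidate allele ages
#'
#' The allele age is an input, not a fitted parameter (age and selection
#' strength trade off); this re-runs [fit()] at each candidate age and
#' returns the maximized log-likelihood per age for the caller to compare.
#'
#' @param data,landscape,spec,bounds,config As in [fit()].
#' @param ages Candidate allele ages in years BP (> 0).
#' @return data.frame with columns `age_years_bp`, `loglik`, `error`
#'   (NA when the fit succeeded), plus the list of fits as attribute `fits`.
#' @export
profile_allele_age <- function(data, landscape, spec, ages,
                               bounds = parameter_bounds(), config = list()) {
  stopifnot(all(ages > 0))
  fits <- vector("list", length(ages))
  ll <- rep(NA_real_, length(ages))
  err <- rep(NA_character_, length(ages))
  for (i in seq_along(ages)) {
    sp <- spec
    sp$allele_age_years_bp <- ages[i]
    sp$epoch_boundary_years_bp <- min(spec$epoch_boundary_years_bp, ages[i])
    res <- tryCatch(fit(data, landscape, sp, bounds, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      err[i] <- conditionMessage(res)
    } else {
      fits[[i]] <- res
      ll[i] <- res$loglik
    }
  }
  out <- data.frame(age_years_bp = ages, loglik = ll, error = err,
                    stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  out
}
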