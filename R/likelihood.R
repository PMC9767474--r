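#' A single dated, geolocated genotype observation
#'
#' Exactly one evidence payload is populated, selected by `kind`:
#' `genotype_likelihood` carries a (possibly unnormalized) likelihood triplet
#' over 0/1/2 copies of the derived allele (beagle order); `diploid_genotype`
#' a hard genotype call; `pseudohaploid` a single randomly drawn allele
#' (0 = ancestral, 1 = derived), the standard representation for low-coverage
#' ancient DNA.
#'
#' @param id Sample label.
#' @param lat,lon Sampling location, decimal degrees.
#' @param age_years_bp Age in years before present (0 = present day).
#' @param kind One of `"genotype_likelihood"`, `"diploid_genotype"`,
#'   `"pseudohaploid"`.
#' @param gl Numeric triplet (kind `genotype_likelihood`).
#' @param genotype Integer in 0:2 (kind `diploid_genotype`).
#' @param allele 0 or 1 (kind `pseudohaploid`).
#' @return An `aw_observation`.
#' @export
observation <- function(id, lat, lon, age_years_bp,
                        kind = c("genotype_likelihood", "diploid_genotype",
                                 "pseudohaploid"),
                        gl = NULL, genotype = NULL, allele = NULL) {
  kind <- match.arg(kind)
  if (age_years_bp < 0) stop("age must be >= 0 years BP")
  if (kind == "genotype_likelihood") {
    if (is.null(gl) || length(gl) != 3 || any(gl < 0) || sum(gl) == 0)
      stop("kind 'genotype_likelihood' needs a non-negative, non-zero triplet")
    genotype <- NA_integer_; allele <- NA_integer_
  } else if (kind == "diploid_genotype") {
    if (is.null(genotype) || !genotype %in% 0:2)
      stop("kind 'diploid_genotype' needs genotype in {0, 1, 2}")
    gl <- rep(NA_real_, 3); allele <- NA_integer_
  } else {
    if (is.null(allele) || !allele %in% 0:1)
      stop("kind 'pseudohaploid' needs allele in {0, 1}")
    gl <- rep(NA_real_, 3); genotype <- NA_integer_
  }
  structure(list(id = as.character(id), lat = lat, lon = lon,
                 age_years_bp = age_years_bp, kind = kind, gl = gl,
                 genotype = if (is.null(genotype)) NA_integer_ else
                   as.integer(genotype),
                 allele = if (is.null(allele)) NA_integer_ else
                   as.integer(allele)),
            class = "aw_observation")
}

#' A dataset of observations at one locus
#' @param observations List of `aw_observation`.
#' @param locus Locus label.
#' @return An `aw_dataset`.
#' @export
dataset <- function(observations, locus = "locus") {
  if (length(observations) == 0) stop("a dataset must contain observations")
  ok <- vapply(observations, inherits, TRUE, "aw_observation")
  if (!all(ok)) stop("all elements must be aw_observation objects")
  structure(list(observations = observations, locus = locus),
            class = "aw_dataset")
}

#' @export
print.aw_dataset <- function(x, ...) {
  kinds <- table(vapply(x$observations, `[[`, "", "kind"))
  cat(sprintf("aw_dataset '%s': %d observations (%s)\n", x$locus,
              length(x$observations),
              paste(names(kinds), kinds, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
length.aw_dataset <- function(x) length(x$observations)

#' Convert a dataset to a data frame
#' @param x An `aw_dataset`.
#' @param ... Unused.
#' @return A data.frame with one row per observation.
#' @export
as.data.frame.aw_dataset <- function(x, ...) {
  obs <- x$observations
  data.frame(
    id = vapply(obs, `[[`, "", "id"),
    lat = vapply(obs, `[[`, 0, "lat"),
    lon = vapply(obs, `[[`, 0, "lon"),
    age_bp = vapply(obs, `[[`, 0, "age_years_bp"),
    kind = vapply(obs, `[[`, "", "kind"),
    gl0 = vapply(obs, function(o) o$gl[1], 0),
    gl1 = vapply(obs, function(o) o$gl[2], 0),
    gl2 = vapply(obs, function(o) o$gl[3], 0),
    genotype = vapply(obs, `[[`, 0L, "genotype"),
    allele = vapply(obs, `[[`, 0L, "allele"),
    stringsAsFactors = FALSE)
}

#' Hardy-Weinberg genotype prior
#'
#' Binomial(2, p) probabilities of carrying 0, 1, or 2 copies of the derived
#' allele given the local frequency p.
#'
#' @param p Frequency in `[0, 1]`.
#' @return Numeric triplet `((1-p)^2, 2p(1-p), p^2)` summing to 1.
#' @export
genotype_prior <- function(p) {
  if (p < 0 || p > 1) stop("frequency outside [0, 1]")
  c((1 - p)^2, 2 * p * (1 - p), p^2)
}

# floor applied to impossible observations so the optimizer can move away
# from regions of parameter space where some observation has likelihood 0
.aw_loglik_floor <- log(1e-300)

#' Log-likelihood of one observation given the local frequency
#'
#' Genotype-likelihood data: log of the GL triplet integrated against the
#' Hardy-Weinberg prior at p. Hard diploid genotypes are the degenerate
#' triplet with weight 1 at the call. Pseudohaploid calls use the Bernoulli
#' marginal: a randomly drawn allele is derived with probability p.
#'
#' @param obs An `aw_observation`.
#' @param p Frequency in `[0, 1]`.
#' @param floor Log-likelihood floor substituted (with a warning attribute)
#'   when the likelihood is exactly 0; `-Inf` disables flooring.
#' @return Log-probability. If flooring was applied the result carries
#'   attribute `floored = TRUE`.
#' @export
observation_loglik <- function(obs, p, floor = .aw_loglik_floor) {
  if (p < 0 || p > 1) stop("frequency outside [0, 1]")
  lik <- switch(obs$kind,
    genotype_likelihood = sum(obs$gl * genotype_prior(p)),
    diploid_genotype = genotype_prior(p)[obs$genotype + 1],
    pseudohaploid = if (obs$allele == 1) p else 1 - p)
  if (lik > 0) return(log(lik))
  out <- floor
  attr(out, "floored") <- TRUE
  out
}

#' Log-likelihood of a dataset against a frequency surface
#'
#' Sum over independent individuals of [observation_loglik()] evaluated at
#' the surface frequency at each observation's location and age.
#'
#' @param data An `aw_dataset`.
#' @param surface An `aw_surface` from [solve_surface()].
#' @param snap_radius,clamp_old Passed to [frequency_at()].
#' @param floor Per-observation log-likelihood floor (see
#'   [observation_loglik()]).
#' @return Log-likelihood. Attribute `floored_ids` lists observations that
#'   hit the floor, if any.
#' @export
dataset_loglik <- function(data, surface, snap_radius = 1, clamp_old = FALSE,
                           floor = .aw_loglik_floor) {
  stopifnot(inherits(data, "aw_dataset"))
  total <- 0
  floored <- character(0)
  for (obs in data$observations) {
    p <- frequency_at(surface, obs$lat, obs$lon, obs$age_years_bp,
                      snap_radius = snap_radius, clamp_old = clamp_old)
    ll <- observation_loglik(obs, p, floor = floor)
    if (isTRUE(attr(ll, "floored"))) floored <- c(floored, obs$id)
    total <- total + as.numeric(ll)
  }
  if (length(floored)) {
    attr(total, "floored_ids") <- floored
    warning(sprintf("%d observation(s) had zero likelihood (floored): %s",
                    length(floored),
                    paste(utils::head(floored, 5), collapse = ", ")))
  }
  total
}

# Fast path used inside the optimizer: observation contexts precomputed once
# (land-cell index + sample time in generations), likelihood evaluated
# vectorized against a solved surface. Semantics identical to dataset_loglik.
make_contexts <- function(data, landscape, spec, snap_radius = 1,
                          clamp_old = FALSE) {
  li <- land_index(landscape)
  obs <- data$observations
  n <- length(obs)
  cell <- integer(n); tgen <- numeric(n)
  kind <- integer(n)  # 1 gl, 2 genotype, 3 pseudohaploid
  gl <- matrix(0, n, 3); geno <- integer(n); allele <- integer(n)
  for (i in seq_len(n)) {
    o <- obs[[i]]
    rc <- locate(landscape, o$lat, o$lon, snap_radius)
    cell[i] <- li$idx[rc[1], rc[2]]
    t <- (spec$allele_age_years_bp - o$age_years_bp) / spec$generation_time
    if (t < -1e-9) {
      if (!clamp_old)
        stop(sprintf("observation %s predates the allele", o$id))
      t <- 0
    }
    tgen[i] <- max(t, 0)
    kind[i] <- match(o$kind, c("genotype_likelihood", "diploid_genotype",
                               "pseudohaploid"))
    if (kind[i] == 1) gl[i, ] <- o$gl
    if (kind[i] == 2) geno[i] <- o$genotype
    if (kind[i] == 3) allele[i] <- o$allele
  }
  list(cell = cell, tgen = tgen, kind = kind, gl = gl, geno = geno,
       allele = allele, n = n)
}

contexts_loglik <- function(ctx, surface, floor = .aw_loglik_floor) {
  times <- surface$times
  nt <- length(times)
  i <- findInterval(ctx$tgen, times, rightmost.closed = TRUE)
  i[i < 1] <- 1
  i2 <- pmin(i + 1, nt)
  denom <- times[i2] - times[i]
  w <- ifelse(denom > 0, (ctx$tgen - times[i]) / denom, 0)
  w <- pmin(pmax(w, 0), 1)
  pm <- surface$p
  idx1 <- cbind(ctx$cell, i)
  idx2 <- cbind(ctx$cell, i2)
  p <- (1 - w) * pm[idx1] + w * pm[idx2]

  lik <- numeric(ctx$n)
  k1 <- ctx$kind == 1
  if (any(k1)) {
    pr <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
    lik[k1] <- rowSums(ctx$gl[k1, , drop = FALSE] * pr[k1, , drop = FALSE])
  }
  k2 <- ctx$kind == 2
  if (any(k2)) {
    g <- ctx$geno[k2]; pp <- p[k2]
    lik[k2] <- ifelse(g == 0, (1 - pp)^2, ifelse(g == 1, 2 * pp * (1 - pp),
                                                 pp^2))
  }
  k3 <- ctx$kind == 3
  if (any(k3)) lik[k3] <- ifelse(ctx$allele[k3] == 1, p[k3], 1 - p[k3])

  ll <- ifelse(lik > 0, log(lik), floor)
  sum(ll)
}
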