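#' Off-lattice particle set
#'
#' Positions of `N` Brownian particles in `[lo, hi]` (1D) or
#' `[lo, hi] x [0, cy] x [0, cz]` (3D).
#'
#' @param pos numeric vector (1D) or N x 3 matrix (3D) of positions.
#' @param lo,hi region endpoints along `x`.
#' @param cross cross-section extents `c(cy, cz)` in 3D.
#' @return An object of class `particle_set`.
#' @export
particle_set <- function(pos, lo, hi, cross = c(1, 1)) {
  pos <- if (is.matrix(pos)) pos else matrix(pos, ncol = 1L)
  structure(
    list(pos = pos, lo = lo, hi = hi, cross = as.numeric(cross),
         dim = if (ncol(pos) == 3L) 3L else 1L),
    class = "particle_set"
  )
}

#' Drift-corrected Euler-Maruyama diffusion step
#'
#' Each particle moves by `dt * dD_eff/dx` (the x-component only, since
#' blending varies along `x`) plus an independent Gaussian displacement of
#' zero mean and variance `2 * D_eff(y) * dt` per coordinate, with the
#' diffusivity evaluated at the pre-move position.  The drift term is exactly
#' what makes the divergence-form diffusion equation (uniform steady state)
#' the Fokker-Planck limit of the update.  At the blending kinks the one-sided
#' derivative from inside the blending region is used.
#'
#' Positions are not reflected here; call [handle_boundaries()] afterwards.
#'
#' @param particles a [particle_set()].
#' @param geom a [blend_geometry()].
#' @param dt time step.
#' @param diffusivity `"full"`, `"d1"` or `"d2"` (the hybrid's fine side).
#' @param xi optional matrix of standard-normal deviates (same shape as the
#'   positions) for deterministic testing; drawn internally when `NULL`.
#' @return The updated `particle_set`.
#' @export
em_step <- function(particles, geom, dt, diffusivity = c("d2", "full", "d1"),
                    xi = NULL) {
  stopifnot(inherits(particles, "particle_set"), inherits(geom, "blend_geometry"),
            dt > 0)
  diffusivity <- match.arg(diffusivity)
  p <- particles$pos
  if (nrow(p) == 0L) return(particles)
  x <- p[, 1L]
  deff <- switch(diffusivity,
                 full = rep(geom$D, length(x)),
                 d1 = blend_d1(geom, x),
                 d2 = blend_d2(geom, x))
  drift <- switch(diffusivity,
                  full = 0,
                  d1 = -blend_d2_slope(geom, x),
                  d2 = blend_d2_slope(geom, x))
  if (is.null(xi)) {
    xi <- matrix(stats::rnorm(length(p)), nrow = nrow(p))
  }
  sd <- sqrt(2 * deff * dt)
  p[, 1L] <- x + dt * drift + sd * xi[, 1L]
  if (ncol(p) == 3L) {
    p[, 2L] <- p[, 2L] + sd * xi[, 2L]
    p[, 3L] <- p[, 3L] + sd * xi[, 3L]
  }
  particles$pos <- p
  particles
}

reflect_coord <- function(v, lo, hi) {
  # mirror reflection y -> 2w - y, repeated until inside
  out <- which(v < lo | v > hi)
  while (length(out)) {
    v[out] <- ifelse(v[out] < lo, 2 * lo - v[out], v[out])
    v[out] <- ifelse(v[out] > hi, 2 * hi - v[out], v[out])
    out <- out[v[out] < lo | v[out] > hi]
  }
  v
}

#' Reflect particles back into their region
#'
#' Positions beyond a reflecting boundary at `w` are mapped `y -> 2w - y`
#' (repeatedly, until inside).  In 3D each coordinate is reflected
#' independently.  In the compartment-Brownian hybrid this is also how the
#' rare erroneous crossings of the `I1` interface are handled.
#'
#' @param particles a [particle_set()].
#' @return The `particle_set` with all positions inside the region.
#' @export
handle_boundaries <- function(particles) {
  stopifnot(inherits(particles, "particle_set"))
  p <- particles$pos
  if (nrow(p) == 0L) return(particles)
  p[, 1L] <- reflect_coord(p[, 1L], particles$lo, particles$hi)
  if (ncol(p) == 3L) {
    p[, 2L] <- reflect_coord(p[, 2L], 0, particles$cross[1L])
    p[, 3L] <- reflect_coord(p[, 3L], 0, particles$cross[2L])
  }
  particles$pos <- p
  particles
}

#' Pairwise (lambda-rho) bimolecular reactions
#'
#' Every unordered pair of particles at Euclidean distance below `rho` reacts
#' with probability `P_lambda` this step; both partners are removed.  Pairs
#' are processed in randomised order and a particle already consumed in this
#' step is ineligible for further pairs.
#'
#' @param particles a [particle_set()].
#' @param reactions a [reaction_channels()] with `rho` and `P_lambda` set.
#' @return A list with the surviving `particles` and `n_removed`.
#' @export
react_pairs <- function(particles, reactions) {
  stopifnot(inherits(particles, "particle_set"))
  r <- as_reactions(reactions)
  p <- particles$pos
  n <- nrow(p)
  if (n < 2L || r$rho <= 0 || r$P_lambda <= 0) {
    return(list(particles = particles, n_removed = 0L))
  }
  d <- as.matrix(stats::dist(p))
  idx <- which(upper.tri(d) & d < r$rho, arr.ind = TRUE)
  alive <- rep(TRUE, n)
  if (nrow(idx)) {
    idx <- idx[sample.int(nrow(idx)), , drop = FALSE]
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1L]; j <- idx[k, 2L]
      if (alive[i] && alive[j] && stats::runif(1) < r$P_lambda) {
        alive[i] <- FALSE
        alive[j] <- FALSE
      }
    }
  }
  particles$pos <- p[alive, , drop = FALSE]
  list(particles = particles, n_removed = sum(!alive))
}

#' Scalar (zeroth/first-order) reactions for the Brownian engine
#'
#' Each particle is removed with the exact exponential probability
#' `1 - exp(-mu * dt)`; `Poisson(k2 * V * dt)` new particles are placed
#' uniformly in the region, where `V` is the region volume.
#'
#' @param particles a [particle_set()].
#' @param reactions a [reaction_channels()].
#' @param dt time step.
#' @return The updated `particle_set`.
#' @export
react_scalar <- function(particles, reactions, dt) {
  stopifnot(inherits(particles, "particle_set"), dt > 0)
  r <- as_reactions(reactions)
  p <- particles$pos
  if (r$mu > 0 && nrow(p)) {
    keep <- stats::runif(nrow(p)) >= 1 - exp(-r$mu * dt)
    p <- p[keep, , drop = FALSE]
  }
  if (r$k2 > 0) {
    vol <- (particles$hi - particles$lo) *
      if (particles$dim == 3L) prod(particles$cross) else 1
    n_new <- stats::rpois(1L, r$k2 * vol * dt)
    if (n_new > 0) {
      new <- matrix(0, nrow = n_new, ncol = ncol(p))
      new[, 1L] <- stats::runif(n_new, particles$lo, particles$hi)
      if (ncol(p) == 3L) {
        new[, 2L] <- stats::runif(n_new, 0, particles$cross[1L])
        new[, 3L] <- stats::runif(n_new, 0, particles$cross[2L])
      }
      p <- rbind(p, new)
    }
  }
  particles$pos <- p
  particles
}

#' Stand-alone Brownian simulation with constant diffusivity
#'
#' Fixed-time-step Euler-Maruyama diffusion with reflecting boundaries on the
#' full region, plus the configured reactions (exact-exponential decay,
#' Poisson production, lambda-rho pair annihilation).  Used as the
#' finest-scale ground truth for ensemble comparisons.
#'
#' @param particles a [particle_set()].
#' @param D diffusion coefficient.
#' @param reactions a [reaction_channels()] or `NULL`.
#' @param dt time step.
#' @param t_end final time (`t_end / dt` steps are taken).
#' @return The final `particle_set`.
#' @export
brownian_run <- function(particles, D, reactions = NULL, dt, t_end) {
  stopifnot(inherits(particles, "particle_set"))
  r <- as_reactions(reactions)
  nsteps <- as.integer(round(t_end / dt))
  pos0 <- particles$pos
  out <- cpp_brownian_run(pos0, particles$lo, particles$hi,
                          particles$cross[1L], particles$cross[2L],
                          particles$dim, D, r$mu, r$k2, r$rho, r$P_lambda,
                          dt, nsteps)
  particles$pos <- out$pos
  particles
}
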