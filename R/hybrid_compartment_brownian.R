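#' Hybrid state for the compartment-Brownian coupler
#'
#' Couples the compartment engine on `[a, I2]` (diffusivity `D1`) with the
#' off-lattice Brownian engine on `[I1, b]` (diffusivity `D2`), with
#' particle-level synchronization in the blending region every window: after
#' each full window, each blending compartment count equals the number of
#' Brownian particles in its half-open interval `[I1 + (i-1) h, I1 + i h)`,
#' and the total particle number is the sum of the pure compartment counts
#' plus the number of Brownian particles (blending mass counted once).
#'
#' @param geom a [blend_geometry()].
#' @param mesh a [build_mesh()] with `coupling = "compartment-brownian"`.
#' @param C_pure0 initial integer counts of the `n_c` pure compartments on
#'   `[a, I1]`.
#' @param particles a [particle_set()] on `[I1, b]`; the blending compartment
#'   counts are initialised from its histogram.
#' @param influx_left boundary influx (particles/time) into the leftmost
#'   compartment.
#' @return An object of class `hybrid_cb` with components `comp`
#'   (a [compartment_field()]; compartments `1..n_c` pure, the rest blending),
#'   `particles`, `t`, `mesh`, `geom`, a reflection tally `reflections` (how
#'   many erroneous `I1` crossings were reflected back), and a `debug` flag.
#' @export
hybrid_cb_state <- function(geom, mesh, C_pure0, particles, influx_left = 0) {
  stopifnot(inherits(geom, "blend_geometry"), inherits(mesh, "blend_mesh"),
            mesh$coupling == "compartment-brownian",
            inherits(particles, "particle_set"),
            length(C_pure0) == mesh$n_c)
  comp <- compartment_field(geom, geom$a, geom$I2, mesh$h,
                            C0 = c(C_pure0, rep(0, mesh$n_2)),
                            diffusivity = "d1", influx_left = influx_left)
  st <- structure(
    list(comp = comp, particles = particles, t = 0, mesh = mesh, geom = geom,
         reflections = 0L, debug = FALSE),
    class = "hybrid_cb"
  )
  rebin(st)
}

blending_bin <- function(state, x) {
  # half-open binning [I1 + (i-1) h, I1 + i h); a position exactly on an
  # internal boundary belongs to the right cell
  floor((x - state$geom$I1) / state$mesh$h) + 1L
}

particles_in_compartment <- function(state, i) {
  x <- state$particles$pos[, 1L]
  which(x >= state$geom$I1 & x < state$geom$I2 & blending_bin(state, x) == i)
}

#' Reset blending counts from the Brownian histogram
#'
#' Sets each blending compartment count to the number of Brownian particles in
#' `[I1 + (i-1) h, I1 + i h)` (half-open); pure compartment counts are
#' untouched.
#'
#' @param state a [hybrid_cb_state()].
#' @return The re-binned state.
#' @export
rebin <- function(state) {
  stopifnot(inherits(state, "hybrid_cb"))
  m <- state$mesh
  x <- state$particles$pos[, 1L]
  inblend <- x >= state$geom$I1 & x < state$geom$I2
  counts <- tabulate(blending_bin(state, x[inblend]), nbins = m$n_2)
  state$comp$C[m$n_c + seq_len(m$n_2)] <- counts
  state
}

#' Mirror a blending diffusion event onto the particle set
#'
#' After an SSA event has moved one particle from blending compartment `i` to
#' a neighbouring blending compartment, one Brownian particle chosen uniformly
#' at random among those currently in compartment `i` is displaced by exactly
#' `+h` or `-h`.  The compartment counts themselves are the SSA engine's
#' responsibility and are not modified here.
#'
#' @param state a [hybrid_cb_state()].
#' @param i blending compartment index (1..n_2).
#' @param direction `"left"` or `"right"`.
#' @return The updated state.
#' @export
mirror_jump_event <- function(state, i, direction = c("right", "left")) {
  stopifnot(inherits(state, "hybrid_cb"))
  direction <- match.arg(direction)
  members <- particles_in_compartment(state, i)
  if (!length(members)) {
    stop("consistency fault: no Brownian particle in blending compartment ", i,
         call. = FALSE)
  }
  k <- members[sample.int(length(members), 1L)]
  shift <- if (direction == "right") state$mesh$h else -state$mesh$h
  state$particles$pos[k, 1L] <- state$particles$pos[k, 1L] + shift
  state
}

#' Exchange a particle across the pure-compartment/blending interface
#'
#' Realises the particle side of an SSA jump between the last pure compartment
#' and the first blending compartment: a leftward exit (`direction = "out"`)
#' deletes one uniformly chosen Brownian particle of the first blending
#' compartment; a rightward entry (`direction = "in"`) creates one Brownian
#' particle at a position uniform on `[I1, I1 + h)` (with `y`, `z` uniform
#' over the cross-section in 3D).
#'
#' @param state a [hybrid_cb_state()].
#' @param direction `"in"` (into the blending region) or `"out"`.
#' @return The updated state.
#' @export
exchange_at_interface <- function(state, direction = c("in", "out")) {
  stopifnot(inherits(state, "hybrid_cb"))
  direction <- match.arg(direction)
  p <- state$particles$pos
  if (direction == "out") {
    members <- particles_in_compartment(state, 1L)
    if (!length(members)) {
      stop("consistency fault: deletion requested from an empty blending compartment",
           call. = FALSE)
    }
    k <- members[sample.int(length(members), 1L)]
    state$particles$pos <- p[-k, , drop = FALSE]
  } else {
    new <- numeric(ncol(p))
    new[1L] <- stats::runif(1L, state$geom$I1, state$geom$I1 + state$mesh$h)
    if (ncol(p) == 3L) {
      new[2L] <- stats::runif(1L, 0, state$geom$cross[1L])
      new[3L] <- stats::runif(1L, 0, state$geom$cross[2L])
    }
    state$particles$pos <- rbind(p, new)
  }
  state
}

# Shared driver for one-or-more coupling windows.
hybrid_cb_advance <- function(state, reactions = NULL, dt, nwin = 1L) {
  stopifnot(inherits(state, "hybrid_cb"), dt > 0)
  r <- as_reactions(reactions)
  m <- state$mesh
  comp <- state$comp
  k0 <- r$k2 * comp$V
  k0[1L] <- k0[1L] + comp$influx_left
  g <- state$geom
  out <- cpp_hybrid_cb_run(
    comp$C, state$particles$pos,
    m$n_c, m$n_2, g$I1, g$I2, g$b, g$D, m$h,
    g$cross[1L], g$cross[2L], g$dimension,
    comp$rateL, comp$rateR, comp$V, k0, r$mu, r$k1,
    r$k2, r$mu, r$rho, r$P_lambda,
    dt, as.integer(nwin), isTRUE(state$debug)
  )
  state$comp$C <- out$C
  state$particles$pos <- out$pos
  state$reflections <- state$reflections + out$reflections
  state$t <- state$t + nwin * dt
  state
}

#' Advance the compartment-Brownian hybrid by one coupling window
#'
#' One window of length `dt` applies, in order: (1) a Gillespie window on
#' `[a, I2]` with diffusivity `D1`, with every blending diffusion event
#' mirrored immediately onto the particle set ([mirror_jump_event()] /
#' [exchange_at_interface()] semantics) and blending reactions executed by the
#' compartment engine and mirrored by creating or deleting particles; (2) a
#' drift-corrected Euler-Maruyama step with diffusivity `D2` for all particles
#' followed by reflection at `I1` and the outer boundaries, then the
#' pure-Brownian-region reactions (lambda-rho pairs with both partners in
#' `[I2, b]`, exact-exponential decay, Poisson production); (3) a re-binning
#' of the blending counts from the particle histogram.
#'
#' With `state$debug = TRUE` the count-equals-histogram invariant is asserted
#' at the start of every window.
#'
#' @param state a [hybrid_cb_state()].
#' @param reactions a [reaction_channels()] or `NULL`.
#' @param dt window length.
#' @return The advanced state (`t` increased by `dt`).
#' @export
hybrid_cb_window <- function(state, reactions = NULL, dt) {
  hybrid_cb_advance(state, reactions, dt, nwin = 1L)
}

#' @export
region_masses.hybrid_cb <- function(state) {
  m <- state$mesh
  x <- state$particles$pos[, 1L]
  c(C = sum(state$comp$C[seq_len(m$n_c)]),
    H = sum(state$comp$C[m$n_c + seq_len(m$n_2)]),
    B = sum(x >= state$geom$I2))
}

#' Total particle number of a compartment-Brownian state
#'
#' Pure compartment counts plus the number of Brownian particles; the blending
#' mass is counted once (through the particles).
#'
#' @param state a [hybrid_cb_state()].
#' @return Integer total.
#' @export
total_count <- function(state) {
  stopifnot(inherits(state, "hybrid_cb"))
  sum(state$comp$C[seq_len(state$mesh$n_c)]) + nrow(state$particles$pos)
}
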