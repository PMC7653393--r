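#' Hybrid state for the PDE-compartment coupler
#'
#' Operator-split coupling of the finite-volume PDE solver on `[a, I2]`
#' (diffusivity `D1`) with the compartment engine on `[I1, b]` (diffusivity
#' `D2`).  Both representations coexist on the blending region `[I1, I2]` and
#' are kept synchronized every window: after each full window, every blending
#' compartment count equals the integral of the PDE concentration over its
#' `gamma` voxels.
#'
#' The PDE needs no extra right-boundary condition because `D1(I2) = 0`;
#' symmetrically the compartment chain's leftmost face at `I1` has
#' `D2(I1) = 0`, so no jump leaks out of the region.
#'
#' @param geom a [blend_geometry()].
#' @param mesh a [build_mesh()] with `coupling = "pde-compartment"`.
#' @param q0 initial PDE concentration on `[a, I2]` (scalar, vector or
#'   function of position).
#' @param C_pure0 initial integer counts of the `n_c` pure compartments on
#'   `[I2, b]`.
#' @param Ja prescribed flux (`D dc/dx`) at `x = a`; `Ja = -J` injects mass at
#'   rate `J`.
#' @return An object of class `hybrid_pc` with components `pde`
#'   (a [pde_field()]), `comp` (a [compartment_field()] whose first `n_2`
#'   compartments are the blending ones), `t`, `mesh`, `geom` and a
#'   `debug` flag.
#' @export
hybrid_pc_state <- function(geom, mesh, q0, C_pure0, Ja = 0) {
  stopifnot(inherits(geom, "blend_geometry"), inherits(mesh, "blend_mesh"),
            mesh$coupling == "pde-compartment",
            length(C_pure0) == mesh$n_c)
  pde <- pde_field(geom, geom$a, geom$I2, mesh$dx, q0,
                   diffusivity = "d1", Ja = Ja, Jb = 0)
  comp <- compartment_field(geom, geom$I1, geom$b, mesh$h,
                            C0 = c(rep(0, mesh$n_2), C_pure0),
                            diffusivity = "d2")
  st <- structure(
    list(pde = pde, comp = comp, t = 0, mesh = mesh, geom = geom,
         debug = FALSE),
    class = "hybrid_pc"
  )
  sync_pde_to_compartments(st)
}

#' Overwrite blending counts with the PDE mass
#'
#' Sets each blending compartment count to the integral of the PDE
#' concentration over its `gamma` voxels (counts may be non-integer); the
#' pure-compartment region is untouched, and the total blending mass of the
#' two representations agrees by construction.
#'
#' @param state a [hybrid_pc_state()].
#' @return The synchronized state.
#' @export
sync_pde_to_compartments <- function(state) {
  stopifnot(inherits(state, "hybrid_pc"))
  m <- state$mesh
  for (i in seq_len(m$n_2)) {
    vox <- m$n_p + m$gamma * (i - 1L) + seq_len(m$gamma)
    state$comp$C[i] <- sum(state$pde$q[vox]) * m$dx
  }
  state
}

#' Mirror a compartment count change into the PDE
#'
#' Adds `delta / (gamma * dx)` concentration to each of the `gamma` PDE voxels
#' of blending compartment `i`, so the PDE mass in that compartment changes by
#' exactly `delta`.
#'
#' @param state a [hybrid_pc_state()].
#' @param i blending compartment index (1..n_2).
#' @param delta integer count change from one or more SSA events.
#' @return The updated state.
#' @export
push_compartment_delta <- function(state, i, delta) {
  stopifnot(inherits(state, "hybrid_pc"), i >= 1, i <= state$mesh$n_2)
  m <- state$mesh
  vox <- m$n_p + m$gamma * (i - 1L) + seq_len(m$gamma)
  state$pde$q[vox] <- state$pde$q[vox] + delta / (m$gamma * m$dx)
  state
}

# Shared driver for one-or-more coupling windows.
hybrid_pc_advance <- function(state, reactions = NULL, dt, nwin = 1L) {
  stopifnot(inherits(state, "hybrid_pc"), dt > 0)
  r <- as_reactions(reactions)
  m <- state$mesh
  comp <- state$comp
  k0 <- r$k2 * comp$V
  out <- cpp_hybrid_pc_run(
    state$pde$q, comp$C,
    m$dx, state$pde$faceD, state$pde$Ja,
    m$n_p, m$gamma, m$n_2,
    comp$rateL, comp$rateR, comp$V, k0, r$mu, r$k1,
    r$k2, r$mu, r$k1,
    dt, as.integer(nwin), isTRUE(state$debug)
  )
  state$pde$q <- out$q
  state$comp$C <- out$C
  state$t <- state$t + nwin * dt
  state
}

#' Advance the PDE-compartment hybrid by one coupling window
#'
#' One window of length `dt` applies, in order: (1) a PDE step on `[a, I2]`
#' with diffusivity `D1`, with the mean-field reaction term applied only on
#' the pure-PDE voxels; (2) synchronization of the blending compartment counts
#' from the PDE; (3) a Gillespie window on `[I1, b]` with diffusivity `D2` and
#' reactions active everywhere in the compartment region (blending reactions
#' follow the compartment paradigm); (4) mirroring of the accumulated integer
#' count changes of each blending compartment back into its PDE voxels.
#'
#' With `state$debug = TRUE` the blending-consistency invariant is asserted
#' after the window.
#'
#' @param state a [hybrid_pc_state()].
#' @param reactions a [reaction_channels()] or `NULL`.
#' @param dt window length.
#' @return The advanced state (`t` increased by `dt`).
#' @export
hybrid_pc_window <- function(state, reactions = NULL, dt) {
  hybrid_pc_advance(state, reactions, dt, nwin = 1L)
}

#' Region masses of a hybrid state
#'
#' Returns the mass carried by each region of the domain, counting blending
#' mass once: for the PDE-compartment coupler the PDE mass on `[a, I1]`
#' (`P`), the blending compartment counts (`H`) and the pure compartment
#' counts (`C`); for the compartment-Brownian coupler the pure compartment
#' counts on `[a, I1]` (`C`), the blending counts (`H`) and the number of
#' Brownian particles in `[I2, b]` (`B`).
#'
#' @param state a [hybrid_pc_state()] or [hybrid_cb_state()].
#' @return Named numeric vector of region masses.
#' @export
region_masses <- function(state) UseMethod("region_masses")

#' @export
region_masses.hybrid_pc <- function(state) {
  m <- state$mesh
  c(P = pde_mass(state$pde, state$geom$a, state$geom$I1),
    H = sum(state$comp$C[seq_len(m$n_2)]),
    C = sum(state$comp$C[m$n_2 + seq_len(m$n_c)]))
}

#' Total particle number represented by a hybrid state
#'
#' Sums the region masses, counting the blending region once.
#'
#' @param state a hybrid state.
#' @return Total mass (particles).
#' @export
total_mass <- function(state) sum(region_masses(state))
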