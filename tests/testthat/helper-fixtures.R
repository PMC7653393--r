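# Shared fixtures: the standard unit-domain geometry and meshes used by the
# in-package test problems (domain [0,1], interfaces at 1/3 and 2/3, D = 1).

unit_geom <- function(D = 1) blend_geometry(0, 1, 1/3, 2/3, D = D)

unit_mesh <- function(coupling = "pde-compartment") {
  build_mesh(unit_geom(), dx = 1/300, h = 1/30, coupling = coupling)
}

# step initial condition of the redistribution problem: all mass uniform on
# [0, 1/3]
step_ic <- function(N = 1000) {
  function(x) ifelse(x < 1/3, 3 * N, 0)
}

# independent explicit (FTCS) finite-difference oracle for
# dc/dt = D c_xx - mu c on [0,1] with zero-flux / prescribed-gradient ends;
# deliberately a different scheme from the package's solver
ftcs_solve <- function(q0, dx, dt, nsteps, D = 1, mu = 0, Jgrad = 0) {
  q <- q0
  n <- length(q)
  lam <- D * dt / dx^2
  for (s in seq_len(nsteps)) {
    flux <- D * diff(q) / dx              # interior face fluxes
    flux <- c(Jgrad * D, flux, 0)         # prescribed D*dc/dx at x=0, zero at 1
    q <- q + dt * diff(flux) / dx - dt * mu * q
    if (lam > 0.5) stop("FTCS unstable")
  }
  q
}
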