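#' Relative mass error
#'
#' The dimensionless region diagnostic `(hybrid - reference) / reference`,
#' evaluated per region and output time: 0 when the hybrid carries exactly the
#' reference mass in the region.
#'
#' @param hybrid_mass region mass in the hybrid simulation (possibly ensemble
#'   averaged).
#' @param reference_mass region mass of the reference solution; must be
#'   positive (a zero reference is reported as `NA`).
#' @return Numeric vector of relative mass errors.
#' @examples
#' rme(105, 100)  # 0.05
#' @export
rme <- function(hybrid_mass, reference_mass) {
  out <- (hybrid_mass - reference_mass) / reference_mass
  out[reference_mass <= 0] <- NA_real_
  out
}

series_nmax <- function(amp_fun, decay_fun, t, tol = 1e-12, cap = 200000L) {
  # number of cosine modes needed before the next term's amplitude drops
  # below tol
  n <- 1L
  while (n < cap && abs(amp_fun(n)) * exp(-decay_fun(n) * t) >= tol) {
    n <- n + 1L
  }
  n
}

#' Analytic diffusion solution on [0, 1] with zero-flux boundaries
#'
#' Cosine eigenfunction expansion
#' `u(x, t) = N + sum_n A_n cos(n pi x) exp(-D n^2 pi^2 t)` for the pure
#' diffusion equation on the unit interval with zero-flux ends, for either a
#' uniform initial condition with total mass `N` (for which `u == N` at all
#' times) or a step initial condition placing all mass uniformly on
#' `[0, step_frac]`.  The series is truncated when the next term's amplitude
#' falls below `1e-12`; at `t = 0` the initial condition is returned exactly.
#'
#' @param x positions in `[0, 1]`.
#' @param t time (`>= 0`).
#' @param ic `"uniform"` or `"step"`.
#' @param N total mass.
#' @param D diffusion coefficient.
#' @param step_frac right edge of the step initial condition.
#' @return Concentrations `u(x, t)`.
#' @export
diffusion_series <- function(x, t, ic = c("uniform", "step"), N = 1000,
                             D = 1, step_frac = 1/3) {
  ic <- match.arg(ic)
  if (ic == "uniform") return(rep(N, length(x)))
  w <- step_frac
  if (t == 0) return(ifelse(x < w, N / w, ifelse(x == w, N / (2 * w), 0)))
  amp <- function(n) 2 * (N / w) * sin(n * pi * w) / (n * pi)
  nmax <- series_nmax(function(n) 2 * (N / w) / (n * pi),
                      function(n) D * n^2 * pi^2, t)
  n <- seq_len(nmax)
  terms <- outer(x, n, function(xx, nn) cos(nn * pi * xx)) %*%
    (amp(n) * exp(-D * n^2 * pi^2 * t))
  N + as.numeric(terms)
}

#' @describeIn diffusion_series Mass of the analytic solution over
#'   `[lo, hi]`, from the closed-form antiderivative of each mode.
#' @param lo,hi integration window.
#' @export
diffusion_series_mass <- function(lo, hi, t, ic = c("uniform", "step"),
                                  N = 1000, D = 1, step_frac = 1/3) {
  ic <- match.arg(ic)
  base <- N * (hi - lo)
  if (ic == "uniform") return(base)
  w <- step_frac
  if (t == 0) {
    return((N / w) * max(0, min(hi, w) - min(lo, w)))
  }
  nmax <- series_nmax(function(n) 2 * (N / w) / (n * pi),
                      function(n) D * n^2 * pi^2, t)
  n <- seq_len(nmax)
  amp <- 2 * (N / w) * sin(n * pi * w) / (n * pi)
  base + sum(amp * exp(-D * n^2 * pi^2 * t) *
               (sin(n * pi * hi) - sin(n * pi * lo)) / (n * pi))
}

#' Analytic morphogen-gradient solution
#'
#' Solution of `dc/dt = D c_xx - mu c` on `[0, 1]` with flux conditions
#' `c_x(0) = -J`, `c_x(1) = 0` and the uniform initial condition
#' `c0 = D J / mu` (the steady-state mass distributed uniformly):
#' the steady profile
#' `S(x) = J sqrt(D/mu) cosh(sqrt(mu/D) (1 - x)) / sinh(sqrt(mu/D))`
#' plus a cosine transient whose mode `n` decays at rate `mu + D n^2 pi^2`.
#' With this initial condition the total mass is `D J / mu` at every time, so
#' influx and degradation balance exactly throughout.
#'
#' @param x positions in `[0, 1]`.
#' @param t time (`>= 0`).
#' @param J boundary influx parameter (mass enters at rate `D * J`).
#' @param D diffusion coefficient.
#' @param mu degradation rate.
#' @return Concentrations `u(x, t)`.
#' @export
morphogen_profile <- function(x, t, J = 1e4, D = 1, mu = 10) {
  k <- sqrt(mu / D)
  S <- J * sqrt(D / mu) * cosh(k * (1 - x)) / sinh(k)
  if (t == 0) return(rep(D * J / mu, length(x)))
  # B_n = -2 J D / (mu + D n^2 pi^2): cosine coefficients of c0 - S
  nmax <- series_nmax(function(n) 2 * J * D / (mu + D * n^2 * pi^2),
                      function(n) mu + D * n^2 * pi^2, t)
  n <- seq_len(nmax)
  B <- -2 * J * D / (mu + D * n^2 * pi^2)
  terms <- outer(x, n, function(xx, nn) cos(nn * pi * xx)) %*%
    (B * exp(-(mu + D * n^2 * pi^2) * t))
  S + as.numeric(terms)
}

#' @describeIn morphogen_profile Mass of the morphogen solution over
#'   `[lo, hi]` (closed form per mode); the full-domain mass is `D J / mu`
#'   at every `t`.
#' @param lo,hi integration window.
#' @export
morphogen_mass <- function(lo, hi, t, J = 1e4, D = 1, mu = 10) {
  k <- sqrt(mu / D)
  base <- (J * D / mu) * (sinh(k * (1 - lo)) - sinh(k * (1 - hi))) / sinh(k)
  if (t == 0) return (D * J / mu * (hi - lo))
  nmax <- series_nmax(function(n) 2 * J * D / (mu + D * n^2 * pi^2),
                      function(n) mu + D * n^2 * pi^2, t)
  n <- seq_len(nmax)
  B <- -2 * J * D / (mu + D * n^2 * pi^2)
  base + sum(B * exp(-(mu + D * n^2 * pi^2) * t) *
               (sin(n * pi * hi) - sin(n * pi * lo)) / (n * pi))
}

#' Analytic reference region mass for the in-package test problems
#'
#' Dispatches to the analytic solution matching the named problem: uniform
#' steady state, step-initial-condition diffusion, or the morphogen gradient.
#' (The bimolecular problem has no analytic reference; its ground truth is an
#' ensemble of the finest-scale engine, see [ensemble_ground_truth()].)
#'
#' @param config a [problem_config()].
#' @param t time.
#' @param lo,hi region window.
#' @return Reference mass in the window.
#' @export
analytic_region_mass <- function(config, t, lo, hi) {
  switch(config$problem,
    uniform = config$N * (hi - lo) / (config$b - config$a),
    redistribution = diffusion_series_mass(lo, hi, t, "step", N = config$N,
                                           D = config$D,
                                           step_frac = config$I1 - config$a),
    morphogen = morphogen_mass(lo, hi, t, J = config$J, D = config$D,
                               mu = config$mu),
    stop("no analytic reference for problem ", config$problem, call. = FALSE)
  )
}

#' Ensemble ground truth from a single-scale engine
#'
#' Runs the named pure engine on the full domain for `M` seeded repeats and
#' averages the region masses (and, for the compartment engine, the
#' per-compartment counts) at the output times.  Used as the reference for the
#' bimolecular problem, whose mean-field PDE is not an exact description of
#' the stochastic mean.
#'
#' @param config a [problem_config()]; its coupling is overridden.
#' @param engine `"compartment"` or `"brownian"`.
#' @param M ensemble size.
#' @param seed base seed; repeat `m` uses `seed + m`.
#' @return The [run_experiment()] result of the pure engine.
#' @export
ensemble_ground_truth <- function(config, engine = c("compartment", "brownian"),
                                  M = config$repeats, seed = config$seed) {
  engine <- match.arg(engine)
  config$coupling <- paste0("pure-", engine)
  config$repeats <- M
  config$seed <- seed
  run_experiment(config, reference = "none")
}

#' Moment-closure gap of the bimolecular test problem
#'
#' Solves the mean-field PDE `dc/dt = D lap(c) - k1 c^2 + k2` for the
#' production/pair-annihilation system on the cuboid `[0,10] x [0,1] x [0,1]`
#' from the linear initial profile, averages it over the compartment lattice,
#' runs an `M`-repeat ensemble of the full compartment-based model from the
#' same initial distribution, and returns the maximum over compartments of the
#' absolute relative difference of the two densities at time `t`.  The gap is
#' the systematic footprint of the Poisson moment-closure assumption behind
#' the mean-field `-k1 c^2` term.
#'
#' @param config a [problem_config()] for the bimolecular problem.
#' @param M ensemble size for the compartment ground truth.
#' @param seed base seed.
#' @param t comparison time.
#' @return A list with `max_gap` (the maximum absolute relative difference),
#'   and per-compartment vectors `pde_density`, `compartment_density`.
#' @export
moment_closure_gap <- function(config = problem_config("bimolecular3d",
                                                       "pure-compartment"),
                               M = config$repeats, seed = config$seed, t = 1) {
  stopifnot(config$problem == "bimolecular3d")
  # mean-field PDE, meshed along x (the profile is y,z-invariant)
  pcfg <- config
  pcfg$coupling <- "pure-pde"
  geom <- config_geometry(config)
  dx <- config$dx
  f <- pde_field(geom, geom$a, geom$b, dx, q0 = config_profile(config),
                 diffusivity = "full")
  f <- pde_step(f, dt = config$dt_p, nsteps = round(t / config$dt_p),
                reactions = config_reactions(config))
  gamma <- int_div(config$h, dx, "gamma = h/dx")
  ncomp <- int_div(geom$b - geom$a, config$h, "compartments (b-a)/h")
  pde_density <- colMeans(matrix(f$q, nrow = gamma, ncol = ncomp))
  # compartment ground truth
  gt <- ensemble_ground_truth(config, "compartment", M = M, seed = seed)
  counts <- gt$mean_counts[[which(gt$times == t)]]
  vol <- config$h * prod(geom$cross)
  comp_density <- counts / vol
  gap <- abs(pde_density - comp_density) / comp_density
  list(max_gap = max(gap), pde_density = pde_density,
       compartment_density = comp_density)
}
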