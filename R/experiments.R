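#' Run configuration for the built-in test problems
#'
#' Builds the full parameter set for one of the four in-package test problems,
#' with defaults reproducing the reference study conditions:
#' \describe{
#'   \item{uniform}{pure diffusion from a uniform initial condition;
#'     `N = 1000`, `D = 1`, domain `[0, 1]`, interfaces at 1/3 and 2/3,
#'     `h = 1/30`, `dx = 1/300`, `dt = 1e-4`, 500 repeats.}
#'   \item{redistribution}{pure diffusion with all mass initially uniform on
#'     `[a, I1]`; otherwise as `uniform`.}
#'   \item{morphogen}{gradient formation: decay at `mu = 10` everywhere and
#'     boundary influx `D * J` with `J = 1e4` at `x = 0`, starting uniform at
#'     the steady-state concentration `D J / mu`; 1000 repeats.}
#'   \item{bimolecular3d}{production `0 -> A` at `k2 = 89.7` and pair
#'     annihilation `2A -> 0` at `k1 = 0.1` (`rho = 0.06`,
#'     `P_lambda = 2.5e-5`) on `[0,10] x [0,1] x [0,1]` with `h_x = 1/3`,
#'     from the linear initial profile `c(x) = (183 - 18 x)/2` (465 particles
#'     in expectation); 500 repeats.  Compartment counts are always derived
#'     from the region lengths and `h`.}
#' }
#'
#' @param problem one of `"uniform"`, `"redistribution"`, `"morphogen"`,
#'   `"bimolecular3d"`.
#' @param coupling one of `"pde-compartment"`, `"compartment-brownian"`,
#'   `"pure-pde"`, `"pure-compartment"`, `"pure-brownian"`.
#' @param ... named overrides of any config field (e.g. `repeats`, `seed`,
#'   `output_times`, `t_final`).
#' @return An object of class `blend_config`.
#' @examples
#' problem_config("uniform", "compartment-brownian", repeats = 10, seed = 42)
#' @export
problem_config <- function(problem = c("uniform", "redistribution",
                                       "morphogen", "bimolecular3d"),
                           coupling = c("pde-compartment",
                                        "compartment-brownian", "pure-pde",
                                        "pure-compartment", "pure-brownian"),
                           ...) {
  problem <- match.arg(problem)
  coupling <- match.arg(coupling)
  cfg <- list(
    problem = problem, coupling = coupling,
    a = 0, b = 1, I1 = 1/3, I2 = 2/3, D = 1, dimension = 1L,
    cross = c(1, 1), h = 1/30, dx = 1/300, dt_p = 1e-4, dt_b = 1e-4,
    t_final = 1, output_times = c(0.1, 1), N = 1000,
    J = 0, mu = 0, k1 = 0, k2 = 0, rho = 0, P_lambda = 0,
    repeats = 500L, seed = 1L
  )
  if (problem == "morphogen") {
    cfg$J <- 1e4
    cfg$mu <- 10
    cfg$repeats <- 1000L
    cfg$output_times <- c(0.01, 1)
  } else if (problem == "bimolecular3d") {
    cfg$b <- 10
    cfg$I1 <- 10/3
    cfg$I2 <- 20/3
    cfg$dimension <- 3L
    cfg$h <- 1/3
    cfg$N <- 465
    cfg$k1 <- 0.1
    cfg$k2 <- 89.7
    cfg$rho <- 0.06
    cfg$P_lambda <- 2.5e-5
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "blend_config")
}

#' @export
print.blend_config <- function(x, ...) {
  cat(sprintf("blend_config: problem = %s, coupling = %s, N = %g, repeats = %d, seed = %d\n",
              x$problem, x$coupling, x$N, as.integer(x$repeats),
              as.integer(x$seed)))
  invisible(x)
}

#' Geometry, mesh, reactions and initial profile of a configuration
#'
#' Convenience accessors turning a [problem_config()] into the package's
#' working objects.
#'
#' @param config a [problem_config()].
#' @return `config_geometry()`: a [blend_geometry()]; `config_mesh()`: a
#'   [build_mesh()] (hybrid couplings only); `config_reactions()`: a
#'   [reaction_channels()]; `config_profile()`: the initial concentration as a
#'   function of `x` (particles per length, with the unit cross-section
#'   absorbed in 3D).
#' @export
config_geometry <- function(config) {
  blend_geometry(config$a, config$b, config$I1, config$I2, config$D,
                 dimension = config$dimension, cross = config$cross)
}

#' @rdname config_geometry
#' @export
config_mesh <- function(config) {
  build_mesh(config_geometry(config), config$dx, config$h, config$coupling)
}

#' @rdname config_geometry
#' @export
config_reactions <- function(config) {
  reaction_channels(k1 = config$k1, k2 = config$k2, mu = config$mu,
                    rho = config$rho, P_lambda = config$P_lambda)
}

#' @rdname config_geometry
#' @export
config_profile <- function(config) {
  switch(config$problem,
    uniform = {
      c0 <- config$N / (config$b - config$a)
      function(x) rep(c0, length(x))
    },
    redistribution = {
      c0 <- config$N / (config$I1 - config$a)
      I1 <- config$I1
      function(x) ifelse(x < I1, c0, 0)
    },
    morphogen = {
      c0 <- config$D * config$J / config$mu
      function(x) rep(c0, length(x))
    },
    bimolecular3d = {
      scale <- config$N / 465
      function(x) scale * (183 - 18 * x) / 2
    }
  )
}

# Expected mass of the initial profile over [lo, hi] (closed forms).
profile_mass <- function(config, lo, hi) {
  switch(config$problem,
    uniform = config$N * (hi - lo) / (config$b - config$a),
    redistribution = {
      w <- config$I1 - config$a
      config$N / w * max(0, min(hi, config$I1) - min(lo, config$I1))
    },
    morphogen = config$D * config$J / config$mu * (hi - lo),
    bimolecular3d = (config$N / 465) *
      ((183 * hi - 9 * hi^2) - (183 * lo - 9 * lo^2)) / 2
  )
}

# Sample n particle x-positions from the initial profile restricted to
# [lo, hi] (inverse-CDF for the linear profile, uniform otherwise).
sample_profile <- function(n, lo, hi, config) {
  if (n == 0L) return(numeric(0))
  if (config$problem == "bimolecular3d") {
    W <- 183 * (hi - lo) - 9 * (hi^2 - lo^2)
    u <- stats::runif(n)
    (183 - sqrt(183^2 - 36 * (183 * lo - 9 * lo^2 + u * W))) / 18
  } else if (config$problem == "redistribution") {
    stats::runif(n, lo, min(hi, config$I1))
  } else {
    stats::runif(n, lo, hi)
  }
}

# Largest-remainder apportionment of `total` particles over expected shares.
apportion <- function(total, shares) {
  if (sum(shares) <= 0) return(rep(0L, length(shares)))
  expected <- total * shares / sum(shares)
  base <- floor(expected)
  rem <- round(total - sum(base))
  if (rem > 0) {
    ord <- order(expected - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

sample_positions_3d <- function(n, lo, hi, config) {
  pos <- matrix(0, nrow = n, ncol = if (config$dimension == 3L) 3L else 1L)
  pos[, 1L] <- sample_profile(n, lo, hi, config)
  if (config$dimension == 3L) {
    pos[, 2L] <- stats::runif(n, 0, config$cross[1L])
    pos[, 3L] <- stats::runif(n, 0, config$cross[2L])
  }
  pos
}

#' Build the initial state of a configured run
#'
#' Realises the problem-specific initial condition for the configured
#' coupling.  Deterministic components (the PDE field) are set exactly to the
#' initial profile; stochastic components receive integer particle numbers
#' apportioned to the expected region masses by largest remainder, with
#' positions drawn from the normalised profile.  In blending regions the finer
#' representation is sampled first and the coarser matched: the
#' compartment-Brownian coupler samples particle positions and bins them,
#' while the PDE-compartment coupler synchronises the (possibly non-integer)
#' blending counts from the PDE.
#'
#' @param config a [problem_config()].
#' @return A hybrid state, [pde_field()], [compartment_field()] or
#'   [particle_set()] according to `config$coupling`.
#' @export
make_initial_condition <- function(config) {
  geom <- config_geometry(config)
  profile <- config_profile(config)
  influx <- if (config$problem == "morphogen") config$D * config$J else 0
  switch(config$coupling,
    "pde-compartment" = {
      mesh <- config_mesh(config)
      n_pure <- round(profile_mass(config, geom$I2, geom$b))
      xs <- sample_profile(n_pure, geom$I2, geom$b, config)
      C_pure <- tabulate(pmin(floor((xs - geom$I2) / mesh$h) + 1L, mesh$n_c),
                         nbins = mesh$n_c)
      hybrid_pc_state(geom, mesh, q0 = profile, C_pure0 = C_pure,
                      Ja = if (config$problem == "morphogen") -config$D * config$J else 0)
    },
    "compartment-brownian" = {
      mesh <- config_mesh(config)
      shares <- c(profile_mass(config, geom$a, geom$I1),
                  profile_mass(config, geom$I1, geom$b))
      nn <- apportion(config$N, shares)
      xs <- sample_profile(nn[1L], geom$a, geom$I1, config)
      C_pure <- tabulate(pmin(floor((xs - geom$a) / mesh$h) + 1L, mesh$n_c),
                         nbins = mesh$n_c)
      pos <- sample_positions_3d(nn[2L], geom$I1, geom$b, config)
      particles <- particle_set(pos, geom$I1, geom$b, cross = config$cross)
      hybrid_cb_state(geom, mesh, C_pure0 = C_pure, particles = particles,
                      influx_left = influx)
    },
    "pure-pde" = {
      pde_field(geom, geom$a, geom$b, config$dx, q0 = profile,
                diffusivity = "full",
                Ja = if (config$problem == "morphogen") -config$D * config$J else 0)
    },
    "pure-compartment" = {
      n <- int_div(geom$b - geom$a, config$h, "compartments (b-a)/h")
      xs <- sample_profile(config$N, geom$a, geom$b, config)
      C0 <- tabulate(pmin(floor((xs - geom$a) / config$h) + 1L, n), nbins = n)
      compartment_field(geom, geom$a, geom$b, config$h, C0 = C0,
                        diffusivity = "full", influx_left = influx)
    },
    "pure-brownian" = {
      pos <- sample_positions_3d(config$N, geom$a, geom$b, config)
      particle_set(pos, geom$a, geom$b, cross = config$cross)
    },
    stop("unknown coupling ", config$coupling, call. = FALSE)
  )
}

steps_between <- function(t0, t1, dt) {
  ns <- (t1 - t0) / dt
  if (abs(ns - round(ns)) > 1e-6) {
    stop("output times must be integer multiples of the window length",
         call. = FALSE)
  }
  as.integer(round(ns))
}

advance_state <- function(state, config, t0, t1, reactions) {
  if (inherits(state, "hybrid_pc")) {
    hybrid_pc_advance(state, reactions, config$dt_p,
                      steps_between(t0, t1, config$dt_p))
  } else if (inherits(state, "hybrid_cb")) {
    hybrid_cb_advance(state, reactions, config$dt_b,
                      steps_between(t0, t1, config$dt_b))
  } else if (inherits(state, "pde_field")) {
    pde_step(state, config$dt_p, steps_between(t0, t1, config$dt_p), reactions)
  } else if (inherits(state, "compartment_field")) {
    ssa_advance(state, reactions, t0, t1)
  } else if (inherits(state, "particle_set")) {
    brownian_run(state, config$D, reactions, config$dt_b, t1 - t0)
  } else {
    stop("unknown state type")
  }
}

# Region masses (left / blending / right third) and total for any state.
state_masses <- function(state, config) {
  g <- list(a = config$a, I1 = config$I1, I2 = config$I2, b = config$b)
  if (inherits(state, "hybrid_pc") || inherits(state, "hybrid_cb")) {
    m <- region_masses(state)
    c(m, total = if (inherits(state, "hybrid_cb")) total_count(state)
                 else sum(m))
  } else if (inherits(state, "pde_field")) {
    m <- c(pde_mass(state, g$a, g$I1), pde_mass(state, g$I1, g$I2),
           pde_mass(state, g$I2, g$b))
    c(left = m[1], blend = m[2], right = m[3], total = sum(m))
  } else if (inherits(state, "compartment_field")) {
    m <- c(compartment_mass(state, g$a, g$I1),
           compartment_mass(state, g$I1, g$I2),
           compartment_mass(state, g$I2, g$b))
    c(left = m[1], blend = m[2], right = m[3], total = sum(m))
  } else {
    x <- state$pos[, 1L]
    m <- c(sum(x < g$I1), sum(x >= g$I1 & x < g$I2), sum(x >= g$I2))
    c(left = m[1], blend = m[2], right = m[3], total = length(x))
  }
}

state_counts <- function(state) {
  if (inherits(state, "hybrid_pc") || inherits(state, "hybrid_cb")) {
    state$comp$C
  } else if (inherits(state, "compartment_field")) {
    state$C
  } else {
    NULL
  }
}

#' Run a configured ensemble experiment
#'
#' Runs `repeats` seeded realisations of the configured problem/coupling
#' (repeat `m` uses seed `seed + m`), records the region masses and the total
#' particle number at every output time, and — when a reference is available —
#' the region-wise relative mass error of the ensemble mean.  Problems with an
#' exact mean-field description (uniform, redistribution, morphogen) use the
#' analytic solution as the reference; the bimolecular problem requires an
#' [ensemble_ground_truth()] object passed as `reference`.
#'
#' @param config a [problem_config()].
#' @param reference `"auto"` (analytic where available), `"none"`, or a
#'   [run_experiment()] result of a pure engine to compare against.
#' @return An object of class `blend_experiment`: `times`, `region_labels`,
#'   matrices `mass_mean` / `mass_se` (output times x regions),
#'   `total_mean` / `total_se`, per-time mean compartment count vectors
#'   `mean_counts` (where the state has compartments), and an `rme`
#'   data.frame `(time, region, rme, mc_stderr)`.
#' @export
run_experiment <- function(config, reference = "auto") {
  stopifnot(inherits(config, "blend_config"))
  times <- config$output_times
  M <- as.integer(config$repeats)
  reactions <- config_reactions(config)
  nt <- length(times)
  msum <- matrix(0, nt, 4L)
  msq <- matrix(0, nt, 4L)
  csum <- NULL
  for (m in seq_len(M)) {
    set.seed(as.integer(config$seed) + m)
    state <- make_initial_condition(config)
    tcur <- 0
    for (k in seq_len(nt)) {
      state <- advance_state(state, config, tcur, times[k], reactions)
      tcur <- times[k]
      sm <- state_masses(state, config)
      msum[k, ] <- msum[k, ] + sm
      msq[k, ] <- msq[k, ] + sm^2
      cc <- state_counts(state)
      if (!is.null(cc)) {
        if (is.null(csum)) csum <- matrix(0, nt, length(cc))
        csum[k, ] <- csum[k, ] + cc
      }
    }
  }
  mean_all <- msum / M
  var_all <- pmax(msq / M - mean_all^2, 0) * M / max(M - 1, 1)
  se_all <- sqrt(var_all / M)
  labels <- switch(config$coupling,
                   "pde-compartment" = c("P", "H", "C"),
                   "compartment-brownian" = c("C", "H", "B"),
                   c("left", "blend", "right"))
  mass_mean <- mean_all[, 1:3, drop = FALSE]
  mass_se <- se_all[, 1:3, drop = FALSE]
  colnames(mass_mean) <- colnames(mass_se) <- labels
  res <- structure(
    list(config = config, times = times, region_labels = labels,
         mass_mean = mass_mean, mass_se = mass_se,
         total_mean = mean_all[, 4L], total_se = se_all[, 4L],
         mean_counts = if (!is.null(csum)) {
           lapply(seq_len(nt), function(k) csum[k, ] / M)
         },
         rme = NULL),
    class = "blend_experiment"
  )
  res$rme <- experiment_rme(res, reference)
  res
}

experiment_rme <- function(res, reference) {
  config <- res$config
  if (identical(reference, "none")) return(NULL)
  bounds <- rbind(c(config$a, config$I1), c(config$I1, config$I2),
                  c(config$I2, config$b))
  ref_mass <- if (identical(reference, "auto")) {
    if (config$problem == "bimolecular3d") return(NULL)
    sapply(seq_along(res$times), function(k) {
      sapply(1:3, function(r) analytic_region_mass(config, res$times[k],
                                                   bounds[r, 1], bounds[r, 2]))
    })
  } else if (inherits(reference, "blend_experiment")) {
    if (!identical(reference$times, res$times)) {
      stop("reference output times do not match", call. = FALSE)
    }
    t(reference$mass_mean)
  } else {
    stop("reference must be \"auto\", \"none\" or a blend_experiment",
         call. = FALSE)
  }
  do.call(rbind, lapply(seq_along(res$times), function(k) {
    data.frame(time = res$times[k], region = res$region_labels,
               rme = rme(res$mass_mean[k, ], ref_mass[, k]),
               mc_stderr = res$mass_se[k, ] / ref_mass[, k],
               row.names = NULL)
  }))
}

#' @export
print.blend_experiment <- function(x, ...) {
  cat(sprintf("blend_experiment: %s / %s, %d repeats\n", x$config$problem,
              x$config$coupling, as.integer(x$config$repeats)))
  cat("mean region masses:\n")
  print(cbind(time = x$times, x$mass_mean, total = x$total_mean))
  if (!is.null(x$rme)) {
    cat("relative mass error (vs reference):\n")
    print(x$rme, digits = 3)
  }
  invisible(x)
}

#' Read and write run configurations as JSON
#'
#' A [problem_config()] is a flat list of scalars and short numeric vectors,
#' serialised losslessly to JSON; `read_run_config(write_run_config(cfg, f))`
#' is the identity.
#'
#' @param config a [problem_config()].
#' @param path file path.
#' @return `read_run_config()` returns a `blend_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "blend_config"))
  # 17 significant digits: doubles round-trip exactly
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  cfg <- problem_config(raw$problem, raw$coupling)
  fields <- setdiff(names(raw), c("problem", "coupling"))
  for (f in fields) {
    cfg[[f]] <- if (f %in% c("dimension", "repeats", "seed")) {
      as.integer(raw[[f]])
    } else {
      as.numeric(raw[[f]])
    }
  }
  cfg
}

#' Write experiment outputs as CSV
#'
#' `write_rme_csv()` writes the relative-mass-error table
#' `(time, region, rme, mc_stderr)`; `write_masses_csv()` writes the mean
#' region masses and totals per output time.
#'
#' @param result a [run_experiment()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_rme_csv <- function(result, path) {
  stopifnot(inherits(result, "blend_experiment"))
  if (is.null(result$rme)) stop("experiment has no RME table", call. = FALSE)
  utils::write.csv(result$rme, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rme_csv
#' @export
write_masses_csv <- function(result, path) {
  stopifnot(inherits(result, "blend_experiment"))
  df <- data.frame(time = result$times, result$mass_mean,
                   total = result$total_mean, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
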