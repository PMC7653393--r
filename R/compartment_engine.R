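#' Compartment field for the mesoscopic engine
#'
#' A chain of well-mixed compartments of width `h` on `[lo, hi]` (with a
#' `cross`-section in 3D, giving compartment volume `V = h * cy * cz`).
#' Particles jump between neighbouring compartments at per-particle rates
#' derived from the engine's assigned diffusivity evaluated at the *shared
#' face* between the two compartments, divided by `h^2`; this chain has the
#' divergence-form diffusion equation `dc/dt = d/dx(D(x) dc/dx)` as its
#' diffusive limit, and automatically yields zero jump rates at a blending
#' interface where the split diffusivity vanishes.  Rates at the region's
#' outer faces are zero (zero flux).
#'
#' Counts are stored as doubles: the couplers synchronise non-integer mass
#' into blending compartments, while counts outside blending regions stay
#' integer-valued.
#'
#' @param geom a [blend_geometry()].
#' @param lo,hi region endpoints (multiples of `h` apart).
#' @param h compartment width.
#' @param C0 initial counts: scalar or vector of length `n`.
#' @param diffusivity `"full"`, `"d1"` or `"d2"`.
#' @param influx_left zeroth-order boundary influx (particles/time) added to
#'   the leftmost compartment, used to realise a constant-flux boundary
#'   condition mesoscopically.
#' @return An object of class `compartment_field`.
#' @examples
#' g <- blend_geometry(0, 1, 1/3, 2/3, D = 1)
#' f <- compartment_field(g, 0, 1, h = 1/30, C0 = 50)
#' jump_rates(f, 5)  # c(900, 900) for D = 1, h = 1/30
#' @export
compartment_field <- function(geom, lo, hi, h, C0,
                              diffusivity = c("full", "d1", "d2"),
                              influx_left = 0) {
  stopifnot(inherits(geom, "blend_geometry"))
  diffusivity <- match.arg(diffusivity)
  n <- int_div(hi - lo, h, "number of compartments (hi-lo)/h")
  faces <- lo + (0:n) * h
  deff <- switch(diffusivity,
                 full = function(z) rep(geom$D, length(z)),
                 d1 = function(z) blend_d1(geom, z),
                 d2 = function(z) blend_d2(geom, z))
  faceD <- deff(faces)
  faceD[c(1L, n + 1L)] <- 0  # zero-flux outer boundaries
  cross <- if (geom$dimension == 3L) prod(geom$cross) else 1
  C <- if (length(C0) == 1L) rep(C0, n) else C0
  if (length(C) != n) stop("C0 has the wrong length", call. = FALSE)
  structure(
    list(C = as.numeric(C), h = h, lo = lo, hi = hi, n = n,
         centers = lo + (seq_len(n) - 0.5) * h,
         rateL = faceD[seq_len(n)] / h^2,
         rateR = faceD[seq_len(n) + 1L] / h^2,
         V = rep(h * cross, n),
         influx_left = influx_left,
         geom = geom, diffusivity = diffusivity),
    class = "compartment_field"
  )
}

#' Per-particle jump rates of a compartment
#'
#' @param field a [compartment_field()].
#' @param i compartment index.
#' @return Named numeric `c(left = , right = )`, the per-particle rates of
#'   jumping out of compartment `i` in each direction.
#' @export
jump_rates <- function(field, i) {
  stopifnot(inherits(field, "compartment_field"), i >= 1, i <= field$n)
  c(left = field$rateL[i], right = field$rateR[i])
}

#' Event propensities of a compartment field
#'
#' Returns the full propensity table used by the stochastic simulation
#' algorithm: per compartment, the diffusion propensities `C_i * rate` and the
#' reaction propensities (`k2 * V_i` adding one particle, `mu * C_i` removing
#' one, `k1 * C_i (C_i - 1) / (2 V_i)` removing two).  Negative counts
#' (transiently possible in blending compartments) contribute zero.
#'
#' @param field a [compartment_field()].
#' @param reactions a [reaction_channels()] or `NULL`.
#' @return A data.frame with one row per compartment and columns
#'   `diff_left`, `diff_right`, `production`, `decay`, `pair`.
#' @export
propensities <- function(field, reactions = NULL) {
  stopifnot(inherits(field, "compartment_field"))
  r <- as_reactions(reactions)
  Cp <- pmax(field$C, 0)
  k0 <- r$k2 * field$V
  k0[1L] <- k0[1L] + field$influx_left
  data.frame(
    diff_left = Cp * field$rateL,
    diff_right = Cp * field$rateR,
    production = k0,
    decay = r$mu * Cp,
    pair = r$k1 * pmax(Cp * (Cp - 1), 0) / (2 * field$V)
  )
}

#' Advance a compartment field with the Gillespie direct method
#'
#' Executes exact stochastic simulation events (exponential waiting times from
#' the total propensity; event chosen proportionally to propensity) from `t0`
#' until the next event time would exceed `t_end`, leaving the state at
#' `t_end`.  Counts change by integer stoichiometry per event, so diffusion
#' events conserve the total count exactly.
#'
#' @param field a [compartment_field()].
#' @param reactions a [reaction_channels()] or `NULL`.
#' @param t0,t_end window endpoints, `t_end >= t0`.
#' @return The advanced `compartment_field`.
#' @export
ssa_advance <- function(field, reactions = NULL, t0 = 0, t_end) {
  stopifnot(inherits(field, "compartment_field"), t_end >= t0)
  r <- as_reactions(reactions)
  k0 <- r$k2 * field$V
  k0[1L] <- k0[1L] + field$influx_left
  field$C <- cpp_ssa_run(field$C, field$rateL, field$rateR, field$V,
                         k0, r$mu, r$k1, t0, t_end)
  field
}

#' Total count of a compartment field over a window
#'
#' Sums compartment counts whose centres fall in `[x_lo, x_hi]`
#' (compartment-centre attribution).
#'
#' @param field a [compartment_field()].
#' @param x_lo,x_hi window endpoints (defaults: the whole region).
#' @return Total count.
#' @export
compartment_mass <- function(field, x_lo = NULL, x_hi = NULL) {
  stopifnot(inherits(field, "compartment_field"))
  if (is.null(x_lo)) x_lo <- field$lo
  if (is.null(x_hi)) x_hi <- field$hi
  sum(field$C[field$centers >= x_lo & field$centers <= x_hi])
}
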