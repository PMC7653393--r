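#' Reaction system for the production-degradation family
#'
#' Collects the reaction channels used across the engines:
#' \describe{
#'   \item{zeroth order}{production `0 -> A` at rate `k2`
#'     (particles / volume / time); mesoscopic propensity `k2 * V_i`,
#'     Brownian realisation Poisson placement, mean-field term `+k2`.}
#'   \item{first order}{decay `A -> 0` at rate `mu` (1 / time); mesoscopic
#'     propensity `mu * C_i`, Brownian realisation exact exponential thinning
#'     with probability `1 - exp(-mu * dt)`, mean-field term `-mu * c`.}
#'   \item{second order}{pair annihilation `2A -> 0` at mesoscopic rate `k1`
#'     (volume / particles / time); propensity `k1 * C_i * (C_i - 1) / (2 V_i)`
#'     removing 2 particles, which reproduces the mean-field term `-k1 c^2`
#'     under the Poisson moment closure.  The Brownian realisation is the
#'     lambda-rho rule: an unordered pair closer than `rho` reacts with
#'     per-step probability `P_lambda`.}
#' }
#'
#' The mesoscopic rate `k1` and the microscopic pair `(rho, P_lambda)` are
#' configured independently; no compartment-size correction is applied.
#'
#' @param k1 mesoscopic pair-annihilation rate (volume / particles / time).
#' @param k2 production rate (particles / volume / time).
#' @param mu decay rate (1 / time).
#' @param rho interaction radius for the Brownian pair rule (length).
#' @param P_lambda per-step reaction probability for a pair within `rho`.
#' @return An object of class `reaction_system`.
#' @examples
#' reaction_channels(k1 = 0.1, k2 = 89.7, rho = 0.06, P_lambda = 2.5e-5)
#' @export
reaction_channels <- function(k1 = 0, k2 = 0, mu = 0, rho = 0, P_lambda = 0) {
  vals <- c(k1 = k1, k2 = k2, mu = mu, rho = rho, P_lambda = P_lambda)
  if (any(vals < 0)) stop("reaction rates must be non-negative", call. = FALSE)
  structure(as.list(vals), class = "reaction_system")
}

as_reactions <- function(reactions) {
  if (is.null(reactions)) return(reaction_channels())
  stopifnot(inherits(reactions, "reaction_system"))
  reactions
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("reaction_system: 2A->0 at k1 = %g (rho = %g, P_lambda = %g), 0->A at k2 = %g, A->0 at mu = %g\n",
              x$k1, x$rho, x$P_lambda, x$k2, x$mu))
  invisible(x)
}
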