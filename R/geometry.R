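#' Blending geometry: domain, interfaces and split diffusivities
#'
#' Defines the partition of the domain `[a, b]` into a coarse-model region
#' `[a, I1]`, a blending region `[I1, I2]` and a fine-model region `[I2, b]`,
#' together with the complementary split of the macroscopic diffusion
#' coefficient `D` into `D1(x)` and `D2(x)`.  Inside the blending region,
#' `D1(x) = D * beta1(x)` with the blending fraction `beta1` equal to 1 at
#' `I1`, 0 at `I2` and monotonically non-increasing in between; `D2 = D - D1`
#' everywhere, so the two engines together always carry the full diffusivity.
#'
#' The shipped blending fraction is the linear ramp
#' `beta1(x) = (I2 - x) / (I2 - I1)`.  A user-supplied `beta1` function is
#' accepted for the R-level inspection utilities, but the compiled hybrid
#' engines require the linear blend.
#'
#' @param a,b domain endpoints (length units).
#' @param I1,I2 interface positions, `a < I1 < I2 < b`.
#' @param D macroscopic diffusion coefficient (length^2 / time).
#' @param blend `"linear"`, or a function of position returning the blending
#'   fraction `beta1` on `[I1, I2]` (must satisfy `beta1(I1) = 1`,
#'   `beta1(I2) = 0`).
#' @param dimension 1 or 3.  In 3D the interfaces are planes of constant `x`
#'   and blending depends on `x` only; `cross` gives the `y`/`z` extents.
#' @param cross length-2 numeric, the cross-section extents in 3D.
#'
#' @return An object of class `blend_geometry`.
#' @examples
#' g <- blend_geometry(0, 1, 1/3, 2/3, D = 1)
#' blend_d1(g, 0.5)  # 0.5
#' blend_d1(g, 0.5) + blend_d2(g, 0.5)  # = D
#' @export
blend_geometry <- function(a, b, I1, I2, D, blend = "linear",
                           dimension = 1L, cross = c(1, 1)) {
  if (!(a < I1 && I1 < I2 && I2 < b)) {
    stop("interface ordering violated: need a < I1 < I2 < b", call. = FALSE)
  }
  if (!is.numeric(D) || length(D) != 1L || D <= 0) {
    stop("D must be a positive scalar", call. = FALSE)
  }
  if (!dimension %in% c(1L, 3L)) stop("dimension must be 1 or 3", call. = FALSE)
  if (is.character(blend)) {
    blend <- match.arg(blend, "linear")
    beta1 <- function(x) (I2 - x) / (I2 - I1)
    linear <- TRUE
  } else if (is.function(blend)) {
    beta1 <- blend
    linear <- FALSE
    if (abs(beta1(I1) - 1) > 1e-12 || abs(beta1(I2)) > 1e-12) {
      stop("beta1 must satisfy beta1(I1) = 1 and beta1(I2) = 0", call. = FALSE)
    }
  } else {
    stop("blend must be \"linear\" or a function", call. = FALSE)
  }
  structure(
    list(a = a, b = b, I1 = I1, I2 = I2, D = D, beta1 = beta1,
         linear = linear, dimension = as.integer(dimension),
         cross = as.numeric(cross)),
    class = "blend_geometry"
  )
}

#' @export
print.blend_geometry <- function(x, ...) {
  cat(sprintf("blend_geometry: [%g, %g], interfaces at %g and %g, D = %g (%dD, %s blend)\n",
              x$a, x$b, x$I1, x$I2, x$D, x$dimension,
              if (x$linear) "linear" else "custom"))
  invisible(x)
}

#' Split diffusivities D1 and D2
#'
#' `blend_d1()` evaluates the coarse-side diffusivity: `D` on `[a, I1)`,
#' `D * beta1(x)` on `[I1, I2]` and 0 on `(I2, b]`.  `blend_d2()` is its
#' complement, `D - D1(x)`, so `blend_d1(g, x) + blend_d2(g, x) == g$D` for
#' every `x`.
#'
#' @param geom a [blend_geometry()].
#' @param x numeric vector of positions.
#' @return Numeric vector of diffusivities.
#' @export
blend_d1 <- function(geom, x) {
  stopifnot(inherits(geom, "blend_geometry"))
  out <- numeric(length(x))
  left <- x < geom$I1
  right <- x > geom$I2
  mid <- !left & !right
  out[left] <- geom$D
  out[mid] <- geom$D * pmin(pmax(geom$beta1(x[mid]), 0), 1)
  out[right] <- 0
  out
}

#' @rdname blend_d1
#' @export
blend_d2 <- function(geom, x) {
  stopifnot(inherits(geom, "blend_geometry"))
  geom$D - blend_d1(geom, x)
}

# Drift of the fine-side diffusivity dD2/dx for the Euler-Maruyama update;
# at the kinks I1, I2 the one-sided derivative from inside the blending
# region is used (linear blend only).
blend_d2_slope <- function(geom, x) {
  if (!geom$linear) stop("drift is only available for the linear blend", call. = FALSE)
  slope <- geom$D / (geom$I2 - geom$I1)
  ifelse(x >= geom$I1 & x <= geom$I2, slope, 0)
}

int_div <- function(num, den, what) {
  r <- num / den
  if (abs(r - round(r)) > 1e-6 * max(1, abs(r))) {
    stop(sprintf("%s = %g is not an integer (%g / %g)", what, r, num, den),
         call. = FALSE)
  }
  as.integer(round(r))
}

#' Joint mesh for a blending coupler
#'
#' Computes the voxel/compartment bookkeeping shared by the couplers: the
#' number of PDE voxels per compartment `gamma = h / dx`, the voxel counts
#' `n_p` (pure PDE region) and `n_1` (blending region), and the compartment
#' counts `n_2` (blending region) and `n_c` (pure compartment region).  For
#' the PDE-compartment coupler the pure compartment region is `[I2, b]`; for
#' the compartment-Brownian coupler it is `[a, I1]`.
#'
#' All region lengths must be integer multiples of the respective mesh width;
#' a non-integer division is a configuration error naming the offending
#' quantity.
#'
#' @param geom a [blend_geometry()].
#' @param dx PDE voxel width.
#' @param h compartment width (along `x` in 3D).
#' @param coupling `"pde-compartment"` or `"compartment-brownian"`.
#' @return An object of class `blend_mesh` with fields `dx`, `h`, `gamma`,
#'   `n_p`, `n_1`, `n_2`, `n_c` and `coupling`.
#' @examples
#' g <- blend_geometry(0, 1, 1/3, 2/3, D = 1)
#' build_mesh(g, dx = 1/300, h = 1/30)
#' @export
build_mesh <- function(geom, dx, h, coupling = c("pde-compartment",
                                                 "compartment-brownian")) {
  stopifnot(inherits(geom, "blend_geometry"))
  coupling <- match.arg(coupling)
  gamma <- int_div(h, dx, "gamma = h/dx")
  n_1 <- int_div(geom$I2 - geom$I1, dx, "n_1 = (I2-I1)/dx")
  n_2 <- int_div(geom$I2 - geom$I1, h, "n_2 = (I2-I1)/h")
  n_p <- int_div(geom$I1 - geom$a, dx, "n_p = (I1-a)/dx")
  n_c <- if (coupling == "pde-compartment") {
    int_div(geom$b - geom$I2, h, "n_c = (b-I2)/h")
  } else {
    int_div(geom$I1 - geom$a, h, "n_c = (I1-a)/h")
  }
  if (n_1 != gamma * n_2) {
    stop("mesh inconsistency: n_1 != gamma * n_2", call. = FALSE)
  }
  structure(
    list(dx = dx, h = h, gamma = gamma, n_p = n_p, n_1 = n_1,
         n_2 = n_2, n_c = n_c, coupling = coupling),
    class = "blend_mesh"
  )
}

#' @export
print.blend_mesh <- function(x, ...) {
  cat(sprintf("blend_mesh (%s): dx = %g, h = %g, gamma = %d, n_p = %d, n_1 = %d, n_2 = %d, n_c = %d\n",
              x$coupling, x$dx, x$h, x$gamma, x$n_p, x$n_1, x$n_2, x$n_c))
  invisible(x)
}
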