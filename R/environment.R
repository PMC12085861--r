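# Abiotic environment: sunlight availability composition and the cantilever
# wind model on a conical-frustum trunk.

#' Total available sunlight
#'
#' Sum of the overall mean sunlight (OMS), percentage of full sunlight (PFS),
#' variation of sunlight with height (VS_H) and an error term. The components
#' are dimension-agnostic irradiance-proportional scalars; the total is
#' exposed as a diagnostic of the light environment driving phototropic
#' deflection.
#'
#' @param OMS,PFS,VS_H,E Finite numeric components.
#' @return `OMS + PFS + VS_H + E`.
#' @examples
#' total_available_sunlight(1.0, 0.5, -0.2, 0.05)
#' @export
total_available_sunlight <- function(OMS, PFS, VS_H, E = 0) {
  v <- c(OMS, PFS, VS_H, E)
  if (any(!is.finite(v))) stop("sunlight components must be finite",
                               call. = FALSE)
  OMS + PFS + VS_H + E
}

#' Final deflection angle from sunlight and wind
#'
#' `theta_p_f = theta + theta_S + theta_w`: the trunk angle plus the sunlight
#' and wind deflection angles.
#'
#' @param theta Current trunk angle (rad).
#' @param theta_S Sunlight deflection angle (rad).
#' @param theta_w Wind deflection angle (rad).
#' @return Final deflection angle (rad).
#' @examples
#' compose_final_angle(0.1 * pi, 0.3 * pi, 0.21 * pi)  # 0.61 * pi
#' @export
compose_final_angle <- function(theta, theta_S = 0, theta_w = 0) {
  v <- c(theta, theta_S, theta_w)
  if (any(!is.finite(v))) stop("angles must be finite", call. = FALSE)
  theta + theta_S + theta_w
}

#' Density-weighted second moment of the frustum trunk
#'
#' For a conical-frustum trunk of length `k`, top radius `x_top` and base
#' radius `x_base`, the (wood-density-weighted) second moment is
#' \deqn{I = \frac{\rho' \pi k}{10}\,
#'   \frac{|x_{top}^5 - x_{base}^4 x_{top} + x_{base}^5|}{|x_{top}-x_{base}|}.}
#' Absolute values keep `I > 0` for tapered trunks (the raw quotient is
#' negative when `x_top < x_base`, which would be unphysical). Note that the
#' density weighting gives `I` (and hence `Y*I`) nonstandard units; internal
#' consistency across the wind relations is the contract.
#'
#' @param x_top Top radius (m, `>= 0`).
#' @param x_base Base radius (m, `> 0`), distinct from `x_top`.
#' @param k Trunk length (m, `> 0`).
#' @param rho Wood density `rho'` (kg/m^3, `> 0`).
#' @return Second moment `I` (`> 0`).
#' @examples
#' frustum_second_moment(0.10, 0.15, 10, 600)
#' @export
frustum_second_moment <- function(x_top, x_base, k, rho = 600) {
  if (x_top < 0 || x_base <= 0 || k <= 0 || rho <= 0)
    stop("require x_top >= 0, x_base > 0, k > 0, rho > 0", call. = FALSE)
  if (abs(x_top - x_base) < 1e-9)
    stop("singular geometry: x_top == x_base (formula is singular at equal ",
         "radii); perturb one radius", call. = FALSE)
  rho * pi * k / 10 *
    abs(x_top^5 - x_base^4 * x_top + x_base^5) / abs(x_top - x_base)
}

#' Wind-induced tip deflection and deflection angle
#'
#' Cantilever tip deflection under a tip wind force `F`:
#' `D = F k^3 / (3 Y I)`, and the wind deflection angle
#' `theta_w = acos(k / (D + x_top))` with the argument clamped to
#' `[-1, 1]` (for `k > D + x_top` the angle is 0).
#'
#' @param F Tip wind force (N).
#' @param k Trunk length (m, `> 0`).
#' @param Y Elastic modulus (Pa, `> 0`).
#' @param I Second moment from [frustum_second_moment()] (`> 0`).
#' @param x_top Top radius (m).
#' @return List with `D` (m) and `theta_w` (rad).
#' @examples
#' I <- frustum_second_moment(0.10, 0.15, 10, 600)
#' wind_deflection(100, 10, 1.14e10, I, 0.10)
#' @export
wind_deflection <- function(F, k, Y, I, x_top = 0) {
  if (k <= 0 || Y <= 0 || I <= 0)
    stop("k, Y and I must be positive", call. = FALSE)
  D <- F * k^3 / (3 * Y * I)
  arg <- k / (D + x_top)
  theta_w <- acos(min(max(arg, -1), 1))
  list(D = D, theta_w = theta_w)
}

#' Wind-adjusted current curvature
#'
#' Linear elastic constitutive relation between the relaxed and the current
#' curvature: `beta = bstar + q / (Y * I)`.
#'
#' @param bstar Relaxed curvature (1/m).
#' @param q Contact couple (N m).
#' @param Y Elastic modulus (Pa).
#' @param I Second moment (`Y * I > 0`).
#' @return Current curvature `beta` (1/m).
#' @export
wind_adjusted_curvature <- function(bstar, q, Y, I) {
  if (any(Y * I <= 0)) stop("rigidity Y*I must be positive", call. = FALSE)
  bstar + q / (Y * I)
}

#' Wind-adjusted curvature with the frustum moment expanded
#'
#' The same constitutive relation with the frustum second moment substituted
#' in closed form; equals [wind_adjusted_curvature()] with
#' `I = frustum_second_moment(x_top, x_base, k, rho)` to within rounding.
#'
#' @inheritParams wind_adjusted_curvature
#' @inheritParams frustum_second_moment
#' @return Current curvature `beta` (1/m).
#' @export
wind_adjusted_curvature_frustum <- function(bstar, q, Y, x_top, x_base, k,
                                            rho = 600) {
  if (abs(x_top - x_base) < 1e-9)
    stop("singular geometry: x_top == x_base", call. = FALSE)
  num <- 10 * q * abs(x_top - x_base)
  den <- Y * rho * pi * k *
    abs(x_top^5 - x_base^4 * x_top + x_base^5)
  if (any(den <= 0)) stop("rigidity must be positive", call. = FALSE)
  bstar + num / den
}
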