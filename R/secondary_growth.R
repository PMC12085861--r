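# Secondary (diffuse) growth: exponential trunk taper from the bulk-modulus
# relation, DBH anchoring, radial growth velocity and areal mass density.

#' Construct a trunk taper parameterisation
#'
#' The trunk radius at height `k_h` follows the exponential taper
#' \deqn{x(k_h) = \sqrt{\lambda\, e^{-a k_h}},\qquad
#'       a = \rho' g / B,\qquad \lambda = \frac{-\rho' g}{B\pi}\,c',}
#' where `B` is the bulk modulus of the trunk tissue (it carries a built-in
#' negative-sign convention: pressure increase accompanies volume decrease)
#' and `c'` an integration constant. Only the composites `a` and `lambda`
#' enter the radius law, so validity is enforced on `lambda > 0` rather than
#' on `B` and `c'` individually. Either supply `B` and `c_prime` directly, or
#' two anchor radii (`x_base` at ground, `x_dbh` at `breast_height`) from
#' which [calibrate_taper()] derives them.
#'
#' @param rho Wood density `rho'` (kg/m^3).
#' @param g Gravitational field (N/kg).
#' @param B Bulk modulus (Pa); required unless anchors are given.
#' @param c_prime Integration constant; required unless anchors are given.
#' @param x_base,x_dbh Optional anchor radii (m): base radius and radius at
#'   `breast_height`. When given they override `B`/`c_prime` via calibration.
#' @param breast_height Breast height for the DBH anchor (m, default 1.4).
#' @return Object of class `palm_taper` with fields `rho`, `g`, `B`,
#'   `c_prime`, `a`, `lambda`, `breast_height`.
#' @examples
#' tp <- palm_taper(x_base = 0.175, x_dbh = 0.16)
#' radius_at_height(0, tp)    # 0.175
#' dbh(tp)                    # 0.32
#' @export
palm_taper <- function(rho = 600, g = 9.8, B = NULL, c_prime = NULL,
                       x_base = NULL, x_dbh = NULL, breast_height = 1.4) {
  stopifnot(rho > 0, g > 0, breast_height > 0)
  if (!is.null(x_base) && !is.null(x_dbh)) {
    cal <- calibrate_taper(x_base, x_dbh, breast_height, rho, g)
    B <- cal$B; c_prime <- cal$c_prime
  }
  if (is.null(B) || is.null(c_prime))
    stop("supply either (B, c_prime) or anchor radii (x_base, x_dbh)",
         call. = FALSE)
  a <- rho * g / B
  lambda <- (-rho * g / (B * pi)) * c_prime
  if (!is.finite(lambda) || lambda <= 0)
    stop("taper constant must be positive: lambda = (-rho*g/(B*pi))*c' <= 0 ",
         "for this parameterisation", call. = FALSE)
  structure(list(rho = rho, g = g, B = B, c_prime = c_prime,
                 a = a, lambda = lambda, breast_height = breast_height),
            class = "palm_taper")
}

#' @export
print.palm_taper <- function(x, ...) {
  cat("<palm_taper>\n")
  cat(sprintf("  base radius  : %.4f m\n", sqrt(x$lambda)))
  cat(sprintf("  DBH (%.1f m) : %.4f m\n", x$breast_height, dbh(x)))
  cat(sprintf("  taper rate a : %.6g 1/m   (B = %.4g, c' = %.4g)\n",
              x$a, x$B, x$c_prime))
  invisible(x)
}

#' Calibrate the taper from two anchor radii
#'
#' Returns the bulk modulus `B` and integration constant `c'` for which the
#' exponential taper passes exactly through a base radius and a radius
#' observed at height `h`:
#' `a = (2/h) log(x_base_obs / x_at_h_obs)`, `B = rho*g/a`,
#' `c' = -(B*pi/(rho*g)) * x_base_obs^2`.
#'
#' @param x_base_obs Observed base radius (m, `> x_at_h_obs`).
#' @param x_at_h_obs Observed radius at height `h` (m, `> 0`).
#' @param h Anchor height (m, `> 0`).
#' @param rho,g Density and gravity as in [palm_taper()].
#' @return List with `c_prime` and `B`.
#' @examples
#' calibrate_taper(0.16, 0.14, 1.4)
#' @export
calibrate_taper <- function(x_base_obs, x_at_h_obs, h = 1.4,
                            rho = 600, g = 9.8) {
  if (!(h > 0)) stop("anchor height h must be positive", call. = FALSE)
  if (!(x_at_h_obs > 0) || x_at_h_obs >= x_base_obs)
    stop("calibration requires a tapered trunk: 0 < x_at_h_obs < x_base_obs",
         call. = FALSE)
  a <- (2 / h) * log(x_base_obs / x_at_h_obs)
  B <- rho * g / a
  c_prime <- -(B * pi / (rho * g)) * x_base_obs^2
  list(c_prime = c_prime, B = B)
}

#' Trunk radius at a given height
#'
#' @param k_h Height above ground (m, `>= 0`); vectorised.
#' @param taper A [palm_taper()].
#' @return Radius `x(k_h)` (m).
#' @export
radius_at_height <- function(k_h, taper) {
  stopifnot(inherits(taper, "palm_taper"))
  if (any(k_h < 0)) stop("height must be non-negative", call. = FALSE)
  sqrt(taper$lambda * exp(-taper$a * k_h))
}

#' Diameter at breast height
#'
#' Twice the taper radius at the configured breast height (default 1.4 m).
#'
#' @param taper A [palm_taper()].
#' @return DBH (m).
#' @export
dbh <- function(taper) 2 * radius_at_height(taper$breast_height, taper)

#' Radial growth velocity
#'
#' Rate of change of the moving-tip radius as the trunk length passes `k_h`,
#' i.e. the chain rule `V^r = (dx/dk) * a_v = -(a/2) x(k_h) a_v` applied to
#' the taper law (negative: the tip narrows as the tree grows). The
#' `"substituted"` form evaluates the same quantity through the substitutions
#' `Gamma = exp(-a k)` and `zeta = lambda`:
#' `V^r = -(rho' g / B) zeta Gamma a_v / (2 sqrt(zeta Gamma))`.
#'
#' @param k_h Height / trunk length (m); vectorised.
#' @param a_v Apical growth velocity (m/year, `>= 0`).
#' @param taper A [palm_taper()].
#' @param form `"chain"` (default) or `"substituted"`; algebraically equal.
#' @return `V^r` (m/year).
#' @export
radial_velocity <- function(k_h, a_v, taper,
                            form = c("chain", "substituted")) {
  form <- match.arg(form)
  stopifnot(inherits(taper, "palm_taper"))
  if (a_v < 0) stop("a_v must be >= 0", call. = FALSE)
  if (form == "chain") {
    -(taper$a / 2) * radius_at_height(k_h, taper) * a_v
  } else {
    Gamma <- exp(-taper$a * k_h)
    zeta <- taper$lambda
    -(taper$rho * taper$g / taper$B) * zeta * Gamma * a_v /
      (2 * sqrt(zeta * Gamma))
  }
}

#' Cross-section area and areal mass density
#'
#' `A_r = pi x(k_h)^2` and `rho''' = rho' A_r`. The `A_exp` element evaluates
#' the area through the exponential taper form
#' `A = lambda * pi * exp(-a k_h)` directly; it equals `A_r` to rounding.
#'
#' @param k_h Height above ground (m); vectorised.
#' @param taper A [palm_taper()].
#' @return List with `A_r` (m^2), `rho3` (kg/m), `A_exp` (m^2).
#' @export
trunk_area_and_density <- function(k_h, taper) {
  x <- radius_at_height(k_h, taper)
  A <- pi * x^2
  A_exp <- taper$lambda * pi * exp(-taper$a * k_h)
  list(A_r = A, rho3 = taper$rho * A, A_exp = A_exp)
}
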