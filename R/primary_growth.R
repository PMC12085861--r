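# Primary (apical) growth: tropism-driven seeding of curvature/torsion toward
# a preferred growth direction and the small-deflection apical system.

sgn1 <- function(x) ifelse(x >= 0, 1, -1)  # sign with sgn(0) = +1 tie-break

#' Preferred growth direction adjusted for sunlight and wind
#'
#' Combines the gravitropic preferred direction `f_p` with the
#' sunlight-and-wind-adjusted direction `f_p_star` into the final preferred
#' direction: `f_p` is rotated by the trunk movement angle `theta` toward the
#' in-plane normal `f_p_beta`, where
#' `f_p_gamma = (f_p x f_p_star)/||f_p x f_p_star||` and
#' `f_p_beta = f_p_gamma x f_p_star`. The default composition is the
#' renormalised vector sum `f_p cos(theta) + f_p_beta sin(theta)`; a strict
#' literal mode replaces the sum by a cross product of the two scaled terms
#' (it vanishes at `theta` in `{0, pi/2}` and is provided for comparison
#' only).
#'
#' @param f_p Unit preferred direction from growth + gravitropism.
#' @param f_p_star Unit preferred direction including sunlight and wind
#'   (must not be parallel to `f_p`).
#' @param theta Trunk movement angle (rad).
#' @param strict_literal Use the literal cross-product composition.
#' @return List with unit vectors `f_p_F`, `f_p_gamma`, `f_p_beta`.
#' @examples
#' ez <- c(0, 0, 1); ex <- c(1, 0, 0)
#' d <- env_adjusted_direction(ez, (ez + 0.1 * ex) / sqrt(1.01), 0.2)
#' sum(d$f_p_F^2)  # 1
#' @export
env_adjusted_direction <- function(f_p, f_p_star, theta,
                                   strict_literal = FALSE) {
  f_p <- as.numeric(f_p); f_p_star <- as.numeric(f_p_star)
  stopifnot(length(f_p) == 3L, length(f_p_star) == 3L, is.finite(theta))
  cp <- cross3(f_p, f_p_star)
  ncp <- vnorm(cp)
  if (ncp < 1e-12)
    stop("degenerate directions: f_p and f_p_star are parallel, ",
         "the normal f_p_gamma is undefined", call. = FALSE)
  f_p_gamma <- cp / ncp
  f_p_beta <- cross3(f_p_gamma, f_p_star)
  f_p_beta <- f_p_beta / vnorm(f_p_beta)
  v <- if (strict_literal) {
    cross3(f_p * cos(theta), f_p_beta * sin(theta))
  } else {
    f_p * cos(theta) + f_p_beta * sin(theta)
  }
  nv <- vnorm(v)
  if (nv < 1e-12)
    stop("composed direction vanished (strict literal mode at a degenerate ",
         "angle)", call. = FALSE)
  list(f_p_F = v / nv, f_p_gamma = f_p_gamma, f_p_beta = f_p_beta)
}

#' Tropism-driven initial strains toward a target direction
#'
#' Given the final preferred growth direction and the director frame of the
#' newly laid material, returns the initial curvature `beta0`, its along-rod
#' derivative, and the initial torsional strain `gamma0` that steer the
#' tangent toward the target within a look-ahead arc. Writing
#' `c_i = f_target . f_i`:
#' \deqn{\beta_0 = sgn(c_1)\,\frac{\beta_{max}}{2}\sqrt{2(1-c_3)},\quad
#'       \frac{d\beta_0}{dr} = \frac{\beta_{max}^2}{2}
#'         \bigl(c_1 - sgn(c_1)\sqrt{2(1-c_3)}\bigr),}
#' and `gamma0 = sgn(c1) * beta_max * c2 / sqrt(2(1-c3))` when `beta0 != 0`,
#' else 0. Square-root arguments are clamped to `[0, 4]` against rounding;
#' `sgn(0)` is `+1`.
#'
#' @param f_target Unit target direction (typically `f_p_F` from
#'   [env_adjusted_direction()]).
#' @param frame A [material_frame()] at the seeding point.
#' @param beta_max Maximum curvature (1/m, `>= 0`). `beta_max = 0` forces
#'   straight growth (`beta0 = gamma0 = 0`).
#' @return List with `beta0` (1/m), `dbeta0_dr` (1/m^2), `gamma0` (1/m).
#' @seealso [tropism_residuals()] for the second-order projection check.
#' @examples
#' fr <- material_frame()
#' tropism_strains(fr$f3, fr, beta_max = 1)  # aligned target: all zero
#' @export
tropism_strains <- function(f_target, frame, beta_max) {
  f_target <- as.numeric(f_target)
  if (abs(vnorm(f_target) - 1) > 1e-6)
    stop("f_target must be a unit vector", call. = FALSE)
  if (!is_orthonormal_frame(frame))
    stop("frame directors must be orthonormal", call. = FALSE)
  if (beta_max < 0) stop("beta_max must be >= 0", call. = FALSE)
  c1 <- sum(f_target * frame$f1)
  c2 <- sum(f_target * frame$f2)
  c3 <- sum(f_target * frame$f3)
  arg <- min(max(2 * (1 - c3), 0), 4)  # guards |c3| > 1 from rounding
  rt <- sqrt(arg)
  s1 <- sgn1(c1)
  beta0 <- s1 * beta_max / 2 * rt
  dbeta0_dr <- beta_max^2 / 2 * (c1 - s1 * rt)
  gamma0 <- if (beta0 != 0) s1 * beta_max * c2 / rt else 0
  list(beta0 = beta0, dbeta0_dr = dbeta0_dr, gamma0 = gamma0)
}

#' Residuals of the second-order tropism projection system
#'
#' The tropism strains are defined so that a second-order Taylor expansion of
#' the tangent over a look-ahead arc `delta` reproduces the target's
#' projections on the directors:
#' `c1 = beta0*delta + dbeta0_dr*delta^2/2`,
#' `c2 = beta0*gamma0*delta^2/2`, `c3 = 1 - beta0^2*delta^2/2`.
#' This helper evaluates the three residuals (left minus right side) for a
#' given strain triple; the system is satisfied exactly when
#' `beta_max = 2/delta` (the curvature scale that reaches a finite-angle
#' target within `delta`).
#'
#' @param strains List as returned by [tropism_strains()].
#' @param f_target,frame As in [tropism_strains()].
#' @param delta Look-ahead arc length (m, `> 0`).
#' @return Numeric length-3 vector of residuals (f1, f2, f3 projections).
#' @export
tropism_residuals <- function(strains, f_target, frame, delta) {
  stopifnot(delta > 0)
  c1 <- sum(f_target * frame$f1)
  c2 <- sum(f_target * frame$f2)
  c3 <- sum(f_target * frame$f3)
  b <- strains$beta0; db <- strains$dbeta0_dr; g <- strains$gamma0
  c(c1 - (b * delta + db * delta^2 / 2),
    c2 - b * g * delta^2 / 2,
    c3 - (1 - b^2 * delta^2 / 2))
}

#' Curvature change rate from differential maturation
#'
#' Rate of active curving of the stem caused by asymmetric maturation across
#' the cross-section, driven by the misalignment between the final deflection
#' angle and the current trunk angle:
#' `p = (2 v_gamma / s_param^2) * alpha * sin(theta_pf - theta)`.
#'
#' @param v_gamma Maturation velocity (m/year).
#' @param s_param Cross-section scale parameter (m, `> 0`).
#' @param alpha Maximum differential maturation strain (m/m).
#' @param theta_pf Final deflection angle (rad).
#' @param theta Current trunk angle (rad).
#' @return Curvature change rate `p` (1/(m*year)).
#' @examples
#' dms_curvature_rate(0.01, 0.01, 0.001, 0.61 * pi, 0)
#' @export
dms_curvature_rate <- function(v_gamma, s_param, alpha, theta_pf, theta) {
  if (!is.numeric(s_param) || s_param <= 0)
    stop("s_param must be positive", call. = FALSE)
  2 * v_gamma / s_param^2 * alpha * sin(theta_pf - theta)
}

#' Construct the apical small-deflection state
#'
#' Holds the planar apical growth fields on a material grid: contact couple
#' `q(r)` (vanishing at the free tip), relaxed curvature `bstar(r)`, angle
#' field `theta(r)` (clamped to `theta0` at the base) and base-curve
#' position `s(r)` (two columns: along the initial axis and lateral).
#'
#' @param r_grid Material grid from 0 to the current trunk length (m).
#' @param theta0 Initial trunk angle (rad).
#' @param bstar Relaxed curvature field (1/m); recycled.
#' @param p_y Lateral distributed load: a single number (N/m) or a function
#'   `(r, theta) -> load`. Default 0 (a vertical trunk's self-weight has no
#'   lateral component; see [simulate_growth()] for the self-weight option).
#' @return Object of class `apical_state`.
#' @export
apical_state <- function(r_grid, theta0 = 0, bstar = 0, p_y = 0) {
  r_grid <- as.numeric(r_grid)
  if (r_grid[1] != 0 || any(diff(r_grid) <= 0))
    stop("r_grid must be strictly increasing from 0", call. = FALSE)
  n <- length(r_grid)
  structure(list(r = r_grid,
                 q = numeric(n),
                 bstar = rep_len(as.numeric(bstar), n),
                 theta = rep(theta0, n),
                 s = cbind(along = cos(theta0) * r_grid,
                           lateral = sin(theta0) * r_grid),
                 theta0 = theta0,
                 p_y = p_y),
            class = "apical_state")
}

# trapezoidal cumulative integral from the base (r[1]) outward
cumtrapz1 <- function(r, g) {
  n <- length(r)
  c(0, cumsum((g[-1] + g[-n]) / 2 * diff(r)))
}

#' Advance the apical growth system one time step
#'
#' One explicit time step of the small-deflection apical system:
#' \enumerate{
#'   \item the contact couple is integrated inward from the free tip,
#'     `dq/dr = -p_y cos(theta)`, `q(k) = 0`;
#'   \item the relaxed curvature relaxes under changing rigidity,
#'     `d bstar/dt = dYI/dt * q / (YI)^2`, plus any externally supplied
#'     differential-maturation rate `p`;
#'   \item the angle field is integrated outward from the clamped base,
#'     `d theta/dr = bstar + q/YI`, `theta(0) = theta0`;
#'   \item the base curve follows the linearised direction rule
#'     `ds/dr = (cos theta0, sin theta0 + (theta - theta0) cos theta0)`.
#' }
#'
#' @param state An [apical_state()].
#' @param rigidity_fn Function `r -> Y*I` (flexural rigidity, `> 0`).
#' @param dt Time step (years).
#' @param d_rigidity_dt Function `r -> d(Y*I)/dt` (default 0).
#' @param p Differential-maturation curvature rate added to `bstar`
#'   (1/(m*year)); a single number or function of `r`. Default 0.
#' @return The updated `apical_state`.
#' @examples
#' st <- apical_state(seq(0, 1, 0.1))
#' st2 <- apical_step(st, function(r) rep(1, length(r)), dt = 0.05)
#' all.equal(st, st2)  # unloaded straight rod is a fixed point
#' @export
apical_step <- function(state, rigidity_fn, dt,
                        d_rigidity_dt = function(r) numeric(length(r)) ,
                        p = 0) {
  stopifnot(inherits(state, "apical_state"), dt > 0)
  r <- state$r
  n <- length(r)
  YI <- rep_len(rigidity_fn(r), n)
  if (any(!is.finite(YI)) || any(YI <= 0))
    stop("rigidity Y*I must be positive and finite on the grid",
         call. = FALSE)

  py <- state$p_y
  pyv <- if (is.function(py)) py(r, state$theta) else rep_len(py, n)

  # (i) contact couple, tip -> base
  g <- pyv * cos(state$theta)
  G <- cumtrapz1(r, g)
  q <- G[n] - G          # q(r) = int_r^k p_y cos(theta) dr'; q(k) = 0

  # (ii) relaxed-curvature update
  dYI <- rep_len(d_rigidity_dt(r), n)
  pv <- if (is.function(p)) p(r) else rep_len(p, n)
  bstar <- state$bstar + dt * (dYI * q / YI^2 + pv)

  # (iii) angle field, base -> tip
  theta <- state$theta0 + cumtrapz1(r, bstar + q / YI)

  # (iv) linearised base curve
  s_along <- cos(state$theta0) * r
  s_lat <- cumtrapz1(r, sin(state$theta0) +
                       (theta - state$theta0) * cos(state$theta0))

  state$q <- q
  state$bstar <- bstar
  state$theta <- theta
  state$s <- cbind(along = s_along, lateral = s_lat)
  state
}

#' Extend the apical state for newly appeared material
#'
#' Appends grid nodes up to the new trunk length `k_new`; newly laid material
#' receives the relaxed-curvature seed `bstar_new` (the tropism initial
#' condition `beta_max * sin((theta_pf - theta0)/2)` in the simulator) and
#' continues the current tip angle.
#'
#' @param state An [apical_state()].
#' @param k_new New trunk length (m, `>=` current length).
#' @param dr Grid spacing for the appended nodes (m).
#' @param bstar_new Relaxed-curvature seed for new material (1/m).
#' @return The extended `apical_state`.
#' @export
apical_extend <- function(state, k_new, dr, bstar_new = 0) {
  stopifnot(inherits(state, "apical_state"))
  n <- length(state$r)
  k_old <- state$r[n]
  if (k_new <= k_old + 1e-12) return(state)
  r_new <- seq(k_old + dr, k_new, by = dr)
  if (length(r_new) == 0L || r_new[length(r_new)] < k_new - 1e-9)
    r_new <- c(r_new, k_new)
  m <- length(r_new)
  th_tip <- state$theta[n]
  state$r <- c(state$r, r_new)
  state$q <- c(state$q, numeric(m))
  state$bstar <- c(state$bstar, rep(bstar_new, m))
  state$theta <- c(state$theta, rep(th_tip, m))
  dirs <- cbind(cos(state$theta0),
                sin(state$theta0) + (th_tip - state$theta0) * cos(state$theta0))
  s_app <- cbind(state$s[n, 1] + (r_new - k_old) * dirs[1],
                 state$s[n, 2] + (r_new - k_old) * dirs[2])
  colnames(s_app) <- colnames(state$s)
  state$s <- rbind(state$s, s_app)
  state
}
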