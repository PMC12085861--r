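# Growth simulator: orchestrates primary + secondary growth over time and
# emits temporal series (height, DBH vs time) and spatial profiles
# (diameter, growth direction vs height), plus comparison metrics.

#' Construct a coconut palm parameter object
#'
#' Bundles every parameter of the growth model into a classed object. The
#' defaults are the experimental parameter set of the model
#' (`rho = 600` kg/m^3, `g = 9.8` N/kg, `Y = 1.14e10` Pa, `theta0 = 0` rad,
#' `a_v = 0.46` m/year, `V_r = 0.01` m/year, `s0 = 0.01` m, `s_param = 0.01`
#' m, `alpha = 0.001` m/m, `theta_p = pi/2` rad, `beta_max = 0` 1/m,
#' `theta_pf = 0.61*pi` rad). Cultivar presets differ in apical velocity and
#' taper anchors; values beyond the experimental set (taper anchor radii, the
#' dwarf cultivar's apical velocity) are synthetic defaults chosen to be
#' field-realistic, not measured values.
#'
#' @param variety `"WCT"` (West Coast Tall), `"CGD"` (Chowghat Green Dwarf)
#'   or `"custom"`.
#' @param ... Named parameter overrides. Recognised names: `rho`, `g`, `Y`,
#'   `theta0`, `a_v`, `V_r`, `s0`, `s_param`, `alpha`, `theta_p`, `beta_max`,
#'   `theta_pf`, `theta_S`, `F_wind`, `OMS`, `PFS`, `VS_H`, `E_sun`,
#'   `x_base`, `x_dbh`, `breast_height`, `B`, `c_prime`, `self_weight`,
#'   `p_y_wind`.
#' @param config Optional flat named list (e.g. from [read_palm_config()]);
#'   applied before `...`. Unknown keys are rejected.
#' @return Object of class `palm_tree`: parameter list plus a calibrated
#'   [palm_taper()] in `$taper`.
#' @examples
#' tree <- palm_tree("WCT")
#' coef(tree)[c("a_v", "beta_max")]
#' predict(tree, height = 1.4)  # trunk diameter at breast height
#' @export
palm_tree <- function(variety = c("WCT", "CGD", "custom"), ...,
                      config = NULL) {
  if (!is.null(config$variety) && missing(variety))
    variety <- config$variety
  config$variety <- NULL
  variety <- match.arg(variety)
  par <- list(
    rho = 600, g = 9.8, Y = 1.14e10,
    theta0 = 0, a_v = 0.46, V_r = 0.01,
    s0 = 0.01, s_param = 0.01, alpha = 0.001,
    theta_p = pi / 2, beta_max = 0, theta_pf = 0.61 * pi,
    theta_S = 0, F_wind = 0,
    OMS = 0, PFS = 0, VS_H = 0, E_sun = 0,
    x_base = 0.175, x_dbh = 0.160, breast_height = 1.4,
    B = NULL, c_prime = NULL,
    self_weight = TRUE, p_y_wind = 0
  )
  if (variety == "CGD") {   # synthetic dwarf preset
    par$a_v <- 0.25
    par$x_base <- 0.150
    par$x_dbh <- 0.135
  }
  apply_overrides <- function(par, ov, what) {
    if (length(ov) == 0L) return(par)
    unknown <- setdiff(names(ov), names(par))
    if (length(unknown))
      stop("unknown ", what, " key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    par[names(ov)] <- ov
    par
  }
  par <- apply_overrides(par, config, "config")
  par <- apply_overrides(par, list(...), "parameter")

  taper <- if (!is.null(par$B) && !is.null(par$c_prime)) {
    palm_taper(rho = par$rho, g = par$g, B = par$B, c_prime = par$c_prime,
               breast_height = par$breast_height)
  } else {
    palm_taper(rho = par$rho, g = par$g, x_base = par$x_base,
               x_dbh = par$x_dbh, breast_height = par$breast_height)
  }
  if (par$a_v <= 0) stop("a_v must be positive", call. = FALSE)
  structure(c(par, list(variety = variety, taper = taper)),
            class = "palm_tree")
}

#' @export
print.palm_tree <- function(x, ...) {
  cat("<palm_tree> variety:", x$variety, "\n")
  cat(sprintf("  apical velocity a_v : %.3f m/y\n", x$a_v))
  cat(sprintf("  base radius         : %.3f m, DBH %.3f m\n",
              sqrt(x$taper$lambda), dbh(x$taper)))
  cat(sprintf("  beta_max %.3g 1/m, theta0 %.3g rad, theta_p^f %.4g rad\n",
              x$beta_max, x$theta0, x$theta_pf))
  cat(sprintf("  wind force %.3g N, sunlight angle %.3g rad\n",
              x$F_wind, x$theta_S))
  invisible(x)
}

#' @export
coef.palm_tree <- function(object, ...) {
  nm <- c("rho", "g", "Y", "theta0", "a_v", "V_r", "s0", "s_param", "alpha",
          "theta_p", "beta_max", "theta_pf", "theta_S", "F_wind",
          "x_base", "x_dbh", "breast_height")
  unlist(object[nm])
}

#' Predict trunk diameter at height
#'
#' @param object A [palm_tree()].
#' @param height Height(s) above ground (m).
#' @param ... Unused.
#' @return Predicted trunk diameter(s) (m).
#' @export
predict.palm_tree <- function(object, height, ...) {
  2 * radius_at_height(height, object$taper)
}

#' Simulate coconut palm growth
#'
#' Advances the coupled primary/secondary growth model from time 0 to
#' `years`. Per time step: the trunk extends by `a_v * dt`; newly laid
#' material is seeded with the tropism relaxed-curvature initial condition
#' `beta_max * sin((theta_pf - theta0)/2)` (the 3-D tropism strains toward
#' the environment-adjusted preferred direction are recorded as a
#' diagnostic); the small-deflection apical system is advanced one step
#' ([apical_step()]); trunk radii follow the taper law. The lateral
#' distributed load defaults to the lateral projection of self-weight,
#' `rho''' g sin(theta)` (zero for a perfectly vertical trunk), plus any
#' constant wind line load `p_y_wind`; a tip wind force `F_wind` adds the
#' cantilever deflection angle to the preferred direction. The run is fully
#' deterministic.
#'
#' @param tree A [palm_tree()].
#' @param years Simulated span (years, `> 0`).
#' @param dt Time step (years, default 0.05).
#' @param dr Material grid spacing (m, default 0.01).
#' @param profile_step Spatial sampling step of the final profile (m,
#'   default 0.1, from breast height upward).
#' @param record_every Temporal sampling interval of the output series
#'   (years, default 1).
#' @return Object of class `palm_growth`: list with `series` (data.frame
#'   `time_y`, `height_m`, `dbh_m`), `profile` (data.frame `height_m`,
#'   `diameter_m`, `direction_rad`, `horizontal_shift_m`), the final
#'   [apical_state()], tropism diagnostics, and the input `tree`.
#' @examples
#' g <- simulate_growth(palm_tree("WCT"), years = 5)
#' summary(g)
#' @export
simulate_growth <- function(tree, years = 40, dt = 0.05, dr = 0.01,
                            profile_step = 0.1, record_every = 1) {
  stopifnot(inherits(tree, "palm_tree"))
  if (years <= 0 || dt <= 0 || dr <= 0)
    stop("years, dt and dr must be positive", call. = FALSE)

  taper <- tree$taper
  theta0 <- tree$theta0
  bstar_seed <- tree$beta_max * sin((tree$theta_pf - theta0) / 2)

  # lateral distributed load: self-weight projection + constant wind line load
  p_y <- function(r, theta) {
    sw <- if (isTRUE(tree$self_weight)) {
      trunk_area_and_density(pmin(r, 1e6), taper)$rho3 * tree$g * sin(theta)
    } else 0
    sw + tree$p_y_wind
  }

  n_steps <- ceiling(years / dt - 1e-9)
  rec_times <- seq(0, years, by = record_every)
  if (rec_times[length(rec_times)] < years - 1e-9)
    rec_times <- c(rec_times, years)
  series <- data.frame(time_y = rec_times, height_m = NA_real_,
                       dbh_m = NA_real_)
  series$height_m[1] <- 0
  rec_i <- 2L

  # start from the first step's trunk length
  k <- tree$a_v * dt
  state <- apical_state(sort(unique(c(seq(0, k, by = dr), k))),
                        theta0 = theta0, bstar = bstar_seed, p_y = p_y)
  YI_prev <- NULL
  tropism_seed <- NULL

  for (step in seq_len(n_steps)) {
    t_now <- step * dt
    k <- tree$a_v * t_now
    state <- apical_extend(state, k, dr, bstar_new = bstar_seed)

    x_tip <- radius_at_height(k, taper)
    I_trunk <- frustum_second_moment(x_tip, sqrt(taper$lambda),
                                     max(k, dr), taper$rho)
    YI <- tree$Y * I_trunk
    dYI_dt <- if (is.null(YI_prev)) 0 else (YI - YI_prev) / dt
    YI_prev <- YI

    # environment-adjusted preferred direction and tropism seed (diagnostic)
    if (is.null(tropism_seed)) {
      theta_w <- wind_deflection(tree$F_wind, max(k, dr), tree$Y, I_trunk,
                                 x_tip)$theta_w
      f_p <- c(cos(tree$theta_p), sin(tree$theta_p), 0)
      ang_star <- tree$theta_p + tree$theta_S + theta_w
      f_p_star <- c(cos(ang_star), sin(ang_star), 0)
      tropism_seed <- if (vnorm(cross3(f_p, f_p_star)) >= 1e-12) {
        th_tip <- state$theta[length(state$theta)]
        tip_frame <- material_frame(
          f1 = c(-sin(th_tip), cos(th_tip), 0),
          f2 = c(0, 0, 1))
        dir <- env_adjusted_direction(f_p, f_p_star, tree$theta_p)
        tropism_strains(dir$f_p_F, tip_frame, tree$beta_max)
      } else {
        list(beta0 = 0, dbeta0_dr = 0, gamma0 = 0)
      }
    }

    p_rate <- dms_curvature_rate(tree$V_r, tree$s_param, tree$alpha,
                                 tree$theta_pf, state$theta)
    # beta_max caps the active curving: with beta_max = 0 growth is straight
    if (tree$beta_max == 0) p_rate <- 0
    state <- apical_step(state, function(r) rep(YI, length(r)), dt,
                         d_rigidity_dt = function(r) rep(dYI_dt, length(r)),
                         p = p_rate)

    while (rec_i <= nrow(series) && series$time_y[rec_i] <= t_now + 1e-9) {
      n <- length(state$r)
      # height = extent along the initial growth axis
      series$height_m[rec_i] <- state$s[n, 1]
      series$dbh_m[rec_i] <- if (k >= taper$breast_height)
        2 * radius_at_height(taper$breast_height, taper) else NA_real_
      rec_i <- rec_i + 1L
    }
  }

  # spatial profile from breast height upward
  n <- length(state$r)
  h_axis <- state$s[, 1]
  h_max <- h_axis[n]
  prof_h <- if (h_max >= taper$breast_height)
    seq(taper$breast_height, h_max, by = profile_step) else numeric(0)
  profile <- data.frame(
    height_m = prof_h,
    diameter_m = 2 * radius_at_height(prof_h, taper),
    direction_rad = if (length(prof_h))
      stats::approx(h_axis, state$theta, xout = prof_h, rule = 2)$y
      else numeric(0),
    horizontal_shift_m = if (length(prof_h))
      stats::approx(h_axis, state$s[, 2], xout = prof_h, rule = 2)$y
      else numeric(0)
  )

  structure(list(series = series, profile = profile, state = state,
                 tropism = tropism_seed, tree = tree,
                 years = years, dt = dt, dr = dr),
            class = "palm_growth")
}

#' @rdname simulate_growth
#' @param object A [palm_tree()] (for the [stats::simulate()] generic).
#' @param nsim,seed Unused (the growth model is deterministic); present for
#'   generic consistency.
#' @param ... Passed to [simulate_growth()].
#' @export
simulate.palm_tree <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_growth(object, ...)
}

#' @export
print.palm_growth <- function(x, ...) {
  n <- nrow(x$series)
  cat("<palm_growth> ", x$tree$variety, ", ", x$years, " years\n", sep = "")
  cat(sprintf("  final height %.2f m, DBH %.3f m\n",
              x$series$height_m[n], x$series$dbh_m[n]))
  invisible(x)
}

#' @export
summary.palm_growth <- function(object, ...) {
  s <- object$series
  n <- nrow(s)
  out <- list(
    variety = object$tree$variety,
    years = object$years,
    final_height_m = s$height_m[n],
    final_dbh_m = s$dbh_m[n],
    mean_height_rate = s$height_m[n] / s$time_y[n],
    max_horizontal_shift_m = if (nrow(object$profile))
      max(abs(object$profile$horizontal_shift_m)) else 0,
    profile_rows = nrow(object$profile)
  )
  class(out) <- "summary.palm_growth"
  out
}

#' @export
print.summary.palm_growth <- function(x, ...) {
  cat("Coconut palm growth simulation (", x$variety, ")\n", sep = "")
  cat(sprintf("  span                 : %g years\n", x$years))
  cat(sprintf("  final height         : %.2f m (mean rate %.3f m/y)\n",
              x$final_height_m, x$mean_height_rate))
  cat(sprintf("  final DBH            : %.3f m\n", x$final_dbh_m))
  cat(sprintf("  max horizontal shift : %.4f m\n", x$max_horizontal_shift_m))
  cat(sprintf("  profile              : %d samples above breast height\n",
              x$profile_rows))
  invisible(x)
}

#' @export
as.data.frame.palm_growth <- function(x, ...) x$series

#' @export
plot.palm_growth <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  s <- x$series
  graphics::plot(s$time_y, s$height_m, type = "l", xlab = "time (y)",
                 ylab = "height (m)", main = "primary growth")
  graphics::plot(s$time_y, 100 * s$dbh_m, type = "l", xlab = "time (y)",
                 ylab = "DBH (cm)", main = "secondary growth")
  p <- x$profile
  if (nrow(p)) {
    graphics::plot(100 * p$diameter_m, p$height_m, type = "l",
                   xlab = "diameter (cm)", ylab = "height (m)",
                   main = "taper profile")
    graphics::plot(p$horizontal_shift_m, p$height_m, type = "l",
                   xlab = "horizontal shift (m)", ylab = "height (m)",
                   main = "growth direction")
  }
  invisible(x)
}

#' Comparison metrics between predicted and observed series
#'
#' Computes the variance of the prediction-observation error (population
#' form), MAE, RMSE and R^2. Inputs are either aligned numeric vectors or
#' two-column data frames (`abscissa`, `value`); unequal abscissae are
#' aligned by linear interpolation of the prediction onto the observation's
#' abscissa.
#'
#' @param pred,obs Numeric vectors, or two-column data frames.
#' @param scale Unit scale applied to errors before metric computation
#'   (e.g. `100` to report metres as centimetres; variance is then in cm^2).
#' @return Object of class `palm_metrics`: list with `variance`, `mae`,
#'   `rmse`, `r2`, `n`.
#' @examples
#' m <- compare_series(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' m$rmse >= m$mae
#' @export
compare_series <- function(pred, obs, scale = 1) {
  if (is.data.frame(pred) != is.data.frame(obs))
    stop("pred and obs must both be vectors or both be data frames",
         call. = FALSE)
  if (is.data.frame(pred)) {
    stopifnot(ncol(pred) >= 2L, ncol(obs) >= 2L)
    xo <- obs[[1L]]; yo <- obs[[2L]]
    rng <- range(pred[[1L]])
    keep <- xo >= rng[1] - 1e-9 & xo <= rng[2] + 1e-9
    if (sum(keep) < 2L)
      stop("alignment error: fewer than 2 overlapping abscissae",
           call. = FALSE)
    yp <- stats::approx(pred[[1L]], pred[[2L]], xout = xo[keep])$y
    pred <- yp; obs <- yo[keep]
  }
  ok <- is.finite(pred) & is.finite(obs)
  pred <- pred[ok]; obs <- obs[ok]
  n <- length(pred)
  if (n != length(obs)) stop("alignment error: length mismatch",
                             call. = FALSE)
  if (n < 2L) stop("need at least 2 aligned points", call. = FALSE)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("R^2 undefined: observations have zero variance",
                     call. = FALSE)
  e <- (pred - obs) * scale
  structure(list(
    variance = mean((e - mean(e))^2),
    mae = mean(abs(e)),
    rmse = sqrt(mean(e^2)),
    r2 = 1 - sum((pred - obs)^2) / sst,
    n = n
  ), class = "palm_metrics")
}

#' @export
print.palm_metrics <- function(x, ...) {
  cat(sprintf(
    "series comparison (n = %d): variance %.4g, MAE %.4g, RMSE %.4g, R2 %.4f\n",
    x$n, x$variance, x$mae, x$rmse, x$r2))
  invisible(x)
}

# ---- CSV and config I/O ----------------------------------------------------

#' Read and write growth-series and profile CSV files
#'
#' Growth series use the schema `time_y,height_m,dbh_m`; spatial profiles use
#' `height_m,diameter_m,direction_rad,horizontal_shift_m`. Plain UTF-8, `.`
#' decimal separator.
#'
#' @param x A `palm_growth` object (or a data.frame with the right columns).
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_*` return a data.frame.
#' @export
write_growth_series <- function(x, path) {
  d <- if (inherits(x, "palm_growth")) x$series else x
  stopifnot(all(c("time_y", "height_m", "dbh_m") %in% names(d)))
  utils::write.csv(d[c("time_y", "height_m", "dbh_m")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_growth_series
#' @export
write_growth_profile <- function(x, path) {
  d <- if (inherits(x, "palm_growth")) x$profile else x
  cols <- c("height_m", "diameter_m", "direction_rad", "horizontal_shift_m")
  stopifnot(all(cols %in% names(d)))
  utils::write.csv(d[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_growth_series
#' @export
read_growth_series <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_y", "height_m", "dbh_m") %in% names(d)))
  d
}

#' @rdname write_growth_series
#' @export
read_growth_profile <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("height_m", "diameter_m") %in% names(d)))
  d
}

#' Read a flat key/value configuration file
#'
#' YAML-formatted flat key/value text mirroring the parameter names of
#' [palm_tree()]. Nested structures and unknown keys are rejected.
#'
#' @param path Config file path.
#' @return Named list of parameter values.
#' @export
read_palm_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare key `Y` as boolean; map it back
  names(cfg)[names(cfg) == "TRUE"] <- "Y"
  if (!is.list(cfg) || is.null(names(cfg)) || any(names(cfg) == ""))
    stop("config must be a flat named key/value mapping", call. = FALSE)
  if (any(vapply(cfg, function(v) is.list(v) || length(v) != 1L, logical(1))))
    stop("config must be flat: scalar values only", call. = FALSE)
  allowed <- c("rho", "g", "Y", "theta0", "a_v", "V_r", "s0", "s_param",
               "alpha", "theta_p", "beta_max", "theta_pf", "theta_S",
               "F_wind", "OMS", "PFS", "VS_H", "E_sun", "x_base", "x_dbh",
               "breast_height", "B", "c_prime", "self_weight", "p_y_wind",
               "variety")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}
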