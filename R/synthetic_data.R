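# Seeded synthetic data: noisy observations of model growth curves and full
# climber sensor traces from a specified tree, so every pipeline stage is
# testable without field data.

# run code with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# fan a global seed out to per-channel substreams (kept below 2^31)
channel_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 1009 + 97 * idx) %% 2147483647)
}

#' Noisy observations of a growth series
#'
#' Adds i.i.d. Gaussian noise to the heights, DBH and diameter profile of a
#' simulated growth series, emulating field observations of temporal and
#' spatial growth characteristics. Deterministic for a given seed; each
#' channel draws from its own substream.
#'
#' @param growth A `palm_growth` object from [simulate_growth()].
#' @param sigma_height Height noise sd (m, `>= 0`).
#' @param sigma_dbh DBH noise sd (m, `>= 0`).
#' @param sigma_diameter Profile diameter noise sd (m, `>= 0`).
#' @param seed Integer seed.
#' @return A `palm_growth` object with perturbed `series` and `profile`.
#' @export
synth_growth_observations <- function(growth, sigma_height = 0.1,
                                      sigma_dbh = 0.005,
                                      sigma_diameter = 0.005, seed = 1) {
  stopifnot(inherits(growth, "palm_growth"))
  if (any(c(sigma_height, sigma_dbh, sigma_diameter) < 0))
    stop("noise sd must be >= 0", call. = FALSE)
  obs <- growth
  n <- nrow(obs$series)
  obs$series$height_m <- obs$series$height_m +
    with_seed(channel_seed(seed, 1L), stats::rnorm(n, 0, sigma_height))
  obs$series$dbh_m <- obs$series$dbh_m +
    with_seed(channel_seed(seed, 2L), stats::rnorm(n, 0, sigma_dbh))
  m <- nrow(obs$profile)
  if (m > 0L)
    obs$profile$diameter_m <- obs$profile$diameter_m +
      with_seed(channel_seed(seed, 3L), stats::rnorm(m, 0, sigma_diameter))
  obs
}

# C1 slip bump: dip of unit depth over u in (0, 1), zero outside
slip_bump <- function(u) ifelse(u > 0 & u < 1, sin(pi * u)^2, 0)

#' Synthetic climber sensor trace
#'
#' Generates a kinematically consistent sensor log for a robot climbing a
#' frustum-tapered trunk: the height trajectory has smooth acceleration and
#' deceleration ramps (the climb starts and ends at rest), accelerometer
#' channels are derived from the actual trajectory plus gravity, gyroscope
#' and magnetometer encode a constant heading, and the two ultrasonic
#' channels read the frame span minus the trunk diameter at the
#' instantaneous height. Injected artefacts: slip events (transient height
#' dips, which propagate into the IMU channels) and scar spikes (ultrasonic
#' outliers). All noise is Gaussian, seeded, one substream per channel.
#'
#' @param tree A [palm_tree()] or [palm_taper()] describing the trunk.
#' @param climb_to Absolute height of the top of the climb (m).
#' @param mount_height Frame height above ground at start (m, default 1.4:
#'   the robot mounts at breast height).
#' @param climb_speed Cruise speed (m/s, `> 0`, default 0.2).
#' @param rate Sample rate (Hz, default 50).
#' @param frame_span Ultrasonic frame span (m, default 0.6).
#' @param heading Constant true heading (rad).
#' @param sigma_accel,sigma_gyro,sigma_mag,sigma_us Channel noise sd
#'   (m/s^2, rad/s, unitless, m).
#' @param n_slips,slip_magnitude,slip_duration Slip count, depth (m) and
#'   duration (s).
#' @param n_scars,scar_magnitude Scar spike count and magnitude (m).
#' @param seed Integer seed.
#' @return Object of class `synth_trace`: list with `trace` (sensor log
#'   data.frame), `truth` (data.frame `t_s, height_m, diameter_m,
#'   heading_rad` of ground truth at each sample), and the generating
#'   parameters.
#' @export
synth_climber_trace <- function(tree, climb_to = 11.4, mount_height = 1.4,
                                climb_speed = 0.2, rate = 50,
                                frame_span = 0.6, heading = 0.3,
                                sigma_accel = 0.05, sigma_gyro = 0.005,
                                sigma_mag = 0.01, sigma_us = 0.005,
                                n_slips = 2, slip_magnitude = 0.05,
                                slip_duration = 0.4,
                                n_scars = 3, scar_magnitude = 0.05,
                                seed = 1) {
  taper <- if (inherits(tree, "palm_tree")) tree$taper else tree
  stopifnot(inherits(taper, "palm_taper"))
  if (climb_speed <= 0) stop("climb speed must be positive", call. = FALSE)
  if (rate <= 0) stop("sample rate must be positive", call. = FALSE)
  L <- climb_to - mount_height
  t_ramp <- 2
  if (L <= climb_speed * t_ramp)
    stop("climb too short for the speed profile", call. = FALSE)
  g <- taper$g

  T_total <- L / climb_speed + t_ramp
  tt <- seq(0, T_total, by = 1 / rate)
  n <- length(tt)

  # smooth velocity profile: cosine ramps of length t_ramp at both ends
  v <- function(t) {
    ifelse(t < t_ramp, climb_speed * (1 - cos(pi * t / t_ramp)) / 2,
      ifelse(t > T_total - t_ramp,
        climb_speed * (1 - cos(pi * (T_total - t) / t_ramp)) / 2,
        climb_speed))
  }
  h_rel <- cumtrapz1(tt, v(tt))

  # slip events inside the cruise window
  slip_t <- if (n_slips > 0)
    with_seed(channel_seed(seed, 10L),
              stats::runif(n_slips, t_ramp + slip_duration,
                           T_total - t_ramp - slip_duration)) else numeric(0)
  for (ts in slip_t)
    h_rel <- h_rel - slip_magnitude * slip_bump((tt - ts) / slip_duration)

  # kinematically consistent vertical acceleration from the actual trajectory
  hdot <- c(diff(h_rel), 0) * rate
  hddot <- c(0, diff(hdot)) * rate

  mk_noise <- function(idx, sd) {
    with_seed(channel_seed(seed, idx), stats::rnorm(n, 0, sd))
  }
  h_abs <- mount_height + h_rel
  radius <- radius_at_height(h_abs, taper)
  us_true <- (frame_span - 2 * radius) / 2

  trace <- data.frame(
    t_s = tt,
    ax = mk_noise(1L, sigma_accel),
    ay = mk_noise(2L, sigma_accel),
    az = g + hddot + mk_noise(3L, sigma_accel),
    gx = mk_noise(4L, sigma_gyro),
    gy = mk_noise(5L, sigma_gyro),
    gz = mk_noise(6L, sigma_gyro),
    mx = cos(heading) + mk_noise(7L, sigma_mag),
    my = sin(heading) + mk_noise(8L, sigma_mag),
    mz = 0.4 + mk_noise(9L, sigma_mag),
    us_left_m = us_true + mk_noise(11L, sigma_us),
    us_right_m = us_true + mk_noise(12L, sigma_us)
  )

  # scar spikes: short ultrasonic outliers on one side
  scar_idx <- if (n_scars > 0)
    with_seed(channel_seed(seed, 13L),
              sample(seq_len(n - 2L), n_scars)) else integer(0)
  for (si in scar_idx)
    trace$us_left_m[si:(si + 1L)] <- trace$us_left_m[si:(si + 1L)] +
      scar_magnitude

  truth <- data.frame(t_s = tt, height_m = h_abs,
                      diameter_m = 2 * radius,
                      heading_rad = heading)
  structure(list(trace = trace, truth = truth,
                 mount_height = mount_height, frame_span = frame_span,
                 climb_to = climb_to, heading = heading,
                 slip_times = slip_t, scar_idx = sort(scar_idx),
                 seed = seed),
            class = "synth_trace")
}

#' @export
print.synth_trace <- function(x, ...) {
  cat(sprintf(
    "<synth_trace> %d samples, climb %.1f -> %.1f m, %d slips, %d scars\n",
    nrow(x$trace), x$mount_height, x$climb_to,
    length(x$slip_times), length(x$scar_idx)))
  invisible(x)
}
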