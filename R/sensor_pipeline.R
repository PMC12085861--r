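# Climber sensor processing: wavelet denoising, EKF fusion of 9-axis IMU
# data, ultrasonic diameter extraction and anomaly rectification.

# Orthonormal Daubechies scaling filters. db2 in closed form; db4 are the
# standard published constants (Daubechies' extremal-phase family).
daub_filter <- function(wavelet = c("db4", "db2")) {
  wavelet <- match.arg(wavelet)
  h <- switch(wavelet,
    db2 = {
      s3 <- sqrt(3)
      c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
    },
    db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
            -0.027983769416859854, -0.18703481171909309,
            0.030841381835560764, 0.0328830116668852,
            -0.010597401785069032)
  )
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)   # quadrature mirror wavelet filter
  list(h = h, g = g, L = L)
}

dwt_step <- function(x, filt) {
  n <- length(x)
  n2 <- n %/% 2L
  idx <- (outer(0:(filt$L - 1L), 2L * (0:(n2 - 1L)), "+") %% n) + 1L
  X <- matrix(x[idx], nrow = filt$L)
  list(a = as.vector(filt$h %*% X), d = as.vector(filt$g %*% X))
}

idwt_step <- function(a, d, filt) {
  n2 <- length(a)
  n <- 2L * n2
  y <- numeric(n)
  base <- 2L * (0:(n2 - 1L))
  for (m in 0:(filt$L - 1L)) {
    pos <- ((base + m) %% n) + 1L
    y[pos] <- y[pos] + filt$h[m + 1L] * a + filt$g[m + 1L] * d
  }
  y
}

#' Periodised discrete wavelet transform
#'
#' Multi-level orthonormal DWT with circular (periodised) boundary handling.
#' Signals whose length is not a multiple of `2^levels` are padded by edge
#' replication; the original length is restored on inversion, and the
#' round trip is exact to floating-point precision.
#'
#' @param x Numeric signal (length `>= 2`).
#' @param levels Number of decomposition levels.
#' @param wavelet `"db4"` (default) or `"db2"`.
#' @return Object of class `palm_dwt`: list with the coarse approximation
#'   `a`, detail coefficient list `d` (finest first), and bookkeeping.
#' @seealso [idwt_periodic()], [wavelet_denoise()]
#' @export
dwt_periodic <- function(x, levels = 4, wavelet = "db4") {
  x <- as.numeric(x)
  n0 <- length(x)
  if (n0 < 2L) stop("signal too short", call. = FALSE)
  levels <- min(levels, max(1L, floor(log2(n0))))
  block <- 2L^levels
  n <- ceiling(n0 / block) * block
  if (n > n0) x <- c(x, rep(x[n0], n - n0))
  filt <- daub_filter(wavelet)
  d <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a, filt)
    a <- st$a
    d[[j]] <- st$d
  }
  structure(list(a = a, d = d, n0 = n0, n = n, levels = levels,
                 wavelet = wavelet), class = "palm_dwt")
}

#' Inverse periodised discrete wavelet transform
#'
#' @param w A `palm_dwt` object from [dwt_periodic()].
#' @return The reconstructed signal at the original length.
#' @export
idwt_periodic <- function(w) {
  stopifnot(inherits(w, "palm_dwt"))
  filt <- daub_filter(w$wavelet)
  a <- w$a
  for (j in rev(seq_len(w$levels))) a <- idwt_step(a, w$d[[j]], filt)
  a[seq_len(w$n0)]
}

# SURE-optimal soft threshold for coefficients with unit noise scale
sure_threshold <- function(x) {
  n <- length(x)
  if (n == 0L) return(0)
  a <- sort(abs(x))
  cs <- cumsum(a^2)
  k <- seq_len(n)
  risk <- n - 2 * k + cs + (n - k) * a^2
  risk0 <- n + 0  # t = 0: no shrinkage
  tbest <- if (min(risk) < risk0) a[which.min(risk)] else 0
  min(tbest, sqrt(2 * log(max(n, 2))))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Wavelet denoising with SURE thresholding
#'
#' Multi-level Daubechies decomposition, per-level soft thresholding with the
#' threshold chosen by Stein's Unbiased Risk Estimate (capped at the
#' universal threshold), and reconstruction through the inverse transform.
#' The noise scale is estimated robustly from the finest detail level as
#' `sigma = MAD / 0.6745` (median absolute deviation).
#'
#' @param x Numeric signal, length `>= 8`.
#' @param levels Decomposition depth (default 4).
#' @param wavelet Daubechies family member, `"db4"` (default) or `"db2"`.
#' @param threshold `"sure"` (default) or `"none"` (pure round trip).
#' @param sigma Optional known noise standard deviation; estimated when
#'   `NULL`.
#' @return Denoised signal, same length as `x`.
#' @examples
#' set.seed(1)
#' x <- seq(0, 1, length.out = 256)
#' noisy <- x + rnorm(256, sd = 0.1)
#' sd(wavelet_denoise(noisy) - x) < sd(noisy - x)
#' @export
wavelet_denoise <- function(x, levels = 4, wavelet = "db4",
                            threshold = c("sure", "none"), sigma = NULL) {
  threshold <- match.arg(threshold)
  x <- as.numeric(x)
  if (length(x) < 8L)
    stop("signal too short for wavelet denoising (need >= 8 samples)",
         call. = FALSE)
  w <- dwt_periodic(x, levels = levels, wavelet = wavelet)
  if (threshold == "none") return(idwt_periodic(w))
  if (is.null(sigma)) sigma <- stats::median(abs(w$d[[1L]])) / 0.6745
  if (sigma > 0) {
    for (j in seq_len(w$levels)) {
      t_j <- sigma * sure_threshold(w$d[[j]] / sigma)
      w$d[[j]] <- soft_threshold(w$d[[j]], t_j)
    }
  }
  idwt_periodic(w)
}

# ---- EKF fusion -------------------------------------------------------------

ekf_default_config <- function() {
  list(sigma_a = 0.05,     # accelerometer measurement noise (m/s^2)
       sigma_mag = 0.02,   # magnetometer heading noise (rad)
       sigma_gyro = 0.01,  # gyroscope rate noise (rad/s)
       q_jerk = 0.05,      # jerk process intensity per axis
       q_head = 1e-4,      # heading angular-acceleration intensity
       p0_pos = 1e-4, p0_vel = 1e-4, p0_acc = 1e-2, p0_head = 1e-2,
       gravity = 9.8)
}

#' Fuse a climber sensor trace with an extended Kalman filter
#'
#' Estimates planar pose (height, horizontal shift) and heading from a 9-axis
#' IMU trace. The state transition is a degree-3 polynomial (constant-jerk)
#' kinematic model per translation axis -- state `(position, velocity,
#' acceleration, jerk)` -- plus `(heading, heading rate)`. Measurements per
#' sample are the lateral and gravity-compensated vertical accelerometer
#' channels, the magnetometer heading `atan2(my, mx)` (unwrapped against the
#' running estimate), and the gyroscope yaw rate. State and measurement
#' covariances are diagonal-initialised from the config. The update uses the
#' Joseph form, keeping the covariance symmetric positive semi-definite.
#'
#' @param trace A sensor trace: data.frame with columns
#'   `t_s, ax, ay, az, gx, gy, gz, mx, my, mz` (ultrasonic columns ignored
#'   here). Timestamps must be strictly increasing.
#' @param config Named list overriding the default noise configuration
#'   (`sigma_a`, `sigma_mag`, `sigma_gyro`, `q_jerk`, `q_head`, `p0_*`,
#'   `gravity`); all variances must be positive.
#' @return Object of class `palm_pose`: list with `t`, `x` (horizontal
#'   shift, m), `y` (height climbed, m), `vy` (vertical velocity),
#'   `heading` (rad), innovation matrix `innovations` (one row per sample),
#'   per-step covariance minimum eigenvalue `P_mineig`, and `P_final`.
#' @export
ekf_fuse <- function(trace, config = list()) {
  cfg <- utils::modifyList(ekf_default_config(), config)
  num <- unlist(cfg[c("sigma_a", "sigma_mag", "sigma_gyro", "q_jerk",
                      "q_head", "p0_pos", "p0_vel", "p0_acc", "p0_head")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("covariance configuration must be positive", call. = FALSE)
  need <- c("t_s", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
  if (!all(need %in% names(trace)))
    stop("trace must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tt <- trace$t_s
  n <- length(tt)
  if (n < 2L || any(diff(tt) <= 0))
    stop("timestamps must be strictly increasing (>= 2 samples)",
         call. = FALSE)

  # state: [px vx ax jx  py vy ay jy  psi psidot]
  ns <- 10L
  X <- numeric(ns)
  X[9L] <- atan2(trace$my[1L], trace$mx[1L])
  P <- diag(c(cfg$p0_pos, cfg$p0_vel, cfg$p0_acc, cfg$p0_acc,
              cfg$p0_pos, cfg$p0_vel, cfg$p0_acc, cfg$p0_acc,
              cfg$p0_head, cfg$p0_head))
  H <- matrix(0, 4L, ns)
  H[1L, 3L] <- 1; H[2L, 7L] <- 1; H[3L, 9L] <- 1; H[4L, 10L] <- 1
  R <- diag(c(cfg$sigma_a^2, cfg$sigma_a^2, cfg$sigma_mag^2,
              cfg$sigma_gyro^2))
  I10 <- diag(ns)

  out_x <- out_y <- out_vy <- out_psi <- numeric(n)
  innov <- matrix(NA_real_, n, 4L)
  mineig <- numeric(n)

  axis_F <- function(dt) {
    matrix(c(1, dt, dt^2 / 2, dt^3 / 6,
             0, 1, dt, dt^2 / 2,
             0, 0, 1, dt,
             0, 0, 0, 1), 4L, 4L, byrow = TRUE)
  }

  for (i in seq_len(n)) {
    if (i > 1L) {
      dt <- tt[i] - tt[i - 1L]
      Fa <- axis_F(dt)
      Fh <- matrix(c(1, dt, 0, 1), 2L, 2L, byrow = TRUE)
      Fm <- I10
      Fm[1:4, 1:4] <- Fa
      Fm[5:8, 5:8] <- Fa
      Fm[9:10, 9:10] <- Fh
      Ga <- c(dt^3 / 6, dt^2 / 2, dt, 1)
      Qa <- cfg$q_jerk * (Ga %o% Ga) * dt
      Gh <- c(dt^2 / 2, dt)
      Qh <- cfg$q_head * (Gh %o% Gh) * dt
      Q <- matrix(0, ns, ns)
      Q[1:4, 1:4] <- Qa
      Q[5:8, 5:8] <- Qa
      Q[9:10, 9:10] <- Qh
      X <- as.vector(Fm %*% X)
      P <- Fm %*% P %*% t(Fm) + Q
    }
    psi_m <- atan2(trace$my[i], trace$mx[i])
    psi_m <- psi_m + 2 * pi * round((X[9L] - psi_m) / (2 * pi))
    z <- c(trace$ax[i], trace$az[i] - cfg$gravity, psi_m, trace$gz[i])
    nu <- z - as.vector(H %*% X)
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    X <- X + as.vector(K %*% nu)
    IKH <- I10 - K %*% H
    P <- IKH %*% P %*% t(IKH) + K %*% R %*% t(K)
    P <- (P + t(P)) / 2

    out_x[i] <- X[1L]; out_y[i] <- X[5L]; out_vy[i] <- X[6L]
    out_psi[i] <- X[9L]
    innov[i, ] <- nu
    mineig[i] <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
  }
  structure(list(t = tt, x = out_x, y = out_y, vy = out_vy,
                 heading = out_psi, innovations = innov,
                 P_mineig = mineig, P_final = P, config = cfg),
            class = "palm_pose")
}

#' @export
print.palm_pose <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("<palm_pose> %d samples over %.1f s; final height %.3f m, ",
              n, x$t[n] - x$t[1], x$y[n]))
  cat(sprintf("heading %.3f rad\n", x$heading[n]))
  invisible(x)
}

# ---- diameter extraction and rectification ---------------------------------

#' Trunk diameter from opposed ultrasonic ranges
#'
#' With two ultrasonic sensors diametrically opposed on a rigid frame of
#' known span, the trunk diameter is the span minus both sensor-to-trunk
#' distances. Samples yielding a negative diameter (or negative ranges) are
#' flagged invalid and set `NA`; they are meant to be repaired by
#' [rectify_anomalies()], not treated as fatal.
#'
#' @param us_left,us_right Sensor-to-trunk distances (m); vectorised.
#' @param frame_span Distance between the two sensors (m, `> 0`).
#' @return Numeric diameter vector (m) with attribute `"invalid"` (logical).
#' @examples
#' diameter_from_ultrasonic(0.20, 0.20, frame_span = 0.60)  # 0.20
#' @export
diameter_from_ultrasonic <- function(us_left, us_right, frame_span) {
  if (!is.numeric(frame_span) || frame_span <= 0)
    stop("frame_span must be positive", call. = FALSE)
  d <- frame_span - us_left - us_right
  invalid <- !is.finite(d) | d < 0 | us_left < 0 | us_right < 0
  d[invalid] <- NA_real_
  attr(d, "invalid") <- invalid
  d
}

#' Rectify measurement anomalies
#'
#' Repairs the artefacts climbing robots pick up from slips, scars and
#' surface wedges: the diameter stream gets `NA` interpolation followed by a
#' Hampel outlier filter (window 11, 3 MAD), and the height stream is
#' projected onto the non-decreasing cone by isotonic regression
#' (pool-adjacent-violators), enforcing steadily increasing height.
#'
#' @param height Optional height stream (m).
#' @param diameter Optional diameter stream (m), may contain `NA`.
#' @param window Hampel window length (odd, default 11).
#' @param t0 Hampel threshold in MAD units (default 3).
#' @return List with `height`, `diameter`, `n_flagged` (number of repaired
#'   diameter samples, including `NA`s) and `flagged` (their indices).
#' @export
rectify_anomalies <- function(height = NULL, diameter = NULL,
                              window = 11, t0 = 3) {
  flagged <- integer(0)
  if (!is.null(diameter)) {
    bad <- which(!is.finite(diameter))
    if (length(bad) && length(bad) < length(diameter)) {
      ii <- seq_along(diameter)
      diameter[bad] <- stats::approx(ii[-bad], diameter[-bad], xout = bad,
                                     rule = 2)$y
    }
    k <- max(1L, (as.integer(window) - 1L) %/% 2L)
    if (length(diameter) > 2L * k + 1L) {
      hf <- pracma::hampel(diameter, k = k, t0 = t0)
      diameter <- hf$y
      flagged <- sort(unique(c(bad, hf$ind)))
    } else {
      flagged <- bad
    }
  }
  if (!is.null(height) && length(height) >= 2L) {
    height <- stats::isoreg(seq_along(height), height)$yf
  }
  list(height = height, diameter = diameter,
       n_flagged = length(flagged), flagged = flagged)
}

#' Extract tree parameters from a fused pose and diameter stream
#'
#' Resamples the (rectified) diameter stream onto the height axis by linear
#' interpolation and emits the tree measurement: height profile, horizontal
#' shift, heading and diameter against height, plus total height and the
#' DBH read at breast height.
#'
#' @param pose A [ekf_fuse()] result (or list with `t`, `x`, `y`,
#'   `heading`), with `y` already rectified to be non-decreasing.
#' @param diameter Diameter stream (m) on the same time base as `pose`.
#' @param mount_height Absolute height of the sensor frame at trace start
#'   (m); extracted heights are `mount_height + y`.
#' @param breast_height Height of the DBH reading (m, default 1.4).
#' @param profile_step Height sampling step of the profile (m, default 0.1).
#' @return Object of class `tree_measurement`: list with `profile`
#'   (data.frame `height_m, horizontal_shift_m, heading_rad, diameter_m`),
#'   `total_height_m` (top of climb above ground), `climb_m`, `dbh_m`.
#' @export
extract_tree_parameters <- function(pose, diameter, mount_height = 1.4,
                                    breast_height = 1.4,
                                    profile_step = 0.1) {
  if (length(pose$t) != length(diameter))
    stop("alignment error: pose and diameter streams differ in length",
         call. = FALSE)
  h_abs <- mount_height + pose$y
  climb <- max(pose$y)
  if (climb < profile_step) {
    profile <- data.frame(height_m = numeric(0),
                          horizontal_shift_m = numeric(0),
                          heading_rad = numeric(0),
                          diameter_m = numeric(0))
  } else {
    hh <- seq(mount_height, mount_height + climb, by = profile_step)
    # height is non-decreasing after rectification; make strictly usable
    ord <- !duplicated(h_abs)
    profile <- data.frame(
      height_m = hh,
      horizontal_shift_m = stats::approx(h_abs[ord], pose$x[ord], xout = hh,
                                         rule = 2)$y,
      heading_rad = stats::approx(h_abs[ord], pose$heading[ord], xout = hh,
                                  rule = 2)$y,
      diameter_m = stats::approx(h_abs[ord], diameter[ord], xout = hh,
                                 rule = 2)$y)
  }
  dbh_m <- if (mount_height <= breast_height + 1e-9) {
    near <- which(abs(h_abs - breast_height) <= profile_step)
    if (length(near) >= 1L && any(is.finite(diameter[near]))) {
      stats::median(diameter[near], na.rm = TRUE)
    } else {
      ord <- !duplicated(h_abs)
      if (sum(ord) >= 2L)
        stats::approx(h_abs[ord], diameter[ord], xout = breast_height,
                      rule = 2)$y
      else stats::median(diameter, na.rm = TRUE)
    }
  } else NA_real_
  structure(list(profile = profile,
                 total_height_m = mount_height + climb,
                 climb_m = climb,
                 dbh_m = dbh_m),
            class = "tree_measurement")
}

#' @export
print.tree_measurement <- function(x, ...) {
  cat("<tree_measurement>\n")
  cat(sprintf("  total height : %.2f m (climb %.2f m)\n",
              x$total_height_m, x$climb_m))
  cat(sprintf("  DBH          : %s\n",
              if (is.na(x$dbh_m)) "NA" else sprintf("%.3f m", x$dbh_m)))
  cat(sprintf("  profile      : %d samples\n", nrow(x$profile)))
  invisible(x)
}

#' Full sensor-to-measurement chain
#'
#' Runs the complete processing pipeline on a raw climber log: wavelet
#' denoising of every IMU channel, EKF pose fusion, ultrasonic diameter
#' extraction, anomaly rectification (Hampel on diameter, isotonic height),
#' and parameter extraction. When the climb ends at rest
#' (`end_at_rest = TRUE`), the residual vertical-velocity drift of the dead
#' reckoning is closed by subtracting the quadratic position error it
#' implies.
#'
#' @param trace Sensor log data.frame with columns
#'   `t_s, ax, ay, az, gx, gy, gz, mx, my, mz, us_left_m, us_right_m`.
#' @param frame_span Ultrasonic frame span (m).
#' @param mount_height Frame height above ground at trace start (m).
#' @param config EKF noise configuration, see [ekf_fuse()].
#' @param denoise Apply wavelet denoising to the IMU channels first.
#' @param end_at_rest Apply the end-at-rest drift closure.
#' @return A `tree_measurement` (see [extract_tree_parameters()]) with the
#'   fused `pose` and rectification report attached.
#' @export
measure_tree <- function(trace, frame_span = 0.6, mount_height = 1.4,
                         config = list(), denoise = TRUE,
                         end_at_rest = TRUE) {
  need <- c("t_s", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz",
            "us_left_m", "us_right_m")
  if (!all(need %in% names(trace)))
    stop("trace must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tr <- trace
  if (denoise && nrow(tr) >= 8L) {
    for (ch in c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz"))
      tr[[ch]] <- wavelet_denoise(tr[[ch]])
  }
  pose <- ekf_fuse(tr, config = config)
  if (end_at_rest) {
    Tn <- pose$t[length(pose$t)] - pose$t[1L]
    v_end <- pose$vy[length(pose$vy)]
    tau <- pose$t - pose$t[1L]
    pose$y <- pose$y - v_end * tau^2 / (2 * Tn)
  }
  diam <- diameter_from_ultrasonic(tr$us_left_m, tr$us_right_m, frame_span)
  rect <- rectify_anomalies(height = pose$y, diameter = diam)
  pose$y <- rect$height
  out <- extract_tree_parameters(pose, rect$diameter,
                                 mount_height = mount_height)
  out$pose <- pose
  out$n_flagged <- rect$n_flagged
  out$flagged <- rect$flagged
  out
}

#' Read and write climber sensor logs
#'
#' Sensor logs are plain CSV with fixed columns
#' `t_s,ax,ay,az,gx,gy,gz,mx,my,mz,us_left_m,us_right_m`.
#'
#' @param trace Sensor log data.frame.
#' @param path File path.
#' @return `write_sensor_trace` returns `path` invisibly;
#'   `read_sensor_trace` returns the data.frame.
#' @export
write_sensor_trace <- function(trace, path) {
  cols <- c("t_s", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz",
            "us_left_m", "us_right_m")
  stopifnot(all(cols %in% names(trace)))
  utils::write.csv(trace[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensor_trace
#' @export
read_sensor_trace <- function(path) {
  d <- utils::read.csv(path)
  cols <- c("t_s", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz",
            "us_left_m", "us_right_m")
  if (!all(cols %in% names(d)))
    stop("not a sensor log: missing columns", call. = FALSE)
  d
}
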