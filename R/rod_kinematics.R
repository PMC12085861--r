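# Growing-rod kinematics: material frames, the growth schedule, and
# integration of director frames along the material coordinate.

#' Construct a material frame
#'
#' A material frame is a point of the rod's base curve together with the
#' orthonormal director triad `f1, f2, f3` attached to it. The triad must be
#' right-handed: `f3 = f1 x f2`.
#'
#' @param s Position of the material point in 3-space (numeric length 3, m).
#' @param f1,f2 First two unit directors (numeric length 3). `f3` is derived
#'   as their cross product.
#' @param tol Orthonormality tolerance.
#' @return An object of class `material_frame`: a list with fields `s`, `f1`,
#'   `f2`, `f3`.
#' @examples
#' material_frame(f1 = c(1, 0, 0), f2 = c(0, 1, 0))
#' @export
material_frame <- function(s = c(0, 0, 0), f1 = c(1, 0, 0), f2 = c(0, 1, 0),
                           tol = 1e-8) {
  f1 <- as.numeric(f1); f2 <- as.numeric(f2); s <- as.numeric(s)
  stopifnot(length(s) == 3L, length(f1) == 3L, length(f2) == 3L)
  if (abs(vnorm(f1) - 1) > tol || abs(vnorm(f2) - 1) > tol)
    stop("directors f1, f2 must be unit vectors", call. = FALSE)
  if (abs(sum(f1 * f2)) > tol)
    stop("directors f1, f2 must be orthogonal", call. = FALSE)
  structure(list(s = s, f1 = f1, f2 = f2, f3 = cross3(f1, f2)),
            class = "material_frame")
}

#' @export
print.material_frame <- function(x, ...) {
  cat("<material_frame>\n")
  cat("  s : ", paste(signif(x$s, 6), collapse = " "), "\n")
  for (nm in c("f1", "f2", "f3"))
    cat(" ", nm, ":", paste(signif(x[[nm]], 6), collapse = " "), "\n")
  invisible(x)
}

vnorm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

is_orthonormal_frame <- function(frame, tol = 1e-8) {
  M <- rbind(frame$f1, frame$f2, frame$f3)
  max(abs(M %*% t(M) - diag(3))) < tol &&
    vnorm(cross3(frame$f1, frame$f2) - frame$f3) < tol
}

#' Growth schedule of the trunk
#'
#' Under constant apical growth velocity `a_v` the trunk length is
#' `k(t) = a_v * t` and the appearance time of the material point at
#' material coordinate `r` is `f(r) = r / a_v` (the inverse map giving the
#' date each piece of trunk was laid down). A user-supplied monotone
#' length table can replace the constant-velocity law; `k(t)` and the
#' appearance map are then linear interpolants of the table.
#'
#' @param t Time (years, `t >= 0`). May be a vector.
#' @param a_v Apical growth velocity (m/year, `> 0`).
#' @param length_table Optional two-column `data.frame` (`t`, `k`) giving
#'   trunk length against time; `k` must be non-decreasing and `t` strictly
#'   increasing. Overrides `a_v` for evaluation of `k`.
#' @return A list of class `growth_schedule` with fields `k` (trunk length at
#'   `t`, m), `appearance` (function `r ->` appearance time, years), `a_v`
#'   and `t`.
#' @examples
#' gs <- growth_schedule(40, a_v = 0.46)
#' gs$k                  # 18.4 m
#' gs$appearance(0.46)   # 1 year
#' @export
growth_schedule <- function(t, a_v = 0.46, length_table = NULL) {
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  if (is.null(length_table)) {
    if (!is.numeric(a_v) || length(a_v) != 1L || a_v <= 0)
      stop("apical growth velocity a_v must be a single positive number",
           call. = FALSE)
    k <- a_v * t
    appearance <- function(r) {
      if (any(r < 0 | r > max(k) + 1e-12))
        stop("material coordinate outside [0, k(t)]", call. = FALSE)
      r / a_v
    }
  } else {
    stopifnot(is.data.frame(length_table), ncol(length_table) >= 2L)
    tt <- length_table[[1L]]; kk <- length_table[[2L]]
    if (any(diff(tt) <= 0)) stop("table times must be strictly increasing",
                                 call. = FALSE)
    if (any(diff(kk) < 0)) stop("trunk length must be non-decreasing",
                                call. = FALSE)
    k <- stats::approx(tt, kk, xout = t, rule = 2)$y
    appearance <- function(r) {
      if (any(r < min(kk) - 1e-12 | r > max(kk) + 1e-12))
        stop("material coordinate outside table range", call. = FALSE)
      stats::approx(kk, tt, xout = r, ties = "ordered")$y
    }
    a_v <- NA_real_
  }
  structure(list(k = k, appearance = appearance, a_v = a_v, t = t),
            class = "growth_schedule")
}

#' Integrate director frames along the rod
#'
#' Integrates the frame system `d f_i / dr = y x f_i` and the base curve
#' `d s / dr = w1 f1 + w2 f2 + w3 f3` (the Serret-Frenet-type relations of
#' the rod) with a fixed-step 4th-order Runge-Kutta scheme on `r_grid`,
#' re-orthonormalising the triad by Gram-Schmidt after every step to control
#' drift.
#'
#' @param strain_fn Function `r -> list(y = , w = )` returning the
#'   curvature/twist vector `y` (1/m) and the stretch vector `w`
#'   (dimensionless) in the local director basis.
#' @param frame0 Initial [material_frame()] at `r = 0`.
#' @param r_grid Strictly increasing numeric grid starting at 0 (m).
#' @return An object of class `rod_frames`: list with `r`, matrices `s`,
#'   `f1`, `f2`, `f3` (one row per grid node).
#' @examples
#' fr <- integrate_frame(function(r) list(y = c(0, 0, 0), w = c(0, 0, 1)),
#'                       material_frame(), seq(0, 1, by = 0.1))
#' fr$s[11, ]  # straight rod: end point 1 m along f3
#' @export
integrate_frame <- function(strain_fn, frame0, r_grid) {
  if (!inherits(frame0, "material_frame")) frame0 <- do.call(material_frame, frame0)
  if (!is_orthonormal_frame(frame0))
    stop("frame0 must be orthonormal and right-handed", call. = FALSE)
  r_grid <- as.numeric(r_grid)
  if (r_grid[1] != 0 || any(diff(r_grid) <= 0))
    stop("r_grid must be strictly increasing and start at 0", call. = FALSE)

  n <- length(r_grid)
  S <- F1 <- F2 <- F3 <- matrix(0, n, 3)
  state <- c(frame0$f1, frame0$f2, frame0$f3, frame0$s)
  S[1, ] <- frame0$s; F1[1, ] <- frame0$f1; F2[1, ] <- frame0$f2
  F3[1, ] <- frame0$f3

  deriv <- function(r, st) {
    f1 <- st[1:3]; f2 <- st[4:6]; f3 <- st[7:9]
    sw <- strain_fn(r)
    y <- sw$y; w <- sw$w
    c(cross3(y, f1), cross3(y, f2), cross3(y, f3),
      w[1] * f1 + w[2] * f2 + w[3] * f3)
  }

  for (i in seq_len(n - 1L)) {
    h <- r_grid[i + 1L] - r_grid[i]
    r <- r_grid[i]
    k1 <- deriv(r, state)
    k2 <- deriv(r + h / 2, state + h / 2 * k1)
    k3 <- deriv(r + h / 2, state + h / 2 * k2)
    k4 <- deriv(r + h, state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    # Gram-Schmidt renormalisation of the triad
    f1 <- state[1:3]; f1 <- f1 / vnorm(f1)
    f2 <- state[4:6]; f2 <- f2 - sum(f2 * f1) * f1; f2 <- f2 / vnorm(f2)
    f3 <- cross3(f1, f2)
    state[1:9] <- c(f1, f2, f3)
    F1[i + 1L, ] <- f1; F2[i + 1L, ] <- f2; F3[i + 1L, ] <- f3
    S[i + 1L, ] <- state[10:12]
  }
  structure(list(r = r_grid, s = S, f1 = F1, f2 = F2, f3 = F3),
            class = "rod_frames")
}

#' @export
print.rod_frames <- function(x, ...) {
  n <- length(x$r)
  cat("<rod_frames> ", n, " nodes over r in [",
      format(x$r[1]), ", ", format(x$r[n]), "] m\n", sep = "")
  cat("  end point: ", paste(signif(x$s[n, ], 6), collapse = " "), "\n")
  invisible(x)
}
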