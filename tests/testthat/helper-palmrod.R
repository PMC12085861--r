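# shared fixtures and independent oracles

wct <- function(...) palm_tree("WCT", ...)

# random unit vector
runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# closed-form frame/arc for constant curvature y = (0, beta, 0):
# f3 rotates toward f1 about f2; the base curve is a circle of radius 1/beta
arc_endpoint <- function(beta, r, frame0) {
  f1 <- frame0$f1; f3 <- frame0$f3
  list(s = sin(beta * r) / beta * f3 + (1 - cos(beta * r)) / beta * f1,
       f3 = cos(beta * r) * f3 + sin(beta * r) * f1,
       f1 = cos(beta * r) * f1 - sin(beta * r) * f3)
}

# brute-force pool-adjacent-violators (least-squares isotonic regression)
pava_oracle <- function(y) {
  n <- length(y)
  val <- as.numeric(y)
  wt <- rep(1, n)
  blocks <- as.list(seq_len(n))
  vals <- val
  i <- 1L
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(vals)) {
      if (vals[i] > vals[i + 1L] + 1e-15) {
        w <- wt[i] + wt[i + 1L]
        v <- (wt[i] * vals[i] + wt[i + 1L] * vals[i + 1L]) / w
        vals <- c(vals[seq_len(i - 1L)], v,
                  if (i + 2L <= length(vals)) vals[(i + 2L):length(vals)])
        wt <- c(wt[seq_len(i - 1L)], w,
                if (i + 2L <= length(wt)) wt[(i + 2L):length(wt)])
        blocks[[i]] <- c(blocks[[i]], blocks[[i + 1L]])
        blocks[[i + 1L]] <- NULL
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  out <- numeric(n)
  for (b in seq_along(vals)) out[blocks[[b]]] <- vals[b]
  out
}

# brute-force comparison metrics from definitions
metrics_oracle <- function(pred, obs, scale = 1) {
  e <- (pred - obs) * scale
  list(variance = sum((e - sum(e) / length(e))^2) / length(e),
       mae = sum(abs(e)) / length(e),
       rmse = sqrt(sum(e^2) / length(e)),
       r2 = 1 - sum((pred - obs)^2) / sum((obs - sum(obs) / length(obs))^2))
}
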