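# Independent brute-force oracles, deliberately written with plain loops and
# a different algebra than the package internals.

oracle_displacement <- function(x, y) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < 2) return(numeric(0))
  for (i in 2:n) {
    dx <- x[i] - x[i - 1]
    dy <- y[i] - y[i - 1]
    out[i] <- sqrt(dx * dx + dy * dy)
  }
  out
}

oracle_speed <- function(x, y, t) {
  d <- oracle_displacement(x, y)
  n <- length(t)
  out <- rep(NA_real_, n)
  for (i in 2:n) out[i] <- d[i] / (t[i] - t[i - 1])
  out
}

oracle_accel <- function(x, y, t) {
  v <- oracle_speed(x, y, t)
  n <- length(t)
  out <- rep(NA_real_, n)
  for (i in 3:n) out[i] <- (v[i] - v[i - 1]) / (t[i] - t[i - 1])
  out
}

oracle_heading <- function(x, y) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in 2:n) {
    dx <- x[i] - x[i - 1]
    dy <- y[i] - y[i - 1]
    if (dx == 0 && dy == 0) next
    out[i] <- atan2(dy, dx) * 180 / pi
  }
  out
}

# wrap via repeated shifting, independent of the modulo identity
oracle_wrap <- function(a) {
  for (i in seq_along(a)) {
    if (is.na(a[i])) next
    while (a[i] > 180) a[i] <- a[i] - 360
    while (a[i] <= -180) a[i] <- a[i] + 360
  }
  a
}

oracle_polar_counts <- function(angles, n_bins) {
  width <- 360 / n_bins
  lows <- seq(-180, 180 - width, by = width)
  counts <- integer(n_bins)
  for (a in oracle_wrap(angles)) {
    if (is.na(a)) next
    for (b in seq_len(n_bins)) {
      if (a > lows[b] && a <= lows[b] + width) counts[b] <- counts[b] + 1L
    }
  }
  counts
}

rotate_traj <- function(traj, angle_deg, cx = 0, cy = 0) {
  th <- angle_deg * pi / 180
  x <- cx + (traj$x - cx) * cos(th) - (traj$y - cy) * sin(th)
  y <- cy + (traj$x - cx) * sin(th) + (traj$y - cy) * cos(th)
  trajectory(traj$t, x, y, start = attr(traj, "start"))
}

random_traj <- function(n, seed, dt = 0.25) {
  set.seed(seed)
  trajectory((seq_len(n) - 1) * dt,
             cumsum(rnorm(n)), cumsum(rnorm(n)),
             start = as.POSIXct("2026-01-01 07:00:00", tz = "UTC"))
}
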