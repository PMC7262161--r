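#' Construct a trajectory
#'
#' A trajectory is a time-stamped 2-D centroid track in cage coordinates:
#' time in seconds since recording start (strictly increasing), positions in
#' centimetres. Positions may be `NA` to mark gaps (dropped frames); gaps are
#' never interpolated silently, and derivative quantities spanning a gap are
#' undefined.
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y numeric vectors of positions in cm; `NA` marks a gap.
#' @param animal_id optional animal identifier (single string).
#' @param start optional wall-clock `POSIXct` of `t = 0`, kept as metadata
#'   for circadian splitting; time arithmetic always uses `t`.
#' @return A data frame of class `"trajectory"` with columns `t`, `x`, `y`.
#' @examples
#' tr <- trajectory(t = c(0, 0.25, 0.5), x = c(0, 3, 3), y = c(0, 4, 4))
#' calc_displacement(tr)
#' @export
trajectory <- function(t, x, y, animal_id = NULL, start = NULL) {
  if (!is.numeric(t) || !is.numeric(x) || !is.numeric(y))
    stop("t, x, y must be numeric")
  n <- length(t)
  if (n < 1L || length(x) != n || length(y) != n)
    stop("t, x, y must have equal length >= 1")
  if (anyNA(t) || any(!is.finite(t)))
    stop("timestamps must be finite")
  if (n > 1L) {
    dtv <- diff(t)
    bad <- which(dtv <= 0)
    if (length(bad))
      stop(sprintf("timestamps not strictly increasing at index %d", bad[1L] + 1L))
  }
  if (any(is.infinite(x)) || any(is.infinite(y)))
    stop("positions must be finite or NA")
  out <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y))
  class(out) <- c("trajectory", "data.frame")
  attr(out, "animal_id") <- if (is.null(animal_id)) NA_character_ else as.character(animal_id)
  if (!is.null(start)) {
    if (!inherits(start, "POSIXct")) stop("start must be POSIXct")
    attr(out, "start") <- start
  }
  out
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x)
  id <- attr(x, "animal_id")
  cat(sprintf("Trajectory: %d samples over %.1f s%s\n", n,
              if (n > 1) x$t[n] - x$t[1] else 0,
              if (!is.na(id)) paste0(" (animal ", id, ")") else ""))
  gaps <- sum(is.na(x$x) | is.na(x$y))
  if (gaps) cat(sprintf("  %d samples missing (gaps)\n", gaps))
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' @export
summary.trajectory <- function(object, ...) {
  d <- calc_displacement(object)
  k <- if (nrow(object) >= 2) calc_derivatives(object) else NULL
  out <- list(
    n = nrow(object),
    duration_s = if (nrow(object) > 1) diff(range(object$t)) else 0,
    path_length_cm = sum(d, na.rm = TRUE),
    mean_speed_cms = if (is.null(k)) NA_real_ else mean(k$speed, na.rm = TRUE),
    n_gaps = sum(is.na(object$x) | is.na(object$y))
  )
  class(out) <- "summary.trajectory"
  out
}

#' @export
print.summary.trajectory <- function(x, ...) {
  cat(sprintf("%d samples, %.1f s, path length %.1f cm, mean speed %.2f cm/s, %d gaps\n",
              x$n, x$duration_s, x$path_length_cm, x$mean_speed_cms, x$n_gaps))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ..., type = "l", asp = 1,
                            xlab = "x (cm)", ylab = "y (cm)") {
  graphics::plot(x$x, x$y, type = type, asp = asp, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Per-step displacement
#'
#' Euclidean distance between consecutive centroid samples. Entry `n`
#' describes the interval from sample `n-1` to sample `n`; the first entry is
#' `NA` (no preceding sample), and entries adjacent to a positional gap are
#' `NA`.
#'
#' @param traj a [trajectory].
#' @return Numeric vector of length `nrow(traj)` in cm, first element `NA`;
#'   `numeric(0)` for a single-sample trajectory.
#' @export
calc_displacement <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  if (n < 2L) return(numeric(0))
  c(NA_real_, sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Trajectory kinematics: speed and acceleration
#'
#' First and second time derivatives of position along the path:
#' `speed[n] = displacement[n] / (t[n] - t[n-1])` in cm/s and
#' `accel[n] = (speed[n] - speed[n-1]) / (t[n] - t[n-1])` in cm/s^2.
#' Acceleration is defined only where two consecutive speeds exist.
#'
#' @param traj a [trajectory] with at least 2 samples.
#' @return A data frame of class `"cage_kinematics"` with columns `t`, `dt`,
#'   `displacement`, `speed`, `accel`, aligned to sample index (row 1 is the
#'   undefined leading step).
#' @export
calc_derivatives <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  dtv <- c(NA_real_, diff(traj$t))
  dup <- which(dtv[-1L] <= 0)
  if (length(dup))
    stop(sprintf("non-increasing timestamp at index %d", dup[1L] + 1L))
  disp <- calc_displacement(traj)
  speed <- disp / dtv
  accel <- c(NA_real_, diff(speed)) / dtv
  out <- data.frame(t = traj$t, dt = dtv, displacement = disp,
                    speed = speed, accel = accel)
  class(out) <- c("cage_kinematics", "data.frame")
  out
}

#' Gate kinematic steps on a minimum speed
#'
#' Retains steps whose speed is at least `v_min` (inclusive: the printed
#' threshold is itself the smallest retained speed). The default 2 cm/s is
#' the 0.02 m/s gate used for velocity summaries. Undefined speeds (leading
#' step, gaps) are never retained.
#'
#' @param k a `"cage_kinematics"` data frame from [calc_derivatives()].
#' @param v_min minimum speed in cm/s, `>= 0`.
#' @return List with `mask` (logical, per step), `n_retained`, and
#'   `kinematics` (the retained rows).
#' @export
filter_min_speed <- function(k, v_min = 2) {
  stopifnot(inherits(k, "cage_kinematics"))
  if (!is.numeric(v_min) || length(v_min) != 1L || is.na(v_min) || v_min < 0)
    stop("v_min must be a single non-negative number")
  mask <- !is.na(k$speed) & k$speed >= v_min
  list(mask = mask, n_retained = sum(mask), kinematics = k[mask, , drop = FALSE])
}

#' Total distance travelled
#'
#' Path length as the sum of per-step displacements at or above
#' `min_displacement`, a filter eliminating slight apparent movements from
#' sensor jitter. `min_displacement = 0` gives the plain path length.
#'
#' @param traj a [trajectory].
#' @param min_displacement smallest step (cm) contributing to the sum.
#' @return Total distance in cm.
#' @export
total_distance <- function(traj, min_displacement = 0) {
  d <- calc_displacement(traj)
  if (!length(d)) return(0)
  sum(d[!is.na(d) & d >= min_displacement])
}

#' Resample a trajectory onto a regular time grid
#'
#' Output timestamps run from the first to the last original timestamp in
#' steps of `dt` (no extrapolation). Positions are linearly interpolated
#' across gaps of at most `max_gap` seconds between valid samples; grid
#' points falling inside longer gaps are left missing.
#'
#' @param traj a [trajectory].
#' @param dt target sampling interval in seconds, `> 0`.
#' @param max_gap longest original inter-sample gap (s) bridged by linear
#'   interpolation; defaults to `2 * dt`.
#' @return A [trajectory] on the regular grid.
#' @export
resample_regular <- function(traj, dt, max_gap = 2 * dt) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj) == 0L) stop("empty trajectory")
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("dt must be a single positive number")
  ok <- !is.na(traj$x) & !is.na(traj$y)
  tv <- traj$t[ok]; xv <- traj$x[ok]; yv <- traj$y[ok]
  if (length(tv) == 0L) stop("trajectory has no valid positions")
  grid <- seq(traj$t[1L], traj$t[nrow(traj)], by = dt)
  if (length(tv) == 1L) {
    xi <- ifelse(abs(grid - tv) < 1e-9, xv, NA_real_)
    yi <- ifelse(abs(grid - tv) < 1e-9, yv, NA_real_)
    return(trajectory(grid, xi, yi, animal_id = attr(traj, "animal_id"),
                      start = attr(traj, "start")))
  }
  xi <- stats::approx(tv, xv, xout = grid, rule = 1)$y
  yi <- stats::approx(tv, yv, xout = grid, rule = 1)$y
  # blank out grid points bridging a gap longer than max_gap
  idx <- findInterval(grid, tv)
  inner <- idx >= 1L & idx < length(tv)
  gap <- rep(NA_real_, length(grid))
  gap[inner] <- tv[idx[inner] + 1L] - tv[idx[inner]]
  on_sample <- !is.na(idx) & idx >= 1L & idx <= length(tv) &
    abs(grid - tv[pmax(idx, 1L)]) < 1e-9
  blank <- inner & gap > max_gap & !on_sample
  xi[blank] <- NA_real_
  yi[blank] <- NA_real_
  trajectory(grid, xi, yi, animal_id = attr(traj, "animal_id"),
             start = attr(traj, "start"))
}
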