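#' Electrode grid geometry
#'
#' Layout of the capacitive electrodes tiling the cage floor. The default is
#' the 12-electrode board of a digitally ventilated mouse cage, arranged as
#' a 4 x 3 lattice (4 columns along the 35 cm width, 3 rows along the 20 cm
#' depth) with electrode centres at the cell midpoints.
#'
#' @param n_x,n_y electrodes along the cage width and depth.
#' @param cage_width,cage_depth cage floor dimensions in cm.
#' @param centers optional two-column matrix of electrode centres (cm),
#'   overriding the lattice.
#' @return Object of class `"electrode_grid"`: list with `centers` (data
#'   frame `x`, `y`), `cage_width`, `cage_depth`, `pitch` (centre spacing
#'   along x, cm), `n_electrodes`.
#' @export
electrode_grid <- function(n_x = 4, n_y = 3, cage_width = 35, cage_depth = 20,
                           centers = NULL) {
  if (is.null(centers)) {
    cx <- (seq_len(n_x) - 0.5) * cage_width / n_x
    cy <- (seq_len(n_y) - 0.5) * cage_depth / n_y
    centers <- expand.grid(x = cx, y = cy)
  } else {
    centers <- as.data.frame(centers)
    names(centers) <- c("x", "y")
  }
  if (anyDuplicated(centers)) stop("electrode centers must be unique")
  if (any(centers$x < 0 | centers$x > cage_width |
          centers$y < 0 | centers$y > cage_depth))
    stop("electrode centers must lie within the cage bounds")
  out <- list(centers = centers,
              cage_width = cage_width, cage_depth = cage_depth,
              pitch = cage_width / n_x,
              n_electrodes = nrow(centers))
  class(out) <- "electrode_grid"
  out
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("Electrode grid: %d electrodes on a %.0f x %.0f cm floor (pitch %.2f cm)\n",
              x$n_electrodes, x$cage_width, x$cage_depth, x$pitch))
  invisible(x)
}

#' Capacitance recording container
#'
#' Per-frame, per-electrode capacitance values (arbitrary device units) on a
#' nominal 0.25 s sampling grid, together with the grid geometry and the
#' noise threshold used for activity detection.
#'
#' @param t frame timestamps in seconds, strictly increasing.
#' @param values numeric matrix, frames x electrodes.
#' @param grid an [electrode_grid()].
#' @param theta noise threshold in device units for activity events.
#' @return Object of class `"capacitance_recording"`.
#' @export
capacitance_recording <- function(t, values, grid, theta) {
  values <- as.matrix(values)
  if (length(t) != nrow(values)) stop("t must have one entry per frame")
  if (length(t) < 1L) stop("recording needs at least one frame")
  if (ncol(values) != grid$n_electrodes)
    stop(sprintf("recording has %d electrode columns but grid has %d electrodes",
                 ncol(values), grid$n_electrodes))
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("frame timestamps must be strictly increasing")
  if (theta < 0) stop("theta must be non-negative")
  out <- list(t = as.numeric(t), values = values, grid = grid,
              theta = as.numeric(theta))
  class(out) <- "capacitance_recording"
  out
}

#' @export
print.capacitance_recording <- function(x, ...) {
  cat(sprintf("Capacitance recording: %d frames x %d electrodes, theta = %g\n",
              length(x$t), ncol(x$values), x$theta))
  invisible(x)
}

#' Detect activity events
#'
#' An activity event fires for an electrode in an interval when the absolute
#' difference between its two consecutive capacitance measurements strictly
#' exceeds the noise threshold `theta`. Events are invariant to per-electrode
#' baseline offsets because they act on the difference signal.
#'
#' @param rec a [capacitance_recording()] with at least 2 frames.
#' @param theta noise threshold in device units; defaults to the recording's.
#' @return Object of class `"activity_events"`: list with `t` (interval end
#'   timestamps), `events` (logical matrix, intervals x electrodes), and
#'   `total` (per-interval event count).
#' @export
detect_activity <- function(rec, theta = rec$theta) {
  stopifnot(inherits(rec, "capacitance_recording"))
  if (length(rec$t) < 2L) stop("need at least 2 frames to detect activity")
  if (theta < 0) stop("theta must be non-negative")
  d <- abs(diff(rec$values))
  ev <- d > theta
  out <- list(t = rec$t[-1L], events = ev, total = rowSums(ev))
  class(out) <- "activity_events"
  out
}

#' @export
print.activity_events <- function(x, ...) {
  cat(sprintf("Activity events: %d intervals, %d events total (mean %.2f/interval)\n",
              length(x$t), sum(x$total), mean(x$total)))
  invisible(x)
}

#' Estimate position from one interval's capacitance changes
#'
#' The animal's position is estimated as the average of the centres of the
#' active electrodes (those whose absolute capacitance change exceeds
#' `theta`), weighted by the magnitude of the change. With no active
#' electrode the position is missing.
#'
#' @param delta per-electrode capacitance change for one interval.
#' @param grid an [electrode_grid()].
#' @param theta noise threshold in device units.
#' @return Named numeric `c(x =, y =)` in cm, or `c(NA, NA)` when no
#'   electrode is active.
#' @export
estimate_centroid <- function(delta, grid, theta) {
  if (length(delta) != grid$n_electrodes)
    stop("delta must have one value per electrode")
  w <- abs(delta)
  active <- !is.na(w) & w > theta
  if (!any(active)) return(c(x = NA_real_, y = NA_real_))
  w <- w[active]
  c(x = sum(w * grid$centers$x[active]) / sum(w),
    y = sum(w * grid$centers$y[active]) / sum(w))
}

#' Estimate a centroid trajectory from a capacitance recording
#'
#' Applies [estimate_centroid()] to every inter-frame interval; intervals
#' with no active electrode yield positional gaps.
#'
#' @param rec a [capacitance_recording()] with at least 2 frames.
#' @param theta noise threshold; defaults to the recording's.
#' @param start optional wall-clock start passed through to the trajectory.
#' @return A [trajectory] with one sample per interval (timestamps at the
#'   interval ends).
#' @export
estimate_centroids <- function(rec, theta = rec$theta, start = NULL) {
  stopifnot(inherits(rec, "capacitance_recording"))
  if (length(rec$t) < 2L) stop("need at least 2 frames")
  d <- abs(diff(rec$values))
  act <- d > theta
  w <- d * act
  tot <- rowSums(w)
  cx <- as.vector(w %*% rec$grid$centers$x) / tot
  cy <- as.vector(w %*% rec$grid$centers$y) / tot
  none <- tot == 0
  cx[none] <- NA_real_
  cy[none] <- NA_real_
  trajectory(rec$t[-1L], cx, cy, start = start)
}
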