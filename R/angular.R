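#' Wrap angles to (-180, 180]
#'
#' @param a angles in degrees.
#' @return Angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

#' Heading series of a trajectory
#'
#' Direction of the displacement vector at each step, in degrees with east =
#' 0 deg and counter-clockwise positive, wrapped to (-180, 180]. A
#' zero-displacement step has no direction and yields `NA`; all laterality
#' statistics are invariant to the axis convention.
#'
#' @param traj a [trajectory] with at least 2 samples.
#' @return Numeric vector of length `nrow(traj)`; element `n` is the heading
#'   of step `n-1 -> n`, first element `NA`.
#' @export
calc_heading <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj) < 2L) stop("need at least 2 samples for headings")
  dx <- diff(traj$x)
  dy <- diff(traj$y)
  he <- atan2(dy, dx) * 180 / pi
  he[!is.na(dx) & !is.na(dy) & dx == 0 & dy == 0] <- NA_real_
  c(NA_real_, wrap_angle(he))
}

#' Relative turn angles
#'
#' The wrapped heading difference `RTA[n] = wrap(HE[n] - HE[n-1])` in
#' degrees, positive for left (counter-clockwise) heading change under the
#' east = 0 convention; the left/right turn windows are defined on the sign
#' a mouse's turn direction produces, so classification is
#' convention-invariant. Undefined wherever either heading is undefined.
#'
#' @param headings heading series from [calc_heading()].
#' @return Numeric vector of the same length; elements 1 and 2 are `NA`.
#' @export
calc_turn_angles <- function(headings) {
  if (length(headings) < 2L) stop("need at least 2 headings")
  c(NA_real_, wrap_angle(diff(headings)))
}

#' Relative angular velocity
#'
#' `RAV[n] = RTA[n] / (t[n] - t[n-1])` in degrees per second.
#'
#' @param rta turn-angle series (degrees), aligned to sample index.
#' @param t timestamps in seconds, same length.
#' @return Numeric vector of angular velocities (deg/s).
#' @export
calc_angular_velocity <- function(rta, t) {
  if (length(rta) != length(t)) stop("rta and t must have equal length")
  dtv <- c(NA_real_, diff(t))
  dup <- which(dtv[-1L] <= 0)
  if (length(dup))
    stop(sprintf("duplicate or decreasing timestamp at index %d", dup[1L] + 1L))
  rta / dtv
}

#' Classify steps as left turns, right turns, or neither
#'
#' A step is a right turn when its relative turn angle falls in
#' `right_window` (closed interval, default `[30, 90]` degrees) and its speed
#' is at least `v_min` (default 1 cm/s); left turns are symmetric with
#' `left_window` (default `[-90, -30]`). Everything else -- angles outside
#' both windows, sub-threshold speed, undefined angles -- is `"none"`.
#' Boundary angles (exactly 30 or 90) count as turns. By convention the
#' positive window is labelled "right" (matching the laterality-index
#' definition R = #\{RTA in [30, 90]\}); LI is invariant to the axis
#' convention up to the mirror symmetry LI -> 1 - LI.
#'
#' @param rta turn-angle series in degrees.
#' @param speed per-step speed in cm/s, same length.
#' @param right_window,left_window closed intervals in degrees of RTA.
#' @param v_min minimum speed gate in cm/s.
#' @return Character vector in `{"left", "right", "none"}`.
#' @export
classify_turns <- function(rta, speed, right_window = c(30, 90),
                           left_window = c(-90, -30), v_min = 1) {
  if (length(rta) != length(speed)) stop("rta and speed must have equal length")
  if (length(right_window) != 2L || length(left_window) != 2L ||
      right_window[1] > right_window[2] || left_window[1] > left_window[2])
    stop("turn windows must be ordered pairs (low, high)")
  if (right_window[1] <= left_window[2] && left_window[1] <= right_window[2])
    stop("turn windows overlap")
  if (v_min < 0) stop("v_min must be non-negative")
  a <- rta
  ok <- !is.na(a) & !is.na(speed) & speed >= v_min
  lab <- rep("none", length(rta))
  lab[ok & a >= right_window[1] & a <= right_window[2]] <- "right"
  lab[ok & a >= left_window[1] & a <= left_window[2]] <- "left"
  lab
}

#' Laterality index
#'
#' `LI = R / (R + L)`, the fraction of classified turns that are rightward;
#' `LI` lies in `[0, 1]`, with 0.5 indicating no side preference and values
#' below 0.5 a left-turn preference. When no turns were classified the index
#' is undefined (flagged, not zero).
#'
#' @param labels character vector of turn labels from [classify_turns()].
#' @return An object of class `"laterality"`: list with counts `R`, `L`,
#'   index `LI` (`NA` when undefined) and logical `undefined`.
#' @export
laterality_index <- function(labels) {
  R <- sum(labels == "right", na.rm = TRUE)
  L <- sum(labels == "left", na.rm = TRUE)
  out <- list(R = R, L = L,
              LI = if (R + L > 0) R / (R + L) else NA_real_,
              undefined = R + L == 0)
  class(out) <- "laterality"
  out
}

#' @export
print.laterality <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("Laterality: undefined (R = %d, L = %d)\n", x$R, x$L))
  } else {
    cat(sprintf("Laterality index LI = %.4f (R = %d, L = %d)\n", x$LI, x$R, x$L))
  }
  invisible(x)
}

#' Polar binning of angles
#'
#' Histogram of angles over bins partitioning (-180, 180], half-open on the
#' left and closed on the right, optionally accumulating a per-step weight
#' (typically displacement) per bin. The table feeds any plotting layer
#' (polar bar charts of angular movement).
#'
#' @param angles angles in degrees (headings or turn angles); `NA` skipped.
#' @param n_bins number of bins, `>= 2` and dividing 360 evenly.
#' @param weights optional per-angle weights (e.g. displacement in cm).
#' @return Data frame with `bin_left_deg`, `bin_right_deg`, `count`,
#'   `summed_displacement_cm` (`NA` when no weights supplied).
#' @export
polar_bin <- function(angles, n_bins = 36, weights = NULL) {
  if (n_bins < 2 || 360 %% n_bins != 0)
    stop("n_bins must be >= 2 and divide 360 evenly")
  if (!is.null(weights) && length(weights) != length(angles))
    stop("weights must match angles in length")
  width <- 360 / n_bins
  a <- wrap_angle(angles)
  keep <- !is.na(a)
  a <- a[keep]
  stopifnot(all(a > -180 & a <= 180))
  idx <- ceiling((a + 180) / width)
  idx[idx < 1L] <- 1L  # guards numerical edge at -180
  counts <- tabulate(idx, nbins = n_bins)
  wsum <- rep(NA_real_, n_bins)
  if (!is.null(weights)) {
    w <- weights[keep]
    w[is.na(w)] <- 0
    wsum <- as.numeric(tapply(w, factor(idx, levels = seq_len(n_bins)), sum))
    wsum[is.na(wsum)] <- 0
  }
  edges <- seq(-180, 180, by = width)
  data.frame(bin_left_deg = edges[-length(edges)],
             bin_right_deg = edges[-1L],
             count = counts,
             summed_displacement_cm = wsum)
}

#' Turn analysis of a trajectory
#'
#' The package's main fitting-style entry point: computes kinematics,
#' headings, relative turn angles, angular velocities, turn labels, the
#' laterality index and a polar-binned heading table for one trajectory, at
#' the configured thresholds.
#'
#' @param traj a [trajectory] with at least 3 samples.
#' @param right_window,left_window closed turn windows in degrees of RTA.
#' @param v_min minimum speed gate for turn classification, cm/s.
#' @param n_bins number of polar bins for the heading histogram.
#' @return Object of class `"cage_turns"`: list with `records` (per-step data
#'   frame: `t`, `dt`, `displacement`, `speed`, `heading`, `rta`, `rav`,
#'   `label`), `laterality`, `polar`, and `params`.
#' @examples
#' tr <- simulate_path(duration = 60, seed = 1)
#' fit <- turns(tr)
#' coef(fit)
#' @export
turns <- function(traj, right_window = c(30, 90), left_window = c(-90, -30),
                  v_min = 1, n_bins = 36) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj) < 3L) stop("need at least 3 samples for turn analysis")
  k <- calc_derivatives(traj)
  he <- calc_heading(traj)
  rta <- calc_turn_angles(he)
  rav <- calc_angular_velocity(rta, traj$t)
  lab <- classify_turns(rta, k$speed, right_window, left_window, v_min)
  rec <- data.frame(t = traj$t, dt = k$dt, displacement = k$displacement,
                    speed = k$speed, heading = he, rta = rta, rav = rav,
                    label = lab)
  out <- list(records = rec,
              laterality = laterality_index(lab),
              polar = polar_bin(he, n_bins, weights = k$displacement),
              params = list(right_window = right_window,
                            left_window = left_window, v_min = v_min,
                            n_bins = n_bins))
  class(out) <- "cage_turns"
  out
}

#' @export
print.cage_turns <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("Turn analysis: %d steps, windows [%g, %g] / [%g, %g] deg, gate %g cm/s\n",
              n, x$params$left_window[1], x$params$left_window[2],
              x$params$right_window[1], x$params$right_window[2],
              x$params$v_min))
  print(x$laterality)
  invisible(x)
}

#' @export
coef.cage_turns <- function(object, ...) {
  c(R = object$laterality$R, L = object$laterality$L, LI = object$laterality$LI)
}

#' @export
summary.cage_turns <- function(object, ...) {
  rec <- object$records
  out <- list(
    n_steps = nrow(rec),
    coef = coef.cage_turns(object),
    mean_abs_rta = mean(abs(rec$rta), na.rm = TRUE),
    mean_abs_rav = mean(abs(rec$rav), na.rm = TRUE),
    n_undefined = sum(is.na(rec$rta))
  )
  class(out) <- "summary.cage_turns"
  out
}

#' @export
print.summary.cage_turns <- function(x, ...) {
  cat(sprintf("%d steps (%d undefined turn angles)\n", x$n_steps, x$n_undefined))
  cat(sprintf("R = %d, L = %d, LI = %s\n", x$coef[["R"]], x$coef[["L"]],
              formatC(x$coef[["LI"]], digits = 4, format = "f")))
  cat(sprintf("mean |RTA| = %.1f deg, mean |RAV| = %.1f deg/s\n",
              x$mean_abs_rta, x$mean_abs_rav))
  invisible(x)
}

#' Polar bar chart of a turn analysis
#'
#' Draws the binned heading distribution as a polar bar chart (bar length
#' proportional to summed displacement per heading bin, falling back to
#' counts when no weights are present).
#'
#' @param x a `"cage_turns"` object.
#' @param ... further arguments passed to [graphics::polygon()].
#' @export
plot.cage_turns <- function(x, ...) {
  pb <- x$polar
  val <- pb$summed_displacement_cm
  if (all(is.na(val))) val <- pb$count
  r <- val / max(val, 1e-12)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = "Angular movement")
  th <- seq(0, 2 * pi, length.out = 121)
  graphics::lines(cos(th), sin(th), col = "grey80")
  for (i in seq_len(nrow(pb))) {
    a0 <- pb$bin_left_deg[i] * pi / 180
    a1 <- pb$bin_right_deg[i] * pi / 180
    aa <- seq(a0, a1, length.out = 8)
    graphics::polygon(c(0, r[i] * cos(aa)), c(0, r[i] * sin(aa)),
                      col = "steelblue", border = "white", ...)
  }
  invisible(x)
}
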