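# Specular reflection of an unbounded coordinate into [lo, hi] (triangle-wave
# fold): positions equal those of a walk reflecting off the walls.
fold_reflect <- function(p, lo, hi) {
  L <- hi - lo
  q <- (p - lo) %% (2 * L)
  lo + pmin(q, 2 * L - q)
}

parse_hm <- function(s) {
  parts <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
  if (length(parts) != 2 || anyNA(parts)) stop("time must be 'HH:MM'")
  parts[1] * 3600 + parts[2] * 60
}

seconds_of_day <- function(start, t) {
  sod0 <- as.numeric(difftime(start, trunc(start, "days"), units = "secs"))
  (sod0 + t) %% 86400
}

#' Simulate a cage path as a correlated random walk
#'
#' Generates a 2-D trajectory on the sensor sampling grid (default 0.25 s).
#' Headings evolve by per-step turn draws whose sign is positive (toward the
#' right-turn window) with probability `p_right`; step lengths are drawn
#' from an exponential (or fixed) distribution whose mean is scaled up
#' during the dark phase of a 12 h light/dark cycle, and a fraction of steps
#' are rest (zero displacement). The path is confined to the cage by
#' specular reflection at the walls. Fully deterministic given `seed`.
#'
#' Defaults emulate a singly housed mouse: 2 cm/s typical locomotion speed
#' in the light phase, threefold higher dark-phase activity, 40% of frames
#' at rest, lights on 07:00-19:00, recording starting at lights-on.
#'
#' @param duration recording length in seconds (default one day).
#' @param dt sampling interval in seconds (default 0.25, the cage sensor
#'   frame rate).
#' @param seed integer RNG seed (required; simulations are reproducible).
#' @param step_length mean step length in cm per frame during the light
#'   phase (0.5 cm per 0.25 s frame = 2 cm/s while moving).
#' @param dark_gain multiplier on mean step length during the dark phase.
#' @param rest_prob per-step probability of a rest (zero-length) step.
#' @param step_dist `"exponential"` or `"fixed"` step-length distribution.
#' @param turn_dist `"normal"` or `"uniform"` turn-magnitude distribution.
#' @param turn_sd sd (deg) of the normal turn distribution.
#' @param turn_halfwidth half-width (deg) of the uniform turn distribution.
#' @param p_right probability that a turn is rightward (positive RTA).
#' @param cage_width,cage_depth cage floor dimensions in cm.
#' @param start wall-clock `POSIXct` of the first frame (drives the
#'   circadian schedule).
#' @param lights_on,lights_off light-phase boundaries, `"HH:MM"`.
#' @param animal_id optional identifier carried on the trajectory.
#' @return A [trajectory] with `duration/dt` samples and `start` metadata.
#' @examples
#' tr <- simulate_path(duration = 300, seed = 42)
#' summary(tr)
#' @export
simulate_path <- function(duration = 86400, dt = 0.25, seed,
                          step_length = 0.5, dark_gain = 3, rest_prob = 0.4,
                          step_dist = c("exponential", "fixed"),
                          turn_dist = c("normal", "uniform"),
                          turn_sd = 30, turn_halfwidth = 90, p_right = 0.5,
                          cage_width = 35, cage_depth = 20,
                          start = as.POSIXct("2026-01-01 07:00:00", tz = "UTC"),
                          lights_on = "07:00", lights_off = "19:00",
                          animal_id = NULL) {
  if (missing(seed)) stop("seed is required")
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  step_dist <- match.arg(step_dist)
  turn_dist <- match.arg(turn_dist)
  set.seed(seed)
  n_frames <- round(duration / dt)
  t <- (seq_len(n_frames) - 1L) * dt
  n_steps <- n_frames - 1L
  if (n_steps < 1L) stop("duration too short for the chosen dt")

  mag <- switch(turn_dist,
                normal = abs(stats::rnorm(n_steps, 0, turn_sd)),
                uniform = stats::runif(n_steps, 0, turn_halfwidth))
  sgn <- ifelse(stats::runif(n_steps) < p_right, 1, -1)
  he <- stats::runif(1, -180, 180) + cumsum(sgn * mag)

  on <- parse_hm(lights_on); off <- parse_hm(lights_off)
  sod <- seconds_of_day(start, t[-n_frames])
  gain <- ifelse(sod >= on & sod < off, 1, dark_gain)
  if (step_length <= 0) {
    len <- rep(0, n_steps)
  } else {
    len <- switch(step_dist,
                  fixed = step_length * gain,
                  exponential = stats::rexp(n_steps, rate = 1 / (step_length * gain)))
    len[stats::runif(n_steps) < rest_prob] <- 0
  }

  turn <- sgn * mag
  xs <- numeric(n_frames); ys <- numeric(n_frames)
  xs[1L] <- cage_width / 2; ys[1L] <- cage_depth / 2
  he_prev <- stats::runif(1, -180, 180)
  # chunked integration: free CRW until the first wall contact, then a
  # specular bounce (heading mirrored at the wall, turn handedness kept)
  i <- 1L
  w <- 512L
  while (i <= n_steps) {
    j <- min(i + w - 1L, n_steps)
    idx <- i:j
    he_seg <- he_prev + cumsum(turn[idx])
    px <- xs[i] + cumsum(len[idx] * cospi(he_seg / 180))
    py <- ys[i] + cumsum(len[idx] * sinpi(he_seg / 180))
    bad <- which(px < 0 | px > cage_width | py < 0 | py > cage_depth)
    if (!length(bad)) {
      xs[idx + 1L] <- px
      ys[idx + 1L] <- py
      he_prev <- he_seg[length(he_seg)]
      i <- j + 1L
    } else {
      k <- bad[1L]
      if (k > 1L) {
        xs[idx[1L:(k - 1L)] + 1L] <- px[1L:(k - 1L)]
        ys[idx[1L:(k - 1L)] + 1L] <- py[1L:(k - 1L)]
      }
      ex <- fold_reflect(px[k], 0, cage_width)
      ey <- fold_reflect(py[k], 0, cage_depth)
      n0 <- idx[k]
      xs[n0 + 1L] <- ex
      ys[n0 + 1L] <- ey
      he_prev <- atan2(ey - ys[n0], ex - xs[n0]) * 180 / pi
      i <- n0 + 1L
    }
  }
  trajectory(t, xs, ys, animal_id = animal_id, start = start)
}

#' Simulate a capacitance recording from a ground-truth path
#'
#' Forward sensor model: each electrode's capacitance is a per-electrode
#' baseline plus a Gaussian kernel of the animal's distance to the electrode
#' centre (monotone decreasing in distance), plus Gaussian measurement
#' noise. Deterministic given `seed`. The recording's activity threshold is
#' set to `4 * noise_sd`.
#'
#' @param traj ground-truth [trajectory] on the sensor sampling grid.
#' @param grid an [electrode_grid()].
#' @param length_scale kernel length scale in cm.
#' @param gain kernel amplitude in device units.
#' @param noise_sd measurement noise sd in device units.
#' @param baseline mean per-electrode baseline in device units.
#' @param seed integer RNG seed (required).
#' @return A [capacitance_recording()].
#' @export
simulate_recording <- function(traj, grid = electrode_grid(),
                               length_scale = 6, gain = 100, noise_sd = 1,
                               baseline = 1000, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(traj, "trajectory"))
  set.seed(seed)
  n <- nrow(traj)
  ne <- grid$n_electrodes
  base_e <- baseline + stats::rnorm(ne, 0, 0.05 * baseline)
  dx <- outer(traj$x, grid$centers$x, "-")
  dy <- outer(traj$y, grid$centers$y, "-")
  sig <- gain * exp(-0.5 * (dx^2 + dy^2) / length_scale^2)
  sig[is.na(sig)] <- 0  # gaps contribute no signal
  vals <- sig + rep(base_e, each = n) +
    matrix(stats::rnorm(n * ne, 0, noise_sd), n, ne)
  capacitance_recording(traj$t, vals, grid, theta = 4 * noise_sd)
}

#' Simulate a two-group home-cage cohort
#'
#' Emulates the study design: singly housed animals recorded continuously at
#' 0.25 s resolution over consecutive days, in a control group and a
#' treatment group carrying planted effects. Effects scale the treatment
#' group's mean step length (locomotion), its sensor gain (activity
#' amplitude) and its rightward-turn probability (laterality bias);
#' ground-truth values are recorded in the metadata for recovery tests.
#' Per-animal seeds are derived reproducibly from the master seed.
#'
#' @param n_per_group animals per group (study default 12).
#' @param n_days recording days (study default 35).
#' @param effects list with `step_length` (multiplier), `activity_gain`
#'   (multiplier on sensor gain) and `p_right` (treatment-group rightward
#'   turn probability); control values are 1, 1 and 0.5.
#' @param seed master RNG seed (required).
#' @param hours_per_day recorded hours per day (default full 24 h).
#' @param sensors also simulate capacitance recordings (default `TRUE`).
#' @param grid an [electrode_grid()] used for the sensor model.
#' @param dt sampling interval in seconds.
#' @param start wall-clock start of day 0.
#' @param ... further arguments passed to [simulate_path()].
#' @return List with `animals` (each: `animal_id`, `group`, `trajectory`,
#'   optional `recording`, `truth`) and `metadata` (one row per animal with
#'   the planted ground truth).
#' @export
simulate_cohort <- function(n_per_group = 12, n_days = 35,
                            effects = list(step_length = 1, activity_gain = 1,
                                           p_right = 0.5),
                            seed, hours_per_day = 24, sensors = TRUE,
                            grid = electrode_grid(), dt = 0.25,
                            start = as.POSIXct("2026-01-01 07:00:00", tz = "UTC"),
                            ...) {
  if (missing(seed)) stop("seed is required")
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  eff <- utils::modifyList(list(step_length = 1, activity_gain = 1,
                                p_right = 0.5), effects)
  set.seed(seed)
  n_animals <- 2L * n_per_group
  seeds <- sample.int(.Machine$integer.max, 2L * n_animals)
  duration <- n_days * hours_per_day * 3600
  groups <- rep(c("control", "treatment"), each = n_per_group)
  ids <- sprintf("%s%02d", ifelse(groups == "control", "C", "T"),
                 c(seq_len(n_per_group), seq_len(n_per_group)))
  animals <- vector("list", n_animals)
  meta <- data.frame(animal_id = ids, group = groups,
                     step_length = NA_real_, p_right = NA_real_,
                     sensor_gain = NA_real_, seed = seeds[seq_len(n_animals)])
  for (i in seq_len(n_animals)) {
    treated <- groups[i] == "treatment"
    sl <- 0.5 * if (treated) eff$step_length else 1
    pr <- if (treated) eff$p_right else 0.5
    sg <- 100 * if (treated) eff$activity_gain else 1
    tr <- simulate_path(duration = duration, dt = dt, seed = seeds[i],
                        step_length = sl, p_right = pr, start = start,
                        animal_id = ids[i], ...)
    rec <- if (sensors)
      simulate_recording(tr, grid = grid, gain = sg,
                         seed = seeds[n_animals + i])
    meta$step_length[i] <- sl
    meta$p_right[i] <- pr
    meta$sensor_gain[i] <- sg
    animals[[i]] <- list(animal_id = ids[i], group = groups[i],
                         trajectory = tr, recording = rec,
                         truth = list(step_length = sl, p_right = pr,
                                      sensor_gain = sg))
  }
  list(animals = animals, metadata = meta)
}
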