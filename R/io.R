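check_numeric_col <- function(df, col, path) {
  v <- df[[col]]
  if (is.numeric(v)) return(v)
  num <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(num) & !is.na(v) & !(trimws(v) %in% c("", "NA")))
  if (length(bad))
    stop(sprintf("%s: column '%s' not numeric at data row %d (value '%s')",
                 path, col, bad[1L], v[bad[1L]]))
  num
}

#' Read a centroid trajectory CSV
#'
#' Expected schema: header `time_s,x_cm,y_cm` (comma-separated, decimal
#' point, UTF-8), optional `animal_id` column with a single value. Missing
#' positions may be blank or `NA` (gaps). Errors name the offending row.
#'
#' @param path CSV file path.
#' @param start optional `POSIXct` wall clock of `time_s = 0`.
#' @return A [trajectory].
#' @export
read_centroids <- function(path, start = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("time_s", "x_cm", "y_cm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  tv <- check_numeric_col(df, "time_s", path)
  xv <- check_numeric_col(df, "x_cm", path)
  yv <- check_numeric_col(df, "y_cm", path)
  if (length(tv) > 1L) {
    bad <- which(diff(tv) <= 0)
    if (length(bad))
      stop(sprintf("%s: time_s not strictly increasing at data row %d",
                   path, bad[1L] + 1L))
  }
  id <- NULL
  if ("animal_id" %in% names(df)) {
    ids <- unique(df$animal_id)
    if (length(ids) != 1L)
      stop(sprintf("%s: expected a single animal_id, found %d", path, length(ids)))
    id <- ids
  }
  trajectory(tv, xv, yv, animal_id = id, start = start)
}

#' Write a centroid trajectory CSV
#'
#' @param traj a [trajectory].
#' @param path output CSV path.
#' @export
write_centroids <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- data.frame(time_s = traj$t, x_cm = traj$x, y_cm = traj$y)
  id <- attr(traj, "animal_id")
  if (!is.null(id) && !is.na(id)) df$animal_id <- id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a raw sensor CSV
#'
#' Expected schema: `time_s,e01,...,eNN` with one electrode column per grid
#' electrode; the electrode count must match the grid.
#'
#' @param path CSV file path.
#' @param grid an [electrode_grid()].
#' @param theta activity noise threshold in device units.
#' @return A [capacitance_recording()].
#' @export
read_sensor <- function(path, grid, theta = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"time_s" %in% names(df)) stop(sprintf("%s: missing column time_s", path))
  ecols <- grep("^e[0-9]+$", names(df), value = TRUE)
  if (length(ecols) != grid$n_electrodes)
    stop(sprintf("%s: %d electrode columns but grid has %d electrodes",
                 path, length(ecols), grid$n_electrodes))
  tv <- check_numeric_col(df, "time_s", path)
  ecols <- ecols[order(ecols)]
  for (cc in ecols) df[[cc]] <- check_numeric_col(df, cc, path)
  vals <- as.matrix(df[, ecols, drop = FALSE])
  capacitance_recording(tv, vals, grid, theta)
}

#' Write a raw sensor CSV
#'
#' @param rec a [capacitance_recording()].
#' @param path output CSV path.
#' @export
write_sensor <- function(rec, path) {
  stopifnot(inherits(rec, "capacitance_recording"))
  vals <- as.data.frame(rec$values)
  names(vals) <- sprintf("e%02d", seq_len(ncol(vals)))
  utils::write.csv(cbind(data.frame(time_s = rec$t), vals), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a grid sidecar config (YAML)
#'
#' Records cage dimensions, electrode centres and the activity threshold so
#' a raw sensor CSV is self-describing.
#'
#' @param grid an [electrode_grid()].
#' @param path output YAML path.
#' @param theta activity threshold stored alongside the geometry.
#' @export
write_grid_config <- function(grid, path, theta = 0) {
  yaml::write_yaml(list(cage_width = grid$cage_width,
                        cage_depth = grid$cage_depth,
                        theta = theta,
                        centers_x = grid$centers$x,
                        centers_y = grid$centers$y), path)
  invisible(path)
}

#' Read a grid sidecar config (YAML)
#'
#' @param path YAML path written by [write_grid_config()].
#' @return List with `grid` (an [electrode_grid()]) and `theta`.
#' @export
read_grid_config <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- electrode_grid(cage_width = y$cage_width, cage_depth = y$cage_depth,
                         centers = cbind(y$centers_x, y$centers_y))
  list(grid = grid, theta = if (is.null(y$theta)) 0 else y$theta)
}

#' Default run configuration
#'
#' All analysis thresholds in one place; every default matches the printed
#' protocol value where one exists (0.25 s frames, 0.02 m/s velocity gate,
#' 1 cm/s laterality gate, turn windows [30, 90] / [-90, -30] deg, lights
#' 07:00-19:00, 12 electrodes). Speed thresholds may be given in m/s; the
#' cm/s form is derived.
#'
#' @param ... named overrides of the defaults.
#' @return A named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    dt_s = 0.25,
    min_speed_ms = 0.02,
    turn_min_speed_cms = 1,
    min_displacement_cm = 0,
    right_window = c(30, 90),
    left_window = c(-90, -30),
    polar_bins = 36,
    lights_on = "07:00",
    lights_off = "19:00",
    n_electrodes = 12,
    theta = 4,
    max_gap_s = 0.5
  )
  over <- list(...)
  bad <- setdiff(names(over), c(names(cfg), "min_speed_cms"))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  if (is.null(over$min_speed_cms)) {
    cfg$min_speed_cms <- cfg$min_speed_ms * 100
  } else {
    cfg$min_speed_cms <- over$min_speed_cms
    cfg$min_speed_ms <- over$min_speed_cms / 100
  }
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

#' Read a run configuration YAML, merged over the defaults
#'
#' @param path YAML file path.
#' @return A `"run_config"` list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Write a run configuration YAML
#'
#' @param cfg a `"run_config"`.
#' @param path output YAML path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
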