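#' Split timestamps into circadian phases
#'
#' Daytime is the light phase, `[lights_on, lights_off)` (default
#' 07:00-19:00); everything else is night. Boundaries are half-open: the
#' lights-on instant is day, the lights-off instant is night.
#'
#' @param times `POSIXct` wall-clock times, or numeric seconds-of-day.
#' @param lights_on,lights_off phase boundaries as `"HH:MM"` strings.
#' @return Factor with levels `c("day", "night")`.
#' @export
split_day_night <- function(times, lights_on = "07:00", lights_off = "19:00") {
  on <- parse_hm(lights_on); off <- parse_hm(lights_off)
  if (on >= off) stop("lights_on must precede lights_off within the day")
  sod <- if (inherits(times, "POSIXct")) {
    as.numeric(difftime(times, trunc(times, "days"), units = "secs"))
  } else {
    as.numeric(times) %% 86400
  }
  factor(ifelse(sod >= on & sod < off, "day", "night"),
         levels = c("day", "night"))
}

#' Per-animal, per-day, per-phase summaries
#'
#' Splits a trajectory (and optionally its activity-event series) into
#' calendar days and circadian phases and computes, for each day x phase
#' (day, night, and the full-24 h "overall"): summed activity events, total
#' distance at the configured minimum displacement, mean speed over steps
#' passing the velocity gate, right/left turn counts and the laterality
#' index. Steps are assigned to the day and phase of their end timestamp.
#' Periods with no data yield missing metrics, not zeros.
#'
#' @param traj a [trajectory] carrying a `start` wall clock.
#' @param events optional `"activity_events"` from [detect_activity()],
#'   on the same clock as `traj`.
#' @param animal_id identifier for the output rows; defaults to the
#'   trajectory's.
#' @param day0 `POSIXct` reference midnight defining day index 0 (e.g. the
#'   surgery day); defaults to midnight of the recording start day.
#' @param min_displacement smallest step (cm) counted into distance.
#' @param speed_gate_cms velocity gate (cm/s) for mean speed (default
#'   2 cm/s = 0.02 m/s).
#' @param turn_v_min,right_window,left_window turn-classification settings,
#'   see [classify_turns()].
#' @param lights_on,lights_off circadian boundaries, `"HH:MM"`.
#' @return Data frame with columns `animal_id`, `day`, `phase`, `activity`,
#'   `distance_cm`, `mean_speed_cms`, `n_right`, `n_left`, `li`.
#' @export
summarize_periods <- function(traj, events = NULL, animal_id = NULL,
                              day0 = NULL, min_displacement = 0,
                              speed_gate_cms = 2, turn_v_min = 1,
                              right_window = c(30, 90),
                              left_window = c(-90, -30),
                              lights_on = "07:00", lights_off = "19:00") {
  stopifnot(inherits(traj, "trajectory"))
  start <- attr(traj, "start")
  if (is.null(start)) stop("trajectory must carry a wall-clock start")
  if (is.null(animal_id)) animal_id <- attr(traj, "animal_id")
  if (is.null(day0)) day0 <- trunc(start, "days")

  fit <- turns(traj, right_window = right_window, left_window = left_window,
               v_min = turn_v_min)
  rec <- fit$records
  wall_s <- as.numeric(start) + traj$t
  day_idx <- floor((wall_s - as.numeric(day0)) / 86400)
  phase <- split_day_night(seconds_of_day(start, traj$t), lights_on, lights_off)
  step <- seq_len(nrow(rec))[-1L]  # rows describing an interval

  ev_day <- ev_phase <- NULL
  if (!is.null(events)) {
    ev_wall <- as.numeric(start) + events$t
    ev_day <- floor((ev_wall - as.numeric(day0)) / 86400)
    ev_phase <- split_day_night(seconds_of_day(start, events$t),
                                lights_on, lights_off)
  }

  one <- function(day, ph) {
    m <- step[day_idx[step] == day &
                (ph == "overall" | as.character(phase[step]) == ph)]
    if (!length(m))
      return(data.frame(animal_id = animal_id, day = day, phase = ph,
                        activity = NA_real_, distance_cm = NA_real_,
                        mean_speed_cms = NA_real_, n_right = NA_integer_,
                        n_left = NA_integer_, li = NA_real_))
    d <- rec$displacement[m]
    dist <- sum(d[!is.na(d) & d >= min_displacement])
    sp <- rec$speed[m]
    sp <- sp[!is.na(sp) & sp >= speed_gate_cms]
    lat <- laterality_index(rec$label[m])
    act <- NA_real_
    if (!is.null(events)) {
      em <- ev_day == day & (ph == "overall" | as.character(ev_phase) == ph)
      act <- sum(events$total[em])
    }
    data.frame(animal_id = animal_id, day = day, phase = ph,
               activity = act, distance_cm = dist,
               mean_speed_cms = if (length(sp)) mean(sp) else NA_real_,
               n_right = lat$R, n_left = lat$L, li = lat$LI)
  }

  days <- sort(unique(day_idx[step]))
  out <- do.call(rbind, lapply(days, function(d)
    rbind(one(d, "day"), one(d, "night"), one(d, "overall"))))
  rownames(out) <- NULL
  out
}

#' Pool daily summaries over an inclusive day range
#'
#' Per animal and phase, averages daily metric values over the days in
#' `[day_range[1], day_range[2]]` (both ends included, matching ranges
#' printed as e.g. "1-7"). Missing days are skipped and the number of days
#' actually used is reported. By default the pooled laterality index is
#' recomputed from the summed right and left turn counts over the range
#' (robust to low-turn days); `li_mode = "mean_of_daily"` averages the daily
#' indices instead.
#'
#' @param summaries output of [summarize_periods()] (rows from several
#'   animals may be concatenated).
#' @param day_range inclusive integer range `c(a, b)`, `a <= b`.
#' @param li_mode `"ratio_of_sums"` or `"mean_of_daily"`.
#' @return Data frame with one row per animal x phase: pooled `activity`,
#'   `distance_cm`, `mean_speed_cms`, `n_right`, `n_left`, `li`,
#'   `n_days_used`.
#' @export
pool_day_range <- function(summaries, day_range,
                           li_mode = c("ratio_of_sums", "mean_of_daily")) {
  li_mode <- match.arg(li_mode)
  if (length(day_range) != 2L || day_range[1] > day_range[2])
    stop("day_range must be c(a, b) with a <= b")
  sub <- summaries[summaries$day >= day_range[1] &
                     summaries$day <= day_range[2], , drop = FALSE]
  if (!nrow(sub))
    stop(sprintf("no days in [%s, %s]; available days: %s",
                 day_range[1], day_range[2],
                 paste(sort(unique(summaries$day)), collapse = ", ")))
  key <- interaction(sub$animal_id, sub$phase, drop = TRUE)
  pooled <- lapply(split(sub, key), function(g) {
    R <- sum(g$n_right, na.rm = TRUE)
    L <- sum(g$n_left, na.rm = TRUE)
    li <- switch(li_mode,
                 ratio_of_sums = if (R + L > 0) R / (R + L) else NA_real_,
                 mean_of_daily = mean(g$li, na.rm = TRUE))
    data.frame(animal_id = g$animal_id[1L], phase = g$phase[1L],
               activity = mean(g$activity, na.rm = TRUE),
               distance_cm = mean(g$distance_cm, na.rm = TRUE),
               mean_speed_cms = mean(g$mean_speed_cms, na.rm = TRUE),
               n_right = R, n_left = L, li = li,
               n_days_used = sum(!is.na(g$distance_cm)))
  })
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  out[order(out$animal_id, out$phase), , drop = FALSE]
}

#' Group mean and standard error of the mean
#'
#' `SEM = sd / sqrt(n)` with the sample (n-1 denominator) standard
#' deviation; a single-observation group has an undefined SEM (`NA`,
#' flagged), and an empty group is an error.
#'
#' @param values numeric vector of per-animal values.
#' @param group grouping factor or character vector, same length.
#' @return Data frame with `group`, `n`, `mean`, `sem`.
#' @export
group_mean_sem <- function(values, group) {
  if (!length(values)) stop("no values supplied")
  if (length(values) != length(group))
    stop("values and group must have equal length")
  group <- as.factor(group)
  n <- tabulate(group, nbins = nlevels(group))
  if (any(n == 0))
    stop(sprintf("empty group: %s",
                 paste(levels(group)[n == 0], collapse = ", ")))
  mu <- as.numeric(tapply(values, group, mean))
  sdv <- as.numeric(tapply(values, group, stats::sd))
  data.frame(group = levels(group), n = n, mean = mu,
             sem = ifelse(n > 1, sdv / sqrt(n), NA_real_))
}

.long_metrics <- c("activity", "distance_cm", "mean_speed_cms",
                   "n_right", "n_left", "li")

#' Export summaries as a long-format cohort table
#'
#' Tidies per-period summaries into one row per animal x day x phase x
#' metric, with the experimental group attached -- the input format for
#' longitudinal models (GEE/GLM with time and group as fixed effects) in
#' external statistics tooling. Keys must be unique and every animal must
#' be mapped to a group.
#'
#' @param summaries output of [summarize_periods()].
#' @param groups data frame with columns `animal_id`, `group` covering all
#'   animals in `summaries`.
#' @param path optional CSV path to write (stable column order,
#'   round-trip-safe).
#' @param metrics metric columns to export.
#' @return The long data frame (invisibly when `path` is given).
#' @export
export_long_table <- function(summaries, groups, path = NULL,
                              metrics = .long_metrics) {
  missing_cols <- setdiff(metrics, names(summaries))
  if (length(missing_cols))
    stop("summaries lack metric columns: ", paste(missing_cols, collapse = ", "))
  gm <- stats::setNames(as.character(groups$group), groups$animal_id)
  unmapped <- setdiff(unique(summaries$animal_id), names(gm))
  if (length(unmapped))
    stop("animals missing from group map: ", paste(unmapped, collapse = ", "))
  long <- do.call(rbind, lapply(metrics, function(m)
    data.frame(animal_id = summaries$animal_id,
               group = gm[as.character(summaries$animal_id)],
               day = summaries$day, phase = as.character(summaries$phase),
               metric = m, value = as.numeric(summaries[[m]]))))
  rownames(long) <- NULL
  key <- paste(long$animal_id, long$day, long$phase, long$metric, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate animal x day x phase x metric keys in summaries")
  long <- long[order(long$animal_id, long$day, long$phase, long$metric), ]
  rownames(long) <- NULL
  if (!is.null(path)) {
    utils::write.csv(long, path, row.names = FALSE)
    return(invisible(long))
  }
  long
}

#' Read a long-format cohort table written by [export_long_table()]
#'
#' @param path CSV path.
#' @return The validated long data frame.
#' @export
read_long_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "day", "phase", "metric", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  key <- paste(df$animal_id, df$day, df$phase, df$metric, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("duplicate key at data row %d (%s, day %s, %s, %s)",
                 i, df$animal_id[i], df$day[i], df$phase[i], df$metric[i]))
  }
  df
}
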