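test_that("day/night split uses half-open boundaries at the light switches", {
  base <- as.POSIXct("2026-03-02 00:00:00", tz = "UTC")
  at <- function(h, m = 0) base + h * 3600 + m * 60
  ph <- split_day_night(c(at(8), at(6, 59), at(19), at(7), at(18, 59), at(0)))
  expect_equal(as.character(ph), c("day", "night", "night", "day", "day", "night"))
  expect_error(split_day_night(at(8), lights_on = "20:00", lights_off = "19:00"),
               "precede")
  # numeric seconds-of-day accepted too
  expect_equal(as.character(split_day_night(c(7 * 3600, 19 * 3600 - 1))),
               c("day", "day"))
})

test_that("every sample lands in exactly one phase", {
  tr <- simulate_path(duration = 3 * 3600, dt = 5, seed = 101)
  ph <- split_day_night(attr(tr, "start") + tr$t)
  expect_false(anyNA(ph))
  expect_equal(sum(ph == "day") + sum(ph == "night"), nrow(tr))
})

test_that("period summaries hold the period metrics and degrade to NA", {
  start <- as.POSIXct("2026-01-01 07:00:00", tz = "UTC")
  still <- trajectory((0:99) * 0.25, rep(5, 100), rep(5, 100), start = start,
                      animal_id = "m1")
  sm <- summarize_periods(still)
  day_row <- sm[sm$phase == "day", ]
  expect_equal(day_row$distance_cm, 0)
  expect_true(is.na(day_row$li))          # no classified turns: undefined
  night_row <- sm[sm$phase == "night", ]
  expect_true(is.na(night_row$distance_cm))  # no night data: missing, not 0

  tr <- simulate_path(duration = 2 * 3600, seed = 103, animal_id = "m2")
  sm <- summarize_periods(tr)
  ov <- sm[sm$phase == "overall", ]
  expect_equal(ov$distance_cm, total_distance(tr), tolerance = 1e-6)
})

test_that("day + night additivity of distance, activity and turn counts", {
  # start mid-afternoon so the recording spans both phases and a midnight
  start <- as.POSIXct("2026-01-01 17:00:00", tz = "UTC")
  tr <- simulate_path(duration = 16 * 3600, dt = 2, seed = 107, start = start,
                      animal_id = "m3")
  g <- electrode_grid()
  rec <- simulate_recording(tr, g, seed = 108)
  ev <- detect_activity(rec)
  sm <- summarize_periods(tr, events = ev)
  for (d in unique(sm$day)) {
    s <- sm[sm$day == d, ]
    pick <- function(ph, col) {
      v <- s[s$phase == ph, col]
      if (length(v) == 0 || is.na(v)) 0 else v
    }
    for (col in c("distance_cm", "activity", "n_right", "n_left")) {
      expect_equal(pick("day", col) + pick("night", col),
                   pick("overall", col), tolerance = 1e-6)
    }
  }
})

test_that("day-range pooling is an inclusive filtered mean", {
  sm <- data.frame(animal_id = "a", day = c(1, 2, 3, 5),
                   phase = "overall",
                   activity = c(10, 20, 30, 100),
                   distance_cm = c(2, 4, 6, 50),
                   mean_speed_cms = c(1, 2, 3, 10),
                   n_right = c(5, 5, 5, 1), n_left = c(5, 0, 5, 0),
                   li = c(0.5, 1, 0.5, 1))
  p11 <- pool_day_range(sm, c(1, 1))
  expect_equal(p11$distance_cm, 2)
  p13 <- pool_day_range(sm, c(1, 3))
  expect_equal(p13$distance_cm, 4)
  expect_equal(p13$li, 15 / 25)  # ratio of summed counts, not mean of ratios
  expect_equal(pool_day_range(sm, c(1, 3), li_mode = "mean_of_daily")$li, 2 / 3)
  expect_equal(p13$n_days_used, 3)
  expect_error(pool_day_range(sm, c(7, 9)), "available days: 1, 2, 3, 5")
  expect_error(pool_day_range(sm, c(3, 1)), "a <= b")

  # permutation invariance in day order, and oracle filtered mean
  set.seed(109)
  days <- sample(1:20, 12)
  vals <- rnorm(12)
  smr <- data.frame(animal_id = "b", day = days, phase = "overall",
                    activity = vals, distance_cm = vals,
                    mean_speed_cms = vals, n_right = 1, n_left = 1, li = 0.5)
  perm <- smr[sample(nrow(smr)), ]
  rng <- c(5, 15)
  keep <- days >= 5 & days <= 15
  expect_equal(pool_day_range(smr, rng)$distance_cm, mean(vals[keep]))
  expect_equal(pool_day_range(perm, rng)$distance_cm,
               pool_day_range(smr, rng)$distance_cm)
})

test_that("group mean and SEM follow the n-1 sample definition", {
  g <- group_mean_sem(c(1, 2, 3), rep("a", 3))
  expect_equal(g$mean, 2)
  expect_equal(g$sem, 1 / sqrt(3), tolerance = 1e-9)

  same <- group_mean_sem(rep(4.2, 5), rep("a", 5))
  expect_equal(same$sem, 0)

  single <- group_mean_sem(c(1, 2, 3), c("a", "a", "b"))
  expect_true(is.na(single$sem[single$group == "b"]))
  expect_error(group_mean_sem(numeric(0), character(0)), "no values")
  expect_error(group_mean_sem(1:2, factor(c("a", "a"), levels = c("a", "b"))),
               "empty group: b")
})

test_that("long-format export is tidy, keyed, and round-trips through CSV", {
  sm <- expand.grid(animal_id = c("a1", "a2"), day = 1:2,
                    phase = c("day", "night", "overall"),
                    stringsAsFactors = FALSE)
  set.seed(113)
  for (m in c("activity", "distance_cm", "mean_speed_cms", "n_right",
              "n_left", "li"))
    sm[[m]] <- rnorm(nrow(sm))
  groups <- data.frame(animal_id = c("a1", "a2"),
                       group = c("control", "treatment"))
  long <- export_long_table(sm, groups)
  expect_equal(nrow(long), 2 * 2 * 3 * 6)  # animals x days x phases x metrics

  path <- tempfile(fileext = ".csv")
  export_long_table(sm, groups, path = path)
  back <- read_long_table(path)
  expect_equal(back, long, tolerance = 1e-12)

  expect_error(export_long_table(sm, groups[1, , drop = FALSE]),
               "missing from group map: a2")
  dup <- rbind(sm, sm[1, ])
  expect_error(export_long_table(dup, groups), "duplicate")
  utils::write.csv(rbind(long, long[1, ]), path, row.names = FALSE)
  expect_error(read_long_table(path), "duplicate key")
})
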