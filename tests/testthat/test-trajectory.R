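test_that("trajectory constructor validates its invariants", {
  expect_s3_class(trajectory(0, 1, 2), "trajectory")
  expect_error(trajectory(c(0, 1, 1), 1:3, 1:3), "strictly increasing")
  expect_error(trajectory(c(0, 2, 1), 1:3, 1:3), "index 3")
  expect_error(trajectory(c(0, NA), 1:2, 1:2), "finite")
  expect_error(trajectory(0:1, c(1, Inf), 1:2), "finite or NA")
  expect_silent(tr <- trajectory(0:2, c(1, NA, 3), c(1, NA, 3)))
})

test_that("displacement matches Euclidean geometry", {
  tr <- trajectory(c(0, 0.25), c(0, 3), c(0, 4))
  expect_equal(calc_displacement(tr), c(NA, 5))

  still <- trajectory(0:9, rep(2, 10), rep(7, 10))
  expect_equal(calc_displacement(still), c(NA, rep(0, 9)))

  expect_identical(calc_displacement(trajectory(0, 1, 1)), numeric(0))

  tr <- random_traj(50, seed = 11)
  expect_equal(calc_displacement(tr), oracle_displacement(tr$x, tr$y),
               tolerance = 1e-12)
})

test_that("speed and acceleration are first and second time derivatives", {
  # straight line, 2 cm per 0.25 s frame
  n <- 20
  tr <- trajectory((0:(n - 1)) * 0.25, (0:(n - 1)) * 2, rep(0, n))
  k <- calc_derivatives(tr)
  expect_equal(k$speed[-1], rep(8, n - 1))
  expect_equal(k$accel[-(1:2)], rep(0, n - 2))

  tr <- random_traj(100, seed = 3)
  k <- calc_derivatives(tr)
  expect_equal(k$speed, oracle_speed(tr$x, tr$y, tr$t), tolerance = 1e-9)
  expect_equal(k$accel, oracle_accel(tr$x, tr$y, tr$t), tolerance = 1e-9)

  # duplicate timestamps are named: bypass the constructor check
  bad <- trajectory(c(0, 1, 2), 1:3, 1:3)
  bad$t[3] <- bad$t[2]
  expect_error(calc_derivatives(bad), "index 3")
})

test_that("speed gate is inclusive and counts match a linear scan", {
  n <- 12
  tr <- trajectory((0:(n - 1)), (0:(n - 1)) * 1, rep(0, n))  # all 1 cm/s
  k <- calc_derivatives(tr)
  expect_equal(filter_min_speed(k, 2)$n_retained, 0)
  expect_equal(filter_min_speed(k, 1)$n_retained, n - 1)  # threshold retained
  expect_equal(filter_min_speed(k, 0)$n_retained, n - 1)

  tr <- random_traj(200, seed = 5)
  k <- calc_derivatives(tr)
  for (v in c(0.5, 2, 4)) {
    manual <- sum(k$speed >= v, na.rm = TRUE)
    expect_equal(filter_min_speed(k, v)$n_retained, manual)
  }
  expect_error(filter_min_speed(k, -1), "non-negative")
})

test_that("total distance honours the minimum-displacement filter", {
  sq <- trajectory(0:4, c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0))
  expect_equal(total_distance(sq), 40)

  set.seed(8)
  jit <- trajectory(0:99, cumsum(runif(100, -0.05, 0.05)),
                    cumsum(runif(100, -0.05, 0.05)))
  expect_equal(total_distance(jit, min_displacement = 0.2), 0)

  tr <- random_traj(80, seed = 9)
  d <- oracle_displacement(tr$x, tr$y)
  for (m in c(0, 0.5, 1.5)) {
    expect_equal(total_distance(tr, m), sum(d[!is.na(d) & d >= m]),
                 tolerance = 1e-12)
  }
})

test_that("regular resampling interpolates short gaps and leaves long ones", {
  tr <- trajectory((0:19) * 0.25, sin(0:19), cos(0:19))
  expect_equal(resample_regular(tr, 0.25)$x, tr$x)
  expect_equal(resample_regular(tr, 0.25)$t, tr$t)

  # one dropped frame on a straight line: midpoint recovered
  keep <- setdiff(1:11, 6)
  tr <- trajectory(((1:11) - 1)[keep] * 0.25, (0:10)[keep] * 2, rep(0, 10))
  rs <- resample_regular(tr, 0.25, max_gap = 0.6)
  expect_equal(rs$x[6], 10)

  # gaps beyond max_gap stay missing; count them with an independent scan
  set.seed(21)
  t_full <- (0:200) * 0.25
  drop <- sort(sample(2:200, 60))
  keep <- setdiff(seq_along(t_full), drop)
  tr <- trajectory(t_full[keep], cumsum(rnorm(length(keep))),
                   cumsum(rnorm(length(keep))))
  max_gap <- 0.5
  rs <- resample_regular(tr, 0.25, max_gap = max_gap)
  expected_missing <- 0L
  for (g in seq_along(rs$t)) {
    tg <- rs$t[g]
    if (any(abs(tr$t - tg) < 1e-9)) next
    i <- max(which(tr$t < tg))
    if (tr$t[i + 1] - tr$t[i] > max_gap) expected_missing <- expected_missing + 1L
  }
  expect_equal(sum(is.na(rs$x)), expected_missing)
  expect_error(resample_regular(trajectory(0, 1, 1)[0, ], 0.25))
})

test_that("kinematics are invariant to translation and rotation", {
  tr <- random_traj(100, seed = 13)
  k0 <- calc_derivatives(tr)

  shifted <- trajectory(tr$t, tr$x + 123.4, tr$y - 56.7)
  k1 <- calc_derivatives(shifted)
  expect_equal(k1$displacement, k0$displacement, tolerance = 1e-9)
  expect_equal(k1$speed, k0$speed, tolerance = 1e-9)
  expect_equal(k1$accel, k0$accel, tolerance = 1e-9)

  rot <- rotate_traj(tr, 37, cx = 5, cy = -2)
  k2 <- calc_derivatives(rot)
  expect_equal(k2$displacement, k0$displacement, tolerance = 1e-9)
  expect_equal(k2$speed, k0$speed, tolerance = 1e-9)
})

test_that("path length dominates net displacement", {
  for (s in 1:5) {
    tr <- random_traj(60, seed = 100 + s)
    net <- sqrt((tr$x[60] - tr$x[1])^2 + (tr$y[60] - tr$y[1])^2)
    expect_gte(total_distance(tr), net)
  }
})
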