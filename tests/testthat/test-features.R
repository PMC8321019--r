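# reference analytic curve for feature tests: the phantom ground truth
# sampled densely, which has exact plateaus, touch points and peaks
gt_curve <- local({
  tr <- make_trajectory(tiny_spec())
  t <- seq(0, 2, by = 0.002)
  list(curve = velocity_curve(t, tr$fun$v_normal(t)), truth = tr)
})

test_that("crossing primitive: interpolation, analytic roots, exact zeros", {
  expect_equal(find_zero_crossings(c(1.0, 1.1), c(-2, 2), floor = 1e-9),
               1.05)
  t <- seq(0, 1, by = 0.01)
  cr <- find_zero_crossings(t, sin(2 * pi * t), floor = 1e-9)
  expect_equal(length(cr), 3L)
  expect_lt(max(abs(cr - c(0, 0.5, 1))), 1e-3)
  # an exact-zero sample between a - and + neighbour keeps its own time
  expect_equal(find_zero_crossings(c(0, 1, 2), c(-2, 0, 4), floor = 0.5), 1)
  # a sub-floor dip that does not change sign is not a crossing
  expect_equal(length(find_zero_crossings(c(0, 1, 2), c(2, 0.1, 3),
                                          floor = 0.5)), 0L)
})

test_that("stop points recover the analytic t0..t5 on the phantom curve", {
  st <- zero_crossings(gt_curve$curve, cbind(0, 2))
  expect_true(st$complete[1])
  truth <- gt_curve$truth$stop_points[1, ]
  # t1..t4 are plateau midpoints / touch points: recovered exactly
  expect_lt(max(abs(unlist(st[1, 3:6]) - truth[2:5])), 0.002)
  # t0/t5 sit where |v| passes the noise floor, a floor-dependent bias
  # of order floor / acceleration (~15 ms here)
  expect_lt(abs(st$t0[1] - truth["t0"]), 0.02)
  expect_lt(abs(st$t5[1] - truth["t5"]), 0.02)
  # every reported point has |interpolated v| at or below the floor
  v_at <- approx(gt_curve$curve$times, gt_curve$curve$values,
                 xout = unlist(st[1, 2:7]))$y
  expect_true(all(abs(v_at) <= 0.5 + 1e-9))
  # stop points map to displacement extrema: s is extremal near t2/t4
  s <- gt_curve$truth$fun$s
  expect_lt(abs(s(st$t2[1]) - min(s(seq(0, 2, 0.001)))), 0.05)
  expect_lt(abs(s(st$t4[1]) - min(s(seq(0, 2, 0.001)))), 0.05)
})

test_that("truncated windows yield five crossings mapped to t0..t4", {
  # cut the curve before the return to rest, like a 1.56 s cine window
  keep <- gt_curve$curve$times < 1.45
  cut <- velocity_curve(gt_curve$curve$times[keep],
                        gt_curve$curve$values[keep])
  st <- zero_crossings(cut, cbind(0, 1.45))
  expect_false(st$complete[1])
  expect_equal(st$n_crossings[1], 5L)
  expect_true(is.na(st$t5[1]))
  expect_lt(abs(st$t4[1] - gt_curve$truth$stop_points[1, "t4"]), 0.01)
  # far too few crossings: repetition flagged entirely
  flat <- velocity_curve(seq(0, 2, 0.01), rep(0, 201))
  stf <- zero_crossings(flat, cbind(0, 2))
  expect_false(stf$complete[1])
  expect_true(all(is.na(stf[1, 2:7])))
})

test_that("peak extraction: analytic extrema, sign pattern, zero curve", {
  st <- zero_crossings(gt_curve$curve, cbind(0, 2))
  pk <- peak_velocities(gt_curve$curve, st)
  vpk <- 15 * cos(5 * pi / 180)
  expect_equal(pk$left_min, -vpk, tolerance = 1e-3)
  expect_equal(pk$max, vpk, tolerance = 1e-3)
  expect_equal(pk$right_min, -vpk, tolerance = 1e-3)
  expect_true(pk$left_min < 0 && pk$max > 0 && pk$right_min < 0)
  z <- velocity_curve(seq(0, 2, 0.01), rep(0, 201))
  stz <- data.frame(rep = 1, t0 = 0.1, t1 = 0.3, t2 = 0.7, t3 = 1.0,
                    t4 = 1.4, t5 = 1.6, n_crossings = 6, complete = TRUE)
  expect_equal(peak_velocities(z, stz)$max, 0)
})

test_that("phase means: constants, time weighting, quadrature oracle", {
  t <- seq(0, 1, by = 0.001)
  stc <- data.frame(rep = 1, t0 = 0, t1 = 0.0, t2 = 0.5, t3 = 0.8,
                    t4 = 1.0, t5 = 1.0, n_crossings = 6, complete = TRUE)
  const <- velocity_curve(t, rep(-3, length(t)))
  expect_equal(phase_means(const, stc)$opening1, 3)
  half <- velocity_curve(t, ifelse(t < 0.25, 0, 10))
  expect_equal(phase_means(half, stc)$opening1, 5, tolerance = 0.01)
  # quadrature oracle on the analytic phantom curve
  st <- zero_crossings(gt_curve$curve, cbind(0, 2))
  pm <- phase_means(gt_curve$curve, st)
  f <- function(x) abs(gt_curve$truth$fun$v_normal(x))
  for (iv in list(c("t1", "t2", "opening1"), c("t2", "t3", "closure"),
                  c("t3", "t4", "opening2"))) {
    a <- st[[iv[1]]][1]; b <- st[[iv[2]]][1]
    ref <- integrate(f, a, b, subdivisions = 500)$value / (b - a)
    expect_lt(abs(pm[[iv[3]]][1] - ref) / ref, 0.02)
  }
})

test_that("timing statistics: zero case, hand arithmetic, exclusions", {
  t_marks <- data.frame(rep = 1:2, t0 = 0, t1 = c(0.40, 2.40),
                        t2 = c(0.70, 2.70), t3 = c(1.00, 3.00),
                        t4 = c(1.30, 3.30), t5 = 0,
                        n_crossings = 6, complete = TRUE)
  q_same <- data.frame(rep = 1:2, q1 = t_marks$t1, q2 = t_marks$t2,
                       q3 = t_marks$t3, q4 = t_marks$t4, flagged = FALSE)
  s0 <- timing_stats(t_marks, q_same)
  expect_true(all(s0$mean_ms == 0) && all(s0$sd_ms == 0))
  # differences {60, 70} ms -> mean 65, sd ~7.07
  q2 <- q_same
  q2[, c("q1", "q2", "q3", "q4")] <-
    q_same[, c("q1", "q2", "q3", "q4")] + c(0.060, 0.070)
  s1 <- timing_stats(t_marks, q2)
  expect_equal(s1$mean_ms, rep(65, 4))
  expect_equal(s1$sd_ms, rep(sd(c(60, 70)), 4), tolerance = 1e-9)
  expect_equal(round(s1$sd_ms[1], 2), 7.07)
  # flagged repetitions are excluded pairwise
  q3 <- q2; q3$flagged[2] <- TRUE
  s2 <- timing_stats(t_marks, q3)
  expect_equal(s2$n, rep(1L, 4))
  expect_equal(s2$mean_ms, rep(60, 4))
  expect_error(timing_stats(t_marks, q_same[0, ]), "matched")
})

test_that("aggregation reports deviations only with >= 2 repetitions", {
  one <- data.frame(rep = 1, left_min = -7.38, max = 19.74,
                    right_min = -8.43)
  a1 <- aggregate_peaks(one)
  expect_true(all(is.na(a1$sd)))
  expect_equal(a1$mean, c(-7.38, 19.74, -8.43))
  expect_equal(unname(format_mean_sd(a1)),
               c("-7.38", "19.74", "-8.43"))
  two <- data.frame(rep = 1:2, left_min = c(-15, -17), max = c(20, 22),
                    right_min = c(-16, -18))
  a2 <- aggregate_peaks(two)
  expect_equal(a2$mean[1], -16)
  expect_equal(a2$sd[1], sd(c(-15, -17)))
  expect_equal(round(a2$sd[1], 2), 1.41)
  expect_match(format_mean_sd(a2)[["left_min"]], "-16.00 \\(1.41\\)")
})
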