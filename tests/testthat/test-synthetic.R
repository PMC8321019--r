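test_that("trajectory validation rejects bad specs and handles degeneracy", {
  expect_error(phantom_spec(cycle_period = 0), "cycle_period")
  expect_error(phantom_spec(peak_speed = -1), "peak_speed")
  expect_error(make_trajectory(phantom_spec(peak_speed = 2, rest_gap = 10)),
               "rest_gap")
  # zero peak speed: constant trajectory, all velocities zero
  tr0 <- make_trajectory(phantom_spec(peak_speed = 0))
  expect_true(all(tr0$v_normal == 0))
  expect_equal(max(tr0$pos[, 3]) - min(tr0$pos[, 3]), 0)
})

test_that("trajectory has the /tata/ structure: plateaus, closures, (-,+,-)", {
  tr <- make_trajectory(tiny_spec())
  st <- tr$stop_points[1, ]
  # contact (s = 0) at both closure stop points, bottom at t2/t4
  expect_lt(abs(tr$fun$s(st["t1"])), 1e-9)
  expect_lt(abs(tr$fun$s(st["t3"])), 1e-9)
  expect_equal(unname(tr$fun$s(st["t2"])), min(tr$fun$s(tr$times)),
               tolerance = 1e-9)
  # zero velocity at every stop point
  expect_true(all(abs(tr$fun$v_normal(st)) < 1e-9))
  # velocity sign pattern between consecutive stop points
  mid <- function(a, b) tr$fun$v_normal((st[a] + st[b]) / 2)
  expect_lt(mid("t1", "t2"), 0)
  expect_gt(mid("t2", "t3"), 0)
  expect_lt(mid("t3", "t4"), 0)
  # genuine plateau (not just a point) around each consonant closure
  expect_true(all(abs(tr$fun$v_normal(st["t1"] + c(-0.03, 0.03))) < 1e-9))
  expect_true(all(abs(tr$fun$v_normal(st["t3"] + c(-0.03, 0.03))) < 1e-9))
})

test_that("analytic velocity matches a finite-difference oracle at 1 kHz", {
  tr <- make_trajectory(phantom_spec())
  t <- seq(0.001, 3.999, by = 0.001)
  h <- 5e-4
  fd <- (tr$fun$s(t + h) - tr$fun$s(t - h)) / (2 * h) / 10  # mm/s -> cm/s
  analytic <- tr$fun$v_normal(t) / cos(5 * pi / 180)
  expect_lt(max(abs(fd - analytic)), 0.01)
})

test_that("ground-truth velocity is consistent across modalities", {
  tr <- make_trajectory(tiny_spec())
  t <- seq(0, 2, by = 0.01)
  # the velocity the PC encoder uses IS the derivative of the trajectory's
  # slice-normal component used for RT rendering
  d <- signed_distance_to_slice_edge(
    cbind(tr$geometry$contact[1] + tr$fun$s(t) * tr$geometry$motion_dir[1],
          tr$geometry$contact[2] + tr$fun$s(t) * tr$geometry$motion_dir[2],
          tr$geometry$contact[3] + tr$fun$s(t) * tr$geometry$motion_dir[3]),
    tr$geometry$pc)
  h <- 1e-6
  fd <- (tr$fun$s(t + h) - tr$fun$s(t - h)) / (2 * h) *
    cos(5 * pi / 180) / 10
  expect_lt(max(abs(fd - tr$fun$v_normal(t))), 1e-6)
  expect_equal(d, unname(tr$fun$s(t) * cos(5 * pi / 180)),
               tolerance = 1e-9)
})

test_that("real-time rendering: apex, plateau frames, determinism, FOV", {
  spec <- tiny_spec()
  tr <- make_trajectory(spec)
  rt <- render_rt_series(tr, spec)
  # apex pixel (argmax) at the ground-truth tip within 1 pixel, per frame
  for (k in c(1, 25, 60)) {
    am <- which(rt$frames[, , k] == max(rt$frames[, , k]), arr.ind = TRUE)
    expect_lt(abs(am[1, 1] - 1 - tr$fun$tip_row(rt$times[k])), 1)
    expect_lt(abs(am[1, 2] - 1 - tr$fun$tip_col(rt$times[k])), 1)
  }
  # zero motion during the closure plateau: consecutive frames identical
  ks <- which(rt$times > 0.40 & rt$times < 0.52)
  expect_identical(rt$frames[, , ks[1]], rt$frames[, , ks[2]])
  # seeded determinism
  spec_n <- tiny_spec(noise_sd = 0.02)
  expect_identical(render_rt_series(make_trajectory(spec_n), spec_n)$frames,
                   render_rt_series(make_trajectory(spec_n), spec_n)$frames)
  # trajectory leaving the FOV is rejected
  big <- tiny_spec(peak_speed = 60)
  expect_error(render_rt_series(make_trajectory(big), big), "field of view")
})

test_that("phase-contrast rendering: round trip, aliasing guard, air mask", {
  spec <- tiny_spec()
  tr <- make_trajectory(spec)
  pc <- render_pc_series(tr, spec)
  v <- roi_velocity(pc, roi_spec(13, 13, 5))
  gt <- tr$fun$v_normal(v$times)
  expect_lt(max(abs(v$values - gt)), spec$venc / 4095 + 1e-9)
  # aliasing: velocity beyond venc rejected unless wrapped
  expect_error(render_pc_series(tr, spec, venc = 10), "VENC")
  expect_s3_class(render_pc_series(tr, spec, venc = 10, aliased = TRUE),
                  "pc_series")
  # air pixels stay below the 5% mask of every frame
  for (k in c(1, 10)) {
    mag <- pc$magnitude[, , k]
    expect_lt(mag[1, 1], 0.05 * max(mag))
  }
  expect_identical(render_pc_series(make_trajectory(spec), spec)$phase_codes,
                   pc$phase_codes)
})

test_that("audio rendering: levels, durations, silence, overlap, determinism", {
  spec <- tiny_spec()
  tr <- make_trajectory(spec)
  au <- render_audio(tr, spec)
  env <- envelope(au)
  segs <- detect_segments(env, estimate_background(env))
  lab <- classify_segments(segs)
  # one beep + two vowels per cycle, vowels louder than the beep
  expect_equal(sum(lab == "beep"), spec$n_cycles)
  expect_equal(sum(lab == "speech"), 2 * spec$n_cycles)
  expect_gt(min(segs$mean_level[lab == "speech"]),
            max(segs$mean_level[lab == "beep"]))
  # every vowel interval exceeds the 0.1 s segmentation rule
  expect_true(all(tr$vowel_intervals[, 2] - tr$vowel_intervals[, 1] > 0.1))
  # silence-only phantom: no segments downstream
  mute <- tiny_spec(beep_level = 0, vowel_level = 0, scanner_level = 0)
  au0 <- render_audio(make_trajectory(mute), mute)
  env0 <- envelope(au0)
  expect_equal(nrow(detect_segments(env0, 1e-6)), 0L)
  # overlapping configured segments are rejected: with a 0.7 s lag the
  # second vowel of a cycle collides with the next cycle's beep
  bad <- tiny_spec(acoustic_lag = 0.7, n_cycles = 2)
  expect_error(render_audio(make_trajectory(bad), bad), "overlap")
  expect_identical(render_audio(make_trajectory(spec), spec)$samples,
                   au$samples)
})
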