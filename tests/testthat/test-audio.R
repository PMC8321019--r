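test_that("envelope: constants, impulse widening, brute-force oracle", {
  rate <- 1000                       # 10 ms window = 11 samples
  tone <- rep(c(0.4, -0.4), 200)
  env <- envelope(tone, rate)
  expect_true(all(abs(env$level - 0.4) < 1e-12))
  # a single impulse is widened to one window by the max stage; the
  # median stage keeps a window-long run but nothing beyond it
  x <- numeric(400); x[200] <- 1
  mx <- articuvel:::.running_max(abs(x), 11)
  expect_equal(sum(mx > 0), 11)
  lev <- envelope(x, rate)$level
  expect_lte(sum(lev > 0), 11)
  expect_true(all(which(lev > 0) >= 195 & which(lev > 0) <= 205))
  expect_error(envelope(numeric(0), rate), "empty")

  set.seed(19)
  y <- rnorm(800)
  got <- envelope(y, rate)$level
  w <- 11; r <- 5; n <- length(y)
  naive_max <- sapply(seq_len(n), function(i)
    max(abs(y[max(1, i - r):min(n, i + r)])))
  naive_med <- sapply(seq_len(n), function(i)
    median(naive_max[max(1, i - r):min(n, i + r)]))
  expect_identical(articuvel:::.running_max(abs(y), w), naive_max)
  i <- (r + 1):(n - r)               # interior (end rule differs at edges)
  expect_equal(got[i], naive_med[i])
})

test_that("segment detection: duration rule with strict inequality", {
  rate <- 1000
  mk <- function(len) {
    x <- numeric(3000)
    x[1000 + seq_len(len)] <- 0.5
    structure(list(level = x, times = (seq_along(x) - 1) / rate,
                   rate = rate), class = "audio_envelope")
  }
  expect_equal(nrow(detect_segments(mk(200), 0.1)), 1L)   # 0.2 s
  expect_equal(nrow(detect_segments(mk(50), 0.1)), 0L)    # 0.05 s
  expect_equal(nrow(detect_segments(mk(100), 0.1)), 0L)   # exactly 0.1 s
  expect_equal(nrow(detect_segments(mk(101), 0.1)), 1L)
  seg <- detect_segments(mk(200), 0.1)
  expect_equal(seg$end - seg$start, 0.2)
  expect_error(detect_segments(mk(200), -1), "non-negative")
})

test_that("raising the background level never creates segments", {
  set.seed(23)
  x <- abs(rnorm(4000)) * rep(c(0.1, 1, 0.1, 0.7), each = 1000)
  env <- envelope(x, 1000)
  bgs <- seq(0, 2, by = 0.1)
  prev <- NULL
  for (bg in bgs) {
    segs <- detect_segments(env, bg)
    if (!is.null(prev)) {
      # every segment at the higher threshold lies inside one detected
      # at the lower threshold, and total duration is non-increasing
      if (nrow(segs) > 0) {
        inside <- vapply(seq_len(nrow(segs)), function(i)
          any(prev$start <= segs$start[i] + 1e-9 &
                prev$end >= segs$end[i] - 1e-9), logical(1))
        expect_true(all(inside))
      }
      dur <- function(s) if (nrow(s) == 0) 0 else sum(s$end - s$start)
      expect_lte(dur(segs), dur(prev) + 1e-9)
    }
    prev <- segs
  }
})

test_that("segment classification by mean level", {
  segs <- data.frame(start = c(0, 1, 2), end = c(0.2, 1.3, 2.3),
                     mean_level = c(0.21, 0.39, 0.38))
  expect_equal(classify_segments(segs), c("beep", "speech", "speech"))
  eq <- data.frame(start = 0:2, end = 0:2 + 0.2, mean_level = rep(0.3, 3))
  expect_warning(lab <- classify_segments(eq), "equal")
  expect_true(all(lab == "speech"))
  expect_identical(classify_segments(segs[0, ]), character())
  expect_equal(classify_segments(segs, threshold = 0.4),
               rep("beep", 3))
})

test_that("vowel marks: phantom oracle, flagged repetitions, manual override", {
  spec <- tiny_spec()
  tr <- make_trajectory(spec)
  au <- render_audio(tr, spec)
  env <- envelope(au)
  segs <- detect_segments(env, estimate_background(env))
  lab <- classify_segments(segs)
  t0 <- spec$lead_in
  marks <- vowel_marks(segs, lab, cbind(t0, t0 + 2))
  expect_false(marks$flagged[1])
  truth_q <- t0 + tr$stop_points[1, c("t1", "t2", "t3", "t4")] + 0.05
  expect_lt(max(abs(unlist(marks[1, 2:5]) - truth_q)), 0.010)
  # a repetition without its second vowel is flagged
  drop2 <- segs[-nrow(segs), ]
  m2 <- vowel_marks(drop2, lab[-length(lab)], cbind(t0, t0 + 2))
  expect_true(m2$flagged[1])
  expect_true(all(is.na(m2[1, 2:5])))
  # manual CSV-style corrections override verbatim
  man <- data.frame(rep = 1, q1 = 1.0, q2 = 1.2, q3 = 1.5, q4 = 1.7)
  m3 <- vowel_marks(drop2, lab[-length(lab)], cbind(t0, t0 + 2),
                    manual = man)
  expect_equal(unlist(m3[1, 2:5], use.names = FALSE),
               c(1.0, 1.2, 1.5, 1.7))
  expect_false(m3$flagged[1])
})

test_that("audio-to-MRI alignment: subtraction, residual, jitter median", {
  rec <- audio_recording(numeric(100), rate = 16000,
                         sequence_end_time = 50)
  al <- align_audio_to_mri(rec, 42)
  expect_equal(al$start, 8)
  expect_equal(al$offset, 8)
  # constant 12 ms TTL-vs-generator discrepancy
  rec2 <- audio_recording(numeric(100), rate = 16000,
                          ttl_times = 8.012 + 0:4 * 2,
                          generator_times = 0:4 * 2,
                          sequence_end_time = 50)
  al2 <- align_audio_to_mri(rec2, 42)
  expect_equal(al2$residual, 0.012)
  expect_equal(al2$offset, 8.012)
  # jittered timestamps: residual is their median, within the jitter
  jit <- c(-0.003, 0.001, 0.003, -0.001, 0.002)
  rec3 <- audio_recording(numeric(100), rate = 16000,
                          ttl_times = 8 + 0:4 * 2 + jit,
                          generator_times = 0:4 * 2,
                          sequence_end_time = 50)
  al3j <- align_audio_to_mri(rec3, 42)
  expect_equal(al3j$residual, median(jit))
  expect_lt(abs(al3j$residual), 0.003 + 1e-9)
  # detection path on the phantom: noise ending within 5 ms
  spec <- tiny_spec()
  tr <- make_trajectory(spec)
  au <- render_audio(tr, spec)
  au$sequence_end_time <- NA_real_
  al3 <- align_audio_to_mri(au, spec$n_cycles * spec$cycle_period)
  expect_lt(abs(al3$noise_end - (spec$lead_in + 2)), 0.005)
  expect_lt(abs(al3$offset - spec$lead_in), 0.005)
  mute <- audio_recording(numeric(1600), rate = 16000)
  expect_error(align_audio_to_mri(mute, 1), "no scanner-noise")
})

test_that("spectrogram: tone concentration, silence, Parseval", {
  rate <- 16000
  t <- seq_len(8000) / rate
  sp <- audio_spectrogram(sin(2 * pi * 1000 * t), rate)
  peak_bin <- apply(sp$magnitude, 2, which.max)
  expect_true(all(abs(sp$freqs[peak_bin] - 1000) < 50))
  sp0 <- audio_spectrogram(numeric(4000), rate)
  expect_true(all(sp0$magnitude == 0))
  # energy conservation: one-sided magnitudes vs windowed signal energy
  set.seed(31)
  x <- rnorm(8000)
  sp1 <- audio_spectrogram(x, rate)
  n <- sp1$window_samples
  half <- nrow(sp1$magnitude)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  starts <- round(sp1$times * rate - (n - 1) / 2) + 1
  e_sig <- sum(sapply(starts, function(s) sum((x[s:(s + n - 1)] * w)^2)))
  m2 <- sp1$magnitude^2
  e_spec <- (2 * colSums(m2) - m2[1, ] - m2[half, ] * (n %% 2 == 0)) / n
  expect_lt(abs(sum(e_spec) - e_sig) / e_sig, 0.01)
})

test_that("WAV writer/reader round trip", {
  spec <- tiny_spec()
  au <- render_audio(make_trajectory(spec), spec)
  f <- tempfile(fileext = ".wav")
  write_wav(au, f)
  back <- read_wav(f)
  expect_equal(back$rate, au$rate)
  expect_lt(max(abs(back$samples - au$samples)), 1 / 32767)
  unlink(f)
})
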