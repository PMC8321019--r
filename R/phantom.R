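#' Specification of the synthetic /tata/ phantom
#'
#' Describes a deformable "tongue" blob repeating a two-closure /tata/
#' gesture against a static palate, imaged simultaneously (in the phantom
#' world) by a real-time mid-sagittal series, a through-plane
#' velocity-encoded cine series in an oblique slice touching the palate,
#' and a microphone. Defaults follow the reference acquisition protocol:
#' 2 s stimulus period, 19.98 ms real-time frame interval (TR 2.22 ms x 9
#' radial spokes), 35.52 ms cine frame interval (TR 5.92 ms x 2 velocity
#' encodings x 3 lines per segment), 44 cine frames per dynamic series,
#' VENC 30 cm/s, 16 kHz audio. Peak speed defaults to 15 cm/s, inside the
#' 8-25 cm/s range observed for tongue-tip /tata/ gestures.
#'
#' @param cycle_period stimulus period in seconds.
#' @param n_cycles number of /tata/ repetitions in the real-time series.
#' @param frame_interval_rt real-time frame interval, seconds.
#' @param frame_interval_pc cine frame interval, seconds.
#' @param n_frames_pc frames per reconstructed cine dynamic series.
#' @param peak_speed peak tongue-tip speed along its motion direction,
#'   cm/s (0 gives a static degenerate phantom).
#' @param rest_gap rest distance of the tip below the palate contact
#'   point, mm.
#' @param image_shape image matrix `(rows, cols)` in pixels.
#' @param fov field of view in mm (square).
#' @param noise_sd Gaussian intensity noise, as a fraction of the maximal
#'   tissue intensity.
#' @param theta_deg angle between the tip motion direction and the cine
#'   slice normal, degrees (slice positioning imperfection).
#' @param acoustic_lag lag of vowel onsets/offsets behind the kinematic
#'   stop points, seconds.
#' @param venc velocity-encoding threshold of the cine series, cm/s.
#' @param audio_rate audio sampling rate, Hz.
#' @param lead_in audio recorded before the imaging sequence starts, s.
#' @param tail audio recorded after the sequence ends, s.
#' @param beep_level,vowel_level,scanner_level peak amplitudes of the
#'   stimulus beep, the vowel bursts and the scanner noise (full scale 1;
#'   speech is deliberately louder than the beep, as in real recordings).
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   phantom outputs.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(cycle_period = 2, n_cycles = 2,
                         frame_interval_rt = 0.01998,
                         frame_interval_pc = 0.03552,
                         n_frames_pc = 44,
                         peak_speed = 15, rest_gap = 10,
                         image_shape = c(64, 64), fov = 96,
                         noise_sd = 0.02, theta_deg = 5,
                         acoustic_lag = 0.05, venc = 30,
                         audio_rate = 16000, lead_in = 0.5, tail = 1,
                         beep_level = 0.15, vowel_level = 0.5,
                         scanner_level = 0.03, seed = 42L) {
  if (cycle_period <= 0) stop("cycle_period must be positive")
  if (peak_speed < 0) stop("peak_speed must be non-negative")
  if (fov <= 0) stop("fov must be positive")
  if (n_cycles < 1) stop("need at least one cycle")
  if (frame_interval_rt <= 0 || frame_interval_pc <= 0)
    stop("frame intervals must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  image_shape <- rep(as.integer(image_shape), length.out = 2L)
  spec <- list(cycle_period = cycle_period, n_cycles = as.integer(n_cycles),
               frame_interval_rt = frame_interval_rt,
               frame_interval_pc = frame_interval_pc,
               n_frames_pc = as.integer(n_frames_pc),
               peak_speed = peak_speed, rest_gap = rest_gap,
               image_shape = image_shape, fov = fov, noise_sd = noise_sd,
               theta_deg = theta_deg, acoustic_lag = acoustic_lag,
               venc = venc, audio_rate = audio_rate, lead_in = lead_in,
               tail = tail, beep_level = beep_level,
               vowel_level = vowel_level, scanner_level = scanner_level,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# Cycle layout, as fractions of the period. One repetition: rest, rise to
# the first closure, closure plateau (/t/), descent (/a/), re-closure,
# second plateau (/t/), second descent (/a/), return to rest. Transitions
# are quintic smoothsteps, so velocity is C1 with exact plateaus.
.phases <- c(rest1 = 0.08, rise = 0.10, clo1 = 0.10, down1 = 0.10,
             up = 0.10, clo2 = 0.10, down2 = 0.10, back = 0.10,
             rest2 = 0.22)

.smoothstep <- function(s) s * s * s * (10 + s * (-15 + 6 * s))
.dsmoothstep <- function(s) 30 * s * s * (1 - s) * (1 - s)

# Displacement amplitude (mm) of the closure<->open transitions for a
# given peak speed: quintic smoothstep peaks at 1.875 * amplitude / dur.
.phantom_amplitude <- function(spec) {
  dur <- .phases[["down1"]] * spec$cycle_period
  spec$peak_speed * 10 * dur / 1.875
}

# Piecewise closed form of the tip displacement s(t) along its motion
# direction, in mm, with s = 0 at palate contact, negative below.
.phantom_sfun <- function(spec) {
  tt <- spec$cycle_period
  edges <- cumsum(c(0, .phases)) * tt
  amp <- .phantom_amplitude(spec)
  gap <- spec$rest_gap
  if (spec$peak_speed == 0)
    return(list(s = function(t) rep(-gap, length(t)),
                ds = function(t) rep(0, length(t))))
  if (amp <= gap)
    stop("peak_speed too small for rest_gap: the tip would not pass ",
         "through its rest level on the way back up")
  # (from, to) level of each phase; plateaus have from == to
  lev <- rbind(rest1 = c(-gap, -gap), rise = c(-gap, 0), clo1 = c(0, 0),
               down1 = c(0, -amp), up = c(-amp, 0), clo2 = c(0, 0),
               down2 = c(0, -amp), back = c(-amp, -gap),
               rest2 = c(-gap, -gap))
  s <- function(t) {
    tc <- t %% tt
    k <- findInterval(tc, edges, rightmost.closed = TRUE)
    k[k > 9L] <- 9L
    frac <- (tc - edges[k]) / (edges[k + 1L] - edges[k])
    as.vector(lev[k, 1L] + (lev[k, 2L] - lev[k, 1L]) * .smoothstep(frac))
  }
  ds <- function(t) {
    tc <- t %% tt
    k <- findInterval(tc, edges, rightmost.closed = TRUE)
    k[k > 9L] <- 9L
    dur <- edges[k + 1L] - edges[k]
    frac <- (tc - edges[k]) / dur
    as.vector((lev[k, 2L] - lev[k, 1L]) * .dsmoothstep(frac) / dur)
  }
  list(s = s, ds = ds)
}

#' Closed-form phantom trajectory and ground truth
#'
#' Builds the analytic /tata/ tip trajectory: per cycle a rest plateau, a
#' rise to palate contact, a zero-velocity closure plateau, a descent, an
#' intermediate re-closure, a second descent and a return to rest. The
#' velocity between consecutive stop points t1..t4 therefore follows the
#' (-, +, -) pattern characteristic of the gesture. All quantities
#' (trajectory, through-plane velocity, stop points, vowel intervals,
#' beep times) come from the same closed form, so the returned normal
#' velocity is the exact analytic derivative of the trajectory's
#' slice-normal component.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_truth` with fields `times` (1 kHz
#'   grid), `pos` (n x 3 mm patient coordinates), `v_normal` (cm/s),
#'   `stop_points` (n_cycles x 6 matrix, t0..t5 in seconds),
#'   `vowel_intervals`, `beep_times`, analytic accessors in `fun`
#'   (`s`, `ds`, `v_normal`, `tip_row`, `tip_col`), and the phantom
#'   `geometry` (real-time and oblique-cine slice geometries, motion
#'   direction, palate contact point, pixel spacing).
#' @export
make_trajectory <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  tt <- spec$cycle_period
  th <- spec$theta_deg * pi / 180
  m <- c(0, sin(th), cos(th))                 # tip motion direction (unit)
  contact <- c(0, 40, 60)                     # palate contact point, mm
  sp <- spec$fov / spec$image_shape
  f <- .phantom_sfun(spec)

  # patient frame: axis 1 left-right, 2 posterior-anterior, 3 feet-to-head
  rt_row_dir <- c(0, 0, -1); rt_col_dir <- c(0, 1, 0)
  tip_row0 <- round(0.19 * spec$image_shape[1])
  tip_col0 <- round(spec$image_shape[2] / 2)
  rt_origin <- contact - tip_row0 * sp[1] * rt_row_dir -
    tip_col0 * sp[2] * rt_col_dir
  geom_rt <- slice_geometry(rt_origin, rt_row_dir, rt_col_dir, thickness = 8)

  # oblique cine slice: horizontal, upper edge through the contact point
  pc_n <- c(0, 0, 1); pc_thick <- 6
  pc_origin <- contact - (pc_thick / 2) * pc_n - 30 * c(1, 0, 0) - 30 * c(0, 1, 0)
  geom_pc <- slice_geometry(pc_origin, c(1, 0, 0), c(0, 1, 0),
                            thickness = pc_thick)

  # in-plane projection of the motion direction, pixels per mm of s
  m_row <- sum(m * rt_row_dir) / sp[1]
  m_col <- sum(m * rt_col_dir) / sp[2]
  cos_th <- cos(th)

  times <- seq(0, spec$n_cycles * tt, by = 0.001)
  svals <- f$s(times)
  pos <- cbind(contact[1] + svals * m[1],
               contact[2] + svals * m[2],
               contact[3] + svals * m[3])
  colnames(pos) <- c("x_mm", "y_mm", "z_mm")
  v_normal <- f$ds(times) * cos_th / 10     # mm/s along normal -> cm/s

  e <- cumsum(c(0, .phases)) * tt
  stop1 <- c(t0 = e[["rest1"]],
             t1 = (e[["rise"]] + e[["clo1"]]) / 2,
             t2 = e[["down1"]],
             t3 = (e[["up"]] + e[["clo2"]]) / 2,
             t4 = e[["down2"]],
             t5 = e[["back"]])
  stops <- t(vapply(seq_len(spec$n_cycles) - 1L,
                    function(k) stop1 + k * tt, numeric(6)))
  colnames(stops) <- names(stop1)

  lag <- spec$acoustic_lag
  vowels <- do.call(rbind, lapply(seq_len(spec$n_cycles), function(i) {
    rbind(c(stops[i, "t1"], stops[i, "t2"]) + lag,
          c(stops[i, "t3"], stops[i, "t4"]) + lag)
  }))
  colnames(vowels) <- c("start", "end")
  beeps <- (seq_len(spec$n_cycles) - 1L) * tt

  structure(list(
    times = times, pos = pos, v_normal = v_normal,
    stop_points = stops, vowel_intervals = vowels, beep_times = beeps,
    fun = list(
      s = f$s, ds = f$ds,
      v_normal = function(t) f$ds(t) * cos_th / 10,
      tip_row = function(t) tip_row0 + f$s(t) * m_row,
      tip_col = function(t) tip_col0 + f$s(t) * m_col),
    geometry = list(rt = geom_rt, pc = geom_pc, motion_dir = m,
                    contact = contact, spacing = sp,
                    tip_row0 = tip_row0, tip_col0 = tip_col0),
    spec = spec), class = "phantom_truth")
}

# evaluate an expression with a fixed RNG state, restoring the caller's
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

# static + moving scene of the mid-sagittal phantom at tip pixel (tr, tc):
# faint background, bright palate band, tongue blob peaking at the tip
.rt_scene <- function(tr, tc, spec, geom_info) {
  ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
  sp <- geom_info$spacing
  r <- matrix(seq_len(ny) - 1, ny, nx)
  cc <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx)
  th <- spec$theta_deg * pi / 180
  # unit in-plane motion direction in pixel steps (rows point down)
  mr <- -cos(th); mc <- sin(th)
  dpar <- ((r - tr) * mr + (cc - tc) * mc) * sp[1]   # mm along motion (up +)
  dperp <- (-(r - tr) * mc + (cc - tc) * mr) * sp[1]
  # sharp air-tissue falloff above the apex, longer body falloff below;
  # a strongly one-sided profile biases SSD flow at the boundary, so the
  # below-tip scale is kept moderate
  sig_par <- ifelse(dpar > 0, 3, 6)
  sig_perp <- 6
  blob <- exp(-0.5 * (dpar / sig_par)^2 - 0.5 * (dperp / sig_perp)^2)
  img <- pmax(blob, 0.05)
  pr <- geom_info$tip_row0 - 3
  pal_rows <- max(1, pr - 2):pr
  pal_cols <- max(1, geom_info$tip_col0 - 11):min(nx, geom_info$tip_col0 + 13)
  img[pal_rows, pal_cols] <- pmax(img[pal_rows, pal_cols], 0.7)
  img
}

#' Render the real-time mid-sagittal magnitude series of the phantom
#'
#' Each frame shows a smooth high-intensity blob whose apex sits at the
#' ground-truth tip position, plus a static bright palate band. Frames are
#' temporal averages over the acquisition window, which produces motion
#' blur proportional to the instantaneous speed (real-time MRI of fast
#' articulators blurs in exactly this way). Optional Gaussian intensity
#' noise is added with the spec seed, so identical (spec, seed) give
#' bit-identical stacks.
#'
#' @param truth a [make_trajectory()] result.
#' @param spec the matching [phantom_spec()].
#' @param blur logical; average `n_blur` sub-frames over the frame window.
#' @param n_blur sub-frames used for the temporal average.
#' @return a [frame_series()] with the mid-sagittal slice geometry.
#' @export
render_rt_series <- function(truth, spec = truth$spec, blur = TRUE,
                             n_blur = 5L) {
  stopifnot(inherits(truth, "phantom_truth"))
  dt <- spec$frame_interval_rt
  nf <- floor(spec$n_cycles * spec$cycle_period / dt)
  times <- (seq_len(nf) - 1) * dt
  gi <- truth$geometry
  ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
  rows <- truth$fun$tip_row(times); cols <- truth$fun$tip_col(times)
  if (any(rows < 1) || any(rows > ny - 2) || any(cols < 1) ||
      any(cols > nx - 2))
    stop("phantom trajectory leaves the field of view")
  offs <- if (blur && n_blur > 1L)
    seq(-0.5, 0.5, length.out = n_blur) * dt else 0
  frames <- array(0, c(ny, nx, nf))
  for (k in seq_len(nf)) {
    acc <- matrix(0, ny, nx)
    for (o in offs)
      acc <- acc + .rt_scene(truth$fun$tip_row(times[k] + o),
                             truth$fun$tip_col(times[k] + o), spec, gi)
    frames[, , k] <- acc / length(offs)
  }
  if (spec$noise_sd > 0)
    frames <- .with_seed(spec$seed, {
      pmax(frames + array(stats::rnorm(length(frames), 0, spec$noise_sd),
                          dim(frames)), 0)
    })
  frame_series(frames, times, gi$spacing, geometry = gi$rt)
}

#' Render the velocity-encoded phase-contrast cine series of the phantom
#'
#' Produces one reconstructed dynamic series (44 frames by default)
#' starting at the cycle trigger. The oblique slice sees a tongue
#' cross-section disc whose magnitude dips as the tip descends (a mild
#' partial-volume stand-in) but always stays above the 5% masking level;
#' tissue pixels carry the 12-bit code of the instantaneous through-plane
#' velocity, air pixels carry near-zero magnitude and uniformly random
#' codes, which exercises the magnitude-mask rule of the decoder.
#'
#' @param truth a [make_trajectory()] result.
#' @param spec the matching [phantom_spec()].
#' @param venc encoding threshold, cm/s.
#' @param aliased allow velocities beyond `venc` and wrap their codes; by
#'   default such a spec is rejected.
#' @return a [pc_series()].
#' @export
render_pc_series <- function(truth, spec = truth$spec, venc = spec$venc,
                             aliased = FALSE) {
  stopifnot(inherits(truth, "phantom_truth"))
  nf <- spec$n_frames_pc
  dt <- spec$frame_interval_pc
  times <- (seq_len(nf) - 1) * dt
  v <- truth$fun$v_normal(times)
  if (!aliased && max(abs(v)) >= venc)
    stop("phantom velocity reaches VENC; raise venc or set aliased = TRUE")
  ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
  sp <- spec$fov / ny
  r <- matrix(seq_len(ny) - 1, ny, nx)
  cc <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx)
  cr <- (ny - 1) / 2; ccol <- (nx - 1) / 2
  dist_mm <- sqrt((r - cr)^2 + (cc - ccol)^2) * sp
  disc <- 1 / (1 + exp((dist_mm - 10) / 0.75))       # soft 10 mm disc
  tissue <- disc > 0.5
  amp <- .phantom_amplitude(spec)
  depth <- if (spec$peak_speed > 0) -truth$fun$s(times) / amp else rep(0, nf)

  mag <- array(0, c(ny, nx, nf))
  codes <- array(0L, c(ny, nx, nf))
  out <- .with_seed(spec$seed + 1L, {
    for (k in seq_len(nf)) {
      mk <- disc * (1 - 0.5 * depth[k])
      mk[!tissue] <- 0.015
      if (spec$noise_sd > 0)
        mk <- pmax(mk + matrix(stats::rnorm(ny * nx, 0, spec$noise_sd * 0.2),
                               ny, nx), 0)
      ck <- matrix(encode_velocity(v[k], venc, wrap = aliased), ny, nx)
      ck[!tissue] <- sample.int(4096L, sum(!tissue), replace = TRUE) - 1L
      mag[, , k] <- mk
      codes[, , k] <- ck
    }
    list(mag = mag, codes = codes)
  })
  pc_series(out$mag, out$codes, venc = venc, frame_interval = dt,
            trigger_times = 0, geometry = truth$geometry$pc)
}

#' Render the simultaneous audio recording of the phantom
#'
#' 16 kHz mono signal containing, per cycle, a 1 kHz stimulus beep at the
#' cycle start and two band-limited (0-4000 Hz) vowel bursts spanning the
#' ground-truth vowel intervals, each louder than the beep; broadband
#' scanner noise covers the whole acquisition and stops sharply at the
#' sequence end. TTL timestamps equal the beep times in the audio clock;
#' generator timestamps are the same events in the MRI clock.
#'
#' @param truth a [make_trajectory()] result.
#' @param spec the matching [phantom_spec()].
#' @return an [audio_recording()].
#' @export
render_audio <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "phantom_truth"))
  fs <- spec$audio_rate
  seq_dur <- spec$n_cycles * spec$cycle_period
  n <- round((spec$lead_in + seq_dur + spec$tail) * fs)
  t0 <- spec$lead_in

  segs <- rbind(cbind(truth$beep_times, truth$beep_times + 0.15),
                truth$vowel_intervals)
  o <- order(segs[, 1])
  so <- segs[o, , drop = FALSE]
  if (nrow(so) > 1 && any(so[-1, 1] < so[-nrow(so), 2]))
    stop("configured beep/vowel segments overlap")

  .with_seed(spec$seed + 2L, {
    x <- numeric(n)
    if (spec$scanner_level > 0) {
      idx <- seq(round(t0 * fs) + 1, min(n, round((t0 + seq_dur) * fs)))
      x[idx] <- x[idx] + spec$scanner_level * stats::rnorm(length(idx))
    }
    add_burst <- function(x, start, dur, wave) {
      i0 <- round(start * fs); len <- length(wave)
      idx <- (i0 + 1):(i0 + len)
      keep <- idx >= 1 & idx <= n
      x[idx[keep]] <- x[idx[keep]] + wave[keep]
      x
    }
    ramp <- function(len, fs) {
      nr <- min(round(0.005 * fs), floor(len / 2))
      env <- rep(1, len)
      if (nr > 0) {
        up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
        env[seq_len(nr)] <- up
        env[len + 1 - seq_len(nr)] <- up
      }
      env
    }
    if (spec$beep_level > 0)
      for (b in truth$beep_times) {
        len <- round(0.15 * fs)
        tone <- spec$beep_level * sin(2 * pi * 1000 * seq_len(len) / fs) *
          ramp(len, fs)
        x <- add_burst(x, t0 + b, 0.15, tone)
      }
    if (spec$vowel_level > 0)
      for (i in seq_len(nrow(truth$vowel_intervals))) {
        dur <- truth$vowel_intervals[i, 2] - truth$vowel_intervals[i, 1]
        len <- round(dur * fs)
        w <- stats::rnorm(len)
        # brick-wall low-pass below 4 kHz: vowel energy lives in 0-4000 Hz
        wf <- stats::fft(w)
        kcut <- floor(4000 / fs * len)
        keep <- c(seq_len(kcut + 1), seq(len - kcut + 1, len))
        mask <- rep(0, len); mask[keep] <- 1
        w <- Re(stats::fft(wf * mask, inverse = TRUE)) / len
        w <- spec$vowel_level * w / max(abs(w)) * ramp(len, fs)
        x <- add_burst(x, t0 + truth$vowel_intervals[i, 1], dur, w)
      }
    x <- pmin(pmax(x, -1), 1)
    audio_recording(x, rate = fs,
                    ttl_times = t0 + truth$beep_times,
                    generator_times = truth$beep_times,
                    sequence_end_time = t0 + seq_dur)
  })
}

#' Generate the full phantom data set
#'
#' Convenience wrapper producing ground truth plus all three synthetic
#' modalities from one spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with `truth`, `rt` ([frame_series()]), `pc`
#'   ([pc_series()]), `audio` ([audio_recording()]) and the `spec`.
#' @export
phantom_dataset <- function(spec = phantom_spec()) {
  truth <- make_trajectory(spec)
  list(truth = truth,
       rt = render_rt_series(truth, spec),
       pc = render_pc_series(truth, spec),
       audio = render_audio(truth, spec),
       spec = spec)
}

#' Write a phantom data set to plain-text files
#'
#' Ground truth goes to CSV (`time_s, x_mm, y_mm, z_mm, v_normal_cm_s`),
#' the spec and seed to a JSON sidecar, image stacks to one CSV per frame
#' under `rt/` and `pc_mag/`, `pc_phase/`, and audio to 16-bit PCM WAV.
#'
#' @param ds a [phantom_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- data.frame(time_s = ds$truth$times, ds$truth$pos,
                   v_normal_cm_s = ds$truth$v_normal)
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(ds$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  write_stack <- function(a, sub) {
    d <- file.path(dir, sub); dir.create(d, showWarnings = FALSE)
    for (k in seq_len(dim(a)[3]))
      utils::write.table(a[, , k],
                         file.path(d, sprintf("frame_%04d.csv", k)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
  }
  write_stack(ds$rt$frames, "rt")
  write_stack(ds$pc$magnitude, "pc_mag")
  write_stack(ds$pc$phase_codes, "pc_phase")
  write_wav(ds$audio, file.path(dir, "audio.wav"))
  invisible(dir)
}
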