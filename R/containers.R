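#' Timed stack of 2D magnitude images
#'
#' The basic container for dynamic MRI magnitude data: a `ny x nx x nf`
#' array of non-negative intensities with a timestamp per frame, the
#' in-plane pixel spacing, and (optionally) the slice geometry needed to
#' map pixel indices into patient coordinates.
#'
#' @param frames numeric array `ny x nx x nf` (a single matrix is promoted
#'   to one frame).
#' @param times numeric vector of frame timestamps in seconds, strictly
#'   increasing, length `nf`.
#' @param spacing pixel spacing in mm, `(row, col)`; a scalar is recycled.
#' @param geometry optional [slice_geometry()] of the imaging plane.
#' @return an object of class `frame_series`.
#' @export
frame_series <- function(frames, times, spacing, geometry = NULL) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (!all(is.finite(frames))) stop("frame intensities must be finite")
  nf <- dim(frames)[3L]
  times <- as.numeric(times)
  if (length(times) != nf) stop("one timestamp per frame required")
  if (nf > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  spacing <- rep(as.numeric(spacing), length.out = 2L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(frames = frames, times = times, spacing = spacing,
                 geometry = geometry),
            class = "frame_series")
}

#' @exportS3Method base::print
print.frame_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_series> %d x %d pixels, %d frames, %.4g-%.4g s, spacing %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$times[1], x$times[d[3]],
              x$spacing[1], x$spacing[2]))
  invisible(x)
}

#' @export
length.frame_series <- function(x) dim(x$frames)[3L]

#' Paired magnitude / phase-code stacks from a phase-contrast acquisition
#'
#' Phase images are stored as the raw integer codes found in 16-bit DICOM
#' pixel data; the vendor dialect assumed throughout is a 12-bit payload
#' (values 0..4095) mapping linearly onto phase `(-pi, pi)` and hence onto
#' velocity `(-venc, venc)` along the through-plane encoding direction.
#'
#' @param magnitude numeric array `ny x nx x nf`.
#' @param phase_codes integer array congruent with `magnitude`, codes in
#'   `[0, 65535]` (12-bit payload expected by the decoder).
#' @param venc velocity-encoding threshold in cm/s (phase `pi` maps to
#'   `+venc`).
#' @param frame_interval seconds between reconstructed cine frames.
#' @param trigger_times seconds; start of each reconstructed dynamic
#'   series relative to the common (MRI) clock.
#' @param geometry optional [slice_geometry()] of the oblique slice.
#' @param encoding_dir label, through-plane positive direction.
#' @return an object of class `pc_series`.
#' @export
pc_series <- function(magnitude, phase_codes, venc, frame_interval,
                      trigger_times = 0, geometry = NULL,
                      encoding_dir = "through-plane, feet-to-head positive") {
  if (is.matrix(magnitude)) magnitude <- array(magnitude, c(dim(magnitude), 1L))
  if (is.matrix(phase_codes)) phase_codes <- array(phase_codes, c(dim(phase_codes), 1L))
  stopifnot(length(dim(magnitude)) == 3L)
  if (!identical(dim(magnitude), dim(phase_codes)))
    stop("magnitude and phase stacks must be congruent")
  if (any(phase_codes < 0) || any(phase_codes >= 65536))
    stop("phase codes must lie in [0, 65536)")
  if (venc <= 0) stop("venc must be positive")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  structure(list(magnitude = magnitude,
                 phase_codes = phase_codes,
                 venc = venc,
                 frame_interval = frame_interval,
                 trigger_times = as.numeric(trigger_times),
                 geometry = geometry,
                 encoding_dir = encoding_dir),
            class = "pc_series")
}

#' @exportS3Method base::print
print.pc_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf("<pc_series> %d x %d pixels, %d frames, VENC %.3g cm/s, dt %.4g ms\n",
              d[1], d[2], d[3], x$venc, 1000 * x$frame_interval))
  invisible(x)
}

#' Time-stamped scalar velocity samples
#'
#' @param times seconds, strictly increasing.
#' @param values cm/s; `NA` marks frames flagged as missing (e.g. a fully
#'   magnitude-masked ROI).
#' @param sign_convention label describing the sign; the package-wide
#'   convention is positive velocity for upward (closing) tongue motion.
#' @return an object of class `velocity_curve`.
#' @export
velocity_curve <- function(times, values,
                           sign_convention = "positive = upward/closure") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(is.infinite(values))) stop("velocity values must be finite or NA")
  structure(list(times = times, values = values,
                 sign_convention = sign_convention),
            class = "velocity_curve")
}

#' @exportS3Method base::print
print.velocity_curve <- function(x, ...) {
  cat(sprintf("<velocity_curve> %d samples, %.4g-%.4g s, range [%.3g, %.3g] cm/s (%s)\n",
              length(x$times), min(x$times), max(x$times),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              x$sign_convention))
  invisible(x)
}

#' Sub-pixel point trajectory through a frame series
#'
#' @param points numeric matrix `nf x 2` of 0-based `(row, col)` positions.
#' @param times seconds per frame, strictly increasing.
#' @param clipped logical, whether any point had to be clipped to the
#'   image bounds during propagation.
#' @return an object of class `tracked_trajectory`.
#' @export
tracked_trajectory <- function(points, times, clipped = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be an n x 2 (row, col) matrix")
  if (nrow(points) != length(times)) stop("one point per frame required")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  colnames(points) <- c("row", "col")
  structure(list(points = points, times = as.numeric(times),
                 clipped = isTRUE(clipped)),
            class = "tracked_trajectory")
}

#' @exportS3Method base::print
print.tracked_trajectory <- function(x, ...) {
  cat(sprintf("<tracked_trajectory> %d frames, %.4g-%.4g s%s\n",
              nrow(x$points), x$times[1], x$times[length(x$times)],
              if (x$clipped) " [clipped]" else ""))
  invisible(x)
}

#' Mono audio recording with synchronization side channels
#'
#' @param samples numeric vector in `[-1, 1]`.
#' @param rate sampling rate in Hz (16000 in the reference protocol).
#' @param ttl_times seconds; stimulus-generator pulses as recorded on the
#'   TTL channel of the audio system (audio clock).
#' @param generator_times seconds; the same pulses as logged by the
#'   stimulus generator itself (MRI clock).
#' @param sequence_end_time seconds (audio clock) at which the scanner
#'   noise of the imaging sequence ends, if logged externally.
#' @return an object of class `audio_recording`.
#' @export
audio_recording <- function(samples, rate = 16000, ttl_times = numeric(),
                            generator_times = numeric(),
                            sequence_end_time = NA_real_) {
  if (rate <= 0) stop("rate must be positive")
  if (is.unsorted(ttl_times)) stop("ttl_times must be non-decreasing")
  if (is.unsorted(generator_times)) stop("generator_times must be non-decreasing")
  structure(list(samples = as.numeric(samples), rate = rate,
                 ttl_times = as.numeric(ttl_times),
                 generator_times = as.numeric(generator_times),
                 sequence_end_time = sequence_end_time),
            class = "audio_recording")
}

#' @exportS3Method base::print
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %.3f s @ %g Hz, %d TTL events\n",
              length(x$samples) / x$rate, x$rate, length(x$ttl_times)))
  invisible(x)
}

#' Imaging-slice geometry in patient coordinates
#'
#' Patient coordinates are a right-handed mm frame whose third axis points
#' feet-to-head ("up"). A slice is described by the patient-space position
#' of pixel (0, 0), the unit direction vectors of increasing row and
#' column index, and the slab thickness; the through-plane normal is the
#' cross product of the two in-plane directions.
#'
#' @param origin patient-space mm position of pixel `(0, 0)`.
#' @param row_dir,col_dir orthonormal 3-vectors (direction of increasing
#'   row / column index).
#' @param thickness slice thickness in mm.
#' @return an object of class `slice_geometry` with a precomputed unit
#'   `normal`.
#' @export
slice_geometry <- function(origin, row_dir, col_dir, thickness = 6) {
  origin <- as.numeric(origin); row_dir <- as.numeric(row_dir)
  col_dir <- as.numeric(col_dir)
  stopifnot(length(origin) == 3L, length(row_dir) == 3L, length(col_dir) == 3L)
  if (abs(sqrt(sum(row_dir^2)) - 1) > 1e-8 ||
      abs(sqrt(sum(col_dir^2)) - 1) > 1e-8)
    stop("row_dir and col_dir must be unit vectors")
  if (abs(sum(row_dir * col_dir)) > 1e-8)
    stop("row_dir and col_dir must be orthogonal")
  if (thickness <= 0) stop("thickness must be positive")
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  structure(list(origin = origin, row_dir = row_dir, col_dir = col_dir,
                 normal = normal, thickness = thickness),
            class = "slice_geometry")
}

#' Through-plane unit normal with positive feet-to-head component
#'
#' @param geom a [slice_geometry()].
#' @return unit 3-vector; flipped if needed so its third (feet-to-head)
#'   component is non-negative, matching the "positive = upwards" sign
#'   convention used for all velocities.
#' @export
slice_normal_up <- function(geom) {
  n <- geom$normal
  if (n[3] < 0) n <- -n
  n
}
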