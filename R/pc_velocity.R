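#' Decode 16-bit phase-contrast codes to phase
#'
#' The vendor dialect assumed here stores a 12-bit payload in the 16-bit
#' DICOM pixel: `phase = -pi + code / (2^12 - 1) * 2 * pi`, so code 0
#' maps to `-pi` and code 4095 to `+pi`.
#'
#' @param code integer vector in `[0, 4095]`.
#' @return phase in radians, in `[-pi, pi]`.
#' @export
decode_phase <- function(code) {
  if (any(code < 0) || any(code > 4095))
    stop("phase codes outside [0, 4095]: the decoder assumes a 12-bit ",
         "payload in the 16-bit container")
  -pi + code / 4095 * 2 * pi
}

#' Convert phase to velocity
#'
#' `v = phase * venc / pi`: `-pi` corresponds to `-venc` and `+pi` to
#' `+venc` along the encoding direction.
#'
#' @param phase radians, `|phase| <= pi`.
#' @param venc velocity-encoding threshold, cm/s.
#' @return velocity in cm/s.
#' @export
phase_to_velocity <- function(phase, venc) {
  if (any(abs(phase) > pi + 1e-12)) stop("|phase| must not exceed pi")
  if (venc <= 0) stop("venc must be positive")
  phase * venc / pi
}

#' Encode a velocity into a 12-bit phase-contrast code
#'
#' Exact inverse of [decode_phase()] + [phase_to_velocity()] up to
#' rounding: `code = round((v / venc + 1) / 2 * 4095)`. Used by the
#' phantom generator; with `wrap = TRUE` velocities beyond `venc` alias
#' around the 12-bit range like a real phase measurement.
#'
#' @param v velocity, cm/s.
#' @param venc encoding threshold, cm/s.
#' @param wrap allow aliasing instead of rejecting `|v| >= venc`.
#' @return integer codes in `[0, 4095]`.
#' @export
encode_velocity <- function(v, venc, wrap = FALSE) {
  if (venc <= 0) stop("venc must be positive")
  if (!wrap && any(abs(v) > venc))
    stop("velocity beyond venc would alias; set wrap = TRUE to allow")
  phase <- v / venc * pi
  if (wrap) phase <- ((phase + pi) %% (2 * pi)) - pi
  code <- round((phase + pi) / (2 * pi) * 4095)
  as.integer(pmin(pmax(code, 0), 4095))
}

#' Region-of-interest specification
#'
#' @param row,col 0-based top-left pixel of the square ROI.
#' @param size side in pixels (5 in the reference protocol, i.e.
#'   5.6 x 5.6 mm at FOV 220 mm / matrix 196).
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(row, col, size = 5) {
  if (size < 1) stop("ROI size must be positive")
  structure(list(row = as.integer(row), col = as.integer(col),
                 size = as.integer(size)), class = "roi_spec")
}

#' ROI-averaged velocity from a phase-contrast series
#'
#' Per frame, the decoded velocities of the ROI pixels are averaged
#' without further filtering; pixels whose magnitude is below
#' `mask_frac` (5%) of the maximal magnitude are excluded to remove the
#' influence of low-density (air) regions whose phase is essentially
#' random. If every ROI pixel of a frame is masked, the frame's value is
#' reported missing (`NA`), never zero. Timestamps are
#' `trigger_time + frame_index * frame_interval`.
#'
#' @param series a [pc_series()].
#' @param roi a [roi_spec()], fully inside the image.
#' @param mask_frac magnitude mask threshold, fraction of the maximum.
#' @param mask_scope `"frame"` (default: per-frame maximum, robust to
#'   global intensity drift) or `"series"` (one global maximum).
#' @return a [velocity_curve()] with `NA` at fully masked frames.
#' @export
roi_velocity <- function(series, roi, mask_frac = 0.05,
                         mask_scope = c("frame", "series")) {
  stopifnot(inherits(series, "pc_series"), inherits(roi, "roi_spec"))
  mask_scope <- match.arg(mask_scope)
  d <- dim(series$magnitude)
  rows <- roi$row + seq_len(roi$size)        # 0-based top-left -> 1-based
  cols <- roi$col + seq_len(roi$size)
  if (roi$row < 0 || roi$col < 0 || max(rows) > d[1] || max(cols) > d[2])
    stop("ROI extends outside the image")
  gmax <- max(series$magnitude)
  nf <- d[3]
  vals <- numeric(nf)
  for (k in seq_len(nf)) {
    mag <- series$magnitude[, , k]
    mmax <- if (mask_scope == "frame") max(mag) else gmax
    m <- mag[rows, cols]
    codes <- series$phase_codes[rows, cols, k]
    keep <- m >= mask_frac * mmax
    vals[k] <- if (!any(keep)) NA_real_ else
      mean(phase_to_velocity(decode_phase(codes[keep]), series$venc))
  }
  times <- series$trigger_times[1] + (seq_len(nf) - 1) * series$frame_interval
  velocity_curve(times, vals)
}

#' Physical side of a square pixel ROI
#'
#' `side = size * fov / matrix`, reported to 0.1 mm: 5 pixels at
#' FOV 220 mm on a 196 matrix give 5.6 mm.
#'
#' @param roi a [roi_spec()] or integer pixel count.
#' @param fov field of view in mm.
#' @param matrix image matrix size in pixels.
#' @return side length in mm, rounded to 0.1 mm.
#' @export
roi_size_mm <- function(roi, fov = 220, matrix = 196) {
  if (fov <= 0 || matrix <= 0) stop("fov and matrix must be positive")
  size <- if (inherits(roi, "roi_spec")) roi$size else as.numeric(roi)
  round(size * fov / matrix, 1)
}

#' Cine frame interval from sequence parameters
#'
#' One reconstructed cine frame collects `lines_per_segment` k-space
#' lines for each of `n_encodings` velocity encodings, each taking one
#' repetition time: `interval = tr_ms * n_encodings * lines_per_segment`
#' (5.92 ms x 2 x 3 = 35.52 ms in the reference protocol).
#'
#' @param tr_ms repetition time, ms.
#' @param n_encodings velocity-encoding gradients interleaved (2 for a
#'   single-direction phase-contrast scan).
#' @param lines_per_segment k-space lines per segment.
#' @return frame interval in ms.
#' @export
cine_frame_interval <- function(tr_ms = 5.92, n_encodings = 2,
                                lines_per_segment = 3) {
  if (tr_ms <= 0) stop("tr_ms must be positive")
  tr_ms * n_encodings * lines_per_segment
}

#' Duration of a dynamic series
#'
#' @param n_frames frames in the series.
#' @param frame_interval_ms frame interval in ms.
#' @return duration in seconds (44 frames x 35.52 ms = 1.56 s).
#' @export
series_duration <- function(n_frames = 44,
                            frame_interval_ms = cine_frame_interval()) {
  n_frames * frame_interval_ms / 1000
}
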