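#' Map a pixel trajectory into patient coordinates
#'
#' `p_mm = origin + row * spacing_r * row_dir + col * spacing_c * col_dir`
#' using the slice position/orientation metadata of the imaging plane
#' (the information a DICOM header carries in ImagePositionPatient /
#' ImageOrientationPatient).
#'
#' @param traj a [tracked_trajectory()] (0-based pixel positions).
#' @param geom the [slice_geometry()] of the imaged plane.
#' @param spacing pixel spacing in mm `(row, col)`; scalar recycled.
#' @return matrix `nf x 3` of mm positions (columns `x_mm, y_mm, z_mm`).
#' @export
trajectory_to_patient <- function(traj, geom, spacing) {
  stopifnot(inherits(traj, "tracked_trajectory"),
            inherits(geom, "slice_geometry"))
  spacing <- rep(as.numeric(spacing), length.out = 2L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  p <- outer(rep(1, nrow(traj$points)), geom$origin) +
    (traj$points[, 1] * spacing[1]) %o% geom$row_dir +
    (traj$points[, 2] * spacing[2]) %o% geom$col_dir
  colnames(p) <- c("x_mm", "y_mm", "z_mm")
  p
}

#' Signed distance from points to the upper edge of an oblique slice
#'
#' The upper edge is the boundary plane of the slab offset by
#' `+thickness/2` along the through-plane normal (taken with positive
#' feet-to-head component). Distances are measured along that normal, so
#' they are positive on the "up" side and invariant under in-plane
#' displacement. The companion displacement/velocity sign convention
#' follows: positive displacement is up, positive velocity is upwards
#' (towards closure).
#'
#' @param p_mm matrix `n x 3` (or length-3 vector) of mm positions.
#' @param geom the oblique-slice [slice_geometry()].
#' @return numeric vector of signed distances in mm.
#' @export
signed_distance_to_slice_edge <- function(p_mm, geom) {
  stopifnot(inherits(geom, "slice_geometry"))
  if (is.null(dim(p_mm))) p_mm <- matrix(p_mm, nrow = 1L)
  n <- slice_normal_up(geom)
  edge <- geom$origin + (geom$thickness / 2) * n
  as.vector((p_mm[, 1] - edge[1]) * n[1] + (p_mm[, 2] - edge[2]) * n[2] +
              (p_mm[, 3] - edge[3]) * n[3])
}

#' Differentiate a displacement series into a velocity curve
#'
#' Central differences in the interior, one-sided differences at the
#' ends; input in mm, output in cm/s. An optional moving-average of the
#' input (off by default) is available for noisy tracks.
#'
#' @param d displacement samples in mm.
#' @param times sample times in seconds; alternatively give
#'   `frame_interval` for uniform sampling starting at `t0`.
#' @param frame_interval uniform sampling interval in seconds.
#' @param t0 time of the first sample when `frame_interval` is used.
#' @param smooth_window odd integer; if > 1 the displacement is smoothed
#'   with a centered moving average of that many samples first.
#' @return a [velocity_curve()].
#' @export
differentiate <- function(d, times = NULL, frame_interval = NULL, t0 = 0,
                          smooth_window = 1L) {
  d <- as.numeric(d)
  n <- length(d)
  if (n < 3L) stop("need at least three samples to differentiate")
  if (is.null(times)) {
    if (is.null(frame_interval)) stop("give times or frame_interval")
    times <- t0 + (seq_len(n) - 1) * frame_interval
  }
  if (length(times) != n) stop("times length mismatch")
  if (smooth_window > 1L) {
    if (smooth_window %% 2 != 1) stop("smooth_window must be odd")
    k <- rep(1 / smooth_window, smooth_window)
    pad <- (smooth_window - 1L) / 2L
    dp <- c(rep(d[1], pad), d, rep(d[n], pad))
    d <- as.numeric(stats::filter(dp, k, sides = 2))[pad + seq_len(n)]
  }
  v <- numeric(n)
  v[1] <- (d[2] - d[1]) / (times[2] - times[1])
  v[n] <- (d[n] - d[n - 1]) / (times[n] - times[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    v[i] <- (d[i + 1] - d[i - 1]) / (times[i + 1] - times[i - 1])
  }
  velocity_curve(times, v / 10)   # mm/s -> cm/s
}

#' Relative difference between full speed and its slice-normal component
#'
#' Per sample `| |v_full| - |v_normal| | / |v_full|`; for motion at an
#' angle `theta` to the normal this is exactly `1 - cos(theta)`. Samples
#' with `|v_full|` below `floor_cm_s` are excluded (returned as `NA`).
#'
#' @param traj_mm matrix `n x 3` of mm positions.
#' @param geom the oblique-slice [slice_geometry()].
#' @param times sample times in seconds.
#' @param floor_cm_s exclusion floor for the full speed.
#' @return list with `times`, `rel_diff` (per sample, `NA` where
#'   excluded) and `max` (maximum over included samples).
#' @export
transverse_vs_full_speed <- function(traj_mm, geom, times,
                                     floor_cm_s = 1e-6) {
  stopifnot(nrow(traj_mm) == length(times), nrow(traj_mm) >= 3L)
  n <- nrow(traj_mm)
  i <- 2:(n - 1)
  dt <- times[i + 1] - times[i - 1]
  vfull3 <- (traj_mm[i + 1, , drop = FALSE] -
               traj_mm[i - 1, , drop = FALSE]) / dt / 10
  vfull <- sqrt(rowSums(vfull3^2))
  nvec <- slice_normal_up(geom)
  vnorm <- abs(as.vector(vfull3 %*% nvec))
  rel <- ifelse(vfull > floor_cm_s, abs(vfull - vnorm) / vfull, NA_real_)
  list(times = times[i], rel_diff = rel,
       max = if (all(is.na(rel))) NA_real_ else max(rel, na.rm = TRUE))
}

#' Tongue-tip normal velocity from a tracked real-time trajectory
#'
#' Convenience composition of the real-time route after tracking: map
#' the pixel trajectory to patient coordinates, take the signed distance
#' to the upper edge of the oblique (phase-contrast) slice, and
#' differentiate.
#'
#' @param traj a [tracked_trajectory()].
#' @param rt_geom [slice_geometry()] of the real-time (mid-sagittal)
#'   plane.
#' @param pc_geom [slice_geometry()] of the oblique slice whose normal
#'   defines the velocity direction.
#' @param spacing pixel spacing of the real-time images, mm.
#' @param ... passed to [differentiate()].
#' @return a [velocity_curve()] (cm/s, positive upwards).
#' @export
rt_normal_velocity <- function(traj, rt_geom, pc_geom, spacing, ...) {
  p_mm <- trajectory_to_patient(traj, rt_geom, spacing)
  d <- signed_distance_to_slice_edge(p_mm, pc_geom)
  differentiate(d, times = traj$times, ...)
}
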