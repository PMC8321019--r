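#' Write a velocity curve to CSV
#'
#' Columns `time_s, v_cm_s`; missing (masked) frames are empty fields.
#'
#' @param curve a [velocity_curve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_velocity_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_s = curve$times, v_cm_s = curve$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a velocity curve from CSV
#'
#' @param path file with columns `time_s, v_cm_s`.
#' @return a [velocity_curve()].
#' @export
read_velocity_csv <- function(path) {
  d <- utils::read.csv(path)
  velocity_curve(d$time_s, d$v_cm_s)
}

#' Write a tracked trajectory to CSV
#'
#' Columns `frame, time_s, row, col` (0-based pixel coordinates).
#'
#' @param traj a [tracked_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(data.frame(frame = seq_len(nrow(traj$points)),
                              time_s = traj$times,
                              row = traj$points[, 1],
                              col = traj$points[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a (possibly manual) trajectory annotation from CSV
#'
#' Expects columns `row`, `col` and either `time_s` or both a `frame`
#' column and a `frame_interval` argument.
#'
#' @param path input CSV.
#' @param frame_interval seconds per frame, used when no `time_s`
#'   column exists.
#' @return a [tracked_trajectory()].
#' @export
read_trajectory_csv <- function(path, frame_interval = NULL) {
  d <- utils::read.csv(path)
  times <- if ("time_s" %in% names(d)) d$time_s
  else {
    if (is.null(frame_interval))
      stop("no time_s column; supply frame_interval")
    (d$frame - 1) * frame_interval
  }
  tracked_trajectory(cbind(d$row, d$col), times)
}

#' Read an image stack from a directory of per-frame CSV files
#'
#' Frames are headerless numeric CSV matrices named so that
#' lexicographic order is temporal order (as written by
#' [write_phantom()]).
#'
#' @param dir directory of frame CSVs.
#' @return `ny x nx x nf` array.
#' @export
read_stack_csv <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop("no frame CSVs found in ", dir)
  first <- as.matrix(utils::read.csv(files[1], header = FALSE))
  out <- array(0, c(nrow(first), ncol(first), length(files)))
  out[, , 1] <- first
  for (k in seq_along(files)[-1])
    out[, , k] <- as.matrix(utils::read.csv(files[k], header = FALSE))
  out
}
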