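#' Real-time route: frames to normal-velocity curve
#'
#' Orchestrates the mid-sagittal pipeline: pre-filtering, spatio-
#' temporally regularized registration, tongue-tip propagation from a
#' user-selected start point, mapping into patient coordinates,
#' distance to the oblique slice edge, differentiation. Intermediates
#' are written as CSV when `out_dir` is given.
#'
#' @param rt a [frame_series()] with its slice geometry attached.
#' @param start tip position in the first frame, 0-based `(row, col)`.
#' @param pc_geom [slice_geometry()] of the oblique slice whose normal
#'   defines the measured velocity component.
#' @param preproc a [preproc_params()].
#' @param reg a [reg_params()].
#' @param out_dir optional output directory.
#' @return list with `trajectory` ([tracked_trajectory()]), `curve`
#'   ([velocity_curve()]) and the displacement `field`.
#' @export
run_rt <- function(rt, start, pc_geom, preproc = preproc_params(),
                   reg = reg_params(), out_dir = NULL) {
  if (is.null(start) || length(start) != 2L || any(is.na(start)))
    stop("run_rt needs a start point: the tongue-tip (row, col) in the ",
         "first frame")
  if (is.null(rt$geometry))
    stop("run_rt [preproc/registration]: frame series lacks slice geometry")
  filt <- filter_series(rt, preproc)
  field <- register_series(filt, reg)
  traj <- propagate_point(start, field)
  curve <- rt_normal_velocity(traj, rt$geometry, pc_geom, rt$spacing)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory_csv(traj, file.path(out_dir, "trajectory_rt.csv"))
    write_velocity_csv(curve, file.path(out_dir, "velocity_rt.csv"))
  }
  list(trajectory = traj, curve = curve, field = field)
}

#' Phase-contrast route: paired series to velocity curve
#'
#' Decode the 12-bit phase payload, mask low-magnitude pixels, average
#' over the ROI, timestamp from the trigger.
#'
#' @param pc a [pc_series()].
#' @param roi a [roi_spec()].
#' @param out_dir optional output directory.
#' @param ... passed to [roi_velocity()].
#' @return the [velocity_curve()].
#' @export
run_pc <- function(pc, roi, out_dir = NULL, ...) {
  curve <- roi_velocity(pc, roi, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_velocity_csv(curve, file.path(out_dir, "velocity_pc.csv"))
  }
  curve
}

#' Audio route: recording to q-marks in MRI time
#'
#' Envelope, background estimation, segment detection and
#' classification, per-repetition vowel marks, and audio-to-MRI
#' alignment; the returned marks are in the MRI clock.
#'
#' @param rec an [audio_recording()].
#' @param sequence_duration imaging-sequence duration, seconds.
#' @param cycle_period stimulus period, seconds.
#' @param n_cycles repetitions contained in the sequence.
#' @param background_level optional explicit envelope threshold;
#'   estimated with [estimate_background()] when `NULL`.
#' @return list with `marks` (q1..q4 per repetition, MRI clock),
#'   `segments`, `labels`, `alignment`, `background_level`.
#' @export
run_audio <- function(rec, sequence_duration, cycle_period, n_cycles,
                      background_level = NULL) {
  env <- envelope(rec)
  if (is.null(background_level)) background_level <- estimate_background(env)
  segs <- detect_segments(env, background_level)
  labels <- classify_segments(segs)
  al <- align_audio_to_mri(rec, sequence_duration)
  win_audio <- cbind(al$offset + (seq_len(n_cycles) - 1) * cycle_period,
                     al$offset + seq_len(n_cycles) * cycle_period)
  marks <- vowel_marks(segs, labels, win_audio)
  marks[, c("q1", "q2", "q3", "q4")] <-
    marks[, c("q1", "q2", "q3", "q4")] - al$offset
  list(marks = marks, segments = segs, labels = labels, alignment = al,
       background_level = background_level)
}

#' Compare the two velocity routes against the acoustic landmarks
#'
#' Applies the feature module to both curves: stop points, velocity
#' peaks and per-phase means per repetition, aggregates, and the timing
#' statistics of q - t per landmark for whichever curves have matched
#' acoustic repetitions.
#'
#' @param rt_curve real-time [velocity_curve()] (MRI clock).
#' @param pc_curve phase-contrast [velocity_curve()] (MRI clock), or
#'   `NULL`.
#' @param q_marks acoustic marks in the MRI clock (from [run_audio()]),
#'   or `NULL`.
#' @param windows_rt,windows_pc repetition windows for each curve.
#' @param floor_cm_s noise floor for [zero_crossings()].
#' @param out_dir optional output directory for the JSON report.
#' @return list with per-route `stops`, `peaks`, `means`, aggregates,
#'   and `timing` (q - t statistics per route where computable).
#' @export
run_compare <- function(rt_curve, pc_curve = NULL, q_marks = NULL,
                        windows_rt, windows_pc = NULL, floor_cm_s = 0.5,
                        out_dir = NULL) {
  one <- function(curve, windows) {
    stops <- zero_crossings(curve, windows, floor_cm_s)
    list(stops = stops,
         peaks = peak_velocities(curve, stops),
         means = phase_means(curve, stops))
  }
  rt <- one(rt_curve, windows_rt)
  report <- list(
    rt = c(rt, list(peaks_agg = aggregate_peaks(rt$peaks),
                    means_agg = aggregate_peaks(rt$means))))
  if (!is.null(pc_curve)) {
    if (is.null(windows_pc)) stop("windows_pc required with pc_curve")
    pc <- one(pc_curve, windows_pc)
    report$pc <- c(pc, list(peaks_agg = aggregate_peaks(pc$peaks),
                            means_agg = aggregate_peaks(pc$means)))
  }
  if (!is.null(q_marks)) {
    report$timing_rt <- timing_stats(rt$stops, q_marks)
    if (!is.null(pc_curve)) {
      qp <- q_marks[q_marks$rep %in% report$pc$stops$rep, , drop = FALSE]
      report$timing_pc <- tryCatch(timing_stats(report$pc$stops, qp),
                                   error = function(e) NULL)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         force = TRUE, na = "null")
  }
  report
}

#' End-to-end phantom run
#'
#' Generates the phantom data set and pushes it through both velocity
#' routes and the audio route, then compares everything: the main
#' validation entry point of the package.
#'
#' @param spec a [phantom_spec()].
#' @param preproc,reg,floor_cm_s pipeline parameters.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list with the phantom `ds`, the `rt` run, `pc` curve,
#'   `audio` results, repetition windows and the comparison `report`.
#' @export
run_phantom <- function(spec = phantom_spec(), preproc = preproc_params(),
                        reg = reg_params(), floor_cm_s = 0.5,
                        out_dir = NULL) {
  ds <- phantom_dataset(spec)
  truth <- ds$truth
  start <- c(truth$fun$tip_row(0), truth$fun$tip_col(0))
  rt <- run_rt(ds$rt, start, truth$geometry$pc, preproc, reg,
               out_dir = out_dir)
  ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
  roi <- roi_spec(round((ny - 1) / 2) - 2L, round((nx - 1) / 2) - 2L, 5L)
  pc_curve <- run_pc(ds$pc, roi, out_dir = out_dir)
  audio <- run_audio(ds$audio,
                     sequence_duration = spec$n_cycles * spec$cycle_period,
                     cycle_period = spec$cycle_period,
                     n_cycles = spec$n_cycles)
  tt <- spec$cycle_period
  win_rt <- cbind((seq_len(spec$n_cycles) - 1) * tt,
                  seq_len(spec$n_cycles) * tt)
  win_pc <- cbind(0, spec$n_frames_pc * spec$frame_interval_pc)
  report <- run_compare(rt$curve, pc_curve, audio$marks,
                        windows_rt = win_rt, windows_pc = win_pc,
                        floor_cm_s = floor_cm_s, out_dir = out_dir)
  list(ds = ds, rt = rt, pc_curve = pc_curve, audio = audio,
       windows_rt = win_rt, windows_pc = win_pc, report = report)
}
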