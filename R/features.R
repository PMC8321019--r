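#' Kinematic stop points t0-t5 from a velocity curve
#'
#' Zero-velocity instants are located by linear interpolation between
#' bracketing samples. Because the gesture holds genuine zero-velocity
#' plateaus at the consonant closures, raw sign-crossing detection would
#' fire repeatedly inside sensor noise; runs of samples with `|v|` below
#' `floor_cm_s` are therefore collapsed to a single instant: the
#' midpoint of the run (edges refined by interpolating `|v|` at the
#' floor), or the mean time of exactly-zero samples when present. A
#' sub-floor run touching the window start (the pre-movement rest)
#' contributes its inner edge, i.e. the movement start t0; one touching
#' the window end contributes the movement stop t5.
#'
#' Per repetition window the detected instants are assigned t0..t5 in
#' temporal order: 6 instants give a complete repetition; 5 are assigned
#' t0..t4 with t5 missing (a window that ends before the return to rest,
#' as a 1.56 s cine series inside a 2 s cycle does); anything else flags
#' the repetition and yields no usable points.
#'
#' @param curve a [velocity_curve()] (`NA` samples are ignored).
#' @param windows matrix/data frame of repetition `(start, end)` times.
#' @param floor_cm_s noise floor below which velocity counts as zero.
#' @return data frame `(rep, t0..t5, n_crossings, complete)`; `complete`
#'   is `TRUE` only for six-point repetitions.
#' @export
zero_crossings <- function(curve, windows, floor_cm_s = 0.5) {
  stopifnot(inherits(curve, "velocity_curve"))
  windows <- as.matrix(windows)
  nrep <- nrow(windows)
  out <- data.frame(rep = seq_len(nrep), t0 = NA_real_, t1 = NA_real_,
                    t2 = NA_real_, t3 = NA_real_, t4 = NA_real_,
                    t5 = NA_real_, n_crossings = 0L, complete = FALSE)
  for (i in seq_len(nrep)) {
    sel <- which(curve$times >= windows[i, 1] & curve$times < windows[i, 2] &
                   !is.na(curve$values))
    if (length(sel) < 4L) next
    tt <- curve$times[sel]; vv <- curve$values[sel]
    cr <- .crossings_one(tt, vv, floor_cm_s)
    out$n_crossings[i] <- length(cr)
    if (length(cr) == 6L) {
      out[i, 2:7] <- cr
      out$complete[i] <- TRUE
    } else if (length(cr) == 5L) {
      out[i, 2:6] <- cr
    }
  }
  out
}

#' Zero-crossing instants of a sampled velocity signal
#'
#' The primitive underneath [zero_crossings()]: linear-interpolated sign
#' changes plus collapsed sub-floor runs (see there for the rules), with
#' no repetition bookkeeping.
#'
#' @param times,values velocity samples.
#' @param floor noise floor; `|v|` at or below it counts as zero.
#' @return sorted vector of crossing times.
#' @export
find_zero_crossings <- function(times, values, floor = 0.5) {
  keep <- !is.na(values)
  .crossings_one(times[keep], values[keep], floor)
}

# zero-crossing instants of one window: interpolated sign changes plus
# collapsed sub-floor runs
.crossings_one <- function(tt, vv, floor) {
  n <- length(tt)
  s <- ifelse(abs(vv) <= floor, 0L, ifelse(vv > 0, 1L, -1L))
  r <- rle(s)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  k <- length(r$values)
  cross <- numeric(0)
  # refined edge of a zero run: time where |v| interpolates to the floor
  left_edge <- function(j) {        # between run j-1 (nonzero) and run j
    i <- starts[j]
    if (i == 1L) return(tt[1])
    a <- abs(vv[i - 1L]); b <- abs(vv[i])
    tt[i - 1L] + (a - floor) / (a - b) * (tt[i] - tt[i - 1L])
  }
  right_edge <- function(j) {
    i <- ends[j]
    if (i == n) return(tt[n])
    a <- abs(vv[i]); b <- abs(vv[i + 1L])
    tt[i] + (floor - a) / (b - a) * (tt[i + 1L] - tt[i])
  }
  for (j in seq_len(k)) {
    if (r$values[j] == 0L) {
      idx <- starts[j]:ends[j]
      prev_s <- if (j > 1L) r$values[j - 1L] else NA_integer_
      next_s <- if (j < k) r$values[j + 1L] else NA_integer_
      if (is.na(prev_s) && is.na(next_s)) next       # all-zero window
      if (is.na(prev_s)) { cross <- c(cross, right_edge(j)); next }
      if (is.na(next_s)) { cross <- c(cross, left_edge(j)); next }
      if (prev_s == next_s) next                     # a dip, not a crossing
      zi <- idx[vv[idx] == 0]
      cross <- c(cross,
                 if (length(zi) > 0) mean(tt[zi])
                 else (left_edge(j) + right_edge(j)) / 2)
    } else if (j < k && r$values[j + 1L] != 0L) {
      # direct sign change without sub-floor samples in between
      i <- ends[j]
      v1 <- vv[i]; v2 <- vv[i + 1L]
      cross <- c(cross, tt[i] - v1 * (tt[i + 1L] - tt[i]) / (v2 - v1))
    }
  }
  sort(cross)
}

#' Velocity peaks between stop points
#'
#' Per repetition: the minimum of the sampled curve on (t1, t2), the
#' maximum on (t2, t3) and the minimum on (t3, t4) (no re-interpolation).
#' For the /tata/ gesture the expected sign pattern is (-, +, -): two
#' descents bracketing one closing movement.
#'
#' @param curve a [velocity_curve()].
#' @param stops data frame from [zero_crossings()].
#' @return data frame `(rep, left_min, max, right_min)`; repetitions
#'   lacking t1..t4 or samples in an interval give `NA`s.
#' @export
peak_velocities <- function(curve, stops) {
  ext <- function(a, b, f) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    sel <- curve$times >= a & curve$times <= b & !is.na(curve$values)
    if (!any(sel)) return(NA_real_)
    f(curve$values[sel])
  }
  data.frame(rep = stops$rep,
             left_min = mapply(ext, stops$t1, stops$t2, MoreArgs = list(f = min)),
             max = mapply(ext, stops$t2, stops$t3, MoreArgs = list(f = max)),
             right_min = mapply(ext, stops$t3, stops$t4, MoreArgs = list(f = min)))
}

#' Mean absolute velocity of the utterance phases
#'
#' Mean of `|v|` over the samples in (t1, t2) (first opening), (t2, t3)
#' (closure) and (t3, t4) (second opening). For uniformly sampled curves
#' the sample mean equals the time-weighted mean.
#'
#' @param curve a [velocity_curve()].
#' @param stops data frame from [zero_crossings()].
#' @return data frame `(rep, opening1, closure, opening2)`.
#' @export
phase_means <- function(curve, stops) {
  avg <- function(a, b) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    sel <- curve$times >= a & curve$times <= b & !is.na(curve$values)
    if (!any(sel)) return(NA_real_)
    mean(abs(curve$values[sel]))
  }
  data.frame(rep = stops$rep,
             opening1 = mapply(avg, stops$t1, stops$t2),
             closure = mapply(avg, stops$t2, stops$t3),
             opening2 = mapply(avg, stops$t3, stops$t4))
}

#' Timing statistics between kinematic and acoustic landmarks
#'
#' For each landmark pair i in 1..4, the mean and sample standard
#' deviation (n - 1) of `q_i - t_i` across matched repetitions, in ms.
#' Flagged repetitions on either side are excluded pairwise.
#'
#' @param t_marks data frame from [zero_crossings()].
#' @param q_marks data frame from [vowel_marks()] (same repetition ids
#'   and clock).
#' @return data frame `(landmark, mean_ms, sd_ms, n)`.
#' @export
timing_stats <- function(t_marks, q_marks) {
  m <- merge(t_marks, q_marks, by = "rep")
  if (nrow(m) == 0L) stop("no matched repetitions")
  rows <- lapply(1:4, function(i) {
    d <- (m[[paste0("q", i)]] - m[[paste0("t", i)]]) * 1000
    d <- d[!is.na(d) & !m$flagged]
    data.frame(landmark = paste0("q", i, "-t", i),
               mean_ms = if (length(d)) mean(d) else NA_real_,
               sd_ms = if (length(d) > 1) stats::sd(d) else NA_real_,
               n = length(d))
  })
  if (all(vapply(rows, function(r) r$n, integer(1)) == 0L))
    stop("no matched repetitions with usable landmarks")
  do.call(rbind, rows)
}

#' Aggregate per-repetition peaks or phase means
#'
#' Column-wise mean and sample standard deviation across repetitions;
#' the deviation is reported only when at least two repetitions exist
#' (a single reconstructed cine cycle yields means without deviations).
#'
#' @param per_rep data frame with a `rep` column and one column per
#'   measure (e.g. from [peak_velocities()] or [phase_means()]).
#' @return data frame `(measure, mean, sd, n)`.
#' @export
aggregate_peaks <- function(per_rep) {
  meas <- setdiff(names(per_rep), "rep")
  do.call(rbind, lapply(meas, function(mn) {
    x <- per_rep[[mn]]
    x <- x[!is.na(x)]
    data.frame(measure = mn,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               n = length(x))
  }))
}

#' Format an aggregate table as "mean (sd)" strings
#'
#' @param agg data frame from [aggregate_peaks()].
#' @param digits digits after the decimal point.
#' @return named character vector, deviation omitted when absent.
#' @export
format_mean_sd <- function(agg, digits = 2) {
  out <- ifelse(is.na(agg$sd),
                sprintf("%.*f", digits, agg$mean),
                sprintf("%.*f (%.*f)", digits, agg$mean, digits, agg$sd))
  stats::setNames(out, agg$measure)
}
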