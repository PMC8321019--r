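# centered running maximum, van Herk block algorithm (O(n), vectorized)
.running_max <- function(x, w) {
  if (w <= 1L) return(x)
  r <- (w - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(-Inf, r), x, rep(-Inf, w - 1L - r))
  nb <- ceiling(length(xp) / w)
  xp <- c(xp, rep(-Inf, nb * w - length(xp)))
  m <- matrix(xp, nrow = w)
  pref <- apply(m, 2L, cummax)
  suff <- apply(m[w:1, , drop = FALSE], 2L, cummax)[w:1, , drop = FALSE]
  pv <- as.vector(pref); sv <- as.vector(suff)
  pmax(sv[seq_len(n)], pv[seq_len(n) + (w - 1L)])
}

#' Amplitude envelope of an audio signal
#'
#' The absolute signal is passed through a sliding-window maximum and
#' then a sliding median, both of 10 ms (windows rounded to an odd
#' number of samples). This is the level signal used for segmenting the
#' recording into beeps, speech and background.
#'
#' @param rec an [audio_recording()], or a numeric sample vector.
#' @param rate sampling rate, required when `rec` is a plain vector.
#' @param window window length of both filters, seconds.
#' @return an object of class `audio_envelope`: `level`, `times`, `rate`.
#' @export
envelope <- function(rec, rate = NULL, window = 0.010) {
  if (inherits(rec, "audio_recording")) {
    x <- rec$samples; rate <- rec$rate
  } else {
    x <- as.numeric(rec)
    if (is.null(rate)) stop("rate required for plain sample vectors")
  }
  if (length(x) == 0L) stop("empty signal")
  w <- round(window * rate)
  if (w %% 2 == 0) w <- w + 1L
  lev <- .running_max(abs(x), w)
  if (length(lev) > w) lev <- as.numeric(stats::runmed(lev, w, endrule = "median"))
  structure(list(level = lev, times = (seq_along(x) - 1) / rate,
                 rate = rate), class = "audio_envelope")
}

#' Background level estimate from the envelope
#'
#' Sensible automatic default for the segmentation threshold (the
#' appropriate value depends on subject and sequence): take the samples
#' quieter than `init_frac` of the envelope maximum as provisional
#' silence/background and return their `q`-th quantile.
#'
#' @param env an [envelope()] result.
#' @param init_frac provisional silence cut, fraction of the max level.
#' @param q quantile of the provisional background levels.
#' @return scalar background level.
#' @export
estimate_background <- function(env, init_frac = 0.25, q = 0.95) {
  lev <- env$level
  sil <- lev < init_frac * max(lev)
  if (!any(sil)) sil <- lev <= stats::quantile(lev, 0.1)
  as.numeric(stats::quantile(lev[sil], q))
}

#' Detect candidate signal segments in an envelope
#'
#' Maximal runs whose level strictly exceeds `background_level` and
#' whose duration strictly exceeds `min_duration` (0.1 s): shorter
#' bursts, including one of exactly 0.1 s, are rejected.
#'
#' @param env an [envelope()] result.
#' @param background_level threshold level (>= 0).
#' @param min_duration minimal duration, seconds.
#' @return data frame with `start`, `end` (seconds) and `mean_level`.
#' @export
detect_segments <- function(env, background_level, min_duration = 0.1) {
  if (background_level < 0) stop("background_level must be non-negative")
  above <- env$level > background_level
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / env$rate > min_duration)
  if (!any(keep))
    return(data.frame(start = numeric(), end = numeric(),
                      mean_level = numeric()))
  s <- starts[keep]; e <- ends[keep]
  data.frame(start = (s - 1L) / env$rate, end = e / env$rate,
             mean_level = vapply(seq_along(s), function(i)
               mean(env$level[s[i]:e[i]]), numeric(1)))
}

#' Classify segments as stimulus beeps or speech
#'
#' Speech is reliably louder than the stimulus beep, so segments are
#' separated on their mean envelope level: the sorted levels are split
#' at their largest gap and the upper group is labelled speech. With no
#' usable gap (all levels equal) everything is labelled speech and a
#' warning is raised.
#'
#' @param segments data frame from [detect_segments()].
#' @param threshold optional explicit level threshold overriding the
#'   automatic split.
#' @return character vector of labels, `"beep"` or `"speech"`.
#' @export
classify_segments <- function(segments, threshold = NULL) {
  n <- nrow(segments)
  if (n == 0L) return(character())
  lev <- segments$mean_level
  if (is.null(threshold)) {
    if (n == 1L) return("speech")
    s <- sort(lev)
    gaps <- diff(s)
    if (max(gaps) <= 1e-12) {
      warning("all segment levels equal; labelling everything speech")
      return(rep("speech", n))
    }
    i <- which.max(gaps)
    threshold <- (s[i] + s[i + 1L]) / 2
  }
  ifelse(lev > threshold, "speech", "beep")
}

# low-passed (0-4 kHz) amplitude envelope used for boundary refinement
.band_envelope <- function(x, rate, fmax = 4000) {
  n <- length(x)
  xf <- stats::fft(x)
  kcut <- floor(fmax / rate * n)
  mask <- rep(0, n)
  mask[c(seq_len(kcut + 1L), if (kcut > 0) seq(n - kcut + 1L, n))] <- 1
  lp <- Re(stats::fft(xf * mask, inverse = TRUE)) / n
  envelope(lp, rate)$level
}

#' Acoustic vowel landmarks q1-q4 per repetition
#'
#' Within each repetition window the two speech segments give, in order,
#' onset and offset of the first vowel (q1, q2) and of the second vowel
#' (q3, q4). Repetitions without exactly two speech segments are flagged
#' and excluded from downstream statistics. Optionally each boundary is
#' snapped to where the 0-4 kHz band energy crosses half the segment's
#' median band level (vowels carry strong energy below 4 kHz); manually
#' corrected marks, when supplied, override the detected ones verbatim.
#'
#' @param segments data frame from [detect_segments()].
#' @param labels labels from [classify_segments()].
#' @param windows matrix/data frame with repetition `(start, end)` times
#'   (same clock as the segments).
#' @param rec the [audio_recording()]; required when `refine = TRUE`.
#' @param refine snap boundaries with the band-energy rule.
#' @param manual optional data frame `(rep, q1, q2, q3, q4)` of manual
#'   corrections; rows replace the corresponding repetitions verbatim.
#' @return data frame `(rep, q1, q2, q3, q4, flagged)`.
#' @export
vowel_marks <- function(segments, labels, windows, rec = NULL,
                        refine = FALSE, manual = NULL) {
  windows <- as.matrix(windows)
  nrep <- nrow(windows)
  speech <- segments[labels == "speech", , drop = FALSE]
  out <- data.frame(rep = seq_len(nrep), q1 = NA_real_, q2 = NA_real_,
                    q3 = NA_real_, q4 = NA_real_, flagged = TRUE)
  band <- NULL
  if (refine) {
    if (is.null(rec)) stop("refine = TRUE needs the recording")
    band <- .band_envelope(rec$samples, rec$rate)
  }
  snap <- function(t0, seg) {
    # move the boundary to the nearest half-median band-energy crossing
    i0 <- max(1L, round(seg[1] * rec$rate)); i1 <- min(length(band),
                                                       round(seg[2] * rec$rate))
    ref <- 0.5 * stats::median(band[i0:i1])
    idx <- max(1L, i0 - round(0.05 * rec$rate)):min(length(band),
                                                    i1 + round(0.05 * rec$rate))
    above <- band[idx] >= ref
    cross <- which(diff(above) != 0)
    if (length(cross) == 0L) return(t0)
    tc <- (idx[cross] - 0.5) / rec$rate
    tc[which.min(abs(tc - t0))]
  }
  for (i in seq_len(nrep)) {
    mid <- (speech$start + speech$end) / 2
    inw <- speech[mid >= windows[i, 1] & mid < windows[i, 2], , drop = FALSE]
    if (nrow(inw) == 2L) {
      inw <- inw[order(inw$start), ]
      q <- c(inw$start[1], inw$end[1], inw$start[2], inw$end[2])
      if (refine)
        q <- c(snap(q[1], c(inw$start[1], inw$end[1])),
               snap(q[2], c(inw$start[1], inw$end[1])),
               snap(q[3], c(inw$start[2], inw$end[2])),
               snap(q[4], c(inw$start[2], inw$end[2])))
      out[i, 2:5] <- q
      out$flagged[i] <- FALSE
    }
  }
  if (!is.null(manual)) {
    for (j in seq_len(nrow(manual))) {
      i <- match(manual$rep[j], out$rep)
      if (!is.na(i)) {
        out[i, 2:5] <- manual[j, c("q1", "q2", "q3", "q4")]
        out$flagged[i] <- FALSE
      }
    }
  }
  out
}

#' Align the audio clock to the MRI clock
#'
#' Two-stage alignment: the end of the scanner-noise segment is detected
#' by thresholding the envelope (or taken from the recording's logged
#' sequence end), and the known sequence duration subtracted gives the
#' sequence start in audio time; the residual clock offset is then the
#' median difference between the stimulus-generator timestamps (MRI
#' clock) and the same pulses recorded on the TTL channel (audio clock).
#' `t_mri = t_audio - offset`.
#'
#' @param rec an [audio_recording()].
#' @param sequence_duration duration of the imaging sequence, seconds.
#' @param noise_threshold_frac envelope threshold for the noise-ending
#'   detection, as a fraction of the median envelope level.
#' @return list with `offset` (total audio-to-MRI offset), `start`
#'   (sequence start, audio clock), `residual` and `noise_end`.
#' @export
align_audio_to_mri <- function(rec, sequence_duration,
                               noise_threshold_frac = 0.5) {
  stopifnot(inherits(rec, "audio_recording"))
  if (!is.na(rec$sequence_end_time)) {
    noise_end <- rec$sequence_end_time
  } else {
    env <- envelope(rec)
    thr <- noise_threshold_frac * stats::median(env$level)
    idx <- which(env$level > thr)
    if (length(idx) == 0L) stop("no scanner-noise ending found")
    noise_end <- idx[length(idx)] / rec$rate
  }
  start <- noise_end - sequence_duration
  residual <- 0
  nmatch <- min(length(rec$ttl_times), length(rec$generator_times))
  if (nmatch >= 1L)
    residual <- stats::median(rec$ttl_times[seq_len(nmatch)] -
                                (rec$generator_times[seq_len(nmatch)] + start))
  list(offset = start + residual, start = start, residual = residual,
       noise_end = noise_end)
}

#' Short-time Fourier magnitude spectrogram
#'
#' Hann-windowed STFT, 25 ms window / 10 ms hop by default. One-sided
#' frequency axis up to Nyquist.
#'
#' @param rec an [audio_recording()] or numeric samples.
#' @param rate sampling rate when `rec` is a plain vector.
#' @param window,hop analysis window and hop, seconds.
#' @return list `magnitude` (freq x frame), `freqs` (Hz), `times` (s,
#'   frame centers), `window_samples`.
#' @export
audio_spectrogram <- function(rec, rate = NULL, window = 0.025,
                              hop = 0.010) {
  if (inherits(rec, "audio_recording")) {
    x <- rec$samples; rate <- rec$rate
  } else {
    x <- as.numeric(rec)
    if (is.null(rate)) stop("rate required for plain sample vectors")
  }
  n <- round(window * rate)
  h <- max(1L, round(hop * rate))
  if (length(x) < n) x <- c(x, rep(0, n - length(x)))
  starts <- seq(1L, length(x) - n + 1L, by = h)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  frames <- vapply(starts, function(s) x[s:(s + n - 1L)] * win, numeric(n))
  spec <- Mod(stats::mvfft(frames))
  half <- floor(n / 2) + 1L
  list(magnitude = spec[seq_len(half), , drop = FALSE],
       freqs = (seq_len(half) - 1) * rate / n,
       times = (starts - 1 + (n - 1) / 2) / rate,
       window_samples = n)
}

#' Write a recording as 16-bit PCM WAV
#'
#' @param rec an [audio_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "audio_recording"))
  x <- pmin(pmax(rec$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(rec$rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal reader for the files written by [write_wav()].
#'
#' @param path input file.
#' @param ... further arguments passed to [audio_recording()] (TTL and
#'   generator timestamps are not stored in the WAV).
#' @return an [audio_recording()].
#' @export
read_wav <- function(path, ...) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (hdr != "RIFF") stop("not a RIFF/WAV file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAV file")
  rate <- NULL; samples <- NULL
  while (length(tag <- readChar(con, 4)) == 1L && nchar(tag) == 4L) {
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (tag == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only PCM mono supported")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), n = 2, size = 2, endian = "little"))
      if (size > 16) invisible(readBin(con, raw(), n = size - 16L))
    } else if (tag == "data") {
      samples <- readBin(con, integer(), n = size / 2L, size = 2,
                         endian = "little", signed = TRUE) / 32767
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(rate) || is.null(samples)) stop("malformed WAV file")
  audio_recording(samples, rate = rate, ...)
}
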