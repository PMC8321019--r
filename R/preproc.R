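#' Parameters of the pre-registration filtering chain
#'
#' Defaults reproduce the reference filtering configuration: background
#' assumed to be 10% of the maximal intensity, re-thresholding at 10% of
#' the background-subtracted maximum, a 3 x 3 median filter, edge-aware
#' smoothing with edge strength 0.1 and minimal edge distance 3 pixels,
#' and a 5 x 5 Gaussian of radius 5.
#'
#' All intensity thresholds are fractions of per-image maxima, so the
#' whole chain is invariant to positive rescaling of the input.
#'
#' @param background_frac background level as a fraction of `max(I)`.
#' @param threshold_frac low-intensity cut as a fraction of the
#'   background-subtracted maximum.
#' @param median_size side of the square median window (odd).
#' @param edge_strength fraction of the maximal gradient magnitude below
#'   which structure is treated as texture and smoothed away.
#' @param min_edge_distance pixels; edges closer than this are merged
#'   into a single preserved band.
#' @param gaussian_size side of the Gaussian kernel (odd).
#' @param gaussian_radius radius parameter of the Gaussian; the kernel
#'   uses `sigma = gaussian_radius / 3` (common truncation convention).
#' @return an object of class `preproc_params`.
#' @export
preproc_params <- function(background_frac = 0.1, threshold_frac = 0.1,
                           median_size = 3, edge_strength = 0.1,
                           min_edge_distance = 3, gaussian_size = 5,
                           gaussian_radius = 5) {
  if (background_frac < 0 || background_frac >= 1 ||
      threshold_frac < 0 || threshold_frac >= 1)
    stop("fractions must lie in [0, 1)")
  if (median_size %% 2 != 1 || median_size < 1 ||
      gaussian_size %% 2 != 1 || gaussian_size < 1)
    stop("filter sizes must be odd positive integers")
  structure(list(background_frac = background_frac,
                 threshold_frac = threshold_frac,
                 median_size = as.integer(median_size),
                 edge_strength = edge_strength,
                 min_edge_distance = as.integer(min_edge_distance),
                 gaussian_size = as.integer(gaussian_size),
                 gaussian_radius = gaussian_radius),
            class = "preproc_params")
}

#' Background subtraction
#'
#' `I'(x, y) = I(x, y) - background_frac * max(I)`. The result may
#' contain negatives; they are removed by [threshold_low()]. An all-zero
#' image is returned unchanged.
#'
#' @param img numeric matrix of non-negative intensities.
#' @param p a [preproc_params()].
#' @return matrix of the same shape.
#' @export
subtract_background <- function(img, p = preproc_params()) {
  stopifnot(is.matrix(img))
  imax <- max(img)
  if (imax == 0) return(img)
  img - p$background_frac * imax
}

#' Low-intensity thresholding
#'
#' Keeps pixels strictly greater than `threshold_frac * max(I')` and sets
#' all others (including negatives left by background subtraction) to 0.
#' Values exactly at the threshold map to 0: the defining inequalities
#' are both strict, so the tie is resolved conservatively.
#'
#' @param img_prime background-subtracted image.
#' @param p a [preproc_params()].
#' @return matrix of the same shape, non-negative.
#' @export
threshold_low <- function(img_prime, p = preproc_params()) {
  stopifnot(is.matrix(img_prime))
  thr <- p$threshold_frac * max(img_prime)
  out <- img_prime
  out[!(img_prime > thr)] <- 0
  out
}

# reflect-pad a matrix by pr rows / pc cols on each side
.pad_reflect <- function(img, pr, pc = pr) {
  ny <- nrow(img); nx <- ncol(img)
  ri <- c(rev(seq_len(min(pr, ny))), seq_len(ny),
          ny + 1 - seq_len(min(pr, ny)))
  ci <- c(rev(seq_len(min(pc, nx))), seq_len(nx),
          nx + 1 - seq_len(min(pc, nx)))
  img[ri, ci, drop = FALSE]
}

# row-wise k-th order statistic of an n x m matrix via odd-even
# transposition sort across columns: O(m^2) fully vectorized passes
.row_kth <- function(x, k) {
  m <- ncol(x)
  for (pass in seq_len(m)) {
    start <- if (pass %% 2 == 1) 1L else 2L
    j <- seq.int(start, m - 1L, by = 2L)
    for (jj in j) {
      lo <- pmin(x[, jj], x[, jj + 1L])
      x[, jj + 1L] <- pmax(x[, jj], x[, jj + 1L])
      x[, jj] <- lo
    }
  }
  x[, k]
}

#' Square median filter with reflect padding
#'
#' @param img numeric matrix.
#' @param size odd window side.
#' @return filtered matrix, same shape.
#' @export
median_filter <- function(img, size = 3) {
  if (size %% 2 != 1 || size < 1) stop("median size must be odd positive")
  if (size == 1) return(img)
  r <- (size - 1L) / 2L
  ny <- nrow(img); nx <- ncol(img)
  pad <- .pad_reflect(img, r)
  cols <- matrix(0, ny * nx, size * size)
  k <- 1L
  for (dr in 0:(size - 1L)) for (dc in 0:(size - 1L)) {
    cols[, k] <- as.vector(pad[dr + seq_len(ny), dc + seq_len(nx)])
    k <- k + 1L
  }
  matrix(.row_kth(cols, (size * size + 1L) / 2L), ny, nx)
}

#' Gaussian smoothing with reflect padding
#'
#' Separable `size x size` kernel with `sigma = radius / 3`.
#'
#' @param img numeric matrix.
#' @param size odd kernel side.
#' @param radius radius parameter (mapped to `sigma = radius / 3`).
#' @return filtered matrix, same shape.
#' @export
gaussian_filter <- function(img, size = 5, radius = 5) {
  if (size %% 2 != 1 || size < 1) stop("gaussian size must be odd positive")
  r <- (size - 1L) / 2L
  sigma <- radius / 3
  w <- exp(-0.5 * ((-r):r / sigma)^2)
  w <- w / sum(w)
  ny <- nrow(img); nx <- ncol(img)
  pad <- .pad_reflect(img, r)
  tmp <- matrix(0, ny, nx + 2L * r)
  for (i in seq_along(w))
    tmp <- tmp + w[i] * pad[(i - 1L) + seq_len(ny), , drop = FALSE]
  out <- matrix(0, ny, nx)
  for (i in seq_along(w))
    out <- out + w[i] * tmp[, (i - 1L) + seq_len(nx), drop = FALSE]
  out
}

# 3x3 box mean with reflect padding
.box3 <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- .pad_reflect(img, 1L)
  acc <- matrix(0, ny, nx)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + pad[dr + seq_len(ny), dc + seq_len(nx)]
  acc / 9
}

# binary dilation with a square element of half-width r
.dilate <- function(mask, r) {
  if (r < 1) return(mask)
  ny <- nrow(mask); nx <- ncol(mask)
  pad <- .pad_reflect(mask * 1, r)
  acc <- matrix(0, ny, nx)
  for (dr in 0:(2 * r)) for (dc in 0:(2 * r))
    acc <- acc + pad[dr + seq_len(ny), dc + seq_len(nx)]
  acc > 0
}

#' Edge-preserving texture smoothing
#'
#' Interpretation of the "edge strength / minimal edge distance" stage of
#' the filtering chain (the original operator definition is not public):
#' pixels whose gradient magnitude reaches `edge_strength` times the
#' maximal gradient magnitude are declared edges; the edge set is dilated
#' by half `min_edge_distance` so that edges closer than that distance
#' merge into one preserved band; everything else is treated as texture
#' and replaced by a 3 x 3 box mean.
#'
#' @param img numeric matrix.
#' @param edge_strength fraction of the maximal gradient magnitude.
#' @param min_edge_distance pixels.
#' @return filtered matrix, same shape.
#' @export
edge_preserving_filter <- function(img, edge_strength = 0.1,
                                   min_edge_distance = 3) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- .pad_reflect(img, 1L)
  gx <- (pad[1 + seq_len(ny), 2 + seq_len(nx)] -
           pad[1 + seq_len(ny), seq_len(nx)]) / 2
  gy <- (pad[2 + seq_len(ny), 1 + seq_len(nx)] -
           pad[seq_len(ny), 1 + seq_len(nx)]) / 2
  g <- sqrt(gx^2 + gy^2)
  edges <- g >= edge_strength * max(g)
  edges <- .dilate(edges, floor(min_edge_distance / 2))
  sm <- .box3(img)
  out <- sm
  out[edges] <- img[edges]
  out
}

#' Full pre-registration filtering of one frame
#'
#' Applies, in order: background subtraction, low-intensity thresholding,
#' median filtering, edge-preserving texture smoothing and Gaussian
#' smoothing. The chain removes motion-artifact speckle and texture while
#' keeping tissue boundaries, which is what the subsequent registration
#' needs. Output is non-negative, same shape, and bounded by `max(img)`.
#'
#' @param img numeric matrix of non-negative intensities.
#' @param p a [preproc_params()].
#' @return filtered matrix.
#' @export
filter_frame <- function(img, p = preproc_params()) {
  out <- subtract_background(img, p)
  out <- threshold_low(out, p)
  out <- median_filter(out, p$median_size)
  out <- edge_preserving_filter(out, p$edge_strength, p$min_edge_distance)
  gaussian_filter(out, p$gaussian_size, p$gaussian_radius)
}

#' Filter every frame of a series
#'
#' @param series a [frame_series()].
#' @param p a [preproc_params()].
#' @return a [frame_series()] with filtered frames.
#' @export
filter_series <- function(series, p = preproc_params()) {
  stopifnot(inherits(series, "frame_series"))
  out <- series
  for (k in seq_len(dim(series$frames)[3]))
    out$frames[, , k] <- filter_frame(series$frames[, , k], p)
  out
}
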