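#' Parameters of the spatio-temporally regularized registration
#'
#' The displacement field across the whole series is estimated by
#' minimizing `C(u) = S(u) + lambda * R(u)`, where `S` is the sum of
#' squared intensity differences between each warped frame and its
#' successor and `R = ||(Gx, Gy, Gt/v0) ux||^2 + ||(Gx, Gy, Gt/v0) uy||^2`
#' penalizes spatial and temporal roughness of the two displacement
#' components jointly over the space-time grid.
#'
#' @param lam regularization weight `lambda` (0.01 is the value found
#'   optimal against manual labelling in the reference study).
#' @param v0 space/time smoothness ratio in pixels per frame; the time
#'   gradient is scaled by `1/v0`. No reference value exists. The default
#'   5 is of the order of the peak inter-frame tip displacement at
#'   real-time frame rates: much smaller values penalize the genuine
#'   accelerations of the gesture and visibly clip velocity peaks (see
#'   the vignette's sensitivity discussion).
#' @param n_levels multiresolution pyramid levels (x2 spatial
#'   downsampling per level).
#' @param max_iter Gauss-Newton iterations per level.
#' @param tol stop a level when the relative cost decrease falls below
#'   this.
#' @param cg_tol,cg_maxit tolerance and cap of the conjugate-gradient
#'   solver of the Gauss-Newton normal equations.
#' @return an object of class `reg_params`.
#' @export
reg_params <- function(lam = 0.01, v0 = 5, n_levels = 3, max_iter = 20,
                       tol = 1e-4, cg_tol = 1e-6, cg_maxit = 100) {
  if (lam < 0) stop("lam must be non-negative")
  if (v0 <= 0) stop("v0 must be positive")
  if (n_levels < 1) stop("need at least one level")
  structure(list(lam = lam, v0 = v0, n_levels = as.integer(n_levels),
                 max_iter = as.integer(max_iter), tol = tol,
                 cg_tol = cg_tol, cg_maxit = as.integer(cg_maxit)),
            class = "reg_params")
}

# forward-difference operator on n points, replicated (Neumann) boundary:
# rows 1..n-1 are u[i+1]-u[i], row n is zero
.diff_op <- function(n) {
  if (n == 1L)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(1, 1)))
  Matrix::sparseMatrix(i = c(seq_len(n - 1L), seq_len(n - 1L)),
                       j = c(seq_len(n - 1L), seq.int(2L, n)),
                       x = c(rep(-1, n - 1L), rep(1, n - 1L)),
                       dims = c(n, n))
}

#' Sparse gradient operators on the flattened space-time grid
#'
#' First-difference operators along the column (x), row (y) and time
#' directions for displacement fields stored as `ny x nx x nt` arrays
#' flattened column-major. Replicated boundary: the difference at the
#' last sample of each line is zero. Each operator is `N x N` with
#' `N = ny * nx * nt`.
#'
#' @param dims integer `(ny, nx, nt)`.
#' @return list with sparse matrices `Gx`, `Gy`, `Gt`.
#' @export
build_gradients <- function(dims) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  ny <- dims[1]; nx <- dims[2]; nt <- dims[3]
  iy <- Matrix::Diagonal(ny); ix <- Matrix::Diagonal(nx)
  it <- Matrix::Diagonal(nt)
  list(Gx = it %x% .diff_op(nx) %x% iy,
       Gy = it %x% ix %x% .diff_op(ny),
       Gt = .diff_op(nt) %x% ix %x% iy)
}

# bilinear sampling of a matrix at 0-based (r, c), coordinates clamped to
# the image domain (edge replication outside)
.bilinear <- function(img, r, c) {
  ny <- nrow(img); nx <- ncol(img)
  r <- pmin(pmax(as.vector(r), 0), ny - 1)
  c <- pmin(pmax(as.vector(c), 0), nx - 1)
  i0 <- pmin(floor(r), ny - 2L); j0 <- pmin(floor(c), nx - 2L)
  if (ny == 1L) i0 <- rep(0L, length(r))
  if (nx == 1L) j0 <- rep(0L, length(c))
  fr <- r - i0; fc <- c - j0
  i1 <- pmin(i0 + 1L, ny - 1L); j1 <- pmin(j0 + 1L, nx - 1L)
  v00 <- img[cbind(i0 + 1L, j0 + 1L)]; v10 <- img[cbind(i1 + 1L, j0 + 1L)]
  v01 <- img[cbind(i0 + 1L, j1 + 1L)]; v11 <- img[cbind(i1 + 1L, j1 + 1L)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# squared norms of the forward differences of a ny x nx x nt array,
# identical to ||G. a||^2 with the operators of build_gradients
.rough_sq <- function(a, v0) {
  d <- dim(a)
  sx <- if (d[2] > 1) sum((a[, -1, , drop = FALSE] -
                             a[, -d[2], , drop = FALSE])^2) else 0
  sy <- if (d[1] > 1) sum((a[-1, , , drop = FALSE] -
                             a[-d[1], , , drop = FALSE])^2) else 0
  st <- if (d[3] > 1) sum((a[, , -1, drop = FALSE] -
                             a[, , -d[3], drop = FALSE])^2) else 0
  sx + sy + st / v0^2
}

#' Registration cost and its breakdown
#'
#' `C(u) = S(u) + lambda * R(u)`: `S` sums squared differences between
#' each source frame and its successor warped back by the transition's
#' displacement (`residual_k = I_{k+1}(p + u_k(p)) - I_k(p)`, so `u_k`
#' is the forward motion of the pixel at `p` between frames `k` and
#' `k+1`); `R` is the squared norm of the stacked spatial and (scaled)
#' temporal first differences of both displacement components.
#'
#' @param u displacement field: list with arrays `ux`, `uy` of dims
#'   `ny x nx x (nframes - 1)`.
#' @param frames a [frame_series()] (or plain `ny x nx x nf` array).
#' @param p a [reg_params()].
#' @return list with `total`, `similarity`, `regularity`
#'   (`total = similarity + lam * regularity`).
#' @export
reg_cost <- function(u, frames, p = reg_params()) {
  a <- if (inherits(frames, "frame_series")) frames$frames else frames
  d <- dim(a)
  nt <- d[3] - 1L
  if (!identical(dim(u$ux), c(d[1], d[2], nt)) ||
      !identical(dim(u$uy), c(d[1], d[2], nt)))
    stop("displacement dims must be ny x nx x (nframes - 1)")
  ny <- d[1]; nx <- d[2]
  r0 <- matrix(seq_len(ny) - 1, ny, nx)
  c0 <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx)
  sim <- 0
  for (k in seq_len(nt)) {
    w <- .bilinear(a[, , k + 1L], r0 + u$uy[, , k], c0 + u$ux[, , k])
    sim <- sim + sum((w - as.vector(a[, , k]))^2)
  }
  reg <- .rough_sq(u$ux, p$v0) + .rough_sq(u$uy, p$v0)
  list(total = sim + p$lam * reg, similarity = sim, regularity = reg)
}

# Gram matrix of the stacked gradient operators,
# Gx'Gx + Gy'Gy + Gt'Gt / v0^2, assembled as a Kronecker sum
.ltl <- function(dims, v0) {
  ny <- dims[1]; nx <- dims[2]; nt <- dims[3]
  ay <- Matrix::crossprod(.diff_op(ny))
  ax <- Matrix::crossprod(.diff_op(nx))
  at <- Matrix::crossprod(.diff_op(nt))
  iy <- Matrix::Diagonal(ny); ix <- Matrix::Diagonal(nx)
  it <- Matrix::Diagonal(nt)
  (it %x% ix %x% ay) + (it %x% ax %x% iy) + (at %x% ix %x% iy) / v0^2
}

# block-mean 2x downsampling of every frame (trailing odd row/col dropped)
.downsample2 <- function(a) {
  d <- dim(a)
  ny <- d[1] %/% 2L; nx <- d[2] %/% 2L
  i <- seq_len(2L * ny); j <- seq_len(2L * nx)
  a <- a[i, j, , drop = FALSE]
  (a[seq(1, 2 * ny, 2), seq(1, 2 * nx, 2), , drop = FALSE] +
     a[seq(2, 2 * ny, 2), seq(1, 2 * nx, 2), , drop = FALSE] +
     a[seq(1, 2 * ny, 2), seq(2, 2 * nx, 2), , drop = FALSE] +
     a[seq(2, 2 * ny, 2), seq(2, 2 * nx, 2), , drop = FALSE]) / 4
}

# bilinear spatial resize of a ny x nx x nt array to (ty, tx)
.resize_stack <- function(a, ty, tx) {
  d <- dim(a)
  rr <- if (ty > 1) (seq_len(ty) - 1) * (d[1] - 1) / (ty - 1) else 0
  cc <- if (tx > 1) (seq_len(tx) - 1) * (d[2] - 1) / (tx - 1) else 0
  r <- matrix(rr, ty, tx); c <- matrix(rep(cc, each = ty), ty, tx)
  out <- array(0, c(ty, tx, d[3]))
  for (k in seq_len(d[3]))
    out[, , k] <- matrix(.bilinear(a[, , k], as.vector(r), as.vector(c)),
                         ty, tx)
  out
}

# preconditioned conjugate gradients for the SPD Gauss-Newton system
.pcg <- function(matvec, b, minv, tol, maxit) {
  x <- numeric(length(b))
  r <- b
  z <- minv * r
  p <- z
  rz <- sum(r * z)
  b2 <- sqrt(sum(b * b))
  if (b2 == 0) return(x)
  for (it in seq_len(maxit)) {
    ap <- matvec(p)
    alpha <- rz / sum(p * ap)
    x <- x + alpha * p
    r <- r - alpha * ap
    if (sqrt(sum(r * r)) <= tol * b2) break
    z <- minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}

# one level of Gauss-Newton on pre-built pyramid frames; u modified in
# place semantics via return. Line search keeps the cost non-increasing.
.gn_level <- function(a, u, p) {
  d <- dim(a); ny <- d[1]; nx <- d[2]; nt <- d[3] - 1L
  n <- ny * nx * nt
  ltl <- .ltl(c(ny, nx, nt), p$v0)
  dltl <- Matrix::diag(ltl)
  r0 <- matrix(seq_len(ny) - 1, ny, nx)
  c0 <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx)

  cost_u <- function(u) reg_cost(u, a, p)$total
  c_zero <- cost_u(list(ux = array(0, c(ny, nx, nt)),
                        uy = array(0, c(ny, nx, nt))))
  c_cur <- cost_u(u)
  if (c_cur > c_zero) {     # coarse initialization made things worse
    u <- list(ux = array(0, c(ny, nx, nt)), uy = array(0, c(ny, nx, nt)))
    c_cur <- c_zero
  }
  converged <- FALSE
  trace <- c_cur
  for (it in seq_len(p$max_iter)) {
    res <- numeric(n); jx <- numeric(n); jy <- numeric(n)
    for (k in seq_len(nt)) {
      tgt <- a[, , k + 1L]
      rw <- r0 + u$uy[, , k]; cw <- c0 + u$ux[, , k]
      w <- matrix(.bilinear(tgt, as.vector(rw), as.vector(cw)), ny, nx)
      idx <- (k - 1L) * ny * nx + seq_len(ny * nx)
      res[idx] <- as.vector(w - a[, , k])
      gpad <- .pad_reflect(w, 1L)
      jy[idx] <- as.vector((gpad[2 + seq_len(ny), 1 + seq_len(nx)] -
                              gpad[seq_len(ny), 1 + seq_len(nx)]) / 2)
      jx[idx] <- as.vector((gpad[1 + seq_len(ny), 2 + seq_len(nx)] -
                              gpad[1 + seq_len(ny), seq_len(nx)]) / 2)
    }
    uxv <- as.vector(u$ux); uyv <- as.vector(u$uy)
    lam <- p$lam
    eps <- 1e-9 * (mean(jx^2 + jy^2) + 1)
    rhs <- -c(jx * res + lam * as.vector(ltl %*% uxv),
              jy * res + lam * as.vector(ltl %*% uyv))
    matvec <- function(v) {
      vx <- v[seq_len(n)]; vy <- v[n + seq_len(n)]
      c(jx * jx * vx + jx * jy * vy + lam * as.vector(ltl %*% vx) + eps * vx,
        jx * jy * vx + jy * jy * vy + lam * as.vector(ltl %*% vy) + eps * vy)
    }
    minv <- 1 / c(jx * jx + lam * dltl + eps, jy * jy + lam * dltl + eps)
    step <- .pcg(matvec, rhs, minv, p$cg_tol, p$cg_maxit)
    sx <- array(step[seq_len(n)], c(ny, nx, nt))
    sy <- array(step[n + seq_len(n)], c(ny, nx, nt))
    accepted <- FALSE
    alpha <- 1
    for (ls in 1:6) {
      cand <- list(ux = u$ux + alpha * sx, uy = u$uy + alpha * sy)
      c_new <- cost_u(cand)
      if (c_new <= c_cur) { accepted <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!accepted) break
    u <- cand
    trace <- c(trace, c_new)
    if ((c_cur - c_new) <= p$tol * max(c_cur, .Machine$double.eps)) {
      c_cur <- c_new
      converged <- TRUE
      break
    }
    c_cur <- c_new
  }
  list(u = u, cost = c_cur, converged = converged, trace = trace)
}

#' Estimate the displacement field of a frame series
#'
#' Minimizes the spatio-temporally regularized sum-of-squared-differences
#' cost with a multiresolution Gauss-Newton scheme: the normal equations
#' (image-gradient Jacobian plus the gradient-operator Gram matrix) are
#' solved by preconditioned conjugate gradients at each iteration, a
#' back-tracking line search keeps the cost non-increasing, and coarse
#' solutions are bilinearly upsampled (displacements rescaled) to
#' initialize finer levels. The returned field never has a higher cost
#' than the zero field.
#'
#' @param frames a [frame_series()] (>= 2 frames); typically pre-filtered
#'   with [filter_series()], though raw input is accepted.
#' @param p a [reg_params()].
#' @return an object of class `displacement_field`: arrays `ux`, `uy`
#'   (`ny x nx x (nf - 1)`, pixel units, forward motion between
#'   consecutive frames), frame `times`, the final `cost` breakdown, a
#'   `converged` flag (with a warning when an iteration cap was hit).
#' @export
register_series <- function(frames, p = reg_params()) {
  stopifnot(inherits(frames, "frame_series"))
  a <- frames$frames
  d <- dim(a)
  if (d[3] < 2L) stop("need at least two frames")
  nt <- d[3] - 1L

  pyramid <- list(a)
  lev_ok <- 1L
  for (l in seq_len(p$n_levels - 1L)) {
    top <- pyramid[[l]]
    if (dim(top)[1] < 8L || dim(top)[2] < 8L) break
    pyramid[[l + 1L]] <- .downsample2(top)
    lev_ok <- l + 1L
  }
  u <- NULL
  converged <- TRUE
  for (l in rev(seq_len(lev_ok))) {
    al <- pyramid[[l]]
    dl <- dim(al)
    if (is.null(u)) {
      u <- list(ux = array(0, c(dl[1], dl[2], nt)),
                uy = array(0, c(dl[1], dl[2], nt)))
    } else {
      ry <- dl[1] / dim(u$ux)[1]; rx <- dl[2] / dim(u$ux)[2]
      u <- list(ux = .resize_stack(u$ux, dl[1], dl[2]) * rx,
                uy = .resize_stack(u$uy, dl[1], dl[2]) * ry)
    }
    fit <- .gn_level(al, u, p)
    u <- fit$u
    if (l == 1L) converged <- fit$converged
  }
  if (!converged)
    warning("registration stopped at max_iter before meeting tol; ",
            "returning best iterate")
  structure(list(ux = u$ux, uy = u$uy, times = frames$times,
                 cost = reg_cost(u, a, p), converged = converged,
                 params = p),
            class = "displacement_field")
}

#' @exportS3Method base::print
print.displacement_field <- function(x, ...) {
  d <- dim(x$ux)
  cat(sprintf("<displacement_field> %d x %d px, %d transitions, cost %.6g%s\n",
              d[1], d[2], d[3], x$cost$total,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Propagate a point through a displacement field
#'
#' Starting from a (sub-pixel) position in the first frame, each
#' transition adds the bilinearly interpolated displacement at the
#' current position. Positions are clipped to the image bounds; clipping
#' sets a flag on the returned trajectory.
#'
#' @param start numeric `(row, col)`, 0-based, inside the image.
#' @param field a [register_series()] result (or a list with `ux`, `uy`
#'   arrays and optional `times`).
#' @param times frame timestamps; defaults to those stored in `field`.
#' @return a [tracked_trajectory()] with one point per frame.
#' @export
propagate_point <- function(start, field, times = field$times) {
  d <- dim(field$ux)
  ny <- d[1]; nx <- d[2]; nt <- d[3]
  if (start[1] < 0 || start[1] > ny - 1 || start[2] < 0 ||
      start[2] > nx - 1)
    stop("start point outside image bounds")
  if (is.null(times)) times <- seq_len(nt + 1L) - 1
  pts <- matrix(0, nt + 1L, 2L)
  pts[1L, ] <- start
  clipped <- FALSE
  for (k in seq_len(nt)) {
    pcur <- pts[k, ]
    dx <- .bilinear(field$ux[, , k], pcur[1], pcur[2])
    dy <- .bilinear(field$uy[, , k], pcur[1], pcur[2])
    nxt <- c(pcur[1] + dy, pcur[2] + dx)
    cl <- c(min(max(nxt[1], 0), ny - 1), min(max(nxt[2], 0), nx - 1))
    if (any(cl != nxt)) clipped <- TRUE
    pts[k + 1L, ] <- cl
  }
  tracked_trajectory(pts, times, clipped = clipped)
}

#' Average repeated manual annotations
#'
#' Repeatedly annotated trajectories (e.g. a tongue tip selected several
#' times to reduce labelling subjectivity) are combined by the
#' coordinate-wise mean per frame. Any number of annotations >= 1 is
#' accepted.
#'
#' @param annotations list of [tracked_trajectory()] with identical times.
#' @return a [tracked_trajectory()].
#' @export
average_annotations <- function(annotations) {
  stopifnot(length(annotations) >= 1L)
  nfr <- nrow(annotations[[1L]]$points)
  tms <- annotations[[1L]]$times
  for (a in annotations) {
    if (nrow(a$points) != nfr) stop("annotations have mismatched lengths")
    if (max(abs(a$times - tms)) > 1e-12) stop("annotations have mismatched times")
  }
  acc <- Reduce(`+`, lapply(annotations, function(a) a$points))
  tracked_trajectory(acc / length(annotations), tms,
                     clipped = any(vapply(annotations, function(a) a$clipped,
                                          logical(1))))
}
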