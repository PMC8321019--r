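# Small phantom specs shared across test files. The tiny spec keeps the
# trajectory identical to the default (same period, speeds, closures) but
# shrinks the imaging problem so module tests stay fast; full-size runs
# live in test-acceptance.R only.
tiny_spec <- function(...) {
  args <- list(n_cycles = 1, image_shape = c(32, 32), fov = 48,
               noise_sd = 0, n_frames_pc = 20)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}

# scalar-loop bilinear sampling with clamping, independent of the
# package's vectorized implementation (oracle helper)
naive_bilinear <- function(img, r, c) {
  ny <- nrow(img); nx <- ncol(img)
  r <- min(max(r, 0), ny - 1); c <- min(max(c, 0), nx - 1)
  i0 <- min(floor(r), ny - 2); j0 <- min(floor(c), nx - 2)
  if (ny == 1) i0 <- 0
  if (nx == 1) j0 <- 0
  fr <- r - i0; fc <- c - j0
  i1 <- min(i0 + 1, ny - 1); j1 <- min(j0 + 1, nx - 1)
  (1 - fr) * (1 - fc) * img[i0 + 1, j0 + 1] +
    fr * (1 - fc) * img[i1 + 1, j0 + 1] +
    (1 - fr) * fc * img[i0 + 1, j1 + 1] +
    fr * fc * img[i1 + 1, j1 + 1]
}

# brute-force registration cost: scalar loops straight from the model
# definition (warped SSD + squared forward differences, time scaled)
naive_reg_cost <- function(ux, uy, frames, lam, v0) {
  d <- dim(frames)
  ny <- d[1]; nx <- d[2]; nt <- d[3] - 1
  sim <- 0
  for (k in seq_len(nt)) for (i in seq_len(ny)) for (j in seq_len(nx)) {
    w <- naive_bilinear(frames[, , k + 1],
                        (i - 1) + uy[i, j, k], (j - 1) + ux[i, j, k])
    sim <- sim + (w - frames[i, j, k])^2
  }
  rough <- function(a) {
    s <- 0
    for (k in seq_len(nt)) for (i in seq_len(ny)) for (j in seq_len(nx)) {
      if (j < nx) s <- s + (a[i, j + 1, k] - a[i, j, k])^2
      if (i < ny) s <- s + (a[i + 1, j, k] - a[i, j, k])^2
      if (k < nt) s <- s + (a[i, j, k + 1] - a[i, j, k])^2 / v0^2
    }
    s
  }
  reg <- rough(ux) + rough(uy)
  list(total = sim + lam * reg, similarity = sim, regularity = reg)
}
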