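test_that("gradient operators: nullspaces and hand-computed differences", {
  dims <- c(2, 3, 2)
  g <- build_gradients(dims)
  n <- prod(dims)
  expect_equal(dim(g$Gx), c(n, n))
  # constant along x -> Gx annihilates; constant in time -> Gt annihilates
  f_x_const <- as.vector(array(rep(1:2, 3 * 2), dims))
  expect_equal(as.vector(g$Gx %*% f_x_const), rep(0, n))
  f_t_const <- as.vector(array(rep(1:6, 2), dims))
  expect_equal(as.vector(g$Gt %*% f_t_const), rep(0, n))
  # forward differences with replicated boundary on a 1 x 3 x 1 line
  g2 <- build_gradients(c(1, 3, 1))
  expect_equal(as.vector(g2$Gx %*% c(1, 2, 4)), c(1, 2, 0))
  # operator Gram matrix matches the direct roughness computation
  set.seed(5)
  a <- array(rnorm(n), dims)
  lhs <- sum((g$Gx %*% as.vector(a))^2) + sum((g$Gy %*% as.vector(a))^2) +
    sum((g$Gt %*% as.vector(a))^2) / 4
  expect_equal(lhs, articuvel:::.rough_sq(a, 2), tolerance = 1e-12)
})

test_that("cost: exact minimum, zero-field decomposition, brute-force oracle", {
  set.seed(21)
  p <- reg_params(lam = 0.03, v0 = 1.7)
  ident <- array(rep(matrix(runif(16), 4, 4), 3), c(4, 4, 3))
  z <- list(ux = array(0, c(4, 4, 2)), uy = array(0, c(4, 4, 2)))
  expect_equal(reg_cost(z, ident, p)$total, 0)

  frames <- array(runif(48), c(4, 4, 3))
  c0 <- reg_cost(z, frames, p)
  expect_equal(c0$regularity, 0)
  expect_equal(c0$similarity,
               sum((frames[, , 2] - frames[, , 1])^2) +
                 sum((frames[, , 3] - frames[, , 2])^2))

  u <- list(ux = array(rnorm(32, sd = 0.7), c(4, 4, 2)),
            uy = array(rnorm(32, sd = 0.7), c(4, 4, 2)))
  got <- reg_cost(u, frames, p)
  ref <- naive_reg_cost(u$ux, u$uy, frames, p$lam, p$v0)
  expect_equal(got$total, ref$total, tolerance = 1e-10)
  expect_equal(got$similarity, ref$similarity, tolerance = 1e-10)
  expect_equal(got$total, got$similarity + p$lam * got$regularity,
               tolerance = 1e-9)
  expect_error(reg_cost(z, frames[, , 1:2], p), "dims")
})

test_that("registration: static series, known translation, cost bound", {
  ny <- 32; nx <- 32
  g <- function(r0, c0) outer(0:(ny - 1), 0:(nx - 1), function(r, c)
    exp(-((r - r0)^2 + (c - c0)^2) / 18))
  f1 <- g(15, 14)
  # static series -> essentially zero field
  fs0 <- frame_series(array(rep(f1, 3), c(ny, nx, 3)), (0:2) * 0.02, 1.5)
  fld0 <- register_series(fs0, reg_params())
  expect_lt(max(abs(fld0$ux)), 0.05)
  expect_lt(max(abs(fld0$uy)), 0.05)
  # global 1-pixel x-translation of a smooth blob
  fs1 <- frame_series(array(c(f1, g(15, 15)), c(ny, nx, 2)), c(0, 0.02), 1.5)
  fld1 <- register_series(fs1, reg_params())
  blob <- f1 > 0.3
  expect_lt(abs(mean(fld1$ux[, , 1][blob]) - 1), 0.1)
  expect_lt(abs(mean(fld1$uy[, , 1][blob])), 0.1)
  # the returned field never costs more than the zero field
  set.seed(9)
  noisy <- frame_series(array(runif(8 * 8 * 3), c(8, 8, 3)), 0:2, 1)
  p <- reg_params(n_levels = 1)
  fldn <- suppressWarnings(register_series(noisy, p))
  z <- list(ux = array(0, c(8, 8, 2)), uy = array(0, c(8, 8, 2)))
  expect_lte(fldn$cost$total, reg_cost(z, noisy, p)$total)
})

test_that("stronger regularization does not increase solution roughness", {
  ny <- 24
  g <- function(c0) outer(0:(ny - 1), 0:(ny - 1), function(r, c)
    exp(-((r - 11)^2 + (c - c0)^2) / 12))
  fs <- frame_series(array(c(g(10), g(11.5), g(12.5)), c(ny, ny, 3)),
                     (0:2) * 0.02, 1.5)
  r1 <- suppressWarnings(register_series(fs, reg_params(lam = 0.01)))$cost$regularity
  r2 <- suppressWarnings(register_series(fs, reg_params(lam = 0.1)))$cost$regularity
  expect_lte(r2, r1 + 1e-9)
})

test_that("point propagation: accumulation, interpolation, clipping", {
  z <- list(ux = array(0, c(20, 20, 3)), uy = array(0, c(20, 20, 3)),
            times = (0:3) * 0.1)
  expect_equal(propagate_point(c(5, 5), z)$points,
               matrix(5, 4, 2, dimnames = list(NULL, c("row", "col"))))
  # uniform (u_x = 2, u_y = 0) over 3 transitions: column shifts by 6
  u <- list(ux = array(2, c(20, 20, 3)), uy = array(0, c(20, 20, 3)),
            times = (0:3) * 0.1)
  tj <- propagate_point(c(10, 10), u)
  expect_equal(unname(tj$points[4, ]), c(10, 16))
  # bilinear interpolation of the field at a sub-pixel position
  ux <- array(0, c(20, 20, 1)); ux[11, , 1] <- 1; ux[12, , 1] <- 3
  ub <- list(ux = ux, uy = array(0, c(20, 20, 1)), times = c(0, 1))
  step <- propagate_point(c(10.5, 10), ub)$points[2, 2] - 10
  expect_equal(unname(step), 2)
  # clipping flags and bounds
  ubig <- list(ux = array(30, c(20, 20, 1)), uy = array(0, c(20, 20, 1)),
               times = c(0, 1))
  tj2 <- propagate_point(c(10, 10), ubig)
  expect_true(tj2$clipped)
  expect_equal(unname(tj2$points[2, 2]), 19)
  expect_error(propagate_point(c(-1, 5), z), "bounds")
})

test_that("translation equivariance of tracking (interior region)", {
  ny <- 24
  g <- function(r0, c0) outer(0:(ny - 1), 0:(ny - 1), function(r, c)
    exp(-((r - r0)^2 + (c - c0)^2) / 10))
  mk <- function(dr, dc) frame_series(
    array(c(g(10 + dr, 10 + dc), g(11 + dr, 11 + dc)), c(ny, ny, 2)),
    c(0, 1), 1)
  p <- reg_params(n_levels = 2)
  t1 <- propagate_point(c(10, 10), register_series(mk(0, 0), p))
  t2 <- propagate_point(c(13, 12), register_series(mk(3, 2), p))
  expect_equal(unname(t2$points[2, ] - c(3, 2)), unname(t1$points[2, ]),
               tolerance = 0.05)
})

test_that("manual annotations average coordinate-wise", {
  mk <- function(o) tracked_trajectory(cbind(c(0, 1), c(0, o)), c(0, 1))
  a <- list(mk(0), mk(3), mk(6))
  avg <- average_annotations(a)
  expect_equal(unname(avg$points[2, ]), c(1, 3))
  expect_equal(unname(average_annotations(a[1:2])$points[2, 2]), 1.5)
  expect_identical(average_annotations(list(mk(2)))$points, mk(2)$points)
  short <- tracked_trajectory(cbind(0, 0), 0)
  expect_error(average_annotations(list(mk(0), short)), "length")
})
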