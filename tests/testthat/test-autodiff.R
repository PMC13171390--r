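# The compiled kernels and tape against central finite differences.

linear_readout_grad <- function(build, x, wts) {
  sgbnet:::tape_reset()
  xt <- sgbnet:::nn_tensor(x, requires_grad = TRUE)
  out <- build(xt)
  s <- sgbnet:::record(array(sum(out$v * wts), c(1, 1, 1, 1)), list(out),
                       function(g) list(array(as.numeric(g) * wts, dim(out$v))))
  sgbnet:::nn_backward(s)
  xt$g
}

test_that("convolution gradients match finite differences for both strides", {
  set.seed(42)
  for (stride in c(1L, 2L)) {
    x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
    w <- array(rnorm(3 * 3 * 2 * 3, sd = .5), c(3, 3, 2, 3))
    b <- rnorm(3)
    wt <- sgbnet:::nn_tensor(w, TRUE)
    bt <- sgbnet:::nn_tensor(b, TRUE)
    y0 <- sgbnet:::cpp_conv2d_fwd(x, dim(x), w, dim(w), b, stride)
    wts <- array(rnorm(length(y0)), dim(y0))
    gx <- linear_readout_grad(function(xt) sgbnet:::op_conv(xt, wt, bt, stride),
                              x, wts)
    f <- function(xx) sum(sgbnet:::cpp_conv2d_fwd(xx, dim(x), w, dim(w), b, stride) * wts)
    expect_lt(max(abs(gx - numeric_gradient(f, x))), 1e-6)
    fw <- function(ww) sum(sgbnet:::cpp_conv2d_fwd(x, dim(x), ww, dim(w), b, stride) * wts)
    expect_lt(max(abs(wt$g - numeric_gradient(fw, w))), 1e-6)
    fb <- function(bb) sum(sgbnet:::cpp_conv2d_fwd(x, dim(x), w, dim(w), bb, stride) * wts)
    expect_lt(max(abs(bt$g - numeric_gradient(fb, b))), 1e-6)
  }
})

test_that("pooling and bilinear resize gradients match finite differences", {
  set.seed(7)
  x <- array(sample(seq_len(5 * 6 * 2 * 2)) + 0, c(5, 6, 2, 2))
  y0 <- sgbnet:::cpp_maxpool2_fwd(x, dim(x))$y
  wts <- array(rnorm(length(y0)), dim(y0))
  gx <- linear_readout_grad(sgbnet:::op_maxpool2, x, wts)
  f <- function(xx) sum(sgbnet:::cpp_maxpool2_fwd(xx, dim(x))$y * wts)
  expect_lt(max(abs(gx - numeric_gradient(f, x))), 1e-6)

  for (os in list(c(9L, 11L), c(3L, 2L))) {
    x <- array(rnorm(5 * 6 * 2 * 2), c(5, 6, 2, 2))
    y0 <- sgbnet:::cpp_resize_bilinear_fwd(x, dim(x), os[1], os[2])
    wts <- array(rnorm(length(y0)), dim(y0))
    gx <- linear_readout_grad(function(xt) sgbnet:::op_resize(xt, os[1], os[2]),
                              x, wts)
    f <- function(xx) sum(sgbnet:::cpp_resize_bilinear_fwd(xx, dim(x), os[1], os[2]) * wts)
    expect_lt(max(abs(gx - numeric_gradient(f, x))), 1e-6)
  }
})

test_that("batch-norm training-mode gradients match finite differences", {
  set.seed(11)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  gam <- runif(3, .5, 1.5)
  bet <- rnorm(3)
  mkst <- function() {
    st <- new.env()
    st$running_mean <- rep(0, 3)
    st$running_var <- rep(1, 3)
    st
  }
  gt <- sgbnet:::nn_tensor(gam, TRUE)
  bt <- sgbnet:::nn_tensor(bet, TRUE)
  wts <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  gx <- linear_readout_grad(function(xt)
    sgbnet:::op_bn(xt, gt, bt, mkst(), training = TRUE), x, wts)
  fwd <- function(xx, gg, bb) sgbnet:::no_grad(
    sum(sgbnet:::op_bn(sgbnet:::nn_tensor(xx), sgbnet:::nn_tensor(gg),
                       sgbnet:::nn_tensor(bb), mkst(), TRUE)$v * wts))
  expect_lt(max(abs(gx - numeric_gradient(function(xx) fwd(xx, gam, bet), x))), 1e-5)
  expect_lt(max(abs(gt$g - numeric_gradient(function(gg) fwd(x, gg, bet), gam))), 1e-5)
  expect_lt(max(abs(bt$g - numeric_gradient(function(bb) fwd(x, gam, bb), bet))), 1e-5)
})

test_that("loss gradients match finite differences", {
  set.seed(3)
  p <- array(runif(16, .05, .95), c(4, 4, 1, 1))
  tg <- array(rbinom(16, 1, .4), c(4, 4, 1, 1))
  cases <- list(
    focal = list(
      build = function(xt) sgbnet:::op_focal(xt, tg, 0.25, 2),
      f = function(xx) sgbnet:::no_grad(
        as.numeric(sgbnet:::op_focal(sgbnet:::nn_tensor(xx), tg, 0.25, 2)$v))),
    dice = list(
      build = function(xt) sgbnet:::op_dice_loss(xt, tg),
      f = function(xx) sgbnet:::no_grad(
        as.numeric(sgbnet:::op_dice_loss(sgbnet:::nn_tensor(xx), tg)$v))),
    bce = list(
      build = function(xt) sgbnet:::op_bce(xt, tg),
      f = function(xx) sgbnet:::no_grad(
        as.numeric(sgbnet:::op_bce(sgbnet:::nn_tensor(xx), tg)$v))))
  for (cs in cases) {
    gx <- linear_readout_grad(cs$build, p, array(1, c(1, 1, 1, 1)))
    expect_lt(max(abs(gx - numeric_gradient(cs$f, p))), 1e-5)
  }
})

test_that("channel-broadcast and global-pool ops agree with dense equivalents", {
  set.seed(9)
  x <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  d <- array(rnorm(3 * 2), c(1, 1, 3, 2))
  got <- sgbnet:::no_grad(
    sgbnet:::op_mul_cbcast(sgbnet:::nn_tensor(d), sgbnet:::nn_tensor(x)))$v
  want <- x
  for (n in 1:2) for (c in 1:3) want[, , c, n] <- x[, , c, n] * d[1, 1, c, n]
  expect_equal(got, want)
  gap <- sgbnet:::no_grad(sgbnet:::op_gap(sgbnet:::nn_tensor(x)))$v
  gmp <- sgbnet:::no_grad(sgbnet:::op_gmp(sgbnet:::nn_tensor(x)))$v
  for (n in 1:2) for (c in 1:3) {
    expect_equal(gap[1, 1, c, n], mean(x[, , c, n]))
    expect_equal(gmp[1, 1, c, n], max(x[, , c, n]))
  }
})
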