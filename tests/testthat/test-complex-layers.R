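test_that("complex_conv2d implements true complex multiply-accumulate", {
  # closed-form 1x1 instances
  x <- array(2 + 1i, c(1, 1, 1))
  k <- complex_kernel(array(1 + 1i, c(1, 1, 1, 1)))
  expect_equal(as.vector(complex_conv2d(x, k)), 1 + 3i)

  # identity kernel passes the input through
  k_id <- complex_kernel(array(1 + 0i, c(1, 1, 1, 1)))
  xr <- array(rcomplex(24), c(4, 3, 2))
  k_id2 <- complex_kernel(array(c(1, 0, 0, 1) + 0i, c(1, 1, 2, 2)))
  expect_equal(complex_conv2d(xr, k_id2), xr)

  # purely real input and kernel stay real
  set.seed(1)
  xr <- array(rnorm(36) + 0i, c(3, 4, 3))
  kr <- complex_kernel(array(rnorm(3 * 3 * 3 * 2) + 0i, c(3, 3, 3, 2)))
  expect_equal(max(abs(Im(complex_conv2d(xr, kr)))), 0)
})

test_that("complex_conv2d matches the brute-force oracle on random instances", {
  set.seed(99)
  for (trial in 1:200) {
    H <- sample(1:5, 1); W <- sample(1:5, 1)
    Ci <- sample(1:2, 1); Co <- sample(1:2, 1)
    s <- sample(1:2, 1)
    kk <- sample(c(1, 3), 1)
    if (kk > 1 && (H < 1 || W < 1)) kk <- 1
    x <- array(rcomplex(H * W * Ci), c(H, W, Ci))
    w <- array(rcomplex(kk * kk * Ci * Co), c(kk, kk, Ci, Co))
    b <- rcomplex(Co)
    got <- complex_conv2d(x, complex_kernel(w, b), stride = c(s, s))
    want <- brute_conv2d(x, w, b, s)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("convolutions reject mismatched shapes with a useful message", {
  x <- array(0i, c(4, 4, 3))
  k <- complex_kernel(array(0i, c(3, 3, 2, 4)))
  expect_error(complex_conv2d(x, k), "channel count 3.*c_in 2")
  expect_error(complex_conv2d(x, complex_kernel(array(0i, c(3, 3, 3, 2))),
                              stride = c(3, 3)), "stride")
  expect_error(complex_transposed_conv2d(x, k), "channel count")
})

test_that("complex_transposed_conv2d doubles the grid and matches conv on 1x1", {
  set.seed(7)
  x <- array(rcomplex(5 * 3 * 2), c(5, 3, 2))
  k <- complex_kernel(array(rcomplex(9 * 2 * 4), c(3, 3, 2, 4)), rcomplex(4))
  y <- complex_transposed_conv2d(x, k)
  expect_identical(dim(y), c(10L, 6L, 4L))

  # zero input -> bias only
  y0 <- complex_transposed_conv2d(array(0i, c(5, 3, 2)), k)
  for (co in 1:4) expect_true(all(y0[, , co] == k$bias[co]))

  # degenerate 1x1 input, 1x1 kernel: same value as a stride-1 convolution
  x1 <- array(rcomplex(2), c(1, 1, 2))
  k1 <- complex_kernel(array(rcomplex(2 * 3), c(1, 1, 2, 3)), rcomplex(3))
  yt <- complex_transposed_conv2d(x1, k1)
  yc <- complex_conv2d(x1, k1)
  expect_equal(yt[1, 1, ], yc[1, 1, ], tolerance = 1e-12)
})

test_that("modrelu matches the closed form and preserves phase", {
  expect_equal(modrelu(3 + 4i, -1), 2.4 + 3.2i, tolerance = 1e-12)
  expect_equal(modrelu(1 + 0i, 0), 1 + 0i)
  # clamp below the bias
  z <- 0.3 * exp(1i * seq(0, 2 * pi, length.out = 17))
  expect_true(all(modrelu(z, -0.5) == 0))
  expect_equal(modrelu(0i, 1), 0 + 0i)  # defined as 0 at the origin

  set.seed(2)
  z <- rcomplex(1e5)
  m <- Mod(z); b <- -0.4
  want <- ifelse(m + b > 0, (m + b) * z / m, 0)
  expect_lt(max(abs(modrelu(z, b) - want)), 1e-12)

  # phase equivariance: modrelu(e^{i phi} z) = e^{i phi} modrelu(z)
  phi <- runif(1e4, -pi, pi)
  z <- rcomplex(1e4)
  lhs <- modrelu(exp(1i * phi) * z, -0.3)
  rhs <- exp(1i * phi) * modrelu(z, -0.3)
  expect_lt(max(abs(lhs - rhs)), 1e-12)

  # per-channel bias over the last axis
  z <- array(rcomplex(60), c(5, 4, 3))
  y <- modrelu(z, c(-10, 0, -0.1))
  expect_true(all(y[, , 1] == 0))
  expect_equal(y[, , 2], z[, , 2])
})

test_that("complex Glorot init is seeded and hits the variance target", {
  k1 <- complex_glorot_init(c(3, 3, 4, 8), seed = 5)
  k2 <- complex_glorot_init(c(3, 3, 4, 8), seed = 5)
  expect_identical(k1$weights, k2$weights)
  expect_false(identical(k1$weights,
                         complex_glorot_init(c(3, 3, 4, 8), seed = 6)$weights))
  expect_error(complex_glorot_init(c(3, 3, 0, 8), seed = 1), "positive")

  # Monte-Carlo check: E|w|^2 = 2 / (fan_in + fan_out) within 5%
  k <- complex_glorot_init(c(1, 1, 250, 440), seed = 42)  # 110000 draws
  fan_in <- 250; fan_out <- 440
  target <- 2 / (fan_in + fan_out)
  expect_lt(abs(mean(Mod(k$weights)^2) - target) / target, 0.05)
  expect_true(all(k$bias == 0) && all(k$modrelu_bias == 0))
})

test_that("complex dropout masks jointly, rescales, and is off outside training", {
  z <- array(rcomplex(1000), c(10, 10, 10))
  expect_identical(complex_dropout(z, 0.5, training = FALSE), z)
  expect_identical(complex_dropout(z, 0, training = TRUE), z)
  expect_error(complex_dropout(z, 1), "rate")

  z <- rcomplex(1e6)
  y <- complex_dropout(z, 0.5, training = TRUE, seed = 8)
  frac <- mean(y == 0)
  expect_lt(abs(frac - 0.5), 0.002)
  kept <- y != 0
  # real and imaginary parts are zeroed jointly and survivors scaled by 2
  expect_equal(y[kept], 2 * z[kept])
})

test_that("perp + L2 loss has the documented closed forms", {
  set.seed(3)
  target <- array(rcomplex(50), c(5, 5, 2))
  expect_equal(perp_l2_loss(target, target), 0)

  # orthogonal unit prediction: perp term 1, parallel component 0 so the
  # along-target error is |T| = 1
  t1 <- array(1 + 0i, c(2, 2)); p1 <- array(0 + 1i, c(2, 2))
  expect_equal(perp_l2_loss(p1, t1, lambda_l2 = 1), 2)
  expect_equal(perp_l2_loss(p1, t1, lambda_l2 = 0.25), 1.25)

  # the anti-parallel prediction is penalized, not rewarded
  expect_gt(perp_l2_loss(-t1, t1), 1)

  # vanishing target: the completion pulls the prediction to zero
  expect_equal(perp_l2_loss(p1, 0 * t1, lambda_l2 = 2), 2)

  # parallel scaling: perp exactly 0, loss = lambda (c-1)^2 mean|T|^2
  cc <- 1.7; lam <- 0.5
  loss <- perp_l2_loss(cc * target, target, lambda_l2 = lam)
  expect_equal(loss, lam * (cc - 1)^2 * mean(Mod(target)^2), tolerance = 1e-12)

  expect_error(perp_l2_loss(p1, t1, mask = array(FALSE, c(2, 2))), "mask")
})

test_that("loss gradient agrees with finite differences through conv + modrelu", {
  set.seed(12)
  x <- array(rcomplex(4 * 4 * 2), c(4, 4, 2))
  w <- array(rcomplex(9 * 2 * 2), c(3, 3, 2, 2))
  bias <- rcomplex(2); mb <- c(0.1, -0.2)
  target <- array(rcomplex(32), c(4, 4, 2))
  fwd <- function(wv) {
    k <- complex_kernel(array(wv, dim(w)), bias)
    perp_l2_loss(modrelu(complex_conv2d(x, k), mb), target)
  }
  # analytic gradient via the layer backward passes
  k <- complex_kernel(w, bias)
  z <- complex_conv2d(x, k)
  a <- modrelu(z, mb)
  lg <- perp_l2_loss(a, target, grad = TRUE)
  mr <- ptxmap:::.modrelu_bwd(z, mb, lg$grad)
  cb <- ptxmap:::.cx_conv2d_bwd(x, as.vector(w), mr$gz, 3L, 3L, 1L)
  h <- 1e-6
  idx <- sample(length(w), 12)
  for (i in idx) {
    for (part in c(1, 1i)) {
      wp <- as.vector(w); wp[i] <- wp[i] + part * h
      wm <- as.vector(w); wm[i] <- wm[i] - part * h
      num <- (fwd(wp) - fwd(wm)) / (2 * h)
      ana <- if (part == 1) Re(cb$gw[i]) else Im(cb$gw[i])
      expect_lt(abs(num - ana) / max(1e-4, abs(num)), 1e-4)
    }
  }
})

test_that("dropout off composes with an identity kernel to the identity", {
  set.seed(5)
  x <- array(rcomplex(6 * 6 * 2), c(6, 6, 2))
  k_id <- complex_kernel(array(c(1, 0, 0, 1) + 0i, c(1, 1, 2, 2)))
  y <- complex_conv2d(complex_dropout(x, 0.3, training = FALSE), k_id)
  expect_equal(y, x, tolerance = 1e-14)
})
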