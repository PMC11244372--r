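test_that("kernel_2d matches the nested-loop double-sum oracle", {
  set.seed(21)
  N <- 2
  dx <- random_stable_dssm(N)
  dy <- random_stable_dssm(N)
  contr <- rnorm(N)
  k <- kernel_2d(dx, dy, contr, 8, 8)
  # oracle: K[d1,d2] = sum_n contr[n] * (Abar^d1 Bbar)_n * (Abar^d2 Bbar)_n
  oracle <- matrix(0, 8, 8)
  sx <- dx$Bbar
  for (d1 in 1:8) {
    sy <- dy$Bbar
    for (d2 in 1:8) {
      oracle[d1, d2] <- oracle[d1, d2] + sum(contr * sx * sy)
      sy <- as.numeric(dy$Abar %*% sy)
    }
    sx <- as.numeric(dx$Abar %*% sx)
  }
  expect_equal(k$values, oracle, tolerance = 1e-8)
})

test_that("single-channel kernel is an exact rank-1 outer product", {
  set.seed(22)
  dx <- random_stable_dssm(1)
  dy <- random_stable_dssm(1)
  k <- kernel_2d(dx, dy, 1, 6, 5)
  expect_equal(k$values, outer(as.numeric(k$axis_x), as.numeric(k$axis_y)),
               tolerance = 1e-12)
  expect_equal(qr(k$values)$rank, 1L)
})

test_that("2D kernel rank is bounded by the state dimension", {
  set.seed(23)
  for (N in c(2, 4, 6)) {
    k <- kernel_2d(random_stable_dssm(N), random_stable_dssm(N), rnorm(N),
                   16, 12)
    sv <- svd(k$values)$d
    rank <- sum(sv > 1e-9 * sv[1])
    expect_lte(rank, N)
  }
})

test_that("conv2d_global: impulse response, identity kernel, oracle, linearity", {
  set.seed(24)
  H <- 8; W <- 8
  K <- matrix(rnorm(H * W), H, W)
  # impulse at the origin reproduces the kernel
  imp <- matrix(0, H, W); imp[1, 1] <- 1
  expect_equal(conv2d_global(imp, K), K, tolerance = 1e-10)
  # delta kernel is the identity operator
  dk <- matrix(0, H, W); dk[1, 1] <- 1
  x <- matrix(rnorm(H * W), H, W)
  expect_equal(conv2d_global(x, dk), x, tolerance = 1e-10)
  # FFT path equals the nested double sum
  expect_equal(conv2d_global(x, K), conv2d_oracle(x, K), tolerance = 1e-6)
  # linearity
  x2 <- matrix(rnorm(H * W), H, W)
  expect_equal(conv2d_global(2.5 * x - 1.3 * x2, K),
               2.5 * conv2d_global(x, K) - 1.3 * conv2d_global(x2, K),
               tolerance = 1e-10)
  # extent mismatch is an error, never a silent resample
  expect_error(conv2d_global(matrix(0, 4, 4), K), "extent")
})

test_that("rank-1 global convolution separates into sequential 1D convolutions", {
  set.seed(25)
  H <- 8; W <- 8
  kx <- rnorm(H); ky <- rnorm(W)
  K <- outer(kx, ky)
  x <- matrix(rnorm(H * W), H, W)
  y2 <- conv2d_global(x, K)
  # rows then columns with causal 1D convolutions
  tmp <- apply(x, 2, function(col) causal_conv(col, kernel1d(kx)))
  y1 <- t(apply(tmp, 1, function(row) causal_conv(row, kernel1d(ky))))
  expect_equal(y2, y1, tolerance = 1e-8)
})

test_that("s4_2d_layer runs at multiple resolutions from the same parameters", {
  set.seed(26)
  lay <- s4_2d_layer(3, state_dim = 4)
  x16 <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  x32 <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  y16 <- nn_forward(lay, x16)
  y32 <- nn_forward(lay, x32)
  expect_equal(dim(y16), dim(x16))
  expect_equal(dim(y32), dim(x32))
  # zero input -> zero output (no bias)
  expect_equal(nn_forward(lay, array(0, c(16, 16, 3))),
               array(0, c(16, 16, 3)))
})

test_that("s4_2d_layer equals the manual kernel_2d + conv2d_global composition", {
  set.seed(27)
  lay <- s4_2d_layer(1, state_dim = 4)
  x <- matrix(rnorm(64), 8, 8)
  y <- nn_forward(lay, array(x, c(8, 8, 1)))[, , 1]
  hip <- init_hippo(4)
  dx <- discretize(hip, exp(lay$params$logdx[1]))
  dy <- discretize(hip, exp(lay$params$logdy[1]))
  k <- kernel_2d(dx, dy, lay$params$contr[, 1], 8, 8)
  expect_equal(y, conv2d_global(x, k), tolerance = 1e-10)
})

test_that("kernels at H and 2H agree on shared support after delta rescaling", {
  # The continuous parameterization is what carries resolution flexibility:
  # halving delta while doubling the extent samples the same underlying
  # impulse response twice as finely. Bilinear taps sit at half-sample
  # phases, so the coarse tap at time (i+1/2)d corresponds to the mean of
  # the two fine taps straddling it; with that pairing the kernels agree to
  # a few percent (documenting, not proving, the resolution-invariance
  # claim).
  set.seed(28)
  N <- 4
  hip <- init_hippo(N, C = rnorm(N))
  H <- 16
  kc <- ssm_kernel(discretize(hip, 0.08), H)$values
  kf <- ssm_kernel(discretize(hip, 0.04), 2 * H)$values
  kf_pair <- kf[seq(1, 2 * H, by = 2)] + kf[seq(2, 2 * H, by = 2)]
  denom <- sqrt(mean(kc^2))
  expect_lt(sqrt(mean((kf_pair - kc)^2)) / denom, 0.05)
})

test_that("s4_2d_layer backward matches numeric gradients", {
  set.seed(29)
  lay <- s4_2d_layer(2, state_dim = 3)
  x <- array(rnorm(6 * 5 * 2 * 2), c(6, 5, 2, 2))
  y <- lay$forward(x)
  gy <- array(rnorm(length(y)), dim(y))
  zero_grads(lay)
  gx <- lay$backward(gy)
  f <- function(v) { xx <- x; xx[] <- v; sum(lay$forward(xx) * gy) }
  expect_equal(as.numeric(gx), numeric_grad(f, as.numeric(x)),
               tolerance = 1e-6)
  lay$forward(x)  # restore cache
  zero_grads(lay); lay$backward(gy)
  for (pn in c("contr", "logdx", "logdy")) {
    fp <- function(v) {
      old <- lay$params[[pn]]
      lay$params[[pn]][] <- v
      out <- sum(lay$forward(x) * gy)
      lay$params[[pn]] <- old
      out
    }
    expect_equal(as.numeric(lay$grads[[pn]]),
                 numeric_grad(fp, as.numeric(lay$params[[pn]])),
                 tolerance = 1e-5, info = pn)
  }
})

test_that("bidirectional variant is symmetric in expectation and differentiable", {
  set.seed(30)
  lay <- s4_2d_layer(1, state_dim = 3, bidirectional = TRUE)
  x <- array(0, c(9, 9, 1, 1)); x[5, 5, 1, 1] <- 1
  y <- lay$forward(x)
  # impulse at the center: response reaches all four quadrants
  expect_gt(sum(abs(y[1:4, 1:4, 1, 1])), 0)
  expect_gt(sum(abs(y[6:9, 6:9, 1, 1])), 0)
  gy <- array(rnorm(length(y)), dim(y))
  zero_grads(lay)
  gx <- lay$backward(gy)
  f <- function(v) { xx <- x; xx[] <- v; sum(lay$forward(xx) * gy) }
  expect_equal(as.numeric(gx), numeric_grad(f, as.numeric(x)),
               tolerance = 1e-6)
})
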