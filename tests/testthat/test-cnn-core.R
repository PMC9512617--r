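test_that("identity kernels and shape arithmetic behave", {
  x <- matrix(rnorm(12), 3, 4)
  k1 <- conv_kernels(array(1, c(1, 1, 1, 1)), 0)
  expect_equal(conv2d_forward(x, k1)[, , 1], x)
  # valid-convolution output shape
  x2 <- matrix(rnorm(4 * 24), 4, 24)
  k <- random_kernels(3, 3, 1, 2)
  expect_equal(dim(conv2d_forward(x2, k)), c(2, 22, 2))
  expect_error(conv2d_forward(matrix(0, 2, 2), random_kernels(3, 3, 1, 1)),
               "larger than input")
  # 1d path: width-1 kernel of weight 1 is the identity, height untouched
  s <- matrix(rnorm(2 * 24), 2, 24)
  expect_equal(conv1d_forward(s, conv_kernels(array(1, c(1, 1, 1, 1)), 0))[, , 1], s)
  expect_equal(dim(conv1d_forward(s, random_kernels(1, 3, 1, 4))), c(2, 22, 4))
  expect_error(conv1d_forward(s, random_kernels(2, 3, 1, 1)), "height 1")
})

test_that("forward convolution equals the brute-force loop oracle", {
  set.seed(42)
  for (rep in 1:100) {
    kin <- sample(1:3, 1); kout <- sample(1:3, 1)
    kh <- sample(1:3, 1); kw <- sample(1:4, 1)
    hs <- sample(1:2, 1); ws <- sample(1:2, 1)
    h <- kh + sample(0:4, 1); w <- kw + sample(0:5, 1)
    x <- array(rnorm(h * w * kin), c(h, w, kin))
    k <- random_kernels(kh, kw, kin, kout, c(hs, ws))
    expect_equal(conv2d_forward(x, k),
                 brute_conv(x, k$weights, k$biases, k$strides),
                 tolerance = 1e-12)
  }
})

test_that("convolution is linear in input and weights", {
  set.seed(7)
  x1 <- array(rnorm(40), c(4, 5, 2)); x2 <- array(rnorm(40), c(4, 5, 2))
  k <- random_kernels(2, 3, 2, 3)
  k0 <- k; k0$biases <- rep(0, 3)
  expect_equal(conv2d_forward(x1 + 2 * x2, k0),
               conv2d_forward(x1, k0) + 2 * conv2d_forward(x2, k0),
               tolerance = 1e-12)
  k2 <- k0; k2$weights <- 3 * k0$weights
  expect_equal(conv2d_forward(x1, k2), 3 * conv2d_forward(x1, k0),
               tolerance = 1e-12)
})

test_that("ReLU and its derivative follow the kink convention", {
  z <- c(-2, 0, 3.5)
  expect_equal(activate(z), c(0, 0, 3.5))
  expect_equal(activate_grad(z), c(0, 0, 1))
  expect_equal(activate(activate(z)), activate(z))  # idempotent
})

test_that("max pooling matches the loop oracle and records argmax", {
  expect_equal(maxpool_forward(matrix(c(1, 3, 2, 4), 2, 2), c(2, 2))[1, 1, 1], 4)
  # all-equal tile: first index in column-major order wins
  eq <- maxpool_forward(matrix(5, 2, 2), c(2, 2))
  expect_equal(eq[1, 1, 1], 5)
  expect_equal(attr(eq, "argmax")[1, 1, 1], 1L)
  set.seed(11)
  for (rep in 1:20) {
    x <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
    expect_equal(as.vector(maxpool_forward(x, c(2, 2))),
                 as.vector(brute_maxpool(x, c(2, 2))))
  }
  expect_error(maxpool_forward(matrix(0, 3, 4), c(2, 2)), "divide")
  # backward routes each delta to its argmax position
  x <- matrix(c(1, 3, 2, 4), 2, 2)
  pooled <- maxpool_forward(x, c(2, 2))
  back <- maxpool_backward(array(7, c(1, 1, 1)), attr(pooled, "argmax"),
                           c(2, 2, 1))
  expect_equal(back[, , 1], matrix(c(0, 0, 0, 7), 2, 2))
})

test_that("backward delta and weight gradients satisfy basic identities", {
  set.seed(3)
  k <- random_kernels(2, 2, 1, 2)
  z_prev <- array(abs(rnorm(12)) + 0.1, c(3, 4, 1))  # all positive: sigma'=1
  # zero delta propagates to zero everywhere
  zero <- array(0, c(2, 3, 2))
  expect_equal(conv_backward_delta(zero, k, z_prev), array(0, c(3, 4, 1)))
  g0 <- conv_weight_grad(zero, z_prev, k)
  expect_equal(g0$weights, array(0, dim(k$weights)))
  expect_equal(g0$biases, c(0, 0))
  # 1x1 identity kernel passes deltas through unchanged
  k1 <- conv_kernels(array(1, c(1, 1, 1, 1)), 0)
  d <- array(rnorm(12), c(3, 4, 1))
  expect_equal(conv_backward_delta(d, k1, z_prev), d)
  # unit impulse delta: weight gradient equals the input patch under the kernel
  x <- array(rnorm(12), c(3, 4, 1))
  imp <- array(0, c(2, 3, 1))
  imp[1, 1, 1] <- 1
  ku <- random_kernels(2, 2, 1, 1)
  gw <- conv_weight_grad(imp, x, ku)
  expect_equal(gw$weights[, , 1, 1], x[1:2, 1:2, 1])
  expect_equal(gw$biases, 1)
})

test_that("softmax head is a stable probability simplex map", {
  expect_equal(dense_softmax_forward(numeric(2), matrix(0, 4, 2), numeric(4)),
               rep(0.25, 4))
  set.seed(5)
  W <- matrix(rnorm(12), 3, 4); b <- rnorm(3); f <- rnorm(4)
  p <- dense_softmax_forward(f, W, b)
  expect_true(all(p > 0))
  expect_lt(abs(sum(p) - 1), 1e-12)
  # shift invariance
  expect_equal(dense_softmax_forward(f, W, b + 100), p, tolerance = 1e-9)
  # matches the direct formula at low magnitude
  logits <- as.vector(W %*% f + b)
  expect_equal(p, exp(logits) / sum(exp(logits)), tolerance = 1e-12)
  # survives logits that would overflow a naive implementation
  expect_false(anyNA(dense_softmax_forward(f * 500, W, b)))
})

test_that("finite differences recover closed-form derivatives", {
  # quadratic: d/dx sum(x^2) = 2x, exact to O(eps^2)
  x <- c(0.5, -1.2, 2)
  expect_equal(finite_difference_grads(function(v) sum(v^2), x), 2 * x,
               tolerance = 1e-8)
  # linear: exact to machine precision
  a <- c(3, -1, 7)
  expect_equal(finite_difference_grads(function(v) sum(a * v), x), a,
               tolerance = 1e-9)
})
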