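small_cfg <- function(nonlocal = TRUE, ...) {
  network_config(depth = 3L, base_filters = 8L, nonlocal_enabled = nonlocal,
                 input_size = c(64, 64), ...)
}

test_that("forward pass has the right shape, range, and is deterministic", {
  cfg <- network_config(depth = 3L, base_filters = 8L, input_size = c(64, 64))
  net <- build_unet(cfg, seed = 3)
  set.seed(1)
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  p1 <- cranioseg:::unet_forward(net, x)
  expect_equal(dim(p1), c(64L, 64L, 1L, 2L))
  expect_true(all(p1 > 0 & p1 < 1))
  p2 <- cranioseg:::unet_forward(net, x)
  expect_identical(p1, p2)
})

test_that("config invariants are enforced", {
  expect_error(network_config(depth = 4, input_size = c(100, 100)), "divisible")
  expect_error(network_config(base_filters = 2), "base_filters")
  expect_error(network_config(depth = 3, base_filters = 9, input_size = c(64, 64),
                              nonlocal_channel_reduction = 16), "divisible")
})

test_that("enabling the non-local block adds exactly its analytic parameter count", {
  with_nl <- build_unet(small_cfg(TRUE), seed = 5)
  without <- build_unet(small_cfg(FALSE), seed = 5)
  fb <- 8L * 2L^3L  # bottleneck channels
  expect_equal(count_parameters(with_nl) - count_parameters(without),
               nonlocal_param_count(fb, 2L))
  # and the analytic count is what the weight arrays actually hold
  expect_equal(count_parameters(with_nl$params$nonlocal),
               nonlocal_param_count(fb, 2L))
})

test_that("zero-initialized non-local block is the identity", {
  w <- nonlocal_init(16L, reduction = 2L)
  x <- array(rnorm(8 * 8 * 16 * 2), c(8, 8, 16, 2))
  y <- nonlocal_forward(x, w)
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("embedded-Gaussian attention rows sum to one", {
  set.seed(6)
  w <- nonlocal_init(8L, 2L)
  for (nm in c("theta", "phi", "g")) w[[nm]]$w[] <- rnorm(length(w[[nm]]$w), 0, 0.5)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8, 1))
  out <- nonlocal_forward(x, w, return_attention = TRUE)
  A <- out$attention[[1]]
  expect_equal(dim(A), c(16L, 16L))
  expect_equal(rowSums(A), rep(1, 16), tolerance = 1e-5)
})

test_that("a spatially uniform input stays spatially uniform through attention", {
  set.seed(8)
  w <- nonlocal_init(8L, 2L)
  for (nm in c("theta", "phi", "g", "wz")) w[[nm]]$w[] <- rnorm(length(w[[nm]]$w), 0, 0.3)
  v <- rnorm(8)
  x <- array(rep(v, each = 4), c(2, 2, 8, 1))
  y <- nonlocal_forward(x, w)
  for (c in 1:8) expect_lt(diff(range(y[, , c, 1])), 1e-10)
})

test_that("attention output matches a brute-force double loop on a 2x2 map", {
  set.seed(9)
  C <- 4L; red <- 2L
  w <- nonlocal_init(C, red)
  for (nm in c("theta", "phi", "g", "wz")) {
    w[[nm]]$w[] <- rnorm(length(w[[nm]]$w), 0, 0.4)
    w[[nm]]$b[] <- rnorm(length(w[[nm]]$b), 0, 0.1)
  }
  x <- array(rnorm(2 * 2 * C), c(2, 2, C, 1))
  y <- nonlocal_forward(x, w, variant = "embedded_gaussian")

  # oracle: explicit loops over the 4 positions
  X <- matrix(x[, , , 1], 4, C)          # position-major flattening
  th <- sweep(X %*% w$theta$w, 2, w$theta$b, "+")
  ph <- sweep(X %*% w$phi$w, 2, w$phi$b, "+")
  gg <- sweep(X %*% w$g$w, 2, w$g$b, "+")
  yo <- matrix(0, 4, C)
  for (i in 1:4) {
    s <- numeric(4)
    for (j in 1:4) s[j] <- sum(th[i, ] * ph[j, ])
    a <- exp(s - max(s)); a <- a / sum(a)
    yi <- colSums(a * gg)               # sum_j a_j g_j
    yo[i, ] <- X[i, ] + as.numeric(yi %*% w$wz$w) + w$wz$b
  }
  expect_equal(matrix(y[, , , 1], 4, C), yo, tolerance = 1e-5)
})

test_that("predict_mask thresholds and reassembles volumes", {
  cfg <- small_cfg(FALSE)
  net <- build_unet(cfg, seed = 11)
  vol <- image_volume(array(runif(64 * 64 * 5), c(64, 64, 5)))
  # force a constant head: zero weights, bias +3 -> p ~ 0.95 everywhere
  net$params$head$w[] <- 0
  net$params$head$b[] <- 3
  m1 <- predict_mask(net, vol)
  expect_true(all(m1$data == 1))
  net$params$head$b[] <- -3
  m0 <- predict_mask(net, vol)
  expect_true(all(m0$data == 0))
  # boundary convention: threshold 0 marks every strictly positive probability
  mall <- predict_mask(net, vol, threshold = 0)
  expect_true(all(mall$data == 1))
  expect_equal(m1$spacing, vol$spacing)
  bad <- image_volume(array(0, c(32, 32, 2)))
  expect_error(predict_mask(net, bad), "does not match")
})

test_that("checkpoints round-trip through disk", {
  net <- build_unet(small_cfg(TRUE), seed = 13)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  back <- load_checkpoint(f)
  expect_equal(back$params, net$params)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  expect_identical(cranioseg:::unet_forward(net, x),
                   cranioseg:::unet_forward(back, x))
})
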