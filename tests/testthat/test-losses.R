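test_that("Tversky index matches hand-computed values and reduces to soft Dice", {
  # 10 pixels, 5 positive, p all ones, alpha 0.1, beta 0.9, no smoothing:
  # TI = 5 / (5 + 0.1*5) = 0.909090..
  g <- c(rep(1, 5), rep(0, 5))
  p <- rep(1, 10)
  expect_equal(tversky_index(p, g, 0.1, 0.9, smooth = 0), 5 / 5.5,
               tolerance = 1e-9)
  expect_equal(tversky_loss(p, g, loss_config(alpha = 0.1, beta = 0.9, smooth = 0)),
               1 - 5 / 5.5, tolerance = 1e-9)

  # alpha = beta = 0.5 is exactly the soft Dice coefficient
  set.seed(7)
  for (rep in 1:20) {
    p <- runif(50)
    g <- as.numeric(runif(50) > 0.6)
    expect_equal(tversky_index(p, g, 0.5, 0.5, smooth = 1),
                 oracle_soft_dice(p, g, smooth = 1), tolerance = 1e-9)
    expect_equal(tversky_index(p, g, 0.5, 0.5, smooth = 0.3),
                 oracle_tversky(p, g, 0.5, 0.5, 0.3), tolerance = 1e-12)
  }
})

test_that("perfect predictions give index 1 / loss 0", {
  g <- as.numeric(runif(30) > 0.5)
  expect_equal(tversky_index(g, g, 0.1, 0.9, smooth = 0), 1)
  expect_equal(tversky_loss(g, g, loss_config(smooth = 0)), 0)
  expect_lt(cross_entropy_loss(g, g), 1.1e-7)  # clamp floor
})

test_that("cross-entropy matches closed forms", {
  g <- as.numeric(runif(40) > 0.5)
  expect_equal(cross_entropy_loss(rep(0.5, 40), g), log(2), tolerance = 1e-9)
  # p = (0.9, 0.2), g = (1, 0): -(log(.9) + log(.8)) / 2
  expect_equal(cross_entropy_loss(c(0.9, 0.2), c(1, 0)),
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-9)
})

test_that("total loss is the stated convex combination", {
  set.seed(3)
  p <- runif(64); g <- as.numeric(runif(64) > 0.7)
  cfg <- loss_config()
  expect_equal(total_loss(p, g, cfg),
               0.5 * tversky_loss(p, g, cfg) + 0.5 * cross_entropy_loss(p, g),
               tolerance = 1e-12)
  cfg0 <- loss_config(w_tversky = 1, w_ce = 0)
  expect_equal(total_loss(p, g, cfg0), tversky_loss(p, g, cfg0), tolerance = 1e-12)
  expect_error(loss_config(w_tversky = 0.6, w_ce = 0.6), "must equal 1")
})

test_that("loss decreases monotonically as p moves from 0.5 toward the target", {
  ph <- desk_phantom(seed = 5, composition = "mixed")
  k <- which.max(apply(ph$mask$data, 3, sum))
  g <- ph$mask$data[, , k]
  cfg <- loss_config()
  ts <- seq(0, 1, by = 0.1)
  losses <- vapply(ts, function(t) {
    p <- (1 - t) * 0.5 + t * (g * 0.999 + (1 - g) * 0.001)
    total_loss(p, g, cfg)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("increasing beta strictly penalizes false negatives", {
  set.seed(11)
  p <- runif(100, 0.05, 0.95)
  g <- as.numeric(runif(100) > 0.5)  # both FP and FN mass present
  betas <- seq(0.1, 0.9, by = 0.2)
  ti <- vapply(betas, function(b) tversky_index(p, g, 0.1, b, smooth = 0),
               numeric(1))
  expect_true(all(diff(ti) < 0))
})

test_that("the analytic gradient matches finite differences", {
  set.seed(13)
  p <- runif(30, 0.1, 0.9)
  g <- as.numeric(runif(30) > 0.5)
  cfg <- loss_config()
  ana <- cranioseg:::total_loss_grad(p, g, cfg)
  eps <- 1e-6
  for (i in sample(30, 8)) {
    p1 <- p; p1[i] <- p[i] + eps
    p2 <- p; p2[i] <- p[i] - eps
    num <- (total_loss(p1, g, cfg) - total_loss(p2, g, cfg)) / (2 * eps)
    expect_equal(ana[i], num, tolerance = 1e-5)
  }
})

test_that("one gradient step from p = 0.5 moves mass toward the target", {
  ph <- desk_phantom(seed = 6, composition = "solid")
  k <- which.max(apply(ph$mask$data, 3, sum))
  g <- ph$mask$data[, , k]
  p <- matrix(0.5, nrow(g), ncol(g))
  cfg <- loss_config()
  gr <- cranioseg:::total_loss_grad(p, g, cfg)
  p2 <- pmin(pmax(p - 0.1 * gr / max(abs(gr)), 0), 1)
  conc <- function(p) sum(p * g) / sum(p)   # fraction of mass on target
  expect_gt(conc(p2), conc(p))
})

test_that("shape and range violations are rejected", {
  expect_error(tversky_index(c(0.5, 0.5), c(1, 0, 0)), "differ")
  expect_error(cross_entropy_loss(c(1.5, 0.2), c(1, 0)), "\\[0,1\\]")
  expect_error(tversky_index(c(0.5, 0.5), c(2, 0)), "binary")
})
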