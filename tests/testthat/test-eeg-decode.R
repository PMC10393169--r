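test_that("window averaging matches explicit slices", {
  ep <- toy_epochs()
  wa <- window_average(ep, center = -0.2, width = 0.05)
  idx <- which(ep$times >= -0.225 - 1e-9 & ep$times <= -0.175 + 1e-9)
  expect_equal(wa[3, 5], mean(ep$data[3, 5, idx]))
  # a constant channel averages to itself; a linear ramp to its center value
  ep$data[1, 2, ] <- 7
  ep$data[1, 3, ] <- ep$times
  wa2 <- window_average(ep, center = -0.2, width = 0.05)
  expect_equal(wa2[1, 2], 7)
  expect_equal(wa2[1, 3], -0.2, tolerance = 1e-9)
  expect_error(window_average(ep, center = 5), "window")
})

test_that("fisher weights solve the pooled system and find planted classes", {
  set.seed(9)
  p <- 8; n <- 3000
  delta <- c(2, -1, rep(0, p - 2))
  X <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p), n, p) + rep(delta, each = n))
  labels <- rep(c("a", "b"), each = n)
  st <- litmodel:::class_stats(X, labels)
  w <- fisher_weights(st, shrinkage = 0)$w
  # identity-covariance data: weights align with the class-mean difference
  ang <- sum(w * delta) / sqrt(sum(w^2) * sum(delta^2))
  expect_gt(ang, cos(5 * pi / 180))
  # rotating the data rotates the weights consistently
  Q <- qr.Q(qr(matrix(rnorm(p * p), p)))
  st_rot <- litmodel:::class_stats(X %*% Q, labels)
  w_rot <- fisher_weights(st_rot, shrinkage = 0)$w
  expect_gt(abs(cor(as.numeric(Q %*% w_rot), w)), 0.999)
})

test_that("sliding discrimination is at chance for shuffled labels", {
  ep <- toy_epochs(n_trials = 60, seed = 12)
  set.seed(12)
  labels <- sample(rep(c("x", "y"), 30))
  disc <- sliding_discrimination(ep, labels, width = 0.05,
                                 step = 0.1, range = c(-0.4, 0))
  expect_true(all(abs(disc$az - 0.5) < 0.25))
  expect_lt(abs(mean(disc$az) - 0.5), 0.12)
  # a strongly separated planted class drives Az toward 1
  sel <- labels == "y"
  ep$data[sel, 4, ] <- ep$data[sel, 4, ] + 6
  disc2 <- sliding_discrimination(ep, labels, width = 0.05, step = 0.1,
                                  range = c(-0.4, 0))
  expect_true(all(disc2$az > 0.95))
})

test_that("the forward model inverts rank-one mixtures", {
  set.seed(13)
  a0 <- rnorm(10)
  y <- rnorm(500)
  X <- outer(a0, y)
  expect_equal(forward_model(X, y), a0, tolerance = 1e-12)
  # noise channels orthogonal to y couple weakly
  Xn <- X; Xn[3, ] <- rnorm(500)
  a_hat <- forward_model(Xn, y)
  expect_lt(abs(a_hat[3]), 0.2)
  # doubling y halves the coupling (the formula's normalization)
  expect_equal(forward_model(X, 2 * y), a0 / 2, tolerance = 1e-12)
})

test_that("projection applies the filter everywhere and z-scores globally", {
  ep <- toy_epochs(seed = 14)
  w <- rnorm(8)
  raw <- project_signal(ep, w, zscore = FALSE)
  expect_equal(raw[2, 7], sum(w * ep$data[2, , 7]))
  z <- project_signal(ep, w)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(as.numeric(z)), 1, tolerance = 1e-12)
})
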