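test_that("slope snapshots equal least-squares slopes per window", {
  ep <- toy_epochs(n_trials = 12, seed = 15)
  # plant an exact line and a constant
  ep$data[4, 2, ] <- 3 + 2.5 * ep$times
  ep$data[4, 3, ] <- 1.7
  ev <- matrix(rnorm(12 * length(ep$times)), 12)
  snap <- slope_snapshots(ep, ev, centers = c(-0.15, -0.1), width = 0.05)
  k <- which(snap$trial == 4 & snap$center == -0.15)
  expect_equal(snap$S[2, k], 2.5, tolerance = 1e-9)
  expect_equal(snap$S[3, k], 0, tolerance = 1e-12)
  # noisy line against the lm oracle
  idx <- which(ep$times >= -0.175 - 1e-9 & ep$times <= -0.125 + 1e-9)
  fit <- lm(ep$data[1, 1, idx] ~ ep$times[idx])
  expect_equal(snap$S[1, which(snap$trial == 1 & snap$center == -0.15)],
               unname(coef(fit)[2]), tolerance = 1e-9)
  # evidence pairing averages the same window
  expect_equal(snap$e[k], mean(ev[4, idx]))
  # centering identities
  expect_equal(colSums(snap$S_bar), rep(0, ncol(snap$S_bar)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(mean(snap$e_bar), 0, tolerance = 1e-12)
})

test_that("motor weights find the channel whose slopes track the evidence", {
  set.seed(16)
  n <- 60; fs <- 100
  times <- seq(-0.5, 0.1, by = 1 / fs)
  ev <- matrix(0, n, length(times))
  arr <- array(rnorm(n * 6 * length(times), sd = 0.005),
               c(n, 6, length(times)))
  for (i in seq_len(n)) {
    e_i <- runif(1, 0.5, 2)
    ev[i, ] <- e_i
    arr[i, 4, ] <- arr[i, 4, ] + e_i * (times - times[1])  # slope = evidence
  }
  ep <- eeg_epochs(arr, times, paste0("ch", 1:6), fs)
  snap <- slope_snapshots(ep, ev)
  w <- motor_weights(snap)
  expect_equal(which.max(abs(w)), 4L)
  # centered-fit correlation, checked against the with-intercept lm
  agg <- as.numeric(w %*% snap$S_bar)
  expect_gt(cor(agg, snap$e_bar), 0.9)
  r_lm <- sqrt(summary(lm(snap$e_bar ~ t(snap$S_bar)))$r.squared)
  expect_equal(cor(agg, snap$e_bar), r_lm, tolerance = 0.01)
  # adding a constant to the evidence leaves the solution unchanged
  snap2 <- slope_snapshots(ep, ev + 10)
  expect_equal(motor_weights(snap2), w, tolerance = 1e-8)
  # duplicating a channel splits its weight, aggregated signal unchanged
  arr2 <- array(NA_real_, c(n, 7, length(times)))
  arr2[, 1:6, ] <- arr; arr2[, 7, ] <- arr[, 4, ]
  ep2 <- eeg_epochs(arr2, times, paste0("ch", 1:7), fs)
  snap3 <- slope_snapshots(ep2, ev)
  w2 <- suppressWarnings(motor_weights(snap3))
  expect_equal(w2[4], w2[7], tolerance = 1e-6)
  expect_equal(as.numeric(w2 %*% snap3$S_bar),
               as.numeric(w %*% snap$S_bar), tolerance = 1e-6)
})

test_that("the motor signal is a linear projection with hand-blind weights", {
  ep <- toy_epochs(seed = 18)
  w1 <- rnorm(8); w2 <- rnorm(8)
  expect_equal(motor_signal(ep, w1 + w2),
               motor_signal(ep, w1) + motor_signal(ep, w2),
               tolerance = 1e-12)
  # the weight-estimation interface takes no hand information
  expect_false("hand" %in% names(formals(motor_weights)))
  expect_false("hand" %in% names(formals(slope_snapshots)))
})

test_that("topography maps recover a rank-one generator and split by hand", {
  set.seed(19)
  n <- 200; times <- seq(-0.2, 0.05, by = 0.01)
  topo <- c(1, -0.5, 0.3, -0.8) / sqrt(1.98)
  sig <- matrix(rnorm(n * length(times)), n)
  arr <- array(0, c(n, 4, length(times)))
  # noise comparable to the signal, so the correlation map stays roughly
  # proportional to the planted loadings
  for (i in seq_len(n)) arr[i, , ] <- outer(topo, sig[i, ]) +
    array(rnorm(4 * length(times), sd = 1), c(4, length(times)))
  ep <- eeg_epochs(arr, times, paste0("ch", 1:4), fs = 100,
                   metadata = data.frame(hand = rep(c("left", "right"),
                                                    each = 100)))
  maps <- motor_topography(ep, sig, window = c(-0.2, 0.05),
                           split_by_hand = TRUE)
  expect_gt(abs(cor(maps$all, topo)), 0.9)
  expect_equal(sign(maps$all), sign(topo), ignore_attr = TRUE)
  expect_equal(maps$all, (maps$left + maps$right) / 2, tolerance = 0.1,
               ignore_attr = TRUE)
})
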