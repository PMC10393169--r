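test_that("the band-pass keeps the pass band and removes DC and high tones", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  x10 <- sin(2 * pi * 10 * t)
  x80 <- sin(2 * pi * 80 * t)
  dat <- rbind(x10, x80, rep(5, length(t)))
  out <- bandpass(dat, fs = fs)
  mid <- seq(3 * fs, length(t) - 3 * fs)  # ignore filter edge transients
  amp10 <- max(abs(out[1, mid]))
  expect_gt(amp10, 0.95); expect_lt(amp10, 1.05)
  expect_lt(max(abs(out[3, mid])), 0.05)  # DC gone
  expect_lt(max(abs(out[2, mid])), 0.1)   # 80 Hz strongly attenuated
})

test_that("blink components estimated from calibration are projected out", {
  set.seed(5)
  nch <- 12; ns <- 4000
  topo <- rnorm(nch); topo <- topo / sqrt(sum(topo^2))
  ortho <- rnorm(nch); ortho <- ortho - sum(ortho * topo) * topo
  ortho <- ortho / sqrt(sum(ortho^2))
  calib <- outer(topo, 40 * sin(2 * pi * seq_len(2000) / 200)) +
    matrix(rnorm(nch * 2000), nch)
  task <- outer(topo, rnorm(ns, sd = 8)) + outer(ortho, rnorm(ns, sd = 3)) +
    matrix(rnorm(nch * ns, sd = 0.5), nch)
  res <- blink_pca_removal(task, calib, n_components = 1)
  # residual variance along the planted blink direction is tiny
  before <- var(as.numeric(topo %*% task))
  after <- var(as.numeric(topo %*% res$data))
  expect_lt(after / before, 0.01)
  # the orthogonal signal subspace survives
  expect_gt(var(as.numeric(ortho %*% res$data)) /
              var(as.numeric(ortho %*% task)), 0.95)
  ident <- blink_pca_removal(task, calib, n_components = 0)
  expect_identical(ident$data, task)
  expect_error(blink_pca_removal(task, calib, n_components = 20), "channels")
})

test_that("average referencing zeroes the channel mean and is idempotent", {
  set.seed(6)
  dat <- matrix(rnorm(5 * 100), 5) + 3
  ref <- average_reference(dat)
  expect_lt(max(abs(colMeans(ref))), 1e-12)
  expect_equal(average_reference(ref), ref)
  expect_equal(ref[1, ] - ref[2, ], dat[1, ] - dat[2, ])
})

test_that("epoching slices events and drops out-of-bounds ones", {
  set.seed(7)
  cont <- matrix(rnorm(4 * 1000), 4)
  cont[2, 500] <- 99
  ev <- c(3L, 500L, 995L)                 # first and last out of bounds
  expect_message(
    ep <- epoch_response_locked(cont, ev, window = c(-0.1, 0.1), fs = 100),
    "out of bounds")
  expect_equal(dim(ep$data)[1], 1L)
  i0 <- which(ep$times == 0)
  expect_equal(ep$data[1, 2, i0], 99)
  expect_equal(ep$data[1, , ], cont[, 490:510])
})

test_that("the full preprocessing chain preserves a planted component", {
  design <- synth_design(trials_per_block = 24L, blocks_per_urgency = 1L)
  beh <- generate_behavior(design, seed = 31)
  synth <- generate_eeg(design, beh, seed = 32)
  cont <- tile_continuous(design, synth, seed = 33, blinks = TRUE)
  calib <- generate_blink_calibration(design, duration = 20, seed = 34)
  x <- bandpass(cont$data, fs = cont$fs)
  x <- blink_pca_removal(x, calib$data)$data
  x <- average_reference(x)
  ep <- epoch_response_locked(x, cont$events, design$epoch_window, cont$fs,
                              channels = design$channels,
                              metadata = cont$metadata)
  # matched-filter readout of the planted evidence component
  rec <- project_signal(ep, synth$truth$evidence_topo, zscore = FALSE)
  expect_gt(abs(cor(as.numeric(rec), as.numeric(synth$truth$evidence_signal))),
            0.95)
})
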