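test_that("response-locked stacking aligns threshold crossings at t = 0", {
  p <- lit_params(v = 1.5, a = 1, zr = 0.5, lam = 2, Ter = 0, nd_sd = 0)
  s <- simulate_lit(p, n_trials = 400, t_max = 4, seed = 2, keep_paths = TRUE)
  st <- suppressMessages(response_locked_stack(s$paths, "y",
                                               lags = seq(-0.3, 0, 0.001)))
  i0 <- which(st$lags == 0)
  up <- s$paths$boundary[s$paths$boundary != 0] == 1L
  # mean motor value at the crossing equals the boundary
  expect_equal(mean(st$stack[up, i0]), 0.5, tolerance = 0.01)
  # the stored stack (memory-light path) agrees with slicing full paths
  s2 <- simulate_lit(p, n_trials = 400, t_max = 4, seed = 2,
                     stack_window = c(0.3, 0))
  st2 <- suppressMessages(response_locked_stack(s2$paths, "y"))
  expect_equal(st2$stack[, ncol(st2$stack)], st$stack[, i0])
})

test_that("measurement noise has the requested scale and a seeded stream", {
  m <- matrix(1, 200, 50)
  expect_identical(add_measurement_noise(m, 0), m)
  n1 <- add_measurement_noise(m, 0.015, seed = 4)
  n2 <- add_measurement_noise(m, 0.015, seed = 4)
  expect_identical(n1, n2)
  expect_equal(sd(n1 - m), 0.015, tolerance = 0.02)
  m[1, 1] <- NA
  expect_true(is.na(add_measurement_noise(m, 0.015, seed = 1)[1, 1]))
})

test_that("signal-RT correlation has the stated exact properties", {
  set.seed(8)
  rts <- runif(200, 0.3, 1)
  lags <- seq(-0.1, 0, by = 0.01)
  stack <- matrix(rnorm(200 * 11), 200, 11)
  stack[, 5] <- -rts                      # exact negative relation
  cv <- signal_rt_correlation(stack, rts, lags, smooth = 0)
  expect_equal(cv$r[5], -1)
  # trial-shared offsets leave the curve unchanged
  cv2 <- signal_rt_correlation(stack + 17, rts, lags, smooth = 0)
  expect_equal(cv2$r, cv$r)
  # constant signal across trials maps to zero with a warning
  stack[, 2] <- 3
  expect_warning(cv3 <- signal_rt_correlation(stack, rts, lags, smooth = 0),
                 "constant")
  expect_equal(cv3$r[2], 0)
})

test_that("zero crossing and peak summarize curves as defined", {
  lags <- seq(-0.5, 0, by = 0.01)
  flat <- structure(list(time = lags, r = rep(0.3, length(lags)),
                         n = rep(100, length(lags)), smooth = 0, dt = 0.01),
                    class = "signal_rt_curve")
  expect_true(is.na(zero_crossing(flat)))
  line <- flat
  line$r <- -(lags + 0.2)                 # crosses + to - at t = -0.2
  expect_equal(zero_crossing(line), 0.2, tolerance = 1e-9)
  bump <- flat
  bump$r <- dnorm(lags, mean = -0.15, sd = 0.05)
  expect_equal(peak_time(bump), 0.15, tolerance = 1e-9)
})

test_that("model curves show the two-stage signatures at small scale", {
  r <- fig_signature_study(inv_leaks = c(0.25, 1), n = 8000, seed = 13)
  # single-stage evidence correlation decays to zero at the response
  expect_lt(abs(r$ddm$r0), 0.05)
  expect_gt(r$ddm$min_r, -0.05)
  # two-stage evidence correlation is negative at the response, with a
  # zero-crossing lag and motor peak lag that grow with the inverse leak
  expect_true(all(r$lit$evidence_r0 < 0))
  expect_true(all(diff(r$lit$evidence_zero_lag) > 0))
  expect_true(all(abs(r$lit$motor_r0) < 0.1))
  expect_true(all(diff(r$lit$motor_peak_lag) > 0))
})

test_that("mean trajectories cross before the response only for the LIT", {
  r <- threshold_profile_study(n = 8000, seed = 17)
  i0 <- which(r$lags == 0)
  pre <- which(r$lags < -0.35)
  # at the crossing the LIT separates conditions (high above low)...
  expect_gt(r$lit[i0, "high"], r$lit[i0, "low"])
  # ...after dominating in the other direction earlier
  expect_gt(mean(r$lit[pre, "low"] - r$lit[pre, "high"], na.rm = TRUE), 0)
  # the single-stage model pins both conditions to the bound at t = 0
  expect_lt(abs(r$ddm[i0, "high"] - r$ddm[i0, "low"]), 0.01)
})
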