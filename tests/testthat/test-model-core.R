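test_that("noise-free hitting time matches the closed-form solution", {
  # x(t) = v t, y(t) = v t - (v/lam)(1 - exp(-lam t)); root of y = a/2
  p <- lit_params(v = 1, a = 1, zr = 0.5, lam = 2, sigma_star = 1e-9,
                  Ter = 0, nd_sd = 0)
  s <- simulate_lit(p, n_trials = 1, dt = 0.001, t_max = 3, seed = 1)
  troot <- uniroot(function(t) t - 0.5 * (1 - exp(-2 * t)) - 0.5,
                   c(0.01, 3))$root
  expect_equal(s$paths$boundary, 1L)
  expect_lt(abs(s$paths$fpt - troot), 0.002)
})

test_that("constant input is a fixed point of the motor stage", {
  p <- lit_params(v = 0, a = 4, zr = 0.75, lam = 3, sigma_star = 1e-12,
                  Ter = 0, nd_sd = 0)
  s <- simulate_lit(p, n_trials = 1, dt = 0.001, t_max = 0.5, seed = 2,
                    keep_paths = TRUE)
  expect_close(s$paths$y[1, ], p$x0, 1e-6)
})

test_that("infinite leak collapses the LIT onto the plain diffusion", {
  p_inf <- lit_params(v = 1, a = 2, zr = 0.5, lam = Inf, Ter = 0, nd_sd = 0)
  lit <- simulate_lit(p_inf, n_trials = 20000, t_max = 5, seed = 7)
  ddm <- simulate_ddm(p_inf, n_trials = 20000, t_max = 5, seed = 7)
  # identical machinery and seed: bitwise equal
  expect_identical(lit$paths$fpt, ddm$paths$fpt)
  # and against an independent stream, equal in distribution
  ddm2 <- simulate_ddm(p_inf, n_trials = 20000, t_max = 5, seed = 8)
  expect_lt(ks_distance(lit$paths$fpt[lit$paths$boundary != 0],
                        ddm2$paths$fpt[ddm2$paths$boundary != 0]), 0.02)
  expect_lt(abs(mean(lit$paths$boundary == 1) -
                  mean(ddm2$paths$boundary == 1)), 0.015)
})

test_that("diffusion choice probabilities match the analytic formula", {
  p <- lit_params(v = 1, a = 2, zr = 0.5, lam = Inf, Ter = 0, nd_sd = 0)
  s <- simulate_ddm(p, n_trials = 40000, dt = 2e-4, t_max = 6, seed = 3)
  analytic <- (1 - exp(-2 * 1 * 1)) / (1 - exp(-2 * 1 * 2))
  expect_lt(abs(mean(s$paths$boundary == 1) - analytic), 0.01)
  # symmetry at zero drift
  p0 <- lit_params(v = 0, a = 2, zr = 0.5, lam = Inf, Ter = 0, nd_sd = 0)
  s0 <- simulate_ddm(p0, n_trials = 20000, t_max = 8, seed = 4)
  expect_lt(abs(mean(s0$paths$boundary == 1) - 0.5), 0.015)
})

test_that("collapsing bounds bound the response times", {
  p <- lit_params(v = 0.5, a = 2, zr = 0.5, lam = Inf, Ter = 0, nd_sd = 0,
                  c = 1)
  s <- simulate_ddm(p, n_trials = 5000, t_max = 4, seed = 5)
  expect_true(all(s$paths$boundary != 0L))
  expect_lt(max(s$paths$fpt), 2 / 1 + 1e-9)   # bounds meet at a/c
})

test_that("motor_from_evidence reproduces linear-system responses", {
  # fixed point
  expect_equal(motor_from_evidence(rep(3, 100), lam = 2, y0 = 3, dt = 0.01),
               rep(3, 100))
  # step response relaxes as 1 - exp(-lam t)
  y <- motor_from_evidence(rep(1, 501), lam = 4, y0 = 0, dt = 0.002)
  tt <- seq(0, 1, by = 0.002)
  expect_close(y, 1 - exp(-4 * tt), 1e-10)
  expect_error(motor_from_evidence(1:5, lam = -1, y0 = 0, dt = 0.01))
})

test_that("Euler motor path agrees with the convolution integrator to O(dt)", {
  p <- lit_params(v = 0.5, a = 50, zr = 0.5, lam = 3, Ter = 0, nd_sd = 0)
  dev <- vapply(c(0.002, 0.001), function(dt) {
    s <- simulate_lit(p, n_trials = 2, dt = dt, t_max = 1, seed = 6,
                      keep_paths = TRUE)
    max(vapply(1:2, function(i) {
      x <- s$paths$x[i, ]; y <- s$paths$y[i, ]
      yc <- motor_from_evidence(x, 3, p$x0, dt)
      max(abs(y - yc))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(dev[2], 0.01)
  # halving dt roughly halves the discrepancy (first-order scheme)
  expect_lt(dev[2], dev[1] * 0.7)
})

test_that("simulation is seed-reproducible and respects drift monotonicity", {
  p <- lit_params(v = c(0.5, 1, 1.5), a = 1, zr = 0.5, lam = 2, Ter = 0.3,
                  nd_sd = 0.05)
  a1 <- simulate_lit(p, condition = 2, n_trials = 500, seed = 42)
  a2 <- simulate_lit(p, condition = 2, n_trials = 500, seed = 42)
  expect_identical(a1$paths$fpt, a2$paths$fpt)
  expect_identical(a1$trials$rt, a2$trials$rt)
  # common random numbers across the drift ladder: accuracy is monotone
  acc <- vapply(1:3, function(cc) {
    s <- simulate_lit(p, condition = cc, n_trials = 2000, seed = 9)
    mean(s$paths$boundary == 1)
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
})

test_that("censored trials are retained as no-choice rows", {
  p <- lit_params(v = 0.01, a = 6, zr = 0.5, lam = Inf, Ter = 0.2,
                  nd_sd = 0.02)
  s <- simulate_lit(p, n_trials = 300, t_max = 1, seed = 11)
  cens <- s$paths$boundary == 0L
  expect_gt(sum(cens), 0)
  expect_true(all(s$trials$choice[cens] == "none"))
  expect_true(all(is.na(s$trials$rt[cens])))
  expect_true(all(s$trials$excluded[cens]))
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(lit_params(v = 1, a = -1, zr = 0.5, lam = 1), "'a'")
  expect_error(lit_params(v = 1, a = 1, zr = 1.2, lam = 1), "'zr'")
  expect_error(lit_params(v = 1, a = 1, zr = 0.5, lam = 0), "'lam'")
  p <- lit_params(v = 1, a = 1, zr = 0.5, lam = 1)
  expect_error(simulate_lit(p, n_trials = 10, dt = -0.01), "dt")
  expect_error(simulate_lit(p, n_trials = 10, dt = 0.1, t_max = 0.01))
  expect_error(simulate_lit(p, condition = 5, n_trials = 10), "condition")
})

test_that("non-decision times follow the truncated gaussian", {
  x <- rtrunc_gauss(20000, 0.1, 0.2, seed = 3)
  expect_true(all(x >= 0))
  # moments against direct rejection oracle
  set.seed(99)
  y <- rnorm(2e5, 0.1, 0.2); y <- y[y >= 0]
  expect_lt(abs(mean(x) - mean(y)), 0.01)
  expect_equal(rtrunc_gauss(5, 0.3, 0), rep(0.3, 5))
})
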