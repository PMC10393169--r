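test_that("grid solver respects symmetry and the analytic hitting probability", {
  eff0 <- list(a_eff = 2, x0_eff = 0, v = 0, c = 0, sigma_star = 1)
  g0 <- grid_pdf(eff0, t_max = 6)
  expect_lt(abs(g0$mass_up - 0.5), 1e-3)
  expect_true(all(g0$g_up >= 0) && all(g0$g_lo >= 0))
  expect_lt(g0$mass_err, 1e-3)
  eff1 <- list(a_eff = 2, x0_eff = 0, v = 1, c = 0, sigma_star = 1)
  g1 <- grid_pdf(eff1, t_max = 6)
  analytic <- (1 - exp(-2)) / (1 - exp(-4))
  expect_lt(abs(g1$mass_up - analytic), 2e-3)
})

test_that("grid densities agree with a fine-step simulation histogram", {
  # the Euler scheme detects crossings on grid points only, which acts as
  # a boundary widening of 0.5826 sigma sqrt(dt) per wall; the comparison
  # applies that standard correction to put solver and simulation on the
  # same footing
  dt_sim <- 1e-4
  a_corr <- 2 + 2 * 0.5826 * sqrt(dt_sim)
  eff <- list(a_eff = a_corr, x0_eff = 0.2, v = 1, c = 0, sigma_star = 1)
  g <- grid_pdf(eff, t_max = 5)
  p <- lit_params(v = 1, a = 2, zr = 0.2 / 2 + 0.5, lam = Inf, Ter = 0,
                  nd_sd = 0)
  s <- simulate_ddm(p, n_trials = 1e5, dt = dt_sim, t_max = 5, seed = 31)
  up <- s$paths$fpt[s$paths$boundary == 1L]
  # chi-square over 20 equal-mass bins of the model's upper density
  Fu <- cumsum(g$g_up) * g$dt
  qs <- approx(Fu / g$mass_up, g$time, xout = seq(0.05, 0.95, by = 0.05),
               ties = "ordered")$y
  counts <- table(cut(up, breaks = c(0, qs, Inf)))
  expected <- length(up) / 20
  chi2 <- sum((counts - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 19))
  expect_lt(abs(length(up) / 1e5 - g$mass_up), 5e-3)
})

test_that("grid refinement changes the solution by less than a percent", {
  eff <- list(a_eff = 2, x0_eff = 0, v = 1, c = 0, sigma_star = 1)
  g <- grid_pdf(eff, t_max = 5, dt = 0.002, dx_frac = 0.005)
  gf <- grid_pdf(eff, t_max = 5, dt = 0.001, dx_frac = 0.0025)
  fine <- approx(gf$time, gf$g_up, xout = g$time)$y
  expect_lt(max(abs(g$g_up - fine), na.rm = TRUE) / max(g$g_up), 0.01)
})

test_that("collapsing bounds absorb all mass before completion", {
  eff <- list(a_eff = 2, x0_eff = 0, v = 0.5, c = 1, sigma_star = 1)
  g <- grid_pdf(eff, t_max = 4)
  expect_gt(g$mass_up + g$mass_lo, 0.999)
  expect_lt(max(g$time[g$g_up > 1e-8]), 2 + 0.05)
})

test_that("solver rejects a start on the boundary", {
  expect_error(grid_pdf(list(a_eff = 2, x0_eff = 1, v = 0, c = 0,
                             sigma_star = 1)), "start")
})

test_that("quantile likelihood is deterministic and scales with counts", {
  p <- lit_params(v = c(1, 2), a = 1.5, zr = 0.5, lam = Inf, Ter = 0.3,
                  nd_sd = 0.05)
  dat <- sim_trials(p, 150, seed = 5)
  n1 <- quantile_nll(p, dat, model = "ddm", n_sim = 2000, seed = 9)
  n2 <- quantile_nll(p, dat, model = "ddm", n_sim = 2000, seed = 9)
  expect_identical(n1, n2)
  # doubling every observed count doubles the log-likelihood
  dat2 <- rbind(dat, dat)
  class(dat2) <- c("trial_table", "data.frame")
  n3 <- quantile_nll(p, dat2, model = "ddm", n_sim = 2000, seed = 9)
  expect_equal(n3, 2 * n1, tolerance = 1e-10)
})

test_that("the quantile likelihood prefers the generating parameters", {
  p <- lit_params(v = c(1, 2), a = 1.2, zr = 0.5, lam = Inf, Ter = 0.3,
                  nd_sd = 0.04)
  p_wide <- lit_params(v = c(1, 2), a = 1.8, zr = 0.5, lam = Inf, Ter = 0.3,
                       nd_sd = 0.04)
  wins <- vapply(1:20, function(r) {
    dat <- sim_trials(p, 200, seed = 100 + r)
    quantile_nll(p, dat, "ddm", n_sim = 2000, seed = 7) <
      quantile_nll(p_wide, dat, "ddm", n_sim = 2000, seed = 7)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("information criterion and model configurations are as stated", {
  expect_equal(bic(10, 0, 50), 20)
  expect_equal(bic(0, 2, exp(1)), 2)
  # LIT vs DDM difference on shared data reduces to 2 dNLL + log n
  expect_equal(bic(101, 9, 400) - bic(100, 8, 400), 2 + log(400))
  expect_equal(nll_model_config("ddm")$n_free, 8)
  expect_equal(nll_model_config("lit")$n_free, 9)
  expect_true("lam_speed" %in% nll_model_config("lit")$parameters)
  expect_true("a_speed" %in% nll_model_config("ddm")$parameters)
})
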