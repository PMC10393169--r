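test_that("the boundary-inflation constant comes out of the zeta evaluation", {
  expect_equal(round(inflation_coefficient(), 4), 2.0653)
  h <- hagan_mapping(lam = 1, sigma_star = 1)
  # components recompose into the stated form: 2 eps sigma |zeta(1/2)|
  expect_equal(2 * h$eps * h$sigma * abs(h$zeta_half),
               inflation_coefficient(), tolerance = 1e-12)
  expect_lt(h$zeta_half, 0)
  expect_error(hagan_mapping(Inf))
})

test_that("effective parameters follow the leak mapping", {
  p <- lit_params(v = 1, a = 1, zr = 0.5, lam = 1)
  eff <- effective_params(p)
  expect_equal(eff$a_eff, 3.0653, tolerance = 1e-4)
  expect_equal(eff$x0_eff, 1)           # x0 + v/lam = 0 + 1
  p4 <- lit_params(v = 1, a = 1, zr = 0.5, lam = 4, Ter = 0.3)
  expect_equal(effective_params(p4)$Ter_eff, 0.675)
  # identity in the no-memory limit
  pi_ <- lit_params(v = 2, a = 1.3, zr = 0.4, lam = Inf, Ter = 0.25)
  ei <- effective_params(pi_)
  expect_equal(ei$a_eff, 1.3)
  expect_equal(ei$x0_eff, pi_$x0)
  expect_equal(ei$Ter_eff, 0.25)
})

test_that("simulated boundary inflation scales as the mapping predicts", {
  # regression oracle: the LIT's extra mean first-passage lag over the
  # same-bound diffusion matches the a' inflation effect, proportional to
  # sqrt(inverse leak)
  lags <- vapply(c(0.125, 0.25), function(li) {
    a <- 4
    p <- lit_params(v = 0.001, a = a, zr = 0.5, lam = 1 / li, Ter = 0,
                    nd_sd = 0)
    lit <- simulate_lit(p, n_trials = 8000, t_max = 40, seed = 3)
    pd <- lit_params(v = 0.001, a = a, zr = 0.5, lam = Inf, Ter = 0,
                     nd_sd = 0)
    ddm <- simulate_ddm(pd, n_trials = 8000, t_max = 40, seed = 5)
    mean(lit$paths$fpt[lit$paths$boundary != 0]) -
      mean(ddm$paths$fpt[ddm$paths$boundary != 0])
  }, numeric(1))
  k <- inflation_coefficient()
  pred <- vapply(c(0.125, 0.25), function(li)
    (2 * 4 * k * sqrt(li) + (k * sqrt(li))^2) / 4, numeric(1))
  expect_lt(max(abs(lags - pred) / pred), 0.15)
})

test_that("effective bound collapses linearly to zero", {
  p <- lit_params(v = 1, a = 2, zr = 0.5, lam = Inf, c = 0.5)
  eff <- effective_params(p)
  expect_equal(effective_bound(0, eff), 2)
  expect_equal(eff$completion_time, 4)
  expect_equal(effective_bound(4, eff), 0)
  expect_equal(effective_bound(2, eff),
               (effective_bound(0, eff) + effective_bound(4, eff)) / 2)
  p0 <- lit_params(v = 1, a = 2, zr = 0.5, lam = Inf, c = 0)
  expect_equal(effective_bound(c(0, 1, 5), effective_params(p0)),
               rep(2, 3))
})

test_that("urgency variants expose equal free-parameter counts", {
  vt <- variant_table()
  expect_setequal(vt$variant, c("leak", "bound", "collapse"))
  expect_true(all(vt$n_free == vt$n_free[1]))
  # exactly one parameter carries the urgency code per variant
  u_count <- rowSums(vt[, c("inv_leak", "a", "c")] == "U")
  expect_true(all(u_count == 1))
  expect_true(all(vt$v == "S"))
})
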