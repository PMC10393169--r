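test_that("time scalar is a ratio of condition-mean spreads", {
  expect_equal(time_scalar(c(1, 1.2, 1.4), c(1, 1.2, 1.4)), 1)
  expect_equal(time_scalar(c(0.5, 0.6, 0.7, 0.8), c(1.0, 1.2, 1.4, 1.6)),
               0.5)
  # a shared non-decision constant cancels
  expect_equal(time_scalar(c(0.5, 0.6, 0.7, 0.8) + 0.3,
                           c(1.0, 1.2, 1.4, 1.6)), 0.5)
  expect_equal(time_scalar(c(0.5, 0.6), c(1, 1.2) + 5), 0.5)
  expect_error(time_scalar(c(1, 2), c(1, 1)), "degenerate")
  expect_error(time_scalar(1, 1))
})

test_that("the distribution distance is invariant to a shared shift only", {
  p <- lit_params(v = c(1, 2), a = 2, zr = 0.5, lam = Inf, Ter = 0.3,
                  nd_sd = 0.03)
  dat <- sim_trials(p, 400, seed = 3)
  model <- list("1" = grid_pdf(list(a_eff = 2, x0_eff = 0, v = 1, c = 0,
                                    sigma_star = 1)),
                "2" = grid_pdf(list(a_eff = 2, x0_eff = 0, v = 2, c = 0,
                                    sigma_star = 1)))
  o <- dstar_objective(model, dat)
  shifted <- lapply(model, function(d) { d$time <- d$time + 0.2; d })
  o_shift <- dstar_objective(shifted, dat)
  expect_lt(abs(unclass(o) - unclass(o_shift)), 1e-10)
  expect_equal(attr(o_shift, "shift"), attr(o, "shift") - 0.2)
  # shifting a single condition is detected
  one <- model; one[["1"]]$time <- one[["1"]]$time + 0.2
  expect_gt(unclass(dstar_objective(one, dat)) / unclass(o), 2)
  # a clearly wrong model scores worse than the generator
  wrong <- list("1" = model[["2"]], "2" = model[["1"]])
  expect_gt(unclass(dstar_objective(wrong, dat)), unclass(o))
  expect_error(dstar_objective(model["1"], dat), "missing")
})

test_that("the objective sits near its noise floor for model-drawn data", {
  p <- lit_params(v = c(1, 2), a = 2, zr = 0.5, lam = Inf, Ter = 0.25,
                  nd_sd = 0)
  model <- list("1" = grid_pdf(list(a_eff = 2, x0_eff = 0, v = 1, c = 0,
                                    sigma_star = 1)),
                "2" = grid_pdf(list(a_eff = 2, x0_eff = 0, v = 2, c = 0,
                                    sigma_star = 1)))
  objs <- vapply(1:5, function(r) {
    dat <- sim_trials(p, 1500, seed = 50 + r)
    unclass(dstar_objective(model, dat))
  }, numeric(1))
  perturbed <- list("1" = grid_pdf(list(a_eff = 2.6, x0_eff = 0, v = 1,
                                        c = 0, sigma_star = 1)),
                    "2" = grid_pdf(list(a_eff = 2.6, x0_eff = 0, v = 2,
                                        c = 0, sigma_star = 1)))
  dat <- sim_trials(p, 1500, seed = 50 + 1)
  expect_lt(max(objs), unclass(dstar_objective(perturbed, dat)))
  expect_lt(mean(objs), 0.01)
})

test_that("differential evolution solves a bounded quadratic", {
  target <- c(0.3, -1.2, 2.5)
  fit <- de_optim(function(x) sum((x - target)^2), lower = rep(-5, 3),
                  upper = rep(5, 3), n_pop = 20, n_gen = 60, seed = 4)
  expect_lt(max(abs(fit$par - target)), 0.01)
  fit2 <- de_optim(function(x) sum((x - target)^2), lower = rep(-5, 3),
                   upper = rep(5, 3), n_pop = 20, n_gen = 60, seed = 4)
  expect_identical(fit$par, fit2$par)
})
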