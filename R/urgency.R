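#' Bounded differential evolution optimizer
#'
#' Classic DE/rand/1/bin with reflection at the box bounds. Small and
#' deterministic given `seed`; used for the urgency-mechanism fits where
#' the objective (a grid-solver distribution distance) is cheap but
#' gradient-free.
#'
#' @param fn objective, called with a numeric parameter vector.
#' @param lower,upper box constraints.
#' @param n_pop population size (default 10 x dimension).
#' @param n_gen number of generations.
#' @param F_scale,cr mutation scale and crossover rate.
#' @param seed integer seed (local RNG state).
#' @param init optional matrix of starting members (one per row) included
#'   in the initial population.
#' @return list with `par`, `value`, `n_eval`, `converged` (budget flag:
#'   `FALSE` when the final generation still improved by more than 1%).
#' @export
de_optim <- function(fn, lower, upper, n_pop = NULL, n_gen = 60,
                     F_scale = 0.8, cr = 0.9, seed = 1L, init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  if (is.null(n_pop)) n_pop <- 10L * d
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  pop <- matrix(stats::runif(n_pop * d, lower, upper), n_pop, d, byrow = TRUE)
  if (!is.null(init)) {
    init <- matrix(pmin(pmax(t(init), lower), upper), ncol = d, byrow = TRUE)
    k <- min(nrow(init), n_pop)
    pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  val <- apply(pop, 1, fn)
  n_eval <- n_pop
  prev_best <- min(val)
  last_gain <- Inf
  for (g in seq_len(n_gen)) {
    for (i in seq_len(n_pop)) {
      idx <- sample(setdiff(seq_len(n_pop), i), 3L)
      trial <- pop[idx[1], ] + F_scale * (pop[idx[2], ] - pop[idx[3], ])
      jr <- sample.int(d, 1L)
      keep <- stats::runif(d) > cr & seq_len(d) != jr
      trial[keep] <- pop[i, keep]
      # reflect into the box
      for (rep_ in 1:3) {
        below <- trial < lower; trial[below] <- 2 * lower[below] - trial[below]
        above <- trial > upper; trial[above] <- 2 * upper[above] - trial[above]
      }
      trial <- pmin(pmax(trial, lower), upper)
      tv <- fn(trial)
      n_eval <- n_eval + 1L
      if (tv <= val[i]) { pop[i, ] <- trial; val[i] <- tv }
    }
    gb <- min(val)
    last_gain <- (prev_best - gb) / max(abs(prev_best), 1e-12)
    prev_best <- gb
  }
  ib <- which.min(val)
  list(par = pop[ib, ], value = val[ib], n_eval = n_eval,
       converged = is.finite(last_gain) && last_gain < 0.01)
}

# Parameter layout of the combined urgency model: theta =
# (v1..v4, zr, q1[, q2], ...) where each of inv_leak / a / c contributes one
# value when shared (".") or two (speed, accuracy) when varying ("U").
variant_layout <- function(variant, n_stim = 4L) {
  vt <- variant_table()
  row <- vt[vt$variant == variant, ]
  if (!nrow(row)) stop("unknown variant: ", variant)
  nm <- c(paste0("v", seq_len(n_stim)), "zr")
  for (p in c("inv_leak", "a", "c")) {
    nm <- c(nm, if (row[[p]] == "U") paste0(p, c("_speed", "_accuracy")) else p)
  }
  nm
}

variant_bounds <- function(names) {
  lo <- hi <- numeric(length(names))
  for (i in seq_along(names)) {
    n <- names[i]
    if (grepl("^v", n)) { lo[i] <- -4; hi[i] <- 8 }
    else if (n == "zr") { lo[i] <- 0.1; hi[i] <- 0.9 }
    else if (grepl("^inv_leak", n)) { lo[i] <- 0; hi[i] <- 4 }
    else if (grepl("^a", n)) { lo[i] <- 0.05; hi[i] <- 3 }
    else { lo[i] <- 0; hi[i] <- 3 }  # collapse rate
  }
  list(lower = lo, upper = hi)
}

# Effective diffusion parameters of the combined model for one urgency
# condition: leak enters through boundary inflation and start shift; its
# non-decision shift is absorbed by the per-urgency D* time shift.
combined_eff <- function(theta, names, urgency, condition, n_stim = 4L) {
  pick <- function(p) {
    iu <- match(paste0(p, "_", urgency), names)
    if (!is.na(iu)) theta[iu] else theta[match(p, names)]
  }
  v <- theta[condition]
  zr <- theta[n_stim + 1L]
  linv <- pick("inv_leak"); a <- pick("a"); cc <- pick("c")
  infl <- if (linv > 0) inflation_coefficient() * sqrt(linv) else 0
  list(a_eff = a + infl,
       x0_eff = a * (zr - 0.5) + v * linv,
       v = v, c = cc, sigma_star = 1)
}

#' Fit and compare the urgency-control mechanisms
#'
#' For each variant of [variant_table], minimizes the shift-invariant
#' distribution distance ([dstar_objective], applied per urgency condition
#' with independent shifts and summed) over the combined-model parameters
#' under that variant's constraints, using bounded differential evolution
#' with a fixed seed. Distributions come from the Crank-Nicolson grid
#' solver. All variants have the same number of free parameters, so the
#' minimized objectives are directly comparable and the smallest one
#' designates the winning mechanism.
#'
#' @param data trial table containing both urgency conditions and all
#'   stimulus conditions.
#' @param variants character vector of variants to fit.
#' @param n_pop,n_gen differential-evolution budget per variant.
#' @param seed integer seed (shared structure across variants).
#' @param dt,dx_frac grid-solver resolution.
#' @param shift_range common-shift search range per urgency condition.
#' @param polish_maxit Nelder-Mead iteration budget of the polish stages.
#' @return list with `objectives` (named), `winner`, `fits` (per-variant
#'   optimizer output with named parameters), `n_free` per variant.
#' @export
fit_urgency_models <- function(data, variants = c("leak", "bound", "collapse"),
                               n_pop = 27L, n_gen = 35L, seed = 1L,
                               dt = 0.004, dx_frac = 0.02,
                               shift_range = c(-0.1, 0.8),
                               polish_maxit = 450L) {
  urg <- intersect(c("speed", "accuracy"), unique(data$urgency))
  if (length(urg) < 2) stop("data must contain both urgency conditions")
  conds <- sort(unique(valid_trials(data)$condition))
  n_stim <- length(conds)
  # per-urgency comparison grid: up to the slowest response plus headroom,
  # so deadline-censored mass is treated symmetrically in model and data
  dat_cdfs <- lapply(urg, function(u) {
    du <- data[data$urgency == u, ]
    t_max <- max(valid_trials(du)$rt) + 0.25
    grid <- seq(0, ceiling(t_max / dt) * dt, by = dt)
    Fu <- Fl <- matrix(0, length(grid), n_stim)
    for (j in seq_along(conds)) {
      dc <- data_to_cdfs(du[du$condition == conds[j], ], grid)
      Fu[, j] <- dc$up; Fl[, j] <- dc$lo
    }
    list(up = Fu, lo = Fl, grid = grid)
  })
  names(dat_cdfs) <- urg
  s_lo <- as.integer(floor(shift_range[1] / dt))
  s_hi <- as.integer(ceiling(shift_range[2] / dt))
  objective_for <- function(nm) {
    force(nm)
    function(theta) {
      # graded penalty outside the admissible region (start inside the
      # bounds for every cell) so the optimizer can descend into it
      viol <- 0
      for (u in urg) for (j in seq_along(conds)) {
        eff <- combined_eff(theta, nm, u, j, n_stim)
        viol <- viol + max(0, abs(eff$x0_eff) - (eff$a_eff / 2 - 1e-3))
      }
      if (viol > 0) return(1e5 * (1 + viol))
      tot <- 0
      for (u in urg) {
        grid <- dat_cdfs[[u]]$grid
        n <- length(grid)
        t_max <- grid[n]
        Fm_up <- Fm_lo <- matrix(0, n, n_stim)
        for (j in seq_along(conds)) {
          eff <- combined_eff(theta, nm, u, j, n_stim)
          pdf <- tryCatch(
            grid_pdf(eff, t_max = t_max, dt = dt, dx_frac = dx_frac),
            error = function(e) NULL)
          if (is.null(pdf)) return(1e5)
          Fm_up[, j] <- cumsum(pdf$g_up) * dt
          Fm_lo[, j] <- cumsum(pdf$g_lo) * dt
        }
        tot <- tot + cpp_dstar_scan(Fm_up, Fm_lo, dat_cdfs[[u]]$up,
                                    dat_cdfs[[u]]$lo, s_lo, s_hi,
                                    dt, 4L)$objective
      }
      tot
    }
  }
  # moment-style warm starts: boundary from mean decision time, drifts
  # from observed accuracies at that boundary
  ok <- valid_trials(data)
  A_u <- vapply(urg, function(u)
    2 * sqrt(max(mean(ok$rt[ok$urgency == u]) - 0.3, 0.04)), numeric(1))
  A_bar <- mean(A_u)
  v_guess <- vapply(conds, function(cc) {
    acc <- mean(ok$choice[ok$condition == cc] == "upper")
    acc <- min(max(acc, 0.02), 0.98)
    stats::uniroot(function(v) absorb_prob_upper(v, A_bar / 2, A_bar) - acc,
                   c(-30, 30))$root
  }, numeric(1))
  inits_for <- function(nm) {
    base <- stats::setNames(numeric(length(nm)), nm)
    base[paste0("v", seq_len(n_stim))] <- v_guess
    base["zr"] <- 0.5
    fill <- function(b, a0, li_u, c_u) {
      for (p in names(li_u)) b[p] <- li_u[[p]]
      for (p in names(a0)) b[p] <- a0[[p]]
      for (p in names(c_u)) b[p] <- c_u[[p]]
      b
    }
    mk <- if ("inv_leak_speed" %in% nm) {
      a0 <- max(0.05, min(A_u) * 0.4)
      li <- pmax((A_u - a0) / inflation_coefficient(), 0.05)^2
      fill(base, c(a = a0),
           c(inv_leak_speed = li[[1]], inv_leak_accuracy = li[[2]]),
           c(c = 0.02))
    } else if ("a_speed" %in% nm) {
      li <- 0.25
      infl <- inflation_coefficient() * sqrt(li)
      fill(base, c(a_speed = max(0.05, A_u[[1]] - infl),
                   a_accuracy = max(0.05, A_u[[2]] - infl)),
           c(inv_leak = li), c(c = 0.02))
    } else {
      li <- 0.25
      infl <- inflation_coefficient() * sqrt(li)
      fill(base, c(a = max(0.05, max(A_u) - infl)), c(inv_leak = li),
           c(c_speed = 0.4, c_accuracy = 0.1))
    }
    jit <- sapply(1:3, function(i) mk * (1 + 0.15 * stats::rnorm(length(mk))))
    rbind(mk, t(jit))
  }
  # translate a fitted parameter vector into another variant's layout by
  # matching the per-urgency effective boundary separations
  translate_par <- function(par, from_nm, to_nm) {
    getp <- function(p, u) {
      iu <- match(paste0(p, "_", u), from_nm)
      if (!is.na(iu)) par[iu] else par[match(p, from_nm)]
    }
    kI <- inflation_coefficient()
    A_u <- vapply(c("speed", "accuracy"), function(u) {
      li <- getp("inv_leak", u)
      getp("a", u) + if (li > 0) kI * sqrt(li) else 0
    }, numeric(1))
    out <- stats::setNames(numeric(length(to_nm)), to_nm)
    out[seq_len(n_stim)] <- par[seq_len(n_stim)]
    out["zr"] <- par[match("zr", from_nm)]
    cc <- vapply(c("speed", "accuracy"), function(u) getp("c", u),
                 numeric(1))
    if ("inv_leak_speed" %in% to_nm) {
      a0 <- max(0.05, min(A_u) * 0.5)
      li <- pmin(pmax(((A_u - a0) / kI), 0.02)^2, 4)
      out["a"] <- a0
      out["inv_leak_speed"] <- li[[1]]; out["inv_leak_accuracy"] <- li[[2]]
      out["c"] <- mean(cc)
    } else if ("a_speed" %in% to_nm) {
      li <- min(getp("inv_leak", "speed"), 4)
      out["inv_leak"] <- li
      au <- pmax(A_u - kI * sqrt(li), 0.05)
      out["a_speed"] <- au[[1]]; out["a_accuracy"] <- au[[2]]
      out["c"] <- mean(cc)
    } else {
      li <- min(getp("inv_leak", "speed"), 4)
      out["inv_leak"] <- li
      out["a"] <- max(mean(A_u) - kI * sqrt(li), 0.05)
      out["c_speed"] <- max(cc[[1]], 0.2); out["c_accuracy"] <- cc[[2]]
    }
    out
  }
  # all remaining stochastic pieces (init jitter, polish perturbations) run
  # under a local stream derived from `seed`, so the fit is reproducible
  # regardless of the caller's RNG state
  rng_old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(rng_old)) assign(".Random.seed", rng_old, globalenv()))
  set.seed(as.integer((seed + 65537L) %% .Machine$integer.max))
  fits <- list()
  objs_fn <- list()
  for (vn in variants) {
    nm <- variant_layout(vn, n_stim)
    b <- variant_bounds(nm)
    obj <- objective_for(nm)
    objs_fn[[vn]] <- obj
    ini <- inits_for(nm)
    fit <- de_optim(obj, b$lower, b$upper, n_pop = n_pop,
                    n_gen = n_gen, seed = seed + match(vn, variants),
                    init = ini)
    # local polish (objective clamped into the box) of the DE optimum, the
    # moment-style warm start and a perturbed copy, keeping the best
    clamped <- function(th) obj(pmin(pmax(th, b$lower), b$upper))
    starts <- list(fit$par, ini[1, ],
                   fit$par * (1 + 0.08 * stats::rnorm(length(fit$par))))
    for (start in starts) {
      pol <- stats::optim(start, clamped, method = "Nelder-Mead",
                          control = list(maxit = polish_maxit))
      if (pol$value < fit$value) {
        fit$par <- pmin(pmax(pol$par, b$lower), b$upper)
        fit$value <- pol$value
      }
    }
    names(fit$par) <- nm
    fits[[vn]] <- fit
  }
  # symmetric cross-variant pass: every variant also polishes from the
  # other variants' optima translated into its own layout, so no variant
  # is disadvantaged by a single unlucky search
  for (vn in variants) {
    nm <- variant_layout(vn, n_stim)
    b <- variant_bounds(nm)
    obj <- objs_fn[[vn]]
    clamped <- function(th) obj(pmin(pmax(th, b$lower), b$upper))
    for (dn in setdiff(variants, vn)) {
      start <- translate_par(fits[[dn]]$par, variant_layout(dn, n_stim), nm)
      v0 <- clamped(start)
      # polish only promising translations: the pass exists to rescue a
      # variant whose own search missed, not to burn solver time
      if (v0 > 1.4 * fits[[vn]]$value) next
      pol <- stats::optim(start, clamped, method = "Nelder-Mead",
                          control = list(maxit = min(250L, polish_maxit)))
      if (pol$value < fits[[vn]]$value) {
        fits[[vn]]$par <- stats::setNames(pmin(pmax(pol$par, b$lower),
                                               b$upper), nm)
        fits[[vn]]$value <- pol$value
      }
    }
  }
  objectives <- vapply(fits, `[[`, numeric(1), "value")
  list(objectives = objectives,
       winner = names(objectives)[which.min(objectives)],
       fits = fits,
       n_free = vapply(variants, function(vn)
         length(variant_layout(vn, n_stim)), integer(1)))
}
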