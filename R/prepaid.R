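#' Build a prepaid database of unit-scale LIT choice-RT distributions
#'
#' Precomputes simulated LIT first-passage distributions on a unit time
#' scale (boundary separation fixed to 1; the data-scale boundary is later
#' recovered through time scaling) over a grid of relative starting points
#' `zr` in \[0.1, 0.9\] and inverse leaks `1/lambda` in \[0, 4\]. At each
#' grid point, 100 drift speeds are calibrated (through the effective
#' single-stage approximation and bisection) so the stored accuracies span
#' 0.001 to 0.999; the stored simulated accuracies are produced with common
#' random numbers across the drift ladder, so they are monotone in the
#' drift index. The `inv_leak = 0` slice uses the pure-diffusion sentinel.
#'
#' @param zr_grid,inv_leak_grid grid nodes (defaults: steps of 0.1 over
#'   \[0.1, 0.9\] and 0.5 over \[0, 4\]).
#' @param n_drift drifts per grid point (default 100).
#' @param n_sim simulated trials per stored distribution.
#' @param dt,t_max unit-scale simulation grid (s).
#' @param grid_step time step of the stored defective CDFs.
#' @param acc_range accuracy span of the drift ladder.
#' @param seed integer seed; each grid point derives its own stream, shared
#'   across its drift ladder (common random numbers).
#' @return A `prepaid_db` object.
#' @export
build_prepaid <- function(zr_grid = seq(0.1, 0.9, by = 0.1),
                          inv_leak_grid = seq(0, 4, by = 0.5),
                          n_drift = 100L, n_sim = 2000L,
                          dt = 0.0025, t_max = 10, grid_step = 0.02,
                          acc_range = c(0.001, 0.999), seed = 1L) {
  tgrid <- seq(0, t_max, by = grid_step)
  nz <- length(zr_grid); nl <- length(inv_leak_grid)
  acc_targets <- seq(acc_range[1], acc_range[2], length.out = n_drift)
  dims <- c(nz, nl, n_drift)
  Fup <- array(NA_real_, c(dims, length(tgrid)))
  Flo <- array(NA_real_, c(dims, length(tgrid)))
  mean_dt <- acc_sim <- v_unit <- array(NA_real_, dims)
  nsteps <- as.integer(round(t_max / dt))
  for (iz in seq_len(nz)) {
    for (il in seq_len(nl)) {
      zr <- zr_grid[iz]; linv <- inv_leak_grid[il]
      lam <- if (linv == 0) Inf else 1 / linv
      pseed <- seed + 100003L * iz + 1009L * il
      vv <- calibrate_drift_ladder(acc_targets, zr, linv)
      for (j in seq_len(n_drift)) {
        p <- lit_params(v = vv[j], a = 1, zr = zr, lam = lam, Ter = 0,
                        nd_sd = 0)
        raw <- cpp_simulate(n_sim, dt, nsteps, vv[j], 1, p$x0, 1, lam, 0,
                            0L, FALSE, 0L, 0L, as.double(pseed))
        ok <- raw$boundary != 0L
        fpt <- raw$fpt[ok]; bnd <- raw$boundary[ok]
        Fup[iz, il, j, ] <- findInterval(tgrid, sort(fpt[bnd == 1L])) / n_sim
        Flo[iz, il, j, ] <- findInterval(tgrid, sort(fpt[bnd == -1L])) / n_sim
        mean_dt[iz, il, j] <- mean(fpt)
        acc_sim[iz, il, j] <- mean(bnd == 1L)
        v_unit[iz, il, j] <- vv[j]
      }
    }
  }
  structure(list(zr_grid = zr_grid, inv_leak_grid = inv_leak_grid,
                 acc_targets = acc_targets, time = tgrid,
                 Fup = Fup, Flo = Flo, mean_dt = mean_dt,
                 acc_sim = acc_sim, v_unit = v_unit,
                 n_sim = n_sim, dt_sim = dt, seed = seed),
            class = "prepaid_db")
}

# Analytic absorption probability of a constant-drift diffusion between
# absorbing walls at 0 and A (sigma = 1), starting at z. Negative drifts go
# through the mirror identity to stay numerically stable.
absorb_prob_upper <- function(v, z, A) {
  if (abs(v) < 1e-12) return(z / A)
  if (v < 0) return(1 - absorb_prob_upper(-v, A - z, A))
  expm1(-2 * v * z) / expm1(-2 * v * A)
}

# Drift ladder via the effective single-stage approximation: solve
# P(upper) = target with the leak-inflated boundary separation. The
# start keeps its relative position (the drift-induced start shift cancels
# against an equal bound-center shift and so does not move the absorption
# probability).
calibrate_drift_ladder <- function(acc_targets, zr, inv_leak) {
  infl <- if (inv_leak > 0) inflation_coefficient() * sqrt(inv_leak) else 0
  A <- 1 + infl
  f <- function(v, target) {
    z <- (zr - 0.5) + A / 2      # absolute start inside the inflated walls
    z <- min(max(z, 1e-6), A - 1e-6)
    absorb_prob_upper(v, z, A) - target
  }
  vapply(acc_targets, function(tg) {
    stats::uniroot(f, interval = c(-100, 100), target = tg,
                   tol = 1e-8)$root
  }, numeric(1))
}

#' @export
print.prepaid_db <- function(x, ...) {
  cat(sprintf("prepaid_db: %d zr x %d inverse-leak nodes, %d drifts each\n",
              length(x$zr_grid), length(x$inv_leak_grid),
              length(x$acc_targets)))
  cat(sprintf("  %d simulated trials per distribution, unit grid to %g s\n",
              x$n_sim, max(x$time)))
  invisible(x)
}

#' Redraw first-passage samples from one prepaid grid point
#'
#' Re-runs the database's unit-scale generator (same simulator, same
#' parameter conventions) at a chosen grid point and drift index with a
#' larger number of trials, e.g. to compare the `inv_leak = 0` slice
#' against a direct diffusion simulation.
#'
#' @param db a `prepaid_db`.
#' @param zr,inv_leak grid point (must match nodes).
#' @param drift_index index into the drift ladder.
#' @param n number of trials.
#' @param seed integer seed.
#' @return list with `fpt` and `boundary` of the absorbed trials.
#' @export
prepaid_slice_sample <- function(db, zr, inv_leak, drift_index, n,
                                 seed = 1L) {
  iz <- match(zr, db$zr_grid); il <- match(inv_leak, db$inv_leak_grid)
  if (is.na(iz) || is.na(il)) stop("not a prepaid grid node")
  v <- db$v_unit[iz, il, drift_index]
  lam <- if (inv_leak == 0) Inf else 1 / inv_leak
  sim <- simulate_lit(lit_params(v = v, a = 1, zr = zr, lam = lam, Ter = 0,
                                 nd_sd = 0),
                      n_trials = n, dt = db$dt_sim, t_max = max(db$time),
                      seed = seed)
  ok <- sim$paths$boundary != 0L
  list(fpt = sim$paths$fpt[ok], boundary = sim$paths$boundary[ok], v = v)
}

#' Prepaid-grid fit of the LIT to behavioral data
#'
#' For every `(zr, 1/lambda)` node of the database: pick, per stimulus
#' condition, the drift whose simulated accuracy is closest to the
#' observed accuracy; estimate the time scalar from the condition-mean RTs
#' ([time_scalar]) and refine it over a small multiplicative grid by the
#' fit criterion (censoring of slow conditions biases the raw spread
#' ratio); rescale the stored unit distributions to the data time scale;
#' and evaluate the shift-invariant distance ([dstar_objective]). The
#' minimizing node gives the estimate, with boundary separation mapped
#' back from the time scalar (`a = sqrt(s)` for the unit boundary) and
#' drifts/leak rescaled accordingly. Deterministic given the database.
#'
#' @param data a trial table with all fitted stimulus conditions (a single
#'   urgency condition; speed and accuracy blocks are fitted independently).
#' @param db a `prepaid_db`.
#' @param dt,t_max,shift_range comparison grid passed to [dstar_objective].
#' @param s_refine multiplicative refinement factors applied to the Eq-style
#'   spread-ratio scalar at every node.
#' @return list with the fitted `params` ([lit_params]), `objective`,
#'   `zr`, `inv_leak` (data scale), `s_hat`, and the per-condition drift
#'   indices.
#' @export
prepaid_fit <- function(data, db, dt = 0.004, t_max = 5,
                        shift_range = c(-0.5, 1),
                        s_refine = exp(seq(-0.45, 0.45, length.out = 13)),
                        n_refine = 10L) {
  ok <- valid_trials(data)
  if (!nrow(ok)) stop("all trials censored or excluded")
  conds <- sort(unique(ok$condition))
  o_mean <- vapply(conds, function(cc) mean(ok$rt[ok$condition == cc]),
                   numeric(1))
  o_acc <- vapply(conds, function(cc) {
    oc <- ok[ok$condition == cc, ]
    mean(oc$choice == "upper")
  }, numeric(1))
  nz <- length(db$zr_grid); nl <- length(db$inv_leak_grid)
  # data CDFs are fixed across nodes: compute them once
  grid <- seq(0, t_max, by = dt)
  ng <- length(grid); k <- length(conds)
  Fd_up <- Fd_lo <- matrix(0, ng, k)
  for (j in seq_len(k)) {
    dc <- data_to_cdfs(data[data$condition == conds[j], ], grid)
    Fd_up[, j] <- dc$up; Fd_lo[, j] <- dc$lo
  }
  s_lo <- as.integer(floor(shift_range[1] / dt))
  s_hi <- as.integer(ceiling(shift_range[2] / dt))
  eval_node <- function(iz, il, jdx, s) {
    Fm_up <- Fm_lo <- matrix(0, ng, k)
    for (j in seq_len(k)) {
      Fu <- db$Fup[iz, il, jdx[j], ]
      Fl <- db$Flo[iz, il, jdx[j], ]
      Fm_up[, j] <- stats::approx(db$time * s, Fu, xout = grid, yleft = 0,
                                  yright = Fu[length(Fu)])$y
      Fm_lo[, j] <- stats::approx(db$time * s, Fl, xout = grid, yleft = 0,
                                  yright = Fl[length(Fl)])$y
    }
    cpp_dstar_scan(Fm_up, Fm_lo, Fd_up, Fd_lo, s_lo, s_hi, dt)$objective
  }
  # pass 1: every node at its raw spread-ratio scalar
  nodes <- expand.grid(iz = seq_len(nz), il = seq_len(nl))
  nodes$obj <- Inf
  nodes$s0 <- NA_real_
  jdx_of <- function(iz, il) vapply(o_acc, function(acc)
    which.min(abs(db$acc_sim[iz, il, ] - acc)), integer(1))
  for (r in seq_len(nrow(nodes))) {
    iz <- nodes$iz[r]; il <- nodes$il[r]
    jdx <- jdx_of(iz, il)
    m_mean <- db$mean_dt[cbind(iz, il, jdx)]
    if (any(!is.finite(m_mean))) next
    s0 <- tryCatch(time_scalar(o_mean, m_mean), error = function(e) NA)
    if (!is.finite(s0) || s0 <= 0) next
    nodes$s0[r] <- s0
    nodes$obj[r] <- eval_node(iz, il, jdx, s0)
  }
  if (!any(is.finite(nodes$obj)))
    stop("prepaid fit failed on every grid node")
  # pass 2: refine the time scalar on the most promising nodes, coarse
  # multiplicative grid first, then a fine sweep around each node's best
  top <- order(nodes$obj)[seq_len(min(n_refine, sum(is.finite(nodes$obj))))]
  best <- list(obj = Inf)
  fine <- exp(seq(-0.05, 0.05, length.out = 7))
  for (r in top) {
    iz <- nodes$iz[r]; il <- nodes$il[r]
    jdx <- jdx_of(iz, il)
    nb <- list(obj = Inf, s = NA_real_)
    for (s in nodes$s0[r] * s_refine) {
      obj <- eval_node(iz, il, jdx, s)
      if (obj < nb$obj) nb <- list(obj = obj, s = s)
    }
    for (s in nb$s * fine) {
      obj <- eval_node(iz, il, jdx, s)
      if (obj < nb$obj) nb <- list(obj = obj, s = s)
    }
    if (nb$obj < best$obj)
      best <- list(obj = nb$obj, iz = iz, il = il, jdx = jdx, s = nb$s)
  }
  s <- best$s
  zr <- db$zr_grid[best$iz]
  linv_unit <- db$inv_leak_grid[best$il]
  v_dat <- db$v_unit[best$iz, best$il, best$jdx] / sqrt(s)
  lam_dat <- if (linv_unit == 0) Inf else 1 / (linv_unit * s)
  params <- lit_params(v = v_dat, a = sqrt(s), zr = zr, lam = lam_dat,
                       Ter = 0, nd_sd = 0)
  list(params = params, objective = best$obj, zr = zr,
       inv_leak = linv_unit * s, s_hat = s, drift_index = best$jdx)
}

# A stored unit-scale distribution rescaled to data time: F_s(t) = F(t/s).
rescale_cdf_dist <- function(db, iz, il, j, s) {
  list(time = db$time * s,
       Fup = db$Fup[iz, il, j, ], Flo = db$Flo[iz, il, j, ])
}

# dstar evaluation when the model is given as CDFs rather than densities.
dstar_cdf_objective <- function(model, data, dt, t_max, shift_range) {
  conds <- sort(unique(valid_trials(data)$condition))
  grid <- seq(0, t_max, by = dt)
  n <- length(grid); k <- length(conds)
  Fm_up <- Fm_lo <- Fd_up <- Fd_lo <- matrix(0, n, k)
  for (j in seq_len(k)) {
    mc <- model[[as.character(conds[j])]]
    Fm_up[, j] <- stats::approx(mc$time, mc$Fup, xout = grid, yleft = 0,
                                yright = mc$Fup[length(mc$Fup)])$y
    Fm_lo[, j] <- stats::approx(mc$time, mc$Flo, xout = grid, yleft = 0,
                                yright = mc$Flo[length(mc$Flo)])$y
    dc <- data_to_cdfs(data[data$condition == conds[j], ], grid)
    Fd_up[, j] <- dc$up; Fd_lo[, j] <- dc$lo
  }
  cpp_dstar_scan(Fm_up, Fm_lo, Fd_up, Fd_lo,
                 as.integer(floor(shift_range[1] / dt)),
                 as.integer(ceiling(shift_range[2] / dt)), dt)$objective
}
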