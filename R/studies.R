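#' Two-sample Kolmogorov-Smirnov distance
#'
#' Sup-norm distance between the empirical CDFs of two samples.
#'
#' @param x,y numeric samples.
#' @export
ks_distance <- function(x, y) {
  x <- sort(x); y <- sort(y)
  all_ <- c(x, y)
  max(abs(findInterval(all_, x) / length(x) -
            findInterval(all_, y) / length(y)))
}

#' Fidelity of the effective-diffusion approximation to the LIT
#'
#' For each inverse leak, simulates LIT first-passage times and the
#' matched effective single-stage diffusion ([effective_params]), shifts
#' the diffusion times by the leak-induced non-decision increment
#' `3/(2 lambda)`, and reports the two-sample KS distance plus the
#' mean-decision-time offset against its theoretical value with its
#' Monte-Carlo standard error.
#'
#' @param inv_leaks inverse leaks to probe (s).
#' @param n trials per simulation.
#' @param v,a,zr generating primary-stage parameters.
#' @param dt,t_max simulation grid.
#' @param seed integer seed.
#' @return data.frame, one row per inverse leak: `ks`, `mean_offset`,
#'   `expected_offset` (= `3/(2 lambda)`), `offset_se`.
#' @export
reparam_fidelity_study <- function(inv_leaks = c(0.25, 0.5, 1), n = 1e5,
                                   v = 1, a = 2, zr = 0.5, dt = 0.001,
                                   t_max = 6, seed = 1L) {
  out <- lapply(inv_leaks, function(li) {
    lam <- 1 / li
    p <- lit_params(v = v, a = a, zr = zr, lam = lam, Ter = 0, nd_sd = 0)
    lit <- simulate_lit(p, n_trials = n, dt = dt, t_max = t_max,
                        seed = seed + 3L)
    eff <- effective_params(p)
    pd <- lit_params(v = v, a = eff$a_eff,
                     zr = eff$x0_eff / eff$a_eff + 0.5, lam = Inf,
                     Ter = 0, nd_sd = 0)
    ddm <- simulate_ddm(pd, n_trials = n, dt = dt, t_max = t_max,
                        seed = seed + 7L)
    shift <- 3 / (2 * lam)
    tl <- lit$paths$fpt[lit$paths$boundary != 0L]
    td <- ddm$paths$fpt[ddm$paths$boundary != 0L] + shift
    se <- sqrt(stats::var(tl) / length(tl) + stats::var(td) / length(td))
    data.frame(inv_leak = li,
               ks = ks_distance(tl, td),
               mean_offset = mean(tl) -
                 mean(ddm$paths$fpt[ddm$paths$boundary != 0L]),
               expected_offset = shift,
               offset_se = se,
               p_upper_lit = mean(lit$paths$boundary == 1L),
               p_upper_ddm = mean(ddm$paths$boundary == 1L))
  })
  do.call(rbind, out)
}

#' Pure-diffusion limit of the prepaid grid
#'
#' Draws first-passage samples from the database generator at an
#' `inv_leak = 0` node and compares them with a direct diffusion
#' simulation at the identical parameters via the two-sample KS test.
#'
#' @param db a `prepaid_db`.
#' @param zr grid node.
#' @param drift_index drift-ladder index.
#' @param n samples per side.
#' @param seed integer seed.
#' @return list with `ks`, `p_value`, `n`.
#' @export
prepaid_limit_study <- function(db, zr = 0.5, drift_index = 70L, n = 5e4,
                                seed = 1L) {
  sl <- prepaid_slice_sample(db, zr, 0, drift_index, n, seed = seed + 13L)
  p <- lit_params(v = sl$v, a = 1, zr = zr, lam = Inf, Ter = 0, nd_sd = 0)
  ddm <- simulate_ddm(p, n_trials = n, dt = db$dt_sim, t_max = max(db$time),
                      seed = seed + 31L)
  td <- ddm$paths$fpt[ddm$paths$boundary != 0L]
  kt <- suppressWarnings(stats::ks.test(sl$fpt, td))
  list(ks = unname(kt$statistic), p_value = kt$p.value,
       n = c(length(sl$fpt), length(td)))
}

#' Parameter-recovery experiment for the prepaid fit
#'
#' Replicated self-consistency check: data are generated from known LIT
#' parameters (four stimulus conditions) and refit with [prepaid_fit];
#' a replicate counts as recovered when the fitted relative start is
#' within `zr_tol` and the fitted inverse leak within `leak_tol` of the
#' truth.
#'
#' @param db a `prepaid_db`.
#' @param n_rep replicates.
#' @param n_trials trials per replicate (split over 4 conditions).
#' @param true_params generating [lit_params] (4 drifts).
#' @param zr_tol,leak_tol recovery tolerances.
#' @param seed integer seed.
#' @return list: `recovered` fraction, per-replicate `fits` data.frame.
#' @export
recovery_study <- function(db, n_rep = 20, n_trials = 5000,
                           true_params = lit_params(
                             v = c(0.3, 0.6, 1.0, 1.5), a = 1, zr = 0.5,
                             lam = 1, Ter = 0.3, nd_sd = 0.05),
                           zr_tol = 0.1, leak_tol = 0.5, seed = 1L) {
  per_cond <- n_trials %/% length(true_params$v)
  rows <- lapply(seq_len(n_rep), function(r) {
    tabs <- lapply(seq_along(true_params$v), function(cc) {
      simulate_lit(true_params, condition = cc, n_trials = per_cond,
                   t_max = 6, seed = seed + 1000L * r + cc)$trials
    })
    dat <- do.call(rbind, tabs)
    class(dat) <- c("trial_table", "data.frame")
    fit <- prepaid_fit(dat, db)
    data.frame(rep = r, zr = fit$zr, inv_leak = fit$inv_leak,
               s_hat = fit$s_hat, objective = fit$objective)
  })
  fits <- do.call(rbind, rows)
  hit <- abs(fits$zr - true_params$zr) <= zr_tol + 1e-9 &
    abs(fits$inv_leak - inv_leak(true_params)) <= leak_tol + 1e-9
  list(recovered = mean(hit), fits = fits,
       true = c(zr = true_params$zr, inv_leak = inv_leak(true_params)))
}

#' Simulate behavior from the combined urgency-control model family
#'
#' Generates a full study data set (both urgency conditions, all stimulus
#' cells, design deadlines) from the one-dimensional combined model: per
#' cell an effective diffusion with boundary `a_u + 2.0653 sqrt(li_u)`,
#' start `a_u (zr - 1/2) + v_c li_u`, collapse `c_u`, plus a
#' truncated-Gaussian non-decision time. This is the generator of the
#' mechanism-recovery experiment: the data-generating process is a member
#' of the family being compared.
#'
#' @param design a [synth_design].
#' @param v drifts per stimulus condition.
#' @param zr relative start.
#' @param inv_leak,a,c named numeric of length 1 (shared) or 2
#'   (`speed`/`accuracy` values).
#' @param Ter,nd_sd non-decision component (shared; any per-urgency
#'   non-decision difference is invisible to the shift-invariant fit).
#' @param seed integer seed.
#' @return a `trial_table`.
#' @export
generate_combined_behavior <- function(design, v = c(0.2, 0.45, 0.7, 1.0),
                                       zr = 0.5,
                                       inv_leak = c(speed = 0.3,
                                                    accuracy = 0.8),
                                       a = 0.3, c = 0,
                                       Ter = 0.25, nd_sd = 0.04,
                                       seed = 1L) {
  per <- function(x, u) if (length(x) > 1) x[[u]] else x[[1]]
  n_cell <- design$blocks_per_urgency * design$trials_per_block %/% 4L
  out <- list()
  for (u in c("speed", "accuracy")) {
    for (cond in seq_along(v)) {
      li <- per(inv_leak, u); au <- per(a, u); cu <- per(c, u)
      infl <- if (li > 0) inflation_coefficient() * sqrt(li) else 0
      a_eff <- au + infl
      x0_eff <- au * (zr - 0.5) + v[cond] * li
      p <- lit_params(v = v[cond], a = a_eff,
                      zr = min(max(x0_eff / a_eff + 0.5, 0.02), 0.98),
                      lam = Inf, Ter = Ter, nd_sd = nd_sd, c = cu)
      tt <- simulate_ddm(p, n_trials = n_cell, t_max = 2.5,
                         seed = seed + 911L * match(u, c("speed", "accuracy")) +
                           6007L * cond)$trials
      tt$urgency <- u
      tt$condition <- cond
      out[[paste(u, cond)]] <- tt
    }
  }
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  class(trials) <- c("trial_table", "data.frame")
  apply_deadline(trials, design$deadlines)
}

#' Urgency-mechanism identifiability experiment
#'
#' Model-recovery design: synthetic subjects are generated from a known
#' variant of the combined urgency-control family
#' ([generate_combined_behavior]) and refit with all variants under the
#' equal-parameter D*M comparison ([fit_urgency_models]); the study counts
#' how often the generating mechanism wins. Under the leak mechanism the
#' inverse leak differs between urgency conditions (0.3 s speed vs 0.8 s
#' accuracy, shared boundary); under the bound mechanism the boundary
#' separation differs (shared leak).
#'
#' @param n_subjects synthetic subjects.
#' @param generator `"leak"` or `"bound"`.
#' @param design a [synth_design] (study-sized trial counts).
#' @param n_pop,n_gen differential-evolution budget per variant.
#' @param seed integer seed.
#' @param dt,dx_frac solver resolution forwarded to [fit_urgency_models].
#' @return list: `winners` (character per subject), `win_rate` of the
#'   generating mechanism, `objectives` matrix.
#' @export
mechanism_identifiability_study <- function(n_subjects = 20,
                                            generator = c("leak", "bound"),
                                            design = synth_design(),
                                            n_pop = 27L, n_gen = 35L,
                                            seed = 1L, dt = 0.004,
                                            dx_frac = 0.02) {
  generator <- match.arg(generator)
  winners <- character(n_subjects)
  objs <- matrix(NA_real_, n_subjects, 3,
                 dimnames = list(NULL, c("leak", "bound", "collapse")))
  for (s in seq_len(n_subjects)) {
    trials <- if (generator == "leak") {
      generate_combined_behavior(design,
                                 inv_leak = c(speed = 0.3, accuracy = 0.8),
                                 a = 0.3, seed = seed + 7717L * s)
    } else {
      generate_combined_behavior(design, inv_leak = 0.5,
                                 a = c(speed = 0.15, accuracy = 0.75),
                                 seed = seed + 7717L * s)
    }
    fit <- fit_urgency_models(trials, n_pop = n_pop, n_gen = n_gen,
                              seed = seed + s, dt = dt,
                              dx_frac = dx_frac)
    winners[s] <- fit$winner
    objs[s, names(fit$objectives)] <- fit$objectives
  }
  list(winners = winners, win_rate = mean(winners == generator),
       objectives = objs, generator = generator)
}

#' Model-predicted signal-RT correlation signatures
#'
#' Simulates response-locked accumulator ensembles at the reference
#' conditions, superimposes measurement noise, and summarizes the
#' signal-RT correlation curves: the single-stage diffusion's evidence
#' curve (which decays to zero at the response and stays non-negative),
#' and for each inverse leak the LIT evidence curve (negative at the
#' response, with a zero-crossing lag that grows with the inverse leak)
#' and the LIT motor curve (zero at the response; peak lag grows with the
#' inverse leak).
#'
#' @param inv_leaks inverse leaks to probe (s).
#' @param n trials per simulation.
#' @param v,a,zr generating parameters (drift of the probed condition).
#' @param noise_sd measurement noise SD on the stacked signals.
#' @param lag_pre stack depth before the response (s).
#' @param seed integer seed.
#' @return list with `ddm` (curve summary) and `lit` (data.frame per
#'   inverse leak: evidence `r0`/zero-crossing, motor `r0`/peak lag), plus
#'   the curves themselves.
#' @export
fig_signature_study <- function(inv_leaks = c(0.25, 0.5, 1), n = 1e5,
                                v = 1.5, a = 1, zr = 0.5, noise_sd = 0.015,
                                lag_pre = 0.6, seed = 1L) {
  stack_w <- c(lag_pre, 0)
  pd <- lit_params(v = v, a = a, zr = zr, lam = Inf, Ter = 0, nd_sd = 0)
  dsim <- simulate_ddm(pd, n_trials = n, t_max = 4, seed = seed + 1L,
                       stack_window = stack_w, stack_signal = "x")
  dst <- response_locked_stack(dsim$paths, "x")
  rm(dsim); gc(FALSE)
  dst$stack <- add_measurement_noise(dst$stack, noise_sd, seed = seed + 2L)
  ddm_curve <- signal_rt_correlation(dst, min_n = 200L)
  rm(dst); gc(FALSE)
  lit_rows <- list(); lit_curves <- list()
  for (li in inv_leaks) {
    p <- lit_params(v = v, a = a, zr = zr, lam = 1 / li, Ter = 0, nd_sd = 0)
    # the evidence and motor stacks of the same seeded simulation are
    # taken in two passes so only one 100k-trial matrix is resident
    sim <- simulate_lit(p, n_trials = n, t_max = 4, seed = seed + 10L,
                        stack_window = stack_w, stack_signal = "x")
    stx <- response_locked_stack(sim$paths, "x")
    rm(sim); gc(FALSE)
    stx$stack <- add_measurement_noise(stx$stack, noise_sd,
                                       seed = seed + 11L)
    ce <- signal_rt_correlation(stx, min_n = 200L)
    rm(stx); gc(FALSE)
    sim <- simulate_lit(p, n_trials = n, t_max = 4, seed = seed + 10L,
                        stack_window = stack_w, stack_signal = "y")
    sty <- response_locked_stack(sim$paths, "y")
    rm(sim); gc(FALSE)
    sty$stack <- add_measurement_noise(sty$stack, noise_sd,
                                       seed = seed + 12L)
    cm <- signal_rt_correlation(sty, min_n = 200L)
    rm(sty); gc(FALSE)
    lit_rows[[as.character(li)]] <- data.frame(
      inv_leak = li,
      evidence_r0 = curve_at_response(ce),
      evidence_zero_lag = zero_crossing(ce),
      motor_r0 = curve_at_response(cm),
      motor_peak_lag = peak_time(cm))
    lit_curves[[as.character(li)]] <- list(evidence = ce, motor = cm)
  }
  list(ddm = list(r0 = curve_at_response(ddm_curve),
                  min_r = min(ddm_curve$r, na.rm = TRUE),
                  curve = ddm_curve),
       lit = do.call(rbind, lit_rows),
       curves = lit_curves)
}

#' Mean accumulator trajectories at the threshold crossing
#'
#' Response-locked mean evidence signals for a low and a high drift
#' condition, for the LIT and the single-stage diffusion: under the LIT
#' the two conditions' means cross before the response and differ at it
#' (high above low), while the diffusion pins both to the boundary at the
#' crossing.
#'
#' @param v_low,v_high condition drifts.
#' @param inv_leak LIT inverse leak (s).
#' @param n trials per condition.
#' @param a,zr shared parameters.
#' @param seed integer seed.
#' @return list with per-model matrices of mean signals (`lags` x 2).
#' @export
threshold_profile_study <- function(v_low = 0.8, v_high = 2, inv_leak = 0.5,
                                    n = 2e4, a = 1, zr = 0.5, seed = 1L) {
  run <- function(v, lam, fun) {
    p <- lit_params(v = v, a = a, zr = zr, lam = lam, Ter = 0, nd_sd = 0)
    sim <- fun(p, n_trials = n, t_max = 4, seed = seed,
               stack_window = c(0.6, 0), stack_signal = "x")
    st <- response_locked_stack(sim$paths, "x")
    up <- sim$paths$boundary[sim$paths$boundary != 0L] == 1L
    list(mean = colMeans(st$stack[up, , drop = FALSE], na.rm = TRUE),
         lags = st$lags)
  }
  lam <- 1 / inv_leak
  lit_lo <- run(v_low, lam, simulate_lit)
  lit_hi <- run(v_high, lam, simulate_lit)
  ddm_lo <- run(v_low, Inf, simulate_ddm)
  ddm_hi <- run(v_high, Inf, simulate_ddm)
  list(lags = lit_lo$lags,
       lit = cbind(low = lit_lo$mean, high = lit_hi$mean),
       ddm = cbind(low = ddm_lo$mean, high = ddm_hi$mean))
}

# strict local maxima of a sequence (interior points above both neighbors)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
}

#' End-to-end recovery of planted components from synthetic EEG
#'
#' Runs the decoding and motor-extraction pipeline on default synthetic
#' EEG for a small group of synthetic participants and summarizes:
#' correlation of the forward-model topography at the response with the
#' planted evidence topography; the response-locked Az profile and its
#' early-elevation / dip / late-elevation structure (the two
#' discrimination peaks); the per-urgency evidence-signal-RT zero-crossing
#' lags, estimated on Fisher-z participant-averaged curves; and the
#' contralateral lateralization of the hand-split motor topographies
#' (whose estimation never touches hand labels). Scalar metrics are
#' averaged across participants.
#'
#' @param design a [synth_design].
#' @param seed integer seed; participant p uses `seed + 1000 (p - 1)`.
#' @param n_participants synthetic participants to aggregate (the
#'   zero-crossing ordering is a group-level claim).
#' @param shrinkage covariance shrinkage for the decoder. The default is a
#'   strong fixed intensity: for single-trial component extraction a
#'   heavily shrunk (matched-filter-like) discriminant recovers the
#'   component time course more faithfully than the variance-optimal
#'   whitened solution, which suppresses the high-variance evidence
#'   direction itself.
#' @return list of summary quantities (see details in the vignette).
#' @export
eeg_recovery_study <- function(design = synth_design(), seed = 1L,
                               n_participants = 3L, shrinkage = 0.7) {
  subs <- lapply(seq_len(n_participants), function(p)
    eeg_recover_one(design, seed + 1000L * (p - 1L), shrinkage))
  # Fisher-z average of the per-urgency evidence-signal-RT curves
  zl <- vapply(c("speed", "accuracy"), function(u) {
    zs <- sapply(subs, function(s) atanh(pmin(pmax(s$curves[[u]]$r,
                                                   -1 + 1e-12),
                                              1 - 1e-12)))
    cv <- subs[[1]]$curves[[u]]
    cv$r <- tanh(rowMeans(zs))
    zero_crossing(cv)
  }, numeric(1))
  first <- subs[[1]]
  list(topo_cor = mean(vapply(subs, `[[`, numeric(1), "topo_cor")),
       az = first$az, az_centers = first$az_centers,
       az_early_max = mean(vapply(subs, `[[`, numeric(1), "az_early_max")),
       az_dip = mean(vapply(subs, `[[`, numeric(1), "az_dip")),
       az_late_max = mean(vapply(subs, `[[`, numeric(1), "az_late_max")),
       two_discrimination_peaks =
         all(vapply(subs, `[[`, logical(1), "two_peaks")),
       zero_lag_speed = zl[["speed"]],
       zero_lag_accuracy = zl[["accuracy"]],
       lateralization = rowMeans(vapply(subs, `[[`, numeric(3),
                                        "lateralization")),
       motor_r0 = mean(vapply(subs, `[[`, numeric(1), "motor_r0")),
       participants = subs)
}

# single synthetic participant: decode, project, extract, summarize
eeg_recover_one <- function(design, seed, shrinkage) {
  beh <- generate_behavior(design, seed = seed)
  synth <- generate_eeg(design, beh, seed = seed + 1L)
  ep <- synth$epochs
  meta <- ep$metadata
  coh <- ifelse(meta$condition %in% c(2L, 4L), "high", "low")
  disc <- sliding_discrimination(ep, coh, shrinkage = shrinkage)
  i0 <- which.min(abs(disc$centers))
  w0 <- structure(list(w = disc$filters[, i0], shrinkage = shrinkage,
                       levels = c("low", "high")), class = "spatial_filter")
  evid <- project_signal(ep, w0)
  idx0 <- which(abs(ep$times) <= 0.025 + 1e-9)
  # orient the projection as an upward accumulation: high-evidence trials
  # sit above low-evidence trials at the response (label-based, no ground
  # truth involved)
  if (mean(evid[coh == "high", idx0]) < mean(evid[coh == "low", idx0]))
    evid <- -evid
  # forward topography at the response window, against the planted mixing
  Xr <- t(vapply(seq_along(ep$channels), function(ch)
    as.numeric(ep$data[, ch, idx0]), numeric(length(idx0) * nrow(evid))))
  yr <- as.numeric(evid[, idx0])
  topo <- forward_model(Xr, yr)
  topo_cor <- abs(stats::cor(topo, synth$truth$evidence_topo))
  # discrimination profile: early/late elevations separated by a dip
  az_s <- smooth_ma(disc$az, 3L)
  early <- disc$centers <= -0.25
  mid <- disc$centers > -0.25 & disc$centers < -0.05
  late <- disc$centers >= -0.05
  az_early_max <- max(az_s[early]); az_dip <- min(az_s[mid])
  az_late_max <- max(az_s[late])
  # per-urgency signal-RT curves from the decoded evidence signal
  pre <- ep$times <= 0
  curves <- lapply(c(speed = "speed", accuracy = "accuracy"), function(u) {
    tr <- which(meta$urgency == u)
    signal_rt_correlation(evid[tr, pre, drop = FALSE],
                          rts = meta$rt[tr], lags = ep$times[pre])
  })
  # motor stage: weights from high-evidence trials only, no hand labels
  high <- which(coh == "high")
  snap <- slope_snapshots(ep, evid, subset = high)
  w_m <- motor_weights(snap)
  msig <- motor_signal(ep, w_m)
  # orient the motor signal as a pre-response buildup (label-free)
  pre_idx <- ep$times >= -0.15 & ep$times <= 0
  mm <- colMeans(msig[, pre_idx, drop = FALSE])
  if (utils::tail(mm, 1) < mm[1]) {
    w_m <- -w_m
    msig <- -msig
  }
  tmap <- motor_topography(ep, msig, split_by_hand = TRUE)
  side <- channel_side(ep$channels)
  central <- grepl("^(FC|C|CP)", ep$channels) & side != "mid"
  per_hand <- c(left = mean(tmap$left[central & side == "right"]) -
                  mean(tmap$left[central & side == "left"]),
                right = mean(tmap$right[central & side == "left"]) -
                  mean(tmap$right[central & side == "right"]))
  # joint contralateral contrast: left-minus-right hand map difference,
  # right-minus-left hemisphere (cancels activity common to both hands)
  dmap <- tmap$left - tmap$right
  lateralization <- c(per_hand,
                      contrast = mean(dmap[central & side == "right"]) -
                        mean(dmap[central & side == "left"]))
  cv_m <- signal_rt_correlation(msig[, pre, drop = FALSE], rts = meta$rt,
                                lags = ep$times[pre])
  list(topo_cor = topo_cor,
       az = disc$az, az_centers = disc$centers,
       az_early_max = az_early_max, az_dip = az_dip,
       az_late_max = az_late_max,
       two_peaks = az_early_max > az_dip && az_late_max > az_dip,
       curves = curves,
       lateralization = lateralization,
       motor_r0 = curve_at_response(cv_m))
}
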