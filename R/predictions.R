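#' Response-locked stack of simulated accumulator paths
#'
#' Re-indexes each absorbed trial's signal so that its threshold crossing
#' sits at `t = 0`. Uses the memory-light response-locked stack stored by
#' the simulator when available; otherwise slices the retained full paths.
#' Samples before the trial start are `NA` (ragged stacking, no padding);
#' censored trials are dropped.
#'
#' @param paths a `path_ensemble` (from [simulate_lit]/[simulate_ddm],
#'   with `keep_paths = TRUE` or a `stack_window`).
#' @param signal `"x"` (evidence) or `"y"` (motor).
#' @param lags response-locked times (s, <= 0 before the crossing); defaults
#'   to the stored stack lags.
#' @return list with `stack` (absorbed trials x lags), `lags`, `fpt` (the
#'   decision times of the stacked trials) and `dropped` (censored count).
#' @export
response_locked_stack <- function(paths, signal = c("x", "y"), lags = NULL) {
  signal <- match.arg(signal)
  ok <- paths$boundary != 0L
  dropped <- sum(!ok)
  if (dropped)
    message(dropped, " trial(s) without a crossing excluded from the stack")
  if (!is.null(paths$stack_lags) && is.null(lags)) {
    src <- if (signal == "x") paths$x_stack else paths$y_stack
    if (is.null(src))
      stop("requested signal was not stacked (see stack_signal)")
    mat <- src[ok, , drop = FALSE]
    return(list(stack = mat, lags = paths$stack_lags,
                fpt = paths$fpt[ok], dropped = dropped))
  }
  full <- if (signal == "x") paths$x else paths$y
  if (is.null(full))
    stop("paths were not retained; simulate with keep_paths or stack_window")
  if (is.null(lags)) lags <- seq(-0.5, 0, by = paths$dt)
  lag_steps <- round(lags / paths$dt)
  kcross <- round(paths$fpt[ok] / paths$dt)
  idx <- which(ok)
  mat <- matrix(NA_real_, length(idx), length(lags))
  for (r in seq_along(idx)) {
    cols <- kcross[r] + lag_steps + 1L
    inb <- cols >= 1L & cols <= ncol(full)
    mat[r, inb] <- full[idx[r], cols[inb]]
  }
  list(stack = mat, lags = lags, fpt = paths$fpt[ok], dropped = dropped)
}

#' Superimpose Gaussian measurement noise on signals
#'
#' Adds i.i.d. `N(0, sd)` noise to every (non-missing) entry, emulating
#' measurement noise and residues of unrelated processes on model-derived
#' signals before computing signal-RT correlations.
#'
#' @param signals numeric matrix (or vector).
#' @param sd noise standard deviation (default 0.015).
#' @param seed optional integer seed (local RNG state).
#' @export
add_measurement_noise <- function(signals, sd = 0.015, seed = NULL) {
  if (sd < 0) stop("'sd' must be >= 0")
  if (sd == 0) return(signals)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  noise <- stats::rnorm(length(signals), 0, sd)
  out <- signals + noise
  out[is.na(signals)] <- NA_real_
  out
}

# moving average with shrinking edge windows
smooth_ma <- function(v, k) {
  if (k <= 1L) return(v)
  n <- length(v)
  half <- k %/% 2L
  out <- numeric(n)
  isna <- is.na(v)
  v0 <- ifelse(isna, 0, v)
  cs <- cumsum(c(0, v0))
  cn <- cumsum(c(0, !isna))
  for (i in seq_len(n)) {
    a <- max(1L, i - half); b <- min(n, i + half)
    cnt <- cn[b + 1L] - cn[a]
    out[i] <- if (cnt > 0) (cs[b + 1L] - cs[a]) / cnt else NA_real_
  }
  out
}

#' Signal-RT correlation curve
#'
#' Per response-locked time point, the Pearson correlation across trials
#' between the momentary signal value and the trial's final RT, smoothed
#' with a moving average. Points supported by fewer than `min_n` trials are
#' dropped; a time point with (numerically) constant signal across trials
#' gets correlation 0 with a warning. Because Pearson correlation is
#' location-invariant, an additive offset shared by all trials leaves the
#' curve unchanged. Correlations can optionally be computed and smoothed on
#' the Fisher-z scale (for averaging across synthetic subjects) and are
#' back-transformed for the returned curve.
#'
#' @param stack trials x lags matrix (e.g. from [response_locked_stack]),
#'   or the list that function returns.
#' @param rts final response times of the stacked trials; defaults to the
#'   stack's decision times when a stack list is given.
#' @param lags response-locked times matching the stack columns.
#' @param smooth moving-average window (s); 0 disables smoothing.
#' @param dt lag grid step; inferred from `lags` when missing.
#' @param min_n minimum contributing trials per time point.
#' @param fisher compute/smooth on the Fisher-z scale.
#' @return A `signal_rt_curve`: `time` (lags), `r`, `n`, `smooth`.
#' @export
signal_rt_correlation <- function(stack, rts = NULL, lags = NULL,
                                  smooth = 0.05, dt = NULL, min_n = 10L,
                                  fisher = FALSE) {
  if (is.list(stack) && !is.null(stack$stack)) {
    if (is.null(rts)) rts <- stack$fpt
    if (is.null(lags)) lags <- stack$lags
    stack <- stack$stack
  }
  stopifnot(nrow(stack) == length(rts), ncol(stack) == length(lags))
  if (is.null(dt)) dt <- stats::median(diff(lags))
  M <- !is.na(stack)
  X <- ifelse(M, stack, 0)
  nt <- colSums(M)
  sx <- colSums(X)
  sxx <- colSums(X * X)
  sxy <- colSums(X * rts)
  sy <- colSums(M * rts)
  syy <- colSums(M * rts^2)
  varx <- nt * sxx - sx^2
  vary <- nt * syy - sy^2
  r <- rep(NA_real_, length(lags))
  good <- nt >= min_n & vary > 0
  flat <- good & varx <= .Machine$double.eps * pmax(nt * sxx, 1)
  if (any(flat)) {
    warning("constant signal across trials at ", sum(flat),
            " time point(s); correlation set to 0")
    r[flat] <- 0
  }
  use <- good & !flat
  r[use] <- (nt[use] * sxy[use] - sx[use] * sy[use]) /
    sqrt(varx[use] * vary[use])
  if (fisher) r <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  k <- if (smooth > 0) max(1L, as.integer(round(smooth / dt))) else 1L
  if (k %% 2L == 0L) k <- k + 1L
  keep <- !is.na(r)
  rs <- r
  rs[keep] <- smooth_ma(r[keep], k)
  if (fisher) rs <- tanh(rs)
  structure(list(time = lags, r = rs, n = nt, smooth = smooth, dt = dt),
            class = "signal_rt_curve")
}

#' Motor lag: zero-crossing of a signal-RT correlation curve
#'
#' The latest sign change from positive to negative before `t = 0`,
#' linearly interpolated, returned as a lag in seconds before the response
#' (positive). `NA` when the smoothed curve never crosses.
#'
#' @param curve a `signal_rt_curve`.
#' @export
zero_crossing <- function(curve) {
  t <- curve$time; r <- curve$r
  sel <- which(t <= 0 & !is.na(r))
  t <- t[sel]; r <- r[sel]
  cross <- which(r[-length(r)] > 0 & r[-1] <= 0)
  if (!length(cross)) return(NA_real_)
  i <- cross[length(cross)]
  tc <- t[i] + (t[i + 1] - t[i]) * r[i] / (r[i] - r[i + 1])
  -tc
}

#' Time of peak signal-RT correlation
#'
#' Arg-max of the smoothed curve at or before the response (`t <= 0`); ties
#' resolved to the earliest time. Returned as a lag in seconds before the
#' response (positive), like [zero_crossing].
#'
#' @param curve a `signal_rt_curve`.
#' @export
peak_time <- function(curve) {
  t <- curve$time; r <- curve$r
  sel <- which(t <= 0 & !is.na(r))
  if (!length(sel)) return(NA_real_)
  t <- t[sel]; r <- r[sel]
  -t[which.max(r)]
}

#' Correlation value of the curve at the response
#'
#' @param curve a `signal_rt_curve`.
#' @export
curve_at_response <- function(curve) {
  i <- which.min(abs(curve$time))
  curve$r[i]
}

#' @export
print.signal_rt_curve <- function(x, ...) {
  cat(sprintf("signal_rt_curve: %d lags (%g..%g s), smoothing %g s\n",
              length(x$time), min(x$time), max(x$time), x$smooth))
  cat(sprintf("  r(0) = %.3f, zero-crossing lag = %.3f s, peak lag = %.3f s\n",
              curve_at_response(x), zero_crossing(x), peak_time(x)))
  invisible(x)
}
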