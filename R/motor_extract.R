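#' Per-channel slope snapshots paired with concurrent evidence values
#'
#' For each (trial, window) pair, computes the ordinary least-squares slope
#' (with intercept) of every channel's raw signal inside a 50-ms window,
#' and pairs the snapshot with the trial's evidence-accumulation signal
#' averaged over the same window. Under the LIT the momentary slope of the
#' motor accumulation is proportional to the momentary evidence value, so
#' these pairs identify the motor component. Windows default to centers
#' from -150 ms to -50 ms before the response, every 25 ms; windows outside
#' the epoch support are dropped with a message.
#'
#' @param epochs an [eeg_epochs] object.
#' @param evidence trials x samples matrix of evidence-signal values
#'   time-aligned to `epochs` (e.g. from [project_signal]).
#' @param centers window centers (s).
#' @param width window width (s).
#' @param subset optional logical/integer trial subset (the weight fit uses
#'   high-sensory-evidence trials only).
#' @return list of class `slope_snapshots`: `S` (channels x K slopes), `e`
#'   (length-K evidence values), `S_bar` (per-snapshot channel-mean
#'   removed), `e_bar` (mean-removed), `trial`, `center` bookkeeping.
#' @export
slope_snapshots <- function(epochs, evidence,
                            centers = seq(-0.15, -0.05, by = 0.025),
                            width = 0.05, subset = NULL) {
  d <- epochs$data
  if (!is.null(subset)) {
    d <- d[subset, , , drop = FALSE]
    evidence <- evidence[subset, , drop = FALSE]
  }
  n <- dim(d)[1]; p <- dim(d)[2]
  stopifnot(nrow(evidence) == n, ncol(evidence) == dim(d)[3])
  ok <- centers - width / 2 >= min(epochs$times) - 1e-9 &
    centers + width / 2 <= max(epochs$times) + 1e-9
  if (any(!ok)) message(sum(!ok), " slope window(s) outside epoch support dropped")
  centers <- centers[ok]
  K <- n * length(centers)
  S <- matrix(NA_real_, p, K)
  e <- numeric(K)
  trial <- integer(K); cen <- numeric(K)
  k <- 0L
  for (wi in seq_along(centers)) {
    idx <- which(epochs$times >= centers[wi] - width / 2 - 1e-9 &
                   epochs$times <= centers[wi] + width / 2 + 1e-9)
    tt <- epochs$times[idx]
    tc <- tt - mean(tt)
    denom <- sum(tc^2)
    for (i in seq_len(n)) {
      k <- k + 1L
      # OLS slope with intercept: cov(t, v)/var(t) on the window samples
      S[, k] <- (d[i, , idx] %*% tc) / denom
      e[k] <- mean(evidence[i, idx])
      trial[k] <- i; cen[k] <- centers[wi]
    }
  }
  structure(list(S = S, e = e,
                 S_bar = sweep(S, 2, colMeans(S)),
                 e_bar = e - mean(e),
                 trial = trial, center = cen,
                 channels = epochs$channels),
            class = "slope_snapshots")
}

#' Motor-accumulator sensor weights from slope snapshots
#'
#' Least-squares solution of `w S_bar ~ e_bar` (centered snapshots against
#' centered evidence values) through the Moore-Penrose pseudoinverse, so
#' the spatially aggregated slope `w S_bar` matches the concurrent evidence
#' signal as closely as possible in the least-squares sense. The
#' channel-mean centering of each snapshot and the mean-centering of the
#' evidence make the solution invariant to constants added to either.
#' Rank-deficient snapshot matrices yield the minimum-norm solution with a
#' warning; an optional ridge penalty is available for stability. Hand
#' labels play no role anywhere in this estimation.
#'
#' @param snap a `slope_snapshots` object.
#' @param ridge ridge penalty (default 0 = pseudoinverse).
#' @return numeric channel weight vector.
#' @export
motor_weights <- function(snap, ridge = 0) {
  # fit with an intercept: the objective is a maximally *correlated*
  # aggregated slope, so each channel's snapshot mean is removed as well
  # (the stored S_bar is only centered over sensors within each snapshot)
  Sb <- snap$S_bar - rowMeans(snap$S_bar)
  eb <- snap$e_bar
  p <- nrow(Sb); K <- ncol(Sb)
  if (K <= p)
    warning("fewer snapshots than channels; minimum-norm solution")
  G <- tcrossprod(Sb)                 # p x p
  b <- as.numeric(Sb %*% eb)
  if (ridge > 0) return(as.numeric(solve(G + diag(ridge, p), b)))
  # the per-snapshot channel-mean removal makes G rank p - 1 by
  # construction; the pseudoinverse gives the minimum-norm solution there.
  # Anything below p - 1 signals genuinely degenerate snapshots.
  qrG <- qr(G)
  if (qrG$rank < p - 1L)
    warning("rank-deficient snapshot matrix; minimum-norm solution")
  as.numeric(MASS::ginv(G) %*% b)
}

#' Single-trial motor accumulation signal
#'
#' Channel-weighted sum of the response-locked data at every trial and
#' time point (a plain linear projection, so superposition holds).
#'
#' @param epochs an [eeg_epochs] object.
#' @param w channel weight vector (from [motor_weights]).
#' @return trials x samples matrix.
#' @export
motor_signal <- function(epochs, w) {
  stopifnot(length(w) == dim(epochs$data)[2])
  project_signal(epochs, w, zscore = FALSE)
}

#' Scalp topography of the motor accumulation signal
#'
#' Pearson correlation between each channel's activity and the motor
#' signal, computed over all (trial, sample) pairs inside a response
#' window, for all trials together and optionally split by responding
#' hand (the contralateral-bias validation: the estimation itself never
#' uses hand labels).
#'
#' @param epochs an [eeg_epochs] object; its metadata must carry a `hand`
#'   column when `split_by_hand = TRUE`.
#' @param msignal trials x samples motor signal (from [motor_signal]).
#' @param window time window (s) over which to correlate; the default
#'   (-0.15 to 0.05 s) spans the pre-response buildup, where the motor
#'   amplitude still varies across trials (at the threshold crossing
#'   itself the motor state is pinned, leaving little variance to
#'   correlate).
#' @param split_by_hand also return per-hand maps.
#' @return list with `all` (named per-channel correlations) and, when
#'   split, `left`/`right` maps over the corresponding trials.
#' @export
motor_topography <- function(epochs, msignal, window = c(-0.15, 0.05),
                             split_by_hand = FALSE) {
  idx <- which(epochs$times >= window[1] - 1e-9 &
                 epochs$times <= window[2] + 1e-9)
  corr_map <- function(trials) {
    y <- as.numeric(msignal[trials, idx])
    vapply(seq_along(epochs$channels), function(ch) {
      x <- as.numeric(epochs$data[trials, ch, idx])
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
      stats::cor(x, y)
    }, numeric(1))
  }
  all_tr <- seq_len(dim(epochs$data)[1])
  out <- list(all = stats::setNames(corr_map(all_tr), epochs$channels))
  if (split_by_hand) {
    hand <- epochs$metadata$hand
    if (is.null(hand)) stop("metadata lacks a 'hand' column")
    for (h in c("left", "right")) {
      tr <- which(hand == h)
      out[[h]] <- stats::setNames(corr_map(tr), epochs$channels)
    }
  }
  out
}
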