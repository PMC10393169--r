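#' Window-averaged channel values
#'
#' Time-averages each trial's samples within a window of `width` seconds
#' centered at `center`, returning a trials x channels matrix.
#'
#' @param epochs an [eeg_epochs] object.
#' @param center window center (s, response-locked).
#' @param width window width (s, default 0.05).
#' @export
window_average <- function(epochs, center, width = 0.05) {
  idx <- which(epochs$times >= center - width / 2 - 1e-9 &
                 epochs$times <= center + width / 2 + 1e-9)
  if (!length(idx)) stop("window outside epoch support")
  apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
}

# Class means, per-class covariances and their pooled average from a
# trials x channels matrix and a two-level label vector. Also keeps the
# class-centered observations for the shrinkage estimate.
class_stats <- function(X, labels) {
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("exactly two classes required")
  X1 <- X[labels == lv[1], , drop = FALSE]
  X2 <- X[labels == lv[2], , drop = FALSE]
  if (nrow(X1) < 2 || nrow(X2) < 2) stop("need >= 2 trials per class")
  S1 <- stats::cov(X1); S2 <- stats::cov(X2)
  Xc <- rbind(sweep(X1, 2, colMeans(X1)), sweep(X2, 2, colMeans(X2)))
  list(m1 = colMeans(X1), m2 = colMeans(X2), S1 = S1, S2 = S2,
       Sc = (S1 + S2) / 2, Xc = Xc, levels = lv)
}

# Ledoit-Wolf shrinkage intensity toward the scaled identity, from the
# class-centered observations: the ratio of the summed sampling variance
# of the covariance entries to the squared distance between the sample
# covariance and its identity target.
auto_shrinkage <- function(Sc, Xc = NULL) {
  p <- ncol(Sc)
  mu <- mean(diag(Sc))
  d2 <- sum((Sc - diag(mu, p))^2)
  if (d2 <= 0 || is.null(Xc)) return(0)
  n <- nrow(Xc)
  S_ml <- crossprod(Xc) / n
  phi <- 0
  for (k in seq_len(n)) {
    dk <- tcrossprod(Xc[k, ]) - S_ml
    phi <- phi + sum(dk * dk)
  }
  phi <- phi / n^2
  max(0, min(1, phi / d2))
}

#' Fisher-discriminant spatial filter
#'
#' Solves the pooled-covariance system `Sc w = m2 - m1` with shrinkage
#' regularization of `Sc` toward a scaled identity (needed when a 64 x 64
#' covariance is estimated from a few tens of trials). With identity
#' covariance the filter is proportional to the class-mean difference.
#'
#' @param stats class statistics from two-class window data (list with
#'   `m1`, `m2`, `Sc`, optionally `Xc`), e.g. built internally by
#'   [sliding_discrimination].
#' @param shrinkage shrinkage intensity in \[0, 1\] or `"auto"`
#'   (Ledoit-Wolf estimate from the class-centered window data).
#' @return list of class `spatial_filter`: `w` (channel weights), the
#'   shrinkage used and the class levels.
#' @export
fisher_weights <- function(stats, shrinkage = "auto") {
  Sc <- stats$Sc
  p <- ncol(Sc)
  g <- if (identical(shrinkage, "auto")) auto_shrinkage(Sc, stats$Xc)
       else as.numeric(shrinkage)
  St <- (1 - g) * Sc + g * diag(mean(diag(Sc)), p)
  w <- tryCatch(solve(St, stats$m2 - stats$m1),
                error = function(e)
                  stop("singular pooled covariance; increase shrinkage"))
  structure(list(w = as.numeric(w), shrinkage = g,
                 levels = stats$levels), class = "spatial_filter")
}

#' Sliding-window linear discrimination with leave-one-out Az
#'
#' For each 50-ms window stepped by 25 ms across the response-locked
#' interval, fits the Fisher discriminant on the window-averaged channel
#' values and quantifies discrimination as the area under the ROC curve
#' (Az) of leave-one-trial-out projections (class statistics refitted per
#' fold by downdating). Windows extending past the epoch support are
#' dropped with a message.
#'
#' @param epochs an [eeg_epochs] object.
#' @param labels two-level vector (e.g. low/high sensory evidence), length
#'   = trials.
#' @param width,step window width and step (s).
#' @param range window-center range (s), default -0.575..0.175.
#' @param shrinkage passed to [fisher_weights].
#' @return list: `centers`, `az` per window, `filters` (channels x
#'   windows matrix of full-data weights).
#' @export
sliding_discrimination <- function(epochs, labels, width = 0.05,
                                   step = 0.025, range = c(-0.575, 0.175),
                                   shrinkage = "auto") {
  centers <- seq(range[1], range[2], by = step)
  tmin <- min(epochs$times); tmax <- max(epochs$times)
  ok <- centers - width / 2 >= tmin - 1e-9 & centers + width / 2 <= tmax + 1e-9
  if (any(!ok)) message(sum(!ok), " window(s) past epoch support dropped")
  centers <- centers[ok]
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have two levels")
  n <- dim(epochs$data)[1]
  p <- dim(epochs$data)[2]
  az <- numeric(length(centers))
  filters <- matrix(NA_real_, p, length(centers))
  y01 <- as.integer(labels) - 1L
  for (wi in seq_along(centers)) {
    X <- window_average(epochs, centers[wi], width)
    st <- class_stats(X, labels)
    filters[, wi] <- fisher_weights(st, shrinkage)$w
    # the shrinkage intensity is estimated once per window and reused in
    # every leave-one-out fold
    g_w <- if (identical(shrinkage, "auto")) auto_shrinkage(st$Sc, st$Xc)
           else as.numeric(shrinkage)
    proj <- loo_projections(X, y01, g_w)
    az[wi] <- roc_az(proj, y01)
  }
  list(centers = centers, az = az, filters = filters,
       channels = epochs$channels)
}

# Leave-one-out projections: per held-out trial, refit class means and
# pooled covariance from the remaining trials (scatter downdating) and
# project the held-out observation.
loo_projections <- function(X, y01, shrinkage = "auto") {
  n <- nrow(X); p <- ncol(X)
  idx1 <- y01 == 0L; idx2 <- y01 == 1L
  n1 <- sum(idx1); n2 <- sum(idx2)
  s1 <- colSums(X[idx1, , drop = FALSE]); s2 <- colSums(X[idx2, , drop = FALSE])
  G1 <- crossprod(X[idx1, , drop = FALSE]); G2 <- crossprod(X[idx2, , drop = FALSE])
  proj <- numeric(n)
  for (i in seq_len(n)) {
    xi <- X[i, ]
    if (y01[i] == 0L) {
      m1 <- (s1 - xi) / (n1 - 1L); m2 <- s2 / n2
      C1 <- (G1 - tcrossprod(xi)) / (n1 - 2L) -
        tcrossprod(m1) * (n1 - 1L) / (n1 - 2L)
      C2 <- G2 / (n2 - 1L) - tcrossprod(m2) * n2 / (n2 - 1L)
    } else {
      m1 <- s1 / n1; m2 <- (s2 - xi) / (n2 - 1L)
      C1 <- G1 / (n1 - 1L) - tcrossprod(m1) * n1 / (n1 - 1L)
      C2 <- (G2 - tcrossprod(xi)) / (n2 - 2L) -
        tcrossprod(m2) * (n2 - 1L) / (n2 - 2L)
    }
    Sc <- (C1 + C2) / 2
    g <- as.numeric(shrinkage)
    St <- (1 - g) * Sc + g * diag(mean(diag(Sc)), p)
    w <- solve(St, m2 - m1)
    proj[i] <- sum(w * xi)
  }
  proj
}

# Area under the ROC curve from scores and 0/1 labels (rank statistic).
roc_az <- function(scores, y01) {
  r <- rank(scores)
  n1 <- sum(y01 == 1L); n0 <- sum(y01 == 0L)
  (sum(r[y01 == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Forward-model topography of a discriminating component
#'
#' Per-channel coupling of a component time course `y` with the sensor
#' data: `a = X y / (y' y)`. For exactly rank-1 data `X = a0 y'` this
#' recovers `a0`; channels orthogonal to `y` get near-zero coupling.
#'
#' @param X channels x samples (or channels x trials·samples) matrix.
#' @param y component time course, length = ncol(X).
#' @return numeric vector of per-channel couplings (`forward_topography`).
#' @export
forward_model <- function(X, y) {
  stopifnot(ncol(X) == length(y))
  as.numeric(X %*% y) / sum(y * y)
}

#' Single-trial evidence-signal projection
#'
#' Applies a spatial filter (typically the one trained in the window
#' centered at the response) to every time point of every trial, and
#' z-scores the resulting trials x samples signal matrix with one mean and
#' SD per epochs object (participant-level normalization), so signals can
#' be averaged across trials and participants on a common scale.
#'
#' @param epochs an [eeg_epochs] object.
#' @param filter a `spatial_filter` (or bare weight vector).
#' @param zscore normalize (default TRUE).
#' @return trials x samples matrix of component amplitudes.
#' @export
project_signal <- function(epochs, filter, zscore = TRUE) {
  w <- if (inherits(filter, "spatial_filter")) filter$w else as.numeric(filter)
  d <- epochs$data
  n <- dim(d)[1]; ns <- dim(d)[3]
  out <- matrix(NA_real_, n, ns)
  for (i in seq_len(n)) out[i, ] <- w %*% d[i, , ]
  if (zscore) {
    mu <- mean(out); sd_ <- stats::sd(as.numeric(out))
    if (sd_ > 0) out <- (out - mu) / sd_
  }
  out
}
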