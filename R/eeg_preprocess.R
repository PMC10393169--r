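#' Response-locked EEG epochs container
#'
#' Thin S3 container for a trials x channels x samples array with channel
#' labels, sampling rate, a response-locked time vector (`t = 0` at the
#' button press) and per-trial metadata rows joined to the trial table.
#'
#' @param data numeric array, trials x channels x samples.
#' @param times time vector (s), length = samples, uniform step.
#' @param channels character channel labels, length = channels.
#' @param fs sampling rate (Hz).
#' @param metadata data.frame with one row per trial.
#' @export
eeg_epochs <- function(data, times, channels, fs, metadata = NULL) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[2] == length(channels),
            dim(data)[3] == length(times))
  if (!is.null(metadata) && nrow(metadata) != dim(data)[1])
    stop("metadata row count must equal trial count")
  if (length(times) > 1) {
    step <- diff(times)
    if (max(abs(step - step[1])) > 1e-9) stop("time vector must be uniform")
  }
  structure(list(data = data, times = times, channels = channels, fs = fs,
                 metadata = metadata), class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("eeg_epochs: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  response-locked time %g..%g s\n", min(x$times), max(x$times)))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth band-pass (default 0.5-40 Hz) applied
#' forward-backward (zero phase) along the sample axis, implemented as a
#' high-pass / low-pass cascade (a single narrow band-pass section with a
#' cutoff far below the Nyquist frequency is numerically fragile; the
#' cascade has the same pass band and is stable). Removes DC and preserves
#' pass-band sinusoid amplitudes. Accepts a channels x samples matrix
#' (continuous data) or an `eeg_epochs` object; epoched input is
#' internally reflection-padded to suppress edge transients.
#'
#' @param data matrix (channels x samples) or `eeg_epochs`.
#' @param fs sampling rate (Hz); taken from the epochs object if given.
#' @param low,high band edges (Hz).
#' @param order filter order of each section.
#' @export
bandpass <- function(data, fs = NULL, low = 0.5, high = 40, order = 4) {
  if (inherits(data, "eeg_epochs")) {
    d <- data$data
    ns <- dim(d)[3]
    pad <- min(ns - 1L, as.integer(2 * data$fs / low))
    for (i in seq_len(dim(d)[1])) {
      for (ch in seq_len(dim(d)[2])) {
        v <- d[i, ch, ]
        vp <- c(rev(v[seq_len(pad)]), v, rev(v[ns - seq_len(pad) + 1L]))
        d[i, ch, ] <- bp_filtfilt(vp, data$fs, low, high,
                                  order)[pad + seq_len(ns)]
      }
    }
    data$data <- d
    return(data)
  }
  if (is.null(fs)) stop("'fs' required for matrix input")
  t(apply(data, 1, bp_filtfilt, fs = fs, low = low, high = high,
          order = order))
}

bp_filtfilt <- function(v, fs, low, high, order) {
  hp <- signal::butter(order, low / (fs / 2), type = "high")
  lp <- signal::butter(order, high / (fs / 2), type = "low")
  signal::filtfilt(lp, signal::filtfilt(hp, v))
}

#' PCA-based blink removal from calibration data
#'
#' Estimates the blink subspace as the leading principal component(s) of a
#' blink-rich calibration recording and projects it out of the task data.
#' The cleaned data has its rank reduced by the number of removed
#' components; activity orthogonal to the blink subspace is untouched.
#'
#' @param data channels x samples matrix or `eeg_epochs`.
#' @param calibration channels x samples matrix of blink-dominated
#'   calibration data.
#' @param n_components number of components to remove (default 1; 0 is the
#'   identity).
#' @return list with `data` (cleaned, same shape) and `components`
#'   (channels x n_components removed sensor weightings).
#' @export
blink_pca_removal <- function(data, calibration, n_components = 1L) {
  nch <- if (inherits(data, "eeg_epochs")) dim(data$data)[2] else nrow(data)
  if (n_components > nch) stop("more components than channels")
  if (n_components == 0L)
    return(list(data = data, components = matrix(0, nch, 0)))
  if (nrow(calibration) != nch)
    stop("calibration channel count mismatch")
  cc <- calibration - rowMeans(calibration)
  U <- svd(cc, nu = n_components, nv = 0)$u   # leading spatial components
  P <- diag(nch) - U %*% t(U)
  if (inherits(data, "eeg_epochs")) {
    d <- data$data
    for (i in seq_len(dim(d)[1])) d[i, , ] <- P %*% d[i, , ]
    data$data <- d
    return(list(data = data, components = U))
  }
  list(data = P %*% data, components = U)
}

#' Average re-referencing
#'
#' Subtracts the instantaneous mean over channels from every channel, so
#' the per-sample channel mean is exactly zero. Idempotent; differences
#' between channels are unchanged.
#'
#' @param data channels x samples matrix or `eeg_epochs`.
#' @export
average_reference <- function(data) {
  if (inherits(data, "eeg_epochs")) {
    d <- data$data
    for (i in seq_len(dim(d)[1])) {
      m <- d[i, , ]
      d[i, , ] <- sweep(m, 2, colMeans(m))
    }
    data$data <- d
    return(data)
  }
  sweep(data, 2, colMeans(data))
}

#' Cut response-locked epochs out of continuous data
#'
#' Slices a window around each response event sample; events whose window
#' would extend past the recording are dropped with a message.
#'
#' @param continuous channels x samples matrix.
#' @param events integer sample indices of the responses (t = 0).
#' @param window numeric length-2, window in seconds relative to the event
#'   (e.g. `c(-0.8, 0.25)`).
#' @param fs sampling rate (Hz).
#' @param channels optional channel labels.
#' @param metadata optional data.frame, one row per event; rows of dropped
#'   events are removed.
#' @return an [eeg_epochs] object.
#' @export
epoch_response_locked <- function(continuous, events, window, fs,
                                  channels = NULL, metadata = NULL) {
  pre <- as.integer(round(-window[1] * fs))
  post <- as.integer(round(window[2] * fs))
  ns <- ncol(continuous)
  okev <- events - pre >= 1L & events + post <= ns
  if (any(!okev))
    message(sum(!okev), " event(s) out of bounds dropped")
  events <- events[okev]
  if (!is.null(metadata)) metadata <- metadata[okev, , drop = FALSE]
  nch <- nrow(continuous)
  arr <- array(NA_real_, c(length(events), nch, pre + post + 1L))
  for (i in seq_along(events)) {
    arr[i, , ] <- continuous[, (events[i] - pre):(events[i] + post)]
  }
  if (is.null(channels)) channels <- paste0("ch", seq_len(nch))
  eeg_epochs(arr, seq(-pre, post) / fs, channels, fs, metadata)
}
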