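#' Read / write behavioral trial tables
#'
#' Trial tables are plain CSV with the columns participant, urgency,
#' condition, choice, rt, hand, correct, excluded. The reader validates
#' the column set, choice levels and RT signs, reports offending line
#' numbers, and flags a likely unit error when RTs look like milliseconds
#' (values above 10).
#'
#' @param path file path.
#' @return a `trial_table`.
#' @export
read_trials <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  need <- c("participant", "urgency", "condition", "choice", "rt", "hand",
            "correct", "excluded")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!tab$choice %in% c("upper", "lower", "none"))
  if (length(bad))
    stop("invalid choice at data line(s): ", paste(utils::head(bad, 5),
                                                   collapse = ", "))
  bad_rt <- which(tab$choice != "none" & (!is.finite(tab$rt) | tab$rt <= 0))
  if (length(bad_rt))
    stop("non-positive rt at data line(s): ", paste(utils::head(bad_rt, 5),
                                                    collapse = ", "))
  if (any(tab$rt > 10, na.rm = TRUE))
    warning("rt values above 10 detected; are these milliseconds? ",
            "The package convention is seconds.")
  tab$rt <- as.numeric(tab$rt)
  tab$hand <- as.character(tab$hand)
  tab$hand[tab$hand %in% c("", "NA")] <- NA_character_
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' @rdname read_trials
#' @param trials a `trial_table`.
#' @export
write_trials <- function(trials, path) {
  data.table::fwrite(as.data.frame(trials), path)
  invisible(path)
}

#' Read / write EEG epochs as a plain-text container
#'
#' Epochs are persisted as a directory holding `header.json` (sampling
#' rate, dimensions), `times.csv`, `channels.csv`, `metadata.csv` and
#' `data.csv` (long format: trial, channel, sample, value). Round trips
#' are lossless up to double formatting.
#'
#' @param epochs an [eeg_epochs].
#' @param path directory path.
#' @export
write_epochs <- function(epochs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  jsonlite::write_json(list(fs = epochs$fs, n_trials = d[1],
                            n_channels = d[2], n_samples = d[3]),
                       file.path(path, "header.json"), auto_unbox = TRUE)
  data.table::fwrite(data.table::data.table(time = epochs$times),
                     file.path(path, "times.csv"))
  data.table::fwrite(data.table::data.table(channel = epochs$channels),
                     file.path(path, "channels.csv"))
  if (!is.null(epochs$metadata))
    data.table::fwrite(as.data.frame(epochs$metadata),
                       file.path(path, "metadata.csv"))
  long <- data.table::data.table(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    sample = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.numeric(epochs$data))
  data.table::fwrite(long, file.path(path, "data.csv"))
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  hdr <- jsonlite::read_json(file.path(path, "header.json"),
                             simplifyVector = TRUE)
  times <- data.table::fread(file.path(path, "times.csv"))$time
  channels <- data.table::fread(file.path(path, "channels.csv"))$channel
  if (length(channels) != hdr$n_channels)
    stop("channel-count mismatch between header and channels.csv")
  meta_path <- file.path(path, "metadata.csv")
  metadata <- if (file.exists(meta_path))
    as.data.frame(data.table::fread(meta_path)) else NULL
  long <- data.table::fread(file.path(path, "data.csv"))
  arr <- array(NA_real_, c(hdr$n_trials, hdr$n_channels, hdr$n_samples))
  arr[cbind(long$trial, long$channel, long$sample)] <- long$value
  eeg_epochs(arr, times, channels, hdr$fs, metadata)
}

#' Export a signal-RT curve as delimited text
#'
#' Three columns: response-locked time, (smoothed) correlation, number of
#' contributing trials.
#'
#' @param curve a `signal_rt_curve`.
#' @param path file path.
#' @export
write_curve <- function(curve, path) {
  data.table::fwrite(data.table::data.table(time = curve$time, r = curve$r,
                                            n = curve$n), path)
  invisible(path)
}
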