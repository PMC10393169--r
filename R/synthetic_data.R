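#' Synthetic study design
#'
#' Parameterizes the emulated experiment: a two-alternative categorization
#' task under block-wise speed/accuracy instructions with two sensory
#' evidence (coherence) levels, two response hands, 64-channel EEG.
#' Defaults mirror the study layout: 2 blocks per urgency condition, 160
#' trials per block (40 per category x coherence cell), deadlines 1 s
#' (speed) and 1.6 s (accuracy).
#'
#' Stimulus conditions are indexed 1..4 = category A / low coherence,
#' A / high, category B / low, B / high; the correct response maps to the
#' upper boundary, and the chosen category determines the responding hand
#' through `hand_map`.
#'
#' @param participants number of participants the design describes.
#' @param blocks_per_urgency,trials_per_block block structure.
#' @param deadlines named deadlines (s) per urgency condition.
#' @param hand_map named map from category (`"A"`, `"B"`) to hand.
#' @param fs EEG sampling rate (Hz) of the synthetic epochs.
#' @param epoch_window response-locked epoch extent (s).
#' @param evidence_gain,motor_gain planted component amplitudes (uV per
#'   evidence unit).
#' @param noise_sd sensor noise SD (uV) before spatial correlation.
#' @param noise_cond condition number of the spatial noise covariance.
#' @param noise_ar AR(1) coefficient of the temporal noise coloring.
#' @param blink_gain blink transient amplitude (uV).
#' @return list of class `synth_design`.
#' @export
synth_design <- function(participants = 1L,
                         blocks_per_urgency = 2L, trials_per_block = 160L,
                         deadlines = c(speed = 1, accuracy = 1.6),
                         hand_map = c(A = "left", B = "right"),
                         fs = 200, epoch_window = c(-0.8, 0.25),
                         evidence_gain = 30, motor_gain = 55,
                         noise_sd = 1.5, noise_cond = 10, noise_ar = 0.5,
                         blink_gain = 60) {
  stopifnot(trials_per_block %% 4L == 0L, all(deadlines > 0))
  structure(list(participants = participants,
                 blocks_per_urgency = blocks_per_urgency,
                 trials_per_block = trials_per_block,
                 deadlines = deadlines, hand_map = hand_map,
                 n_channels = 64L, channels = montage_64(),
                 fs = fs, epoch_window = epoch_window,
                 evidence_gain = evidence_gain, motor_gain = motor_gain,
                 noise_sd = noise_sd, noise_cond = noise_cond,
                 noise_ar = noise_ar, blink_gain = blink_gain),
            class = "synth_design")
}

# 64 labels of the extended 10-20 layout. Trailing odd digit = left
# hemisphere, even = right, z = midline.
montage_64 <- function() {
  c("Fp1", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2", "Iz",
    "FT9", "FT10", "TP9", "TP10")
}

#' Hemisphere of a 10-20 channel label
#'
#' @param labels character channel labels.
#' @return `"left"`, `"right"` or `"mid"` per label.
#' @export
channel_side <- function(labels) {
  last <- sub(".*?([0-9]+|z)$", "\\1", labels)
  ifelse(last == "z", "mid",
         ifelse(as.integer(suppressWarnings(as.numeric(last))) %% 2L == 1L,
                "left", "right"))
}

# Named template topography: gaussian-like bump over the listed channels,
# centered (zero mean, so it survives average referencing) and unit-norm.
template_topography <- function(channels, peak, spread = NULL) {
  w <- stats::setNames(numeric(length(channels)), channels)
  w[names(peak)] <- peak
  if (!is.null(spread)) w[names(spread)] <- pmax(w[names(spread)], spread)
  w <- w - mean(w)
  w / sqrt(sum(w^2))
}

# centroparietal build-up cluster; kept disjoint from the motor-strip
# channels so the planted components are spatially separable
evidence_topography <- function(channels) {
  template_topography(channels,
    peak = c(CPz = 1, Pz = 0.9, CP1 = 0.6, CP2 = 0.6, P1 = 0.6, P2 = 0.6,
             POz = 0.5, P3 = 0.3, P4 = 0.3))
}

# Contralateral motor topography: left-hand responses load the right
# central sensors and vice versa.
motor_topography_hand <- function(channels, hand) {
  if (hand == "left") {
    template_topography(channels,
      peak = c(C4 = 1, C6 = 0.7, FC4 = 0.8, FC6 = 0.5, C2 = 0.6, FC2 = 0.4))
  } else {
    template_topography(channels,
      peak = c(C3 = 1, C5 = 0.7, FC3 = 0.8, FC5 = 0.5, C1 = 0.6, FC1 = 0.4))
  }
}

blink_topography <- function(channels) {
  w <- stats::setNames(numeric(length(channels)), channels)
  w[c("Fp1", "Fp2")] <- 1
  w[c("AF7", "AF3", "AF4", "AF8")] <- 0.6
  w[c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")] <- 0.25
  w / sqrt(sum(w^2))
}

#' Default generating LIT parameters per urgency condition
#'
#' The package's reference conditions: shared boundary, start and drifts
#' across urgency conditions, with the speed-accuracy trade-off carried by
#' the motor leak (inverse leak 0.30 s under speed, 0.49 s under accuracy
#' instructions -- a 0.19 s block difference). Drifts (low/high coherence,
#' duplicated over the two categories) and the non-decision component were
#' calibrated once so the simulated group pattern lands near speeded
#' two-choice categorization benchmarks: mean RT about 0.65 s (speed) vs
#' 0.83 s (accuracy), accuracy about 0.76 vs 0.79, deadline misses around
#' 13 %.
#'
#' @param urgency `"speed"` or `"accuracy"`.
#' @export
default_lit_params <- function(urgency = c("speed", "accuracy")) {
  urgency <- match.arg(urgency)
  inv_leak <- c(speed = 0.30, accuracy = 0.49)[[urgency]]
  lit_params(v = c(0.55, 1.1, 0.55, 1.1), a = 0.5, zr = 0.5,
             lam = 1 / inv_leak, Ter = 0.28, nd_sd = 0.05)
}

#' Generate synthetic behavioral data with ground truth
#'
#' Simulates every stimulus x urgency cell of the design with
#' [simulate_lit], applies the deadlines (late trials censored), assigns
#' hands from the category mapping, and retains the latent response-locked
#' evidence/motor snippets of every responded trial as ground truth for
#' the EEG generator and for tests.
#'
#' @param design a [synth_design].
#' @param params named list with `speed` and `accuracy` [lit_params];
#'   defaults to [default_lit_params].
#' @param seed integer seed.
#' @param participant participant id stored in the trial table.
#' @return list of class `synth_behavior`: `trials` (trial table, all
#'   trials), `truth` (generating parameters, per-trial latent stacks at
#'   the simulation rate, stack lags, seed).
#' @export
generate_behavior <- function(design, params = NULL, seed = 1L,
                              participant = 1L) {
  stopifnot(inherits(design, "synth_design"))
  if (is.null(params))
    params <- list(speed = default_lit_params("speed"),
                   accuracy = default_lit_params("accuracy"))
  dt <- 0.001
  pre <- -design$epoch_window[1]; post <- design$epoch_window[2]
  n_cell <- design$blocks_per_urgency * design$trials_per_block %/% 4L
  trials_all <- list(); xs <- list(); ys <- list()
  categories <- c("A", "A", "B", "B")
  for (u in c("speed", "accuracy")) {
    for (cond in 1:4) {
      sim <- simulate_lit(params[[u]], condition = cond, n_trials = n_cell,
                          dt = dt, t_max = 2.5,
                          seed = seed + 17L * match(u, c("speed", "accuracy")) +
                            4099L * cond,
                          stack_window = c(pre, post))
      tt <- sim$trials
      tt$urgency <- u
      tt$participant <- participant
      cat_chosen <- ifelse(tt$choice == "upper", categories[cond],
                           setdiff(c("A", "B"), categories[cond]))
      tt$hand <- ifelse(tt$choice == "none", NA_character_,
                        unname(design$hand_map[cat_chosen]))
      trials_all[[paste(u, cond)]] <- tt
      xs[[paste(u, cond)]] <- sim$paths$x_stack
      ys[[paste(u, cond)]] <- sim$paths$y_stack
      lags <- sim$paths$stack_lags
    }
  }
  trials <- do.call(rbind, trials_all)
  rownames(trials) <- NULL
  class(trials) <- c("trial_table", "data.frame")
  trials <- apply_deadline(trials, design$deadlines)
  structure(list(trials = trials,
                 truth = list(params = params,
                              x_stack = do.call(rbind, xs),
                              y_stack = do.call(rbind, ys),
                              lags = lags, dt = dt, seed = seed)),
            class = "synth_behavior")
}

# Cholesky-type mixing matrix of a random spatial covariance with a fixed
# condition number, deterministic given seed.
noise_mixing <- function(p, cond, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  Q <- qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
  ev <- exp(seq(log(cond), 0, length.out = p))
  ev <- ev / mean(ev)
  Q %*% diag(sqrt(ev))
}

#' Generate synthetic response-locked EEG epochs with planted components
#'
#' Emulates the signal model the analyses assume: sensor data are the sum
#' of an evidence component (a centroparietal topography carrying the
#' absolute deviation of the latent evidence accumulator from its
#' prestimulus baseline, so both choice directions build up with the same
#' sign), a hand-specific contralateral motor component carrying the
#' (signed) motor accumulation, and spatially correlated AR(1) Gaussian
#' sensor noise. Latent snippets come from the behavioral ground truth;
#' samples preceding trial onset sit at the baseline. Only responded
#' (non-excluded) trials yield epochs.
#'
#' @param design a [synth_design].
#' @param behavior a `synth_behavior` from [generate_behavior].
#' @param seed integer seed for the noise.
#' @return list of class `synth_eeg`: `epochs` ([eeg_epochs] with the trial
#'   metadata), `truth` (planted topographies, per-trial clean component
#'   signals at the epoch rate, the generating behavior truth).
#' @export
generate_eeg <- function(design, behavior, seed = 1L) {
  stopifnot(inherits(design, "synth_design"),
            inherits(behavior, "synth_behavior"))
  tr <- behavior$trials
  keep <- which(!tr$excluded)
  meta <- tr[keep, , drop = FALSE]
  lags <- behavior$truth$lags
  step <- as.integer(round(1 / (design$fs * behavior$truth$dt)))
  sub <- seq(1L, length(lags), by = step)
  times <- lags[sub]
  ns <- length(times)
  nch <- design$n_channels
  chans <- design$channels
  A_e <- evidence_topography(chans)
  A_left <- motor_topography_hand(chans, "left")
  A_right <- motor_topography_hand(chans, "right")
  x <- behavior$truth$x_stack[keep, sub, drop = FALSE]
  y <- behavior$truth$y_stack[keep, sub, drop = FALSE]
  x[is.na(x)] <- 0   # prestimulus baseline
  y[is.na(y)] <- 0
  ev_sig <- design$evidence_gain * abs(x)
  # motor preparation builds toward threshold under the executed hand's
  # topography: amplitude is the absolute motor excursion
  mo_sig <- design$motor_gain * abs(y)
  L <- design$noise_sd * noise_mixing(nch, design$noise_cond, seed + 11L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer((seed + 29L) %% .Machine$integer.max))
  rho <- design$noise_ar
  arr <- array(NA_real_, c(length(keep), nch, ns))
  for (i in seq_along(keep)) {
    A_m <- if (identical(meta$hand[i], "left")) A_left else A_right
    clean <- outer(A_e, ev_sig[i, ]) + outer(A_m, mo_sig[i, ])
    z <- matrix(stats::rnorm(nch * ns), nch, ns)
    noise <- L %*% z
    if (rho > 0) {
      for (t in 2:ns)
        noise[, t] <- rho * noise[, t - 1] + sqrt(1 - rho^2) * noise[, t]
    }
    arr[i, , ] <- clean + noise
  }
  epochs <- eeg_epochs(arr, times, chans, design$fs, metadata = meta)
  structure(list(epochs = epochs,
                 truth = list(evidence_topo = A_e,
                              motor_topo = list(left = A_left,
                                                right = A_right),
                              evidence_signal = ev_sig,
                              motor_signal = mo_sig,
                              times = times,
                              behavior = behavior$truth,
                              kept = keep, seed = seed)),
            class = "synth_eeg")
}

#' Generate a blink-rich calibration recording
#'
#' Continuous multichannel data emulating the calibration task in which
#' the participant blinks on cue: background spatially correlated noise
#' plus stereotyped raised-cosine blink transients (about 300 ms wide,
#' every ~1.5 s) carried by a frontal topography. The blink topography is
#' returned as ground truth.
#'
#' @param design a [synth_design].
#' @param duration recording length (s).
#' @param seed integer seed.
#' @param blinks include blink transients (FALSE gives a pure-noise
#'   control recording).
#' @return list: `data` (channels x samples), `fs`, `blink_topo`.
#' @export
generate_blink_calibration <- function(design, duration = 30, seed = 1L,
                                       blinks = TRUE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer((seed + 5L) %% .Machine$integer.max))
  fs <- design$fs
  ns <- as.integer(duration * fs)
  nch <- design$n_channels
  L <- design$noise_sd * noise_mixing(nch, design$noise_cond, seed + 11L)
  dat <- L %*% matrix(stats::rnorm(nch * ns), nch, ns)
  topo <- blink_topography(design$channels)
  if (blinks) {
    width <- as.integer(0.3 * fs)
    pulse <- design$blink_gain * (1 - cos(2 * pi * seq_len(width) / width)) / 2
    onsets <- seq(fs, ns - width, by = as.integer(1.5 * fs))
    onsets <- onsets + sample(-as.integer(0.2 * fs):as.integer(0.2 * fs),
                              length(onsets), replace = TRUE)
    onsets <- onsets[onsets >= 1 & onsets + width <= ns]
    for (o in onsets) {
      dat[, o:(o + width - 1L)] <- dat[, o:(o + width - 1L)] +
        outer(topo, pulse)
    }
  }
  list(data = dat, fs = fs, blink_topo = topo)
}

#' Tile synthetic epochs into a continuous recording
#'
#' Embeds the planted epoch content of a `synth_eeg` into a continuous
#' noise background with inter-trial gaps, returning the recording and the
#' response-event sample indices -- the input format of the preprocessing
#' chain ([bandpass], [blink_pca_removal], [average_reference],
#' [epoch_response_locked]).
#'
#' @param design a [synth_design].
#' @param synth a `synth_eeg` from [generate_eeg].
#' @param iti inter-trial gap (s) between epochs.
#' @param seed seed for the background noise.
#' @param blinks add calibration-style blink transients to the recording.
#' @return list: `data` (channels x samples), `events` (sample index of
#'   each trial's t = 0), `fs`, `metadata`.
#' @export
tile_continuous <- function(design, synth, iti = 0.5, seed = 2L,
                            blinks = FALSE) {
  ep <- synth$epochs
  n <- dim(ep$data)[1]; nch <- dim(ep$data)[2]; ns <- dim(ep$data)[3]
  gap <- as.integer(iti * ep$fs)
  total <- n * (ns + gap) + gap
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer((seed + 41L) %% .Machine$integer.max))
  L <- design$noise_sd * noise_mixing(nch, design$noise_cond, seed + 11L)
  dat <- L %*% matrix(stats::rnorm(nch * total), nch, total)
  pre <- sum(ep$times < 0)
  events <- integer(n)
  pos <- gap
  for (i in seq_len(n)) {
    dat[, (pos + 1L):(pos + ns)] <- ep$data[i, , ]
    events[i] <- pos + pre + 1L
    pos <- pos + ns + gap
  }
  if (blinks) {
    width <- as.integer(0.3 * ep$fs)
    pulse <- design$blink_gain *
      (1 - cos(2 * pi * seq_len(width) / width)) / 2
    topo <- blink_topography(design$channels)
    onsets <- seq(ep$fs, total - width, by = as.integer(2.1 * ep$fs))
    for (o in onsets)
      dat[, o:(o + width - 1L)] <- dat[, o:(o + width - 1L)] +
        outer(topo, pulse)
  }
  list(data = dat, events = events, fs = ep$fs, metadata = ep$metadata)
}
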