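#' Construct a behavioral trial table
#'
#' Standard per-trial record used throughout the package: participant id,
#' urgency condition (block-wise speed/accuracy instruction), stimulus
#' condition index (category x coherence cell), choice (upper/lower boundary
#' or "none" for censored trials), response time in seconds, responding
#' hand, correctness and exclusion flags. Censored trials carry
#' `choice = "none"`, `rt = NA` and are marked excluded.
#'
#' @param condition integer stimulus condition per trial.
#' @param choice character, one of `"upper"`, `"lower"`, `"none"`.
#' @param rt response time (s), `NA` for censored trials.
#' @param participant participant identifier.
#' @param urgency `"speed"` or `"accuracy"`.
#' @param hand `"left"`, `"right"` or `NA`.
#' @param correct logical; defaults to `choice == "upper"` (the simulator
#'   convention that the correct response maps to the upper boundary).
#' @return a `data.frame` with class `trial_table`.
#' @export
make_trial_table <- function(condition, choice, rt,
                             participant = 1L,
                             urgency = "accuracy",
                             hand = NA_character_,
                             correct = NULL) {
  n <- length(choice)
  stopifnot(length(condition) == n, length(rt) == n)
  choice <- as.character(choice)
  if (!all(choice %in% c("upper", "lower", "none")))
    stop("choice must be 'upper', 'lower' or 'none'")
  if (any(!is.na(rt) & rt <= 0 & choice != "none"))
    stop("rt must be positive for responded trials")
  if (is.null(correct)) correct <- choice == "upper"
  tab <- data.frame(
    participant = rep_len(participant, n),
    urgency = rep_len(urgency, n),
    condition = as.integer(condition),
    choice = choice,
    rt = as.numeric(rt),
    hand = rep_len(hand, n),
    correct = correct,
    excluded = choice == "none",
    stringsAsFactors = FALSE
  )
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Apply a response deadline to a trial table
#'
#' Trials slower than the deadline of their urgency condition are censored:
#' choice set to `"none"`, rt to `NA`, excluded flag raised. Mirrors the
#' task's "Too slow!" handling where late trials are excluded rather than
#' resampled.
#'
#' @param trials a trial table.
#' @param deadlines named numeric vector, e.g. `c(speed = 1, accuracy = 1.6)`.
#' @export
apply_deadline <- function(trials, deadlines = c(speed = 1, accuracy = 1.6)) {
  dl <- deadlines[trials$urgency]
  late <- !is.na(trials$rt) & !is.na(dl) & trials$rt > dl
  trials$choice[late] <- "none"
  trials$rt[late] <- NA_real_
  trials$correct[late] <- FALSE
  trials$excluded[late] <- TRUE
  trials
}

valid_trials <- function(trials) {
  trials[!trials$excluded & trials$choice != "none" & !is.na(trials$rt), ,
         drop = FALSE]
}
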