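#' Non-decision-free time scalar between observed and model condition means
#'
#' Ratio of the root-sum-of-squared deviations from the mean of the observed
#' condition-mean RTs to that of the model condition means on the prepaid
#' (unit) scale. Because a non-decision component shared across stimulus
#' conditions adds the same constant to every condition mean, it cancels in
#' the deviations and the estimator is independent of the non-decision
#' distribution.
#'
#' @param o observed mean RT per stimulus condition (s).
#' @param m model mean decision time per condition on the unit scale.
#' @return the positive scalar `s_hat`; observed time = `s_hat` x unit time.
#' @examples
#' time_scalar(c(.5, .6, .7, .8), c(1, 1.2, 1.4, 1.6))  # 0.5
#' @export
time_scalar <- function(o, m) {
  if (length(o) < 2 || length(o) != length(m))
    stop("need >= 2 matched condition means")
  denom <- sqrt(sum((m - mean(m))^2))
  if (denom == 0) stop("model condition means are degenerate (all equal)")
  sqrt(sum((o - mean(o))^2)) / denom
}

# Defective CDFs of a model distribution evaluated on a time grid.
dist_to_cdfs <- function(dist, grid) {
  Fu <- cumsum(dist$g_up) * dist$dt
  Fl <- cumsum(dist$g_lo) * dist$dt
  list(up = stats::approx(dist$time, Fu, xout = grid, yleft = 0,
                          yright = Fu[length(Fu)])$y,
       lo = stats::approx(dist$time, Fl, xout = grid, yleft = 0,
                          yright = Fl[length(Fl)])$y)
}

# Empirical defective CDFs of a trial table on a time grid.
data_to_cdfs <- function(trials, grid) {
  n <- nrow(trials)
  ok <- valid_trials(trials)
  up <- sort(ok$rt[ok$choice == "upper"])
  lo <- sort(ok$rt[ok$choice == "lower"])
  list(up = findInterval(grid, up) / max(n, 1L),
       lo = findInterval(grid, lo) / max(n, 1L))
}

#' Shift-invariant distance between model and data choice-RT distributions
#'
#' A Cramer-von-Mises-type objective: the summed integrated squared
#' difference between model and data defective CDFs (upper and lower
#' boundary, all stimulus conditions), minimized over a single time shift
#' shared by every condition. The shared shift stands in for a non-decision
#' component of unspecified shape common to the conditions, so the
#' objective is invariant under translating all model distributions by a
#' common (grid-aligned) constant, while a shift applied to only one
#' condition changes it. Smaller is better; zero when model equals data up
#' to a shared shift.
#'
#' @param model named list of [grid_pdf]-style distributions, names matching
#'   the stimulus condition indices present in `data`.
#' @param data a trial table (censored trials are ignored; the defective
#'   mass convention divides by the total trial count).
#' @param dt grid step for the comparison (s).
#' @param t_max grid extent (s).
#' @param shift_range numeric length-2, the search range of the common
#'   shift (s); scanned exhaustively in steps of `dt`.
#' @return scalar objective, with attributes `shift` (the optimal common
#'   shift) and `per_condition` grid used.
#' @export
dstar_objective <- function(model, data, dt = 0.002, t_max = 3,
                            shift_range = c(-0.5, 1)) {
  conds <- sort(unique(valid_trials(data)$condition))
  if (!length(conds)) stop("no valid trials in data")
  missing <- setdiff(as.character(conds), names(model))
  if (length(missing))
    stop("model distributions missing for condition(s): ",
         paste(missing, collapse = ", "))
  grid <- seq(0, t_max, by = dt)
  n <- length(grid)
  k <- length(conds)
  Fm_up <- Fm_lo <- Fd_up <- Fd_lo <- matrix(0, n, k)
  for (j in seq_len(k)) {
    cd <- as.character(conds[j])
    mc <- dist_to_cdfs(model[[cd]], grid)
    Fm_up[, j] <- mc$up; Fm_lo[, j] <- mc$lo
    dc <- data_to_cdfs(data[data$condition == conds[j], ], grid)
    Fd_up[, j] <- dc$up; Fd_lo[, j] <- dc$lo
  }
  res <- cpp_dstar_scan(Fm_up, Fm_lo, Fd_up, Fd_lo,
                        as.integer(floor(shift_range[1] / dt)),
                        as.integer(ceiling(shift_range[2] / dt)), dt)
  structure(res$objective, shift = res$shift, class = "dstar")
}

#' @export
print.dstar <- function(x, ...) {
  cat(sprintf("D* objective: %.6g (common shift %.3f s)\n",
              unclass(x), attr(x, "shift")))
  invisible(x)
}
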