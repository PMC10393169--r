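#' Simulate the leaky integrating threshold model
#'
#' Forward simulation by the Euler-Maruyama scheme with step `dt`. Evidence
#' evolves as a constant-drift diffusion
#' \eqn{x_{k+1} = x_k + v\,dt + \sigma^*\sqrt{dt}\,\epsilon_k} from
#' `x0 = a (zr - 1/2)`; the motor accumulator integrates
#' \eqn{y_{k+1} = y_k + \lambda (x_k - y_k) dt} from the adapted start
#' `y(0) = x0`. A trial terminates at the first grid time with
#' `|y| >= a/2`; the reported response time adds a truncated-Gaussian
#' non-decision time. Trials not absorbed by `t_max` are censored
#' (`choice = "none"`).
#'
#' @param params a [lit_params] object.
#' @param condition stimulus condition index selecting the drift from
#'   `params$v`.
#' @param n_trials number of trials (>= 1).
#' @param dt time step (s); the study convention is 1 ms.
#' @param t_max maximum decision time (s), a multiple of `dt`.
#' @param seed integer seed for the simulation stream; `NULL` draws one from
#'   the session RNG.
#' @param keep_paths keep the full `x`/`y` trajectories (memory heavy).
#' @param stack_window optional response-locked window `c(pre, post)` in
#'   seconds; when given, snippets around each threshold crossing are
#'   stored (`t = 0` at the crossing) without retaining full paths, and
#'   the simulation continues `post` seconds past the crossing.
#' @param stack_signal which signals to stack: `"both"`, `"x"` or `"y"`
#'   (large ensembles should request only what they read).
#' @return A list with `paths` (a `path_ensemble`) and `trials` (a trial
#'   table, see [make_trial_table]).
#' @seealso [simulate_ddm], [motor_from_evidence]
#' @export
simulate_lit <- function(params, condition = 1L, n_trials, dt = 0.001,
                         t_max = 3, seed = NULL, keep_paths = FALSE,
                         stack_window = NULL, stack_signal = "both") {
  sim_engine(params, condition, n_trials, dt, t_max, seed, keep_paths,
             stack_window, model = 0L, stack_signal = stack_signal)
}

#' Simulate the standard drift diffusion model
#'
#' As [simulate_lit] but absorption applies directly to the evidence path
#' `x` at `± a/2`, optionally with linearly collapsing bounds
#' `± (a - c t)/2` when `params$c > 0`. The leak parameter is ignored.
#'
#' @inheritParams simulate_lit
#' @export
simulate_ddm <- function(params, condition = 1L, n_trials, dt = 0.001,
                         t_max = 3, seed = NULL, keep_paths = FALSE,
                         stack_window = NULL, stack_signal = "both") {
  sim_engine(params, condition, n_trials, dt, t_max, seed, keep_paths,
             stack_window, model = 1L, stack_signal = stack_signal)
}

sim_engine <- function(params, condition, n_trials, dt, t_max, seed,
                       keep_paths, stack_window, model,
                       stack_signal = "both") {
  stopifnot(inherits(params, "lit_params"))
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  if (t_max < dt) stop("'t_max' must be at least one step")
  if (n_trials < 1) stop("'n_trials' must be >= 1")
  condition <- as.integer(condition)
  if (condition < 1L || condition > length(params$v))
    stop("unknown stimulus condition index")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  nsteps <- as.integer(round(t_max / dt))
  pre <- post <- 0L
  if (!is.null(stack_window)) {
    pre <- as.integer(round(stack_window[1] / dt))
    post <- as.integer(round(stack_window[2] / dt))
  }
  smode <- match(match.arg(stack_signal, c("both", "x", "y")),
                 c("both", "x", "y")) - 1L
  raw <- cpp_simulate(as.integer(n_trials), dt, nsteps, params$v[condition],
                      params$sigma_star, params$x0, params$a,
                      params$lam, params$c, as.integer(model),
                      keep_paths, pre, post, as.double(seed), smode)
  paths <- structure(list(
    time = seq(0, nsteps * dt, by = dt),
    dt = dt,
    x = if (keep_paths) raw$x else NULL,
    y = if (keep_paths) raw$y else NULL,
    x_stack = raw[["x_stack"]], y_stack = raw[["y_stack"]],
    stack_lags = if (pre > 0 || post > 0) seq(-pre, post) * dt else NULL,
    fpt = raw$fpt, boundary = raw$boundary, seed = seed,
    model = if (model == 0L) "lit" else "ddm"
  ), class = "path_ensemble")
  ndt <- rtrunc_gauss(n_trials, params$Ter, params$nd_sd,
                      seed = seed + 104729)
  rt <- raw$fpt + ndt
  trials <- make_trial_table(
    condition = rep(condition, n_trials),
    choice = c("lower", "none", "upper")[raw$boundary + 2L],
    rt = ifelse(raw$boundary == 0L, NA_real_, rt)
  )
  list(paths = paths, trials = trials)
}

#' Truncated-Gaussian non-decision time sampler
#'
#' Draws from a Gaussian with mean `mean` and standard deviation `sd`
#' truncated at zero, by rejection. `sd = 0` returns the constant mean.
#'
#' @param n number of draws.
#' @param mean,sd location and spread before truncation (s).
#' @param seed optional integer seed (local RNG state, restored on exit).
#' @export
rtrunc_gauss <- function(n, mean, sd, seed = NULL) {
  if (sd < 0) stop("'sd' must be >= 0")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, draw[draw >= 0])
  }
  out[seq_len(n)]
}

#' Motor accumulation from an evidence path (convolution oracle)
#'
#' Integrates \eqn{y(t) = \lambda \int^t x(t') e^{\lambda (t'-t)} dt'}
#' initialized at `y0` by exact exponential stepping of the linear
#' first-order system (`y` relaxes toward `x` with time constant `1/lam`).
#' This is an integrator of the same ODE as the Euler-updated motor path in
#' [simulate_lit] and serves as its independent check.
#'
#' @param x_path numeric vector, evidence sampled on a uniform grid.
#' @param lam leak rate (1/s, > 0; `Inf` returns `x_path`).
#' @param y0 initial motor state.
#' @param dt grid step (s).
#' @return numeric vector of the same length as `x_path`.
#' @export
motor_from_evidence <- function(x_path, lam, y0, dt) {
  if (!is.numeric(lam) || lam <= 0) stop("'lam' must be positive")
  if (!is.finite(lam)) return(x_path)
  n <- length(x_path)
  y <- numeric(n)
  y[1] <- y0
  decay <- exp(-lam * dt)
  # exact step response for piecewise-constant input held at x_k over a step
  for (k in seq_len(n - 1L)) {
    y[k + 1L] <- x_path[k] + (y[k] - x_path[k]) * decay
  }
  y
}

#' @export
print.path_ensemble <- function(x, ...) {
  n <- length(x$fpt)
  cat(sprintf("path_ensemble (%s): %d trials, dt = %g s\n", x$model, n, x$dt))
  cat(sprintf("  absorbed: %d upper, %d lower, %d censored\n",
              sum(x$boundary == 1L), sum(x$boundary == -1L),
              sum(x$boundary == 0L)))
  if (!is.null(x$x)) cat("  full paths retained\n")
  if (!is.null(x$stack_lags))
    cat(sprintf("  response-locked stack: lags %g..%g s\n",
                min(x$stack_lags), max(x$stack_lags)))
  invisible(x)
}
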