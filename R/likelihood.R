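#' First-passage choice-RT densities by a Crank-Nicolson grid solver
#'
#' Solves the Fokker-Planck problem for a one-dimensional constant-drift
#' diffusion between two absorbing boundaries (the grid-based approach of
#' the fast-dm family) and returns the defective densities of absorption at
#' the upper and lower boundary on a uniform time grid. Collapsing bounds
#' (`eff$c > 0`) are handled by remapping the spatial domain onto the unit
#' interval at every time step; all mass is then absorbed before the
#' bound-completion time.
#'
#' @param eff an `effective_ddm` object from [effective_params], or any list
#'   with fields `a_eff`, `x0_eff`, `v`, `c`, `sigma_star`.
#' @param drift optional drift override (defaults to `eff$v`).
#' @param t_max,dt time grid extent and step (s).
#' @param dx_frac spatial resolution as a fraction of the boundary
#'   separation (default 0.005 per the solver's reference configuration;
#'   the number of interior nodes is `1/dx_frac - 1`).
#' @return An object of class `choice_rt_dist`: time grid, defective
#'   densities `g_up`, `g_lo`, absorbed masses and the worst-case
#'   mass-conservation error of the scheme.
#' @export
grid_pdf <- function(eff, drift = NULL, t_max = 3, dt = 0.002,
                     dx_frac = 0.005) {
  v <- if (is.null(drift)) eff$v else drift
  if (eff$a_eff <= 0) stop("boundary separation must be positive")
  if (abs(eff$x0_eff) >= eff$a_eff / 2)
    stop("starting point on or outside the boundaries")
  nx <- as.integer(round(1 / dx_frac)) - 1L
  nsteps <- as.integer(round(t_max / dt))
  sol <- cpp_grid_pdf(v, eff$sigma_star, eff$a_eff, eff$x0_eff, eff$c,
                      dt, nsteps, nx)
  if (sol$mass_err > 0.05)
    stop("grid solver instability: mass error ", signif(sol$mass_err, 3))
  structure(list(time = seq(0, nsteps * dt, by = dt),
                 dt = dt,
                 g_up = as.numeric(sol$g_up), g_lo = as.numeric(sol$g_lo),
                 mass_up = sol$mass_up, mass_lo = sol$mass_lo,
                 mass_err = sol$mass_err),
            class = "choice_rt_dist")
}

#' @export
print.choice_rt_dist <- function(x, ...) {
  cat(sprintf("choice_rt_dist: %d time points, dt = %g s\n",
              length(x$time), x$dt))
  cat(sprintf("  absorbed mass: upper %.4f, lower %.4f (err %.2g)\n",
              x$mass_up, x$mass_lo, x$mass_err))
  invisible(x)
}

#' Model configurations for the quantile likelihood fits
#'
#' Free-parameter audit of the two simulation-based quantile-likelihood
#' model configurations: both carry one drift per stimulus condition and a
#' truncated-Gaussian non-decision time (mean and spread) shared across
#' urgency conditions; the single-stage diffusion uses two boundary
#' separations (one per urgency condition), while the LIT uses one shared
#' boundary and two leak parameters.
#'
#' @param model `"ddm"` or `"lit"`.
#' @param n_stim number of stimulus conditions (drifts).
#' @return list with `parameters` (character vector of free-parameter
#'   names) and `n_free`.
#' @export
nll_model_config <- function(model = c("ddm", "lit"), n_stim = 4L) {
  model <- match.arg(model)
  drifts <- paste0("v", seq_len(n_stim))
  pars <- switch(model,
    ddm = c(drifts, "Ter", "nd_sd", "a_speed", "a_accuracy"),
    lit = c(drifts, "Ter", "nd_sd", "a", "lam_speed", "lam_accuracy"))
  list(model = model, parameters = pars, n_free = length(pars))
}

#' Quantile-based Monte-Carlo negative log-likelihood
#'
#' For each stimulus condition, simulates `n_sim` model trials, forms
#' multinomial bins from the deciles (`n_quantiles` quantiles) of the
#' simulated RTs separately per choice with defective-probability
#' weighting, and evaluates the negative log multinomial likelihood of the
#' observed trials in those bins. Occupied bins with zero simulated mass
#' receive the floor probability `1/(2 n_sim)`. Censored trials are
#' excluded. Deterministic given `seed`.
#'
#' @param params a [lit_params] object.
#' @param trials a trial table (single urgency condition).
#' @param model `"lit"` or `"ddm"` simulator.
#' @param n_quantiles number of RT quantiles per choice (default 10).
#' @param n_sim simulated trials per stimulus condition (default 10000).
#' @param seed integer seed.
#' @param dt,t_max simulation grid.
#' @return scalar negative log-likelihood (sum over conditions).
#' @export
quantile_nll <- function(params, trials, model = c("lit", "ddm"),
                         n_quantiles = 10, n_sim = 10000, seed = 1,
                         dt = 0.001, t_max = 4) {
  model <- match.arg(model)
  simfun <- if (model == "lit") simulate_lit else simulate_ddm
  obs <- valid_trials(trials)
  conds <- sort(unique(obs$condition))
  if (!length(conds)) stop("no valid trials")
  nll <- 0
  for (cc in conds) {
    oc <- obs[obs$condition == cc, ]
    if (!nrow(oc)) stop("empty condition ", cc)
    sim <- simfun(params, condition = cc, n_trials = n_sim, dt = dt,
                  t_max = t_max, seed = seed + 7919L * cc)$trials
    sim <- valid_trials(sim)
    for (ch in c("upper", "lower")) {
      srt <- sim$rt[sim$choice == ch]
      ort <- oc$rt[oc$choice == ch]
      p_choice <- length(srt) / n_sim
      if (length(srt) >= n_quantiles) {
        qs <- stats::quantile(srt, probs = seq_len(n_quantiles - 1) / n_quantiles,
                              names = FALSE, type = 7)
        edges <- c(-Inf, qs, Inf)
        pb <- diff(c(0, stats::ecdf(srt)(qs), 1)) * p_choice
        counts <- tabulate(findInterval(ort, edges, left.open = TRUE),
                           nbins = n_quantiles)
      } else {
        pb <- p_choice
        counts <- length(ort)
      }
      pb <- pmax(pb, 1 / (2 * n_sim))
      nll <- nll - sum(counts * log(pb))
    }
  }
  nll
}

#' Bayesian information criterion
#'
#' `2 * nll + k * log(n)`: twice the negative log-likelihood penalized by
#' the free-parameter count `k` at sample size `n`.
#'
#' @param nll negative log-likelihood.
#' @param k number of free parameters.
#' @param n number of trials.
#' @export
bic <- function(nll, k, n) 2 * nll + k * log(n)
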