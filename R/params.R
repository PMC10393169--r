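#' LIT model parameters
#'
#' Constructs the full parameterization of the leaky integrating threshold
#' (LIT) model: a primary constant-drift diffusion accumulating sensory
#' evidence \eqn{x(t)}, re-integrated by a secondary leaky motor accumulator
#' \eqn{dy = \beta(x - y)dt} (with the identifiability convention
#' \eqn{\beta = \lambda}) whose first passage through \eqn{\pm a/2} triggers
#' the response. Setting `lam = Inf` collapses the model onto the standard
#' drift diffusion model (the motor stage has no memory and `y == x`).
#'
#' @param v numeric vector of drift speeds (evidence units/s), one per
#'   stimulus condition.
#' @param a boundary separation (> 0); boundaries sit at `± a/2`.
#' @param zr relative starting point in (0, 1); the absolute start is
#'   `x0 = a * (zr - 0.5)` and the motor accumulator starts adapted at
#'   `y(0) = x0`.
#' @param lam leak rate \eqn{\lambda} (1/s, > 0) of the motor accumulator;
#'   `Inf` is accepted as the pure-DDM sentinel. `1/lam` is the inverse leak,
#'   the time constant of the motor integrator's exponential memory.
#' @param sigma_star diffusion noise scale \eqn{\sigma^*} of the primary
#'   accumulator; fixed to 1 by convention for identifiability.
#' @param Ter mean non-decision time (s, >= 0).
#' @param nd_sd spread of the non-decision time (s, >= 0); the non-decision
#'   time is drawn from a Gaussian with mean `Ter` and SD `nd_sd` truncated
#'   at zero.
#' @param c boundary collapse rate (evidence units/s, >= 0); 0 means fixed
#'   bounds. Used by the single-stage diffusion variants.
#' @return An object of class `lit_params`.
#' @examples
#' p <- lit_params(v = c(1.1, 1.9, 1.1, 1.9), a = 1, zr = 0.5, lam = 2)
#' p
#' @export
lit_params <- function(v, a, zr, lam, sigma_star = 1, Ter = 0.3, nd_sd = 0.05,
                       c = 0) {
  stopifnot(is.numeric(v), length(v) >= 1, all(is.finite(v)))
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive number")
  if (!is.numeric(zr) || length(zr) != 1L || zr <= 0 || zr >= 1)
    stop("'zr' must lie strictly between 0 and 1")
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam <= 0)
    stop("'lam' must be positive (Inf = pure diffusion limit)")
  if (!is.finite(sigma_star) || sigma_star <= 0)
    stop("'sigma_star' must be positive")
  if (!is.finite(Ter) || Ter < 0) stop("'Ter' must be >= 0")
  if (!is.finite(nd_sd) || nd_sd < 0) stop("'nd_sd' must be >= 0")
  if (!is.finite(c) || c < 0) stop("'c' must be >= 0")
  structure(list(v = as.numeric(v), a = a, zr = zr,
                 x0 = a * (zr - 0.5), lam = lam, beta = lam,
                 sigma_star = sigma_star, Ter = Ter, nd_sd = nd_sd, c = c),
            class = "lit_params")
}

#' @export
print.lit_params <- function(x, ...) {
  cat("LIT parameters\n")
  cat("  drift v      :", paste(signif(x$v, 4), collapse = ", "), "\n")
  cat("  boundary a   :", x$a, " (bounds at +/-", x$a / 2, ")\n")
  cat("  start zr     :", x$zr, " (x0 =", signif(x$x0, 4), ")\n")
  if (is.finite(x$lam)) {
    cat("  leak lambda  :", x$lam, " (inverse leak", signif(1 / x$lam, 4), "s)\n")
  } else {
    cat("  leak lambda  : Inf (pure diffusion limit)\n")
  }
  cat("  sigma*       :", x$sigma_star, "\n")
  cat("  Ter, nd_sd   :", x$Ter, ",", x$nd_sd, "\n")
  if (x$c > 0) cat("  collapse c   :", x$c, "\n")
  invisible(x)
}

inv_leak <- function(p) if (is.finite(p$lam)) 1 / p$lam else 0
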