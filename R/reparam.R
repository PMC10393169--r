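#' Boundary-inflation constant from the colored-noise mapping
#'
#' The LIT with a pure-noise evidence stage is equivalent to the
#' deterministic integral of weakly colored noise with correlation-time
#' parameter \eqn{\epsilon = 1/\sqrt{\lambda}} and mapped noise scale
#' \eqn{\sigma = \sigma^*/\sqrt{2}}. The classic colored-noise boundary
#' correction then inflates the boundary separation by
#' \eqn{2\epsilon\sigma|\zeta(1/2)|}, i.e. by
#' \eqn{2|\zeta(1/2)|/\sqrt{2} \cdot \sigma^*/\sqrt{\lambda}}. This function
#' evaluates the dimensionless coefficient \eqn{2|\zeta(1/2)|/\sqrt{2}} from
#' a Riemann zeta evaluation (analytic continuation), not a stored constant.
#'
#' @return The inflation coefficient, about 2.0653.
#' @examples
#' round(inflation_coefficient(), 4)
#' @export
inflation_coefficient <- function() {
  2 * abs(pracma::zeta(0.5)) / sqrt(2)
}

#' Hagan-type colored-noise mapping of LIT parameters
#'
#' Returns the intermediate quantities of the mapping: `eps = 1/sqrt(lam)`,
#' `sigma = sigma_star/sqrt(2)`, the constant `zeta(1/2)` and the resulting
#' dimensionless inflation coefficient.
#'
#' @param lam leak rate (> 0, finite).
#' @param sigma_star primary noise scale.
#' @export
hagan_mapping <- function(lam, sigma_star = 1) {
  if (!is.numeric(lam) || lam <= 0 || !is.finite(lam))
    stop("'lam' must be positive and finite")
  zh <- pracma::zeta(0.5)
  list(eps = 1 / sqrt(lam), sigma = sigma_star / sqrt(2), zeta_half = zh,
       inflation_coefficient = 2 * abs(zh) / sqrt(2))
}

#' Effective single-stage diffusion parameters of a LIT
#'
#' Maps LIT parameters onto the approximately equivalent standard diffusion
#' model: the leak inflates the boundary separation by
#' `inflation_coefficient() * sigma_star / sqrt(lam)`, shifts the starting
#' point by the drift-induced lag `v/lam`, and adds `3/(2 lam)` to the
#' non-decision time. For `lam = Inf` the mapping is the identity.
#'
#' @param lit a [lit_params] object.
#' @param condition stimulus condition index selecting the drift.
#' @return A list of class `effective_ddm` with fields `a_eff`, `x0_eff`,
#'   `Ter_eff`, `c`, `sigma_star`, `completion_time` (time at which
#'   collapsing bounds meet; `Inf` when `c = 0`).
#' @examples
#' p <- lit_params(v = 1, a = 1, zr = 0.5, lam = 1)
#' effective_params(p)$a_eff  # 1 + 2.0653
#' @export
effective_params <- function(lit, condition = 1L) {
  stopifnot(inherits(lit, "lit_params"))
  v <- lit$v[condition]
  if (is.finite(lit$lam)) {
    a_eff <- lit$a + inflation_coefficient() * lit$sigma_star / sqrt(lit$lam)
    x0_eff <- lit$x0 + v / lit$lam
    Ter_eff <- lit$Ter + 3 / (2 * lit$lam)
  } else {
    a_eff <- lit$a
    x0_eff <- lit$x0
    Ter_eff <- lit$Ter
  }
  structure(list(a_eff = a_eff, x0_eff = x0_eff, Ter_eff = Ter_eff,
                 v = v, c = lit$c, sigma_star = lit$sigma_star,
                 nd_sd = lit$nd_sd,
                 completion_time = if (lit$c > 0) a_eff / lit$c else Inf),
            class = "effective_ddm")
}

#' Time-dependent effective boundary separation
#'
#' `max(a_eff - c t, 0)`; with collapse rate `c > 0` the bounds meet at
#' `completion_time = a_eff / c`, which upper-bounds every response time.
#'
#' @param t time (s, >= 0), vectorized.
#' @param eff an `effective_ddm` object from [effective_params].
#' @export
effective_bound <- function(t, eff) {
  pmax(eff$a_eff - eff$c * t, 0)
}

#' Urgency-control model variants
#'
#' The three competing mechanisms for block-wise urgency control, embedded
#' in a common model family (drift per stimulus condition; relative start;
#' leak; boundary separation; collapse rate). Each variant lets exactly one
#' of leak, boundary or collapse differ between the speed and accuracy
#' conditions ("U"), drifts differ between stimulus conditions ("S"), and
#' everything else is shared ("."), so all variants expose the same number
#' of free parameters. The non-decision component is absorbed by the
#' shift-invariant fit criterion per urgency condition, so it is free to
#' differ between urgency conditions in all variants.
#'
#' @return A data.frame with one row per variant (`leak`, `bound`,
#'   `collapse`), the constraint code per parameter and the free-parameter
#'   count.
#' @export
variant_table <- function() {
  vt <- data.frame(
    variant = c("leak", "bound", "collapse"),
    v = "S", zr = ".",
    inv_leak = c("U", ".", "."),
    a = c(".", "U", "."),
    c = c(".", ".", "U"),
    stringsAsFactors = FALSE
  )
  n_stim <- 4L
  vt$n_free <- n_stim +                       # drifts, one per stimulus cell
    1L +                                      # zr
    ifelse(vt$inv_leak == "U", 2L, 1L) +
    ifelse(vt$a == "U", 2L, 1L) +
    ifelse(vt$c == "U", 2L, 1L)
  vt
}
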