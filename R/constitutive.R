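# Constitutive pressure and diffusivity of the multiphase scaffold model.
# All functions are pure and vectorised over n: they sit in the inner loop of
# the PDE solver and of the phase-plane shooting integrator.

# margin below the contact singularity n = 1 - s within which evaluation is
# refused; permits near-saturation evaluation without overflow
.N_MARGIN <- 1e-9

.check_n_domain <- function(n, s) {
  if (any(!is.finite(n)) || any(n < 0))
    stop("cell fraction n must be finite and >= 0", call. = FALSE)
  if (any(n >= 1 - s - .N_MARGIN))
    stop("cell fraction n must stay below 1 - s = ", 1 - s,
         " (contact-pressure singularity)", call. = FALSE)
  invisible(TRUE)
}

#' Cell-phase interaction pressure
#'
#' The extra pressure in the cell phase arising from cell--cell and
#' cell--scaffold interactions,
#' \deqn{\Sigma(n) = \frac{\delta n^2}{1-n-s} + \nu n
#'       + \frac{\delta s n}{1-n-s} - \chi s.}
#' The rational terms are repulsive contact pressures that diverge as the
#' mixture saturates (`n -> 1 - s`), `nu n` is the dispersal pressure, and
#' `-chi s` a constant cell--scaffold attraction offset that never affects
#' the dynamics (it drops out of [dsigma_dn()]).
#'
#' @param n cell volume fraction(s), `0 <= n < 1 - s`.
#' @param p a [dim_params()] object.
#' @return Pressure value(s), same length as `n`.
#' @export
#' @examples
#' p <- dim_params(r_m = 1, r_a = 0, K = 1, mu_n = 1, mu_w = 1,
#'                 delta = 1, nu = 1, chi = 0, s = 0.2)
#' sigma_cell(0.3, p)  # 0.09/0.5 + 0.3 + 0.06/0.5 = 0.6
sigma_cell <- function(n, p) {
  stopifnot(inherits(p, "dim_params"))
  .check_n_domain(n, p$s)
  w <- 1 - n - p$s
  p$delta * n^2 / w + p$nu * n + p$delta * p$s * n / w - p$chi * p$s
}

#' Derivative of the cell-phase interaction pressure
#'
#' Analytic `d Sigma / d n`. The attraction coefficient `chi` enters
#' [sigma_cell()] only through a constant, so it is absent here: attraction to
#' the scaffold exerts no net force on the cells and is dynamically inert.
#'
#' @inheritParams sigma_cell
#' @return Pressure value(s) per unit volume fraction.
#' @export
dsigma_dn <- function(n, p) {
  stopifnot(inherits(p, "dim_params"))
  .check_n_domain(n, p$s)
  w <- 1 - n - p$s
  # d/dn [ delta (n^2 + s n)/w ] = delta [ (2n + s) w + (n^2 + s n) ] / w^2
  p$delta * ((2 * n + p$s) * w + n^2 + p$s * n) / w^2 + p$nu
}

#' Nonlinear cell diffusivity (dimensional)
#'
#' The Darcy closure eliminates the phase velocities and pressures, leaving a
#' single nonlinear diffusivity
#' \deqn{\Phi(n) = \frac{K (1-n-s)}{\mu_n (1-n-s) + \mu_w n}
#'       \frac{d\Sigma}{dn},}
#' which is strictly positive on `0 <= n < 1 - s` whenever `nu > 0`.
#'
#' @inheritParams sigma_cell
#' @return Diffusivity value(s) (length^2/time).
#' @export
#' @examples
#' p <- dim_params(r_m = 1, r_a = 0, K = 1, mu_n = 1, mu_w = 1,
#'                 delta = 1, nu = 1, chi = 0, s = 0.2)
#' Phi(0, p)  # K (nu (1-s) + delta s) / (mu_n (1-s)) = 1.25
Phi <- function(n, p) {
  stopifnot(inherits(p, "dim_params"))
  .check_n_domain(n, p$s)
  w <- 1 - n - p$s
  p$K * w / (p$mu_n * w + p$mu_w * n) * dsigma_dn(n, p)
}

#' Dimensionless cell diffusivity
#'
#' The diffusivity normalised by its value at vanishing cell fraction,
#' `phi(n) = Phi(n)/Phi(0)`, expressed in the dimensionless group:
#' \deqn{\phi(n) = \frac{(1-s)(1-n-s)}{(\eta(1-s)+s)\,(1-(\mu-1)n-s)}
#'       \left[\frac{1-s}{(1-n-s)^2} + \eta - 1\right].}
#' By construction `phi(0) = 1` exactly. For `mu = eta = 1` the expression
#' collapses to `(1-s)/(1-n-s)`. The mixture-viscosity factor
#' `1 - s + (mu - 1) n` is the denominator `mu_n (1-n-s) + mu_w n` of the
#' Darcy closure scaled by `mu_n`; it is strictly positive on the whole
#' admissible range for every `mu > 0`.
#'
#' @param n cell volume fraction(s), `0 <= n < 1 - s`.
#' @param q a [nondim_params()] object (only `s`, `mu`, `eta` are used).
#' @return Dimensionless diffusivity value(s).
#' @export
phi_nd <- function(n, q) {
  s <- q$s
  if (any(!is.finite(n)) || any(n < 0))
    stop("cell fraction n must be finite and >= 0", call. = FALSE)
  if (any(n >= 1 - s - .N_MARGIN))
    stop("cell fraction n must stay below 1 - s = ", 1 - s,
         " (contact-pressure singularity)", call. = FALSE)
  w <- 1 - n - s
  visc <- 1 - s + (q$mu - 1) * n  # (mu_n w + mu_w n) / mu_n
  if (any(visc <= 0))
    stop("mixture viscosity factor 1 - s + (mu - 1) n is non-positive", call. = FALSE)
  (1 - s) * w / ((q$eta * (1 - s) + s) * visc) * ((1 - s) / w^2 + q$eta - 1)
}

# unchecked fast closure for phi(n); inner-loop use only (integrators may
# probe marginally outside the admissible range while stepping)
.phi_factory <- function(q) {
  s <- q$s; eta <- q$eta; mu <- q$mu
  c1 <- (1 - s) / (eta * (1 - s) + s)
  function(n) {
    w <- 1 - n - s
    c1 * w / (1 - s + (mu - 1) * n) * ((1 - s) / w^2 + eta - 1)
  }
}

#' Net cell production rate (dimensionless)
#'
#' Logistic-type net growth `n (kappa - n)`: mitosis fills available pore
#' space while apoptosis removes cells at a constant per-capita rate, which
#' after non-dimensionalisation leaves `kappa = 1 - s - r_a/r_m` as the
#' effective carrying capacity. Roots at `n = 0` and `n = kappa`.
#'
#' @param n cell volume fraction(s), `n >= 0`.
#' @param kappa net growth parameter.
#' @return Rate value(s), same length as `n`.
#' @export
gamma_net <- function(n, kappa) {
  if (any(n < 0)) stop("cell fraction n must be >= 0", call. = FALSE)
  n * (kappa - n)
}
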