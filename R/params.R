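#' Dimensional model parameters
#'
#' Collects the lab-scale parameters of the multiphase scaffold model: kinetic
#' rates of mitosis and apoptosis, scaffold permeability, phase viscosities and
#' the coefficients of the cell-phase interaction pressure. The two repulsion
#' coefficients (cell--cell and cell--scaffold) are taken equal, so a single
#' `delta` is exposed. The dispersal coefficient `nu` must be strictly
#' positive: this keeps the nonlinear diffusivity [Phi()] positive on the whole
#' admissible range of cell fractions and corresponds to cells that tend to
#' spread through the scaffold rather than aggregate.
#'
#' @param r_m mitosis rate (1/time, > 0).
#' @param r_a apoptosis rate (1/time, >= 0).
#' @param K scaffold permeability (length^2, > 0).
#' @param mu_n cell-phase viscosity (pressure x time, > 0).
#' @param mu_w liquid-phase viscosity (pressure x time, > 0).
#' @param delta repulsion coefficient for cell--cell and cell--scaffold
#'   contact pressure (pressure, > 0).
#' @param nu dispersal coefficient (pressure, > 0).
#' @param chi cell--scaffold attraction coefficient (pressure, >= 0). This
#'   term is constant in the cell fraction, so it never enters the dynamics;
#'   it is kept so that the full constitutive pressure [sigma_cell()] can be
#'   evaluated.
#' @param s scaffold volume fraction (dimensionless, 0 < s < 1); the scaffold
#'   porosity is `1 - s`.
#'
#' @return An object of class `"dim_params"` (a named list of the validated
#'   fields).
#' @seealso [nondim_params()], [nondimensionalise()]
#' @export
#' @examples
#' p <- dim_params(r_m = 1, r_a = 0.2, K = 1, mu_n = 1, mu_w = 1,
#'                 delta = 1, nu = 1, chi = 0, s = 0.2)
#' Phi(0, p)
dim_params <- function(r_m, r_a, K, mu_n, mu_w, delta, nu, chi = 0, s) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  p <- list(r_m = num1(r_m, "r_m"), r_a = num1(r_a, "r_a"), K = num1(K, "K"),
            mu_n = num1(mu_n, "mu_n"), mu_w = num1(mu_w, "mu_w"),
            delta = num1(delta, "delta"), nu = num1(nu, "nu"),
            chi = num1(chi, "chi"), s = num1(s, "s"))
  if (p$r_m <= 0) stop("mitosis rate r_m must be > 0", call. = FALSE)
  if (p$r_a < 0) stop("apoptosis rate r_a must be >= 0", call. = FALSE)
  if (p$K <= 0) stop("permeability K must be > 0", call. = FALSE)
  if (p$mu_n <= 0 || p$mu_w <= 0)
    stop("viscosities mu_n, mu_w must be > 0", call. = FALSE)
  if (p$delta <= 0) stop("repulsion coefficient delta must be > 0", call. = FALSE)
  if (p$nu <= 0)
    stop("dispersal coefficient nu must be > 0 (aggregation, nu <= 0, is not supported)",
         call. = FALSE)
  if (p$chi < 0) stop("attraction coefficient chi must be >= 0", call. = FALSE)
  if (p$s <= 0 || p$s >= 1) stop("scaffold fraction s must lie in (0, 1)", call. = FALSE)
  structure(p, class = "dim_params")
}

#' Dimensionless model parameters
#'
#' The dimensionless group `(kappa, s, mu, eta)` that fully governs the
#' non-dimensional model. `kappa = 1 - s - r_a/r_m` is the net growth
#' parameter: its sign selects the large-time regime of the tissue edge
#' (positive: linear growth behind a travelling wave; zero: logarithmic
#' growth; negative: a stationary front with decaying cell fraction).
#' `mu = mu_w/mu_n` is the liquid-to-cell viscosity ratio and
#' `eta = nu/delta` the dispersal-to-repulsion interaction ratio.
#'
#' On construction the dimensionless diffusivity [phi_nd()] is checked to be
#' strictly positive on a grid over `[0, 1 - s)`; parameter combinations that
#' make it vanish or change sign (negative diffusion) are rejected.
#'
#' @param kappa net growth parameter, `kappa <= 1 - s` (any sign).
#' @param s scaffold volume fraction, 0 < s < 1.
#' @param mu viscosity ratio `mu_w/mu_n` (> 0).
#' @param eta interaction ratio `nu/delta` (> 0).
#'
#' @return An object of class `"nondim_params"`.
#' @seealso [phi_nd()], [nondimensionalise()]
#' @export
#' @examples
#' q <- nondim_params(kappa = 0.3, s = 0.2)
#' phi_nd(0.1, q)
nondim_params <- function(kappa, s, mu = 1, eta = 1) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  q <- list(kappa = num1(kappa, "kappa"), s = num1(s, "s"),
            mu = num1(mu, "mu"), eta = num1(eta, "eta"))
  if (q$s <= 0 || q$s >= 1) stop("scaffold fraction s must lie in (0, 1)", call. = FALSE)
  if (q$mu <= 0) stop("viscosity ratio mu must be > 0", call. = FALSE)
  if (q$eta <= 0) stop("interaction ratio eta must be > 0", call. = FALSE)
  if (q$kappa > 1 - q$s + 1e-12)
    stop("kappa must not exceed 1 - s (zero-apoptosis bound)", call. = FALSE)
  q <- structure(q, class = "nondim_params")
  ngrid <- seq(0, 1 - q$s - 1e-6, length.out = 257L)
  ph <- phi_nd(ngrid, q)
  if (any(!is.finite(ph)) || any(ph <= 0))
    stop("phi(n) is not strictly positive on [0, 1 - s): ",
         "these (s, mu, eta) give negative diffusion", call. = FALSE)
  q
}

#' @export
print.dim_params <- function(x, ...) {
  cat("Dimensional scaffold-model parameters\n")
  cat(sprintf("  rates:        r_m = %g, r_a = %g (r_a/r_m = %g)\n",
              x$r_m, x$r_a, x$r_a / x$r_m))
  cat(sprintf("  permeability: K = %g\n", x$K))
  cat(sprintf("  viscosities:  mu_n = %g, mu_w = %g\n", x$mu_n, x$mu_w))
  cat(sprintf("  pressures:    delta = %g, nu = %g, chi = %g\n",
              x$delta, x$nu, x$chi))
  cat(sprintf("  scaffold:     s = %g (porosity %g)\n", x$s, 1 - x$s))
  invisible(x)
}

#' @export
print.nondim_params <- function(x, ...) {
  regime <- if (x$kappa > 0) "linear (travelling wave)"
            else if (x$kappa < 0) "stationary" else "logarithmic"
  cat("Dimensionless scaffold-model parameters\n")
  cat(sprintf("  kappa = %g  [large-time edge regime: %s]\n", x$kappa, regime))
  cat(sprintf("  s = %g, mu = %g, eta = %g\n", x$s, x$mu, x$eta))
  invisible(x)
}

#' Reduce dimensional parameters to the dimensionless group and scales
#'
#' Computes `kappa = 1 - s - r_a/r_m`, `mu = mu_w/mu_n`, `eta = nu/delta`,
#' together with the time and length scales of the non-dimensionalisation:
#' time is measured in units of `1/r_m` and length in units of
#' `sqrt(Phi(0)/r_m)`, where `Phi(0)` is the nonlinear diffusivity evaluated
#' at vanishing cell fraction. The permeability `K` does not survive into the
#' dimensionless group, but it enters the length scale, so dimensional front
#' positions grow with scaffold permeability.
#'
#' @param p a [dim_params()] object.
#' @return A list with components `params` (a [nondim_params()] object) and
#'   `scales` (class `"nondim_scales"`: `time_scale`, `length_scale`, `Phi0`).
#' @export
#' @examples
#' p <- dim_params(r_m = 1, r_a = 0.2, K = 1, mu_n = 1, mu_w = 1,
#'                 delta = 1, nu = 1, chi = 0, s = 0.2)
#' nondimensionalise(p)$params$kappa  # 1 - 0.2 - 0.2 = 0.6
nondimensionalise <- function(p) {
  stopifnot(inherits(p, "dim_params"))
  Phi0 <- Phi(0, p)
  scales <- structure(
    list(time_scale = 1 / p$r_m,
         length_scale = sqrt(Phi0 / p$r_m),
         Phi0 = Phi0),
    class = "nondim_scales")
  q <- nondim_params(kappa = 1 - p$s - p$r_a / p$r_m, s = p$s,
                     mu = p$mu_w / p$mu_n, eta = p$nu / p$delta)
  list(params = q, scales = scales)
}

#' @export
print.nondim_scales <- function(x, ...) {
  cat(sprintf("Non-dimensionalisation scales: time 1/r_m = %g, length sqrt(Phi0/r_m) = %g, Phi0 = %g\n",
              x$time_scale, x$length_scale, x$Phi0))
  invisible(x)
}

#' Growth rates of the spatially uniform steady states
#'
#' The reaction term `n (kappa - n)` has steady states `n = 0` (empty
#' scaffold) and `n = kappa` (carrying capacity). Linearising the reaction
#' about each gives their growth rates `(kappa, -kappa)`: the empty state is
#' stable for `kappa < 0` and the occupied state for `kappa > 0`; at
#' `kappa = 0` both are marginal.
#'
#' @param kappa net growth parameter.
#' @return Named numeric vector `c(lambda0 = kappa, lambda_kappa = -kappa)`.
#' @export
steady_state_eigenvalues <- function(kappa) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, is.finite(kappa))
  c(lambda0 = kappa, lambda_kappa = -kappa)
}

#' Read model parameters from a configuration file
#'
#' Reads a flat YAML mapping of parameter names to numbers and returns either
#' a [nondim_params()] or a [dim_params()] object. Recognised keys are exactly
#' `kappa, s, mu, eta` (dimensionless block) and
#' `r_m, r_a, K, mu_n, mu_w, delta, nu, chi, s` (dimensional block). A file
#' must use one block or the other, never a mixture: the presence of any of
#' `kappa/mu/eta` together with any rate or viscosity key is an error.
#'
#' @param path path to a YAML file.
#' @return A [nondim_params()] or [dim_params()] object.
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("config must be a flat key: value mapping", call. = FALSE)
  nd_keys <- c("kappa", "mu", "eta")
  dim_keys <- c("r_m", "r_a", "K", "mu_n", "mu_w", "delta", "nu", "chi")
  known <- c(nd_keys, dim_keys, "s")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown parameter keys in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  has_nd <- any(nd_keys %in% names(cfg))
  has_dim <- any(dim_keys %in% names(cfg))
  if (has_nd && has_dim)
    stop("config mixes dimensionless (kappa/mu/eta) and dimensional keys; ",
         "use exactly one parameterisation block", call. = FALSE)
  if (!has_nd && !has_dim)
    stop("config contains no recognisable parameter block", call. = FALSE)
  if (has_nd) {
    do.call(nondim_params, cfg[intersect(c("kappa", "s", "mu", "eta"), names(cfg))])
  } else {
    do.call(dim_params, cfg[intersect(c(dim_keys, "s"), names(cfg))])
  }
}
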