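# Travelling-wave speed by phase-plane shooting.
#
# For kappa > 0 the tissue edge settles onto a semi-infinite travelling wave
# n(x - c t). In the flux variable q(z) = phi(n) dn/dz the wave satisfies
#
#   dq/dn = -[ q (c + q) + n (kappa - n) phi(n) ] / (q n),
#
# and the wave is the heteroclinic orbit joining (n, q) = (kappa, 0) to
# (0, -c). Both endpoints are singular, so the integration is launched from
# a linearisation about (kappa, 0) and terminated at a small floor in n; the
# speed is the unique c for which the terminal q reaches -c, located by
# bisection on the sign of the terminal mismatch q + c.

#' Phase-plane shooting problem for the travelling-wave speed
#'
#' @param params a [nondim_params()] object with `kappa > 0`.
#' @param epsilon offset below `n = kappa` at which the integration is
#'   launched along the linearised unstable direction; default `kappa * 1e-4`.
#' @param n_floor small positive floor in `n` at which integration stops;
#'   default `kappa * 1e-6`.
#' @param c_bracket initial speed bracket `c(low, high)`; the default covers
#'   both the `kappa/sqrt(2)` small-growth scaling and Fisher-like
#'   `2 sqrt(kappa)` scalings, and [wave_speed_shooting()] widens it
#'   geometrically if the mismatch does not change sign across it.
#' @return An object of class `"phase_plane_problem"`.
#' @export
phase_plane_problem <- function(params, epsilon = params$kappa * 1e-4,
                                n_floor = params$kappa * 1e-6,
                                c_bracket = NULL) {
  stopifnot(inherits(params, "nondim_params"))
  if (params$kappa <= 0)
    stop("travelling waves require kappa > 0", call. = FALSE)
  if (epsilon <= 0 || epsilon >= params$kappa)
    stop("epsilon must satisfy 0 < epsilon << kappa", call. = FALSE)
  if (n_floor <= 0 || n_floor >= params$kappa - epsilon)
    stop("n_floor must satisfy 0 < n_floor < kappa - epsilon", call. = FALSE)
  if (is.null(c_bracket)) {
    phimax <- max(phi_nd(seq(0, params$kappa, length.out = 65L), params))
    c_bracket <- c(1e-3 * params$kappa,
                   2 * max(sqrt(params$kappa * phimax), params$kappa))
  }
  if (!(c_bracket[1] > 0 && c_bracket[2] > c_bracket[1]))
    stop("c_bracket must satisfy 0 < low < high", call. = FALSE)
  structure(list(params = params, epsilon = epsilon, n_floor = n_floor,
                 c_bracket = c_bracket),
            class = "phase_plane_problem")
}

#' Phase-plane right-hand side dq/dn
#'
#' @param n cell fraction, `0 < n <= kappa`.
#' @param q flux variable, `q < 0` along admissible paths.
#' @param c candidate wave speed.
#' @param params a [nondim_params()] object.
#' @return `dq/dn` at `(n, q)`.
#' @export
phase_rhs <- function(n, q, c, params) {
  if (any(n == 0) || any(q == 0))
    stop("phase-plane RHS is singular at n = 0 or q = 0", call. = FALSE)
  -(q * (c + q) + n * (params$kappa - n) * phi_nd(n, params)) / (q * n)
}

#' Launch point of the heteroclinic integration
#'
#' Linearises the phase plane about the singular fixed point `(kappa, 0)`:
#' along the connecting direction `q = lambda (n - kappa)` the slope solves
#' `kappa lambda^2 + c lambda - kappa phi(kappa) = 0`, whose positive root is
#' taken. Returns the start state a distance `epsilon` below `kappa`.
#'
#' @param c candidate wave speed (> 0).
#' @param pp a [phase_plane_problem()].
#' @return Named vector `c(n = kappa - epsilon, q = -lambda * epsilon)`.
#' @export
series_start <- function(c, pp) {
  stopifnot(c > 0)
  k <- pp$params$kappa
  phik <- phi_nd(k, pp$params)
  lambda <- (-c + sqrt(c^2 + 4 * k^2 * phik)) / (2 * k)
  c(n = k - pp$epsilon, q = -lambda * pp$epsilon)
}

#' Integrate the candidate heteroclinic path
#'
#' Integrates `dq/dn` downward in `n` from the linearised launch point to the
#' floor `n_floor`, stopping early if `q` reaches zero from below (the path
#' turns back before reaching the axis) or `|q|` exceeds a blow-up bound.
#'
#' @inheritParams series_start
#' @param sample logical; keep the sampled `(n, q)` path (default `TRUE`).
#' @return List with `q_terminal`, `n_terminal`, `outcome` (one of
#'   `"reached_floor"`, `"overshoot"`, `"blow_up"`), and (if `sample`) the
#'   path columns `n`, `q`.
#' @export
integrate_heteroclinic <- function(c, pp, sample = TRUE) {
  start <- series_start(c, pp)
  k <- pp$params$kappa
  q_bound <- 50 * max(c, k, 1)
  rhs <- function(n, y, parms) {
    q <- y[1]
    list(-(q * (c + q) + n * (k - n) * parms$phi(n)) / (q * n))
  }
  root <- function(n, y, parms) c(y[1] + 1e-14, abs(y[1]) - q_bound)
  pr <- list(phi = .phi_factory(pp$params))
  nseq <- if (sample)
    seq(start[["n"]], pp$n_floor, length.out = 201L)
  else c(start[["n"]], pp$n_floor)
  sol <- deSolve::lsoda(y = start[["q"]], times = nseq, func = rhs,
                        parms = pr, rtol = 1e-10, atol = 1e-12,
                        rootfunc = root, maxsteps = 1e5)
  nn <- sol[, 1L]; qq <- sol[, 2L]
  n_term <- nn[length(nn)]; q_term <- qq[length(qq)]
  outcome <- if (n_term <= pp$n_floor * (1 + 1e-8)) "reached_floor"
             else if (abs(q_term) >= q_bound * 0.99) "blow_up"
             else "overshoot"
  out <- list(q_terminal = q_term, n_terminal = n_term, outcome = outcome)
  if (sample) { out$n <- nn; out$q <- qq }
  out
}

# terminal mismatch F(c) = q_terminal + c; overshoot paths terminate at
# q ~ 0 (F = c > 0), blow-up paths at large negative q (F < 0), so the sign
# of F brackets the connection from both sides
.shoot_mismatch <- function(c, pp) {
  r <- integrate_heteroclinic(c, pp, sample = FALSE)
  r$q_terminal + c
}

#' Travelling-wave speed by bisection shooting
#'
#' Locates the wave speed `c(kappa, s, mu, eta)` as the root of the terminal
#' mismatch `q(n_floor; c) + c` over a bracketing interval, widening the
#' bracket geometrically if both endpoints give the same mismatch sign.
#'
#' @param params a [nondim_params()] with `kappa > 0`, or a
#'   [phase_plane_problem()].
#' @param tol absolute tolerance on `c` (default 1e-8).
#' @return Object of class `"wave_speed_result"`: `c`, `mismatch`,
#'   `iterations`, `n_profile`, `q_profile` (the sampled heteroclinic path at
#'   the accepted speed), and the `problem`.
#' @export
#' @examples
#' res <- wave_speed_shooting(nondim_params(kappa = 0.3, s = 0.2))
#' res$c
wave_speed_shooting <- function(params, tol = 1e-8) {
  pp <- if (inherits(params, "phase_plane_problem")) params
        else phase_plane_problem(params)
  lo <- pp$c_bracket[1]; hi <- pp$c_bracket[2]
  f_lo <- .shoot_mismatch(lo, pp); f_hi <- .shoot_mismatch(hi, pp)
  widen <- 0L
  while (sign(f_lo) == sign(f_hi) && widen < 8L) {
    lo <- lo / 4; hi <- hi * 2
    f_lo <- .shoot_mismatch(lo, pp); f_hi <- .shoot_mismatch(hi, pp)
    widen <- widen + 1L
  }
  if (sign(f_lo) == sign(f_hi))
    stop("failed to bracket the wave speed: mismatch has the same sign at ",
         signif(lo, 4), " and ", signif(hi, 4), call. = FALSE)
  it <- 0L
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    f_mid <- .shoot_mismatch(mid, pp)
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid }
    else { hi <- mid; f_hi <- f_mid }
    it <- it + 1L
    if (it > 200L) break
  }
  c_hat <- 0.5 * (lo + hi)
  path <- integrate_heteroclinic(c_hat, pp, sample = TRUE)
  structure(list(c = c_hat, mismatch = path$q_terminal + c_hat,
                 iterations = it, n_profile = path$n, q_profile = path$q,
                 outcome = path$outcome, problem = pp),
            class = "wave_speed_result")
}

#' @export
print.wave_speed_result <- function(x, ...) {
  cat(sprintf("Travelling-wave speed c = %.8f (kappa = %g, s = %g, mu = %g, eta = %g)\n",
              x$c, x$problem$params$kappa, x$problem$params$s,
              x$problem$params$mu, x$problem$params$eta))
  cat(sprintf("  terminal mismatch %.3g after %d bisections; path outcome: %s\n",
              x$mismatch, x$iterations, x$outcome))
  invisible(x)
}

#' Reconstruct the travelling-wave profile n(z)
#'
#' Recovers the physical wave coordinate from the heteroclinic path via
#' `dz/dn = phi(n)/q(n)` by trapezoidal quadrature along the sampled path,
#' anchored at `z = 0` where `n = 0` (the tissue edge). The profile is
#' monotone decreasing in `z`, has edge slope `dn/dz = -c`, and approaches
#' the carrying capacity `n = kappa` far behind the front.
#'
#' @param res a [wave_speed_shooting()] result.
#' @return Data frame with columns `z` (<= 0), `n`, `q`, ordered by
#'   increasing `z`.
#' @export
wave_profile <- function(res) {
  stopifnot(inherits(res, "wave_speed_result"))
  nn <- res$n_profile; qq <- res$q_profile
  pp <- res$problem
  integrand <- phi_nd(nn, pp$params) / qq
  # z(n) = int_0^n phi/q dn'; path is sampled from kappa - eps down to floor
  ord <- order(nn)                      # ascending in n
  nasc <- nn[ord]; iasc <- integrand[ord]; qasc <- qq[ord]
  dz <- cumsum(c(0, 0.5 * (iasc[-1] + iasc[-length(iasc)]) * diff(nasc)))
  # anchor: extrapolate from n_floor to n = 0 with dz/dn ~ phi(0)/(-c)
  z0 <- nasc[1] * phi_nd(0, pp$params) / (-res$c)
  z <- z0 + dz
  out <- data.frame(z = z, n = nasc, q = qasc)
  out[order(out$z), , drop = FALSE]
}
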