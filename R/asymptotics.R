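# Closed-form and semi-closed-form solutions for |kappa| << 1 and kappa = 0.
#
# When the cell fraction is small, phi(n) ~ 1 and the substitution
# n = exp(kappa t) N, T = (exp(kappa t) - 1)/kappa maps the moving-boundary
# model onto the parameter-free system N_T = (N N_x)_x - N^2 with
# L'(T) = -N_x(L, T). That system admits an exact cosh-ansatz family
# N = A(T) - B(T) cosh(x/sqrt(2)), whose amplitudes obey a planar ODE system
# with the implicit front law sinh(sqrt(2) L) - sqrt(2) L = alpha T + beta.
# Undoing the time stretch yields explicit large-time laws for n and L at
# small |kappa|, including the stationary front position for kappa < 0 and
# the logarithmic front coefficient 1/sqrt(2).

#' Stretched time of the near-extinction transform
#'
#' `T = (exp(kappa t) - 1) / kappa`, with a series evaluation (`expm1`-based)
#' taking over for `|kappa t|` below 1e-6 so that the `kappa -> 0` limit
#' `T = t` is reached without catastrophic cancellation. For `kappa < 0`,
#' `T -> 1/|kappa|` as `t -> Inf`, which is why fronts stall in that case.
#'
#' @param t non-negative time(s).
#' @param kappa net growth parameter.
#' @return Stretched time(s) `T`.
#' @export
transform_time <- function(t, kappa) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (kappa == 0) return(t)
  out <- ifelse(abs(kappa * t) < 1e-6, t * (1 + kappa * t / 2), expm1(kappa * t) / kappa)
  as.numeric(out)
}

#' Parameters of the cosh-ansatz solution family
#'
#' From the initial amplitudes `0 < B0 < A0` of the profile
#' `N(x, 0) = A0 - B0 cosh(x/sqrt(2))`, computes the implied initial front
#' `L0 = sqrt(2) acosh(A0/B0)` and the constants of the implicit front law
#' `sinh(sqrt(2) L) - sqrt(2) L = alpha T + beta`:
#' `alpha = 2 B0^-2 (A0^2 - B0^2)^(3/2)` and
#' `beta = sinh(sqrt(2) L0) - sqrt(2) L0`.
#'
#' @param A0 uniform amplitude.
#' @param B0 cosh-mode amplitude (`0 < B0 < A0`).
#' @param m optional general-initial-data constant to carry along (see
#'   [general_ic_forms()]); for this family it equals `sqrt(2/alpha)`.
#' @return Object of class `"asymptotic_params"` with fields `A0`, `B0`,
#'   `alpha`, `beta`, `L0`, `m`.
#' @export
#' @examples
#' ap <- alpha_beta(A0 = 0.05, B0 = 0.01)
#' ap$alpha  # 2.35151
alpha_beta <- function(A0, B0, m = NULL) {
  if (!(is.numeric(A0) && is.numeric(B0) && B0 > 0 && A0 > B0))
    stop("amplitudes must satisfy 0 < B0 < A0", call. = FALSE)
  L0 <- sqrt(2) * acosh(A0 / B0)
  alpha <- 2 * B0^-2 * (A0^2 - B0^2)^1.5
  beta <- sinh(sqrt(2) * L0) - sqrt(2) * L0
  if (is.null(m)) m <- sqrt(2 / alpha)
  structure(list(A0 = A0, B0 = B0, alpha = alpha, beta = beta,
                 L0 = L0, m = m),
            class = "asymptotic_params")
}

#' @export
print.asymptotic_params <- function(x, ...) {
  cat(sprintf("Cosh-ansatz parameters: A0 = %g, B0 = %g -> L0 = %.6g, alpha = %.6g, beta = %.6g, m = %.6g\n",
              x$A0, x$B0, x$L0, x$alpha, x$beta, x$m))
  invisible(x)
}

#' Front position from the implicit law
#'
#' Solves `sinh(sqrt(2) L) - sqrt(2) L = alpha T + beta` for the unique
#' positive root, by safeguarded Newton seeded with the large-`T` expansion
#' [L_largeT()] (bisection fallback on `[0, 2 * seed]`); the left-hand side
#' is strictly increasing on `L > 0`, so the root is unique.
#'
#' @param T stretched time(s), >= 0.
#' @param ap an [alpha_beta()] object.
#' @return Front position(s) `L(T)`; `L(0) = L0` by construction of `beta`.
#' @export
solve_L_implicit <- function(T, ap) {
  stopifnot(inherits(ap, "asymptotic_params"))
  if (any(T < 0)) stop("T must be >= 0", call. = FALSE)
  rhs <- ap$alpha * T + ap$beta
  vapply(rhs, function(r) {
    g <- function(L) sinh(sqrt(2) * L) - sqrt(2) * L - r
    seed <- if (2 * r > exp(1)) log(2 * r) / sqrt(2) else max(ap$L0, 1)
    L <- seed
    ok <- FALSE
    for (i in 1:50) {
      gv <- g(L)
      dg <- sqrt(2) * (cosh(sqrt(2) * L) - 1)
      if (dg <= 0) break
      step <- gv / dg
      Lnew <- L - step
      if (Lnew <= 0) break
      if (abs(step) < 1e-13 * max(1, L)) { L <- Lnew; ok <- TRUE; break }
      L <- Lnew
    }
    if (!ok || abs(g(L)) > 1e-8 * max(1, r))
      L <- stats::uniroot(g, c(0, 2 * max(seed, ap$L0, 1)), tol = 1e-14,
                          extendInt = "upX")$root
    L
  }, numeric(1))
}

#' Cosh-ansatz profile N(x, T) through the front position
#'
#' Evaluates the exact ansatz profile in the form parameterised by the
#' current front position,
#' `N = (alpha/2) csch^3(L/sqrt(2)) [cosh(L/sqrt(2)) - cosh(x/sqrt(2))]`,
#' which vanishes at `x = L` and peaks at the tissue centre.
#'
#' @param x position(s), `0 <= x <= L`.
#' @param L current front position (from [solve_L_implicit()]).
#' @param ap an [alpha_beta()] object.
#' @return Profile value(s) `N`.
#' @export
N_profile <- function(x, L, ap) {
  stopifnot(inherits(ap, "asymptotic_params"))
  (ap$alpha / 2) / sinh(L / sqrt(2))^3 * (cosh(L / sqrt(2)) - cosh(x / sqrt(2)))
}

# amplitudes (A, B) implied by the front position L through the ansatz
.AB_from_L <- function(L, ap) {
  cs <- 1 / sinh(L / sqrt(2))^3
  B <- (ap$alpha / 2) * cs
  A <- B * cosh(L / sqrt(2))
  c(A = A, B = B)
}

#' Integrate the cosh-mode amplitude system
#'
#' Numerically integrates the planar system obeyed by the ansatz amplitudes,
#' `dA/dT = -A^2 - B^2/2`, `dB/dT = -3 A B / 2`, from `(A0, B0)`. Both
#' amplitudes decay and the ordering `B < A` is preserved, so the front
#' `L = sqrt(2) acosh(A/B)` stays defined. This is the independent numerical
#' route to the same solution that [solve_L_implicit()]/[N_profile()] give in
#' implicit closed form.
#'
#' @param A0,B0 initial amplitudes (`0 < B0 < A0`).
#' @param T_end final stretched time.
#' @param T_out optional report times (default 200 points, log-spaced tail).
#' @param rel_tol,abs_tol integrator tolerances.
#' @return Data frame with columns `T`, `A`, `B`, `L`.
#' @export
integrate_AB <- function(A0, B0, T_end, T_out = NULL,
                         rel_tol = 1e-10, abs_tol = 1e-12) {
  if (!(B0 > 0 && A0 > B0)) stop("amplitudes must satisfy 0 < B0 < A0", call. = FALSE)
  if (is.null(T_out)) {
    T_out <- unique(c(seq(0, min(1, T_end), length.out = 26L),
                      exp(seq(log(max(1e-2, min(1, T_end))), log(T_end),
                              length.out = 175L))))
    T_out <- sort(unique(c(0, T_out[T_out <= T_end], T_end)))
  }
  rhs <- function(t, y, p) list(c(-y[1]^2 - y[2]^2 / 2, -1.5 * y[1] * y[2]))
  sol <- deSolve::ode(y = c(A = A0, B = B0), times = T_out, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rel_tol, atol = abs_tol)
  out <- as.data.frame(sol)
  names(out)[1] <- "T"
  out$L <- sqrt(2) * acosh(pmax(out$A / out$B, 1))
  out
}

#' Large-T expansion of the front position
#'
#' Two-term inversion of the implicit front law for `T >> 1`:
#' `L(T) ~ ln(2 alpha T)/sqrt(2) * (1 + 1/(alpha T))`. Its slope against
#' `ln T` approaches the universal logarithmic front coefficient
#' `1/sqrt(2)`.
#'
#' @param T stretched time(s) with `2 alpha T > 1`.
#' @param ap an [alpha_beta()] object.
#' @return Front position approximation(s).
#' @export
L_largeT <- function(T, ap) {
  stopifnot(inherits(ap, "asymptotic_params"))
  if (any(2 * ap$alpha * T <= 1))
    stop("L_largeT requires 2 * alpha * T > 1", call. = FALSE)
  log(2 * ap$alpha * T) / sqrt(2) * (1 + 1 / (ap$alpha * T))
}

#' Small-|kappa| front position in the original time
#'
#' Undoes the time stretch in [L_largeT()]:
#' `L ~ ln(2 alpha (exp(kappa t) - 1)/kappa)/sqrt(2) *
#'      (1 + kappa/(alpha (exp(kappa t) - 1)))`.
#' For `kappa > 0` this grows like `kappa t / sqrt(2)` at large time (the
#' delayed travelling wave); for `kappa < 0` it saturates at [L_infinity()];
#' as `kappa -> 0` it reduces to [L_largeT()] with `T = t`.
#'
#' @param t time(s), `t >> 1`.
#' @param kappa net growth parameter, `|kappa| << 1`.
#' @param ap an [alpha_beta()] object.
#' @param warn_validity warn when `|kappa| t` is so large that the underlying
#'   `phi ~ 1` expansion has left its stated window (default `TRUE`, for
#'   `kappa > 0` only; the law remains the correct travelling-wave limit).
#' @return Front position approximation(s).
#' @export
L_smallkappa <- function(t, kappa, ap, warn_validity = TRUE) {
  stopifnot(inherits(ap, "asymptotic_params"))
  if (abs(kappa) >= 0.5)
    warning("L_smallkappa is an expansion for |kappa| << 1; kappa = ", kappa)
  Tt <- transform_time(t, kappa)
  log(2 * ap$alpha * Tt) / sqrt(2) * (1 + 1 / (ap$alpha * Tt))
}

#' Stationary front position for decaying tissue
#'
#' For `kappa < 0` the stretched time saturates at `1/|kappa|`, so the front
#' stalls at
#' `L_inf ~ ln(2 alpha/|kappa|)/sqrt(2) * (1 + |kappa|/alpha)`.
#'
#' @param kappa net growth parameter, strictly negative with `|kappa| << 1`.
#' @param alpha front-law constant (> 0), from [alpha_beta()].
#' @return The stationary front position.
#' @export
#' @examples
#' L_infinity(-0.001, alpha_beta(0.05, 0.01)$alpha)  # 5.98
L_infinity <- function(kappa, alpha) {
  if (kappa >= 0) stop("L_infinity is defined for kappa < 0 only", call. = FALSE)
  stopifnot(alpha > 0)
  ak <- abs(kappa)
  log(2 * alpha / ak) / sqrt(2) * (1 + ak / alpha)
}

#' Small-|kappa| cell-fraction profile at large time
#'
#' Large-time approximations for the cell fraction, dispatching on the sign
#' of `kappa`:
#' for `0 < kappa << 1`,
#' `n ~ kappa - sqrt(2 kappa^3 / alpha) cosh(x/sqrt(2)) exp(-kappa t / 2)`
#' (relaxation onto the travelling wave emerging from `n = kappa`); for
#' `kappa < 0`,
#' `n ~ |kappa| e^{-|kappa| t}/(1 - e^{-|kappa| t}) *
#'      [1 - sqrt(2 |kappa|/(alpha (1 - e^{-|kappa| t}))) cosh(x/sqrt(2))]`
#' (exponential decay against the stationary front). For `kappa = 0` the
#' profile is routed through [general_ic_forms()] with `m = sqrt(2/alpha)`.
#'
#' @param x position(s) within the current front.
#' @param t time, `t >> 1`.
#' @param kappa net growth parameter, `|kappa| << 1`.
#' @param ap an [alpha_beta()] object.
#' @return Cell-fraction approximation(s); values are clipped below at 0
#'   (beyond the predicted front the expansion is negative).
#' @export
n_smallkappa <- function(x, t, kappa, ap) {
  stopifnot(inherits(ap, "asymptotic_params"))
  if (kappa == 0)
    return(general_ic_forms(transform_time(t, 0), sqrt(2 / ap$alpha), x = x)$N)
  if (kappa > 0) {
    v <- kappa - sqrt(2 * kappa^3 / ap$alpha) * cosh(x / sqrt(2)) * exp(-kappa * t / 2)
  } else {
    ak <- abs(kappa)
    decay <- exp(-ak * t)
    pref <- ak * decay / (1 - decay)
    v <- pref * (1 - sqrt(2 * ak / (ap$alpha * (1 - decay))) * cosh(x / sqrt(2)))
  }
  pmax(v, 0)
}

#' Interior-layer similarity profile at the front
#'
#' The self-similar shape of the cell distribution inside the narrow layer at
#' the moving front of the transformed system, in the layer coordinate
#' `theta = x - L`: `f(theta) = 1 - exp(theta/sqrt(2))`, together with the
#' front coefficient `b = 1/sqrt(2)` (returned as the attribute `"b"`). This
#' profile solves `-b f' = (f f')' + f(1 - f)` exactly and pins the
#' universal logarithmic front coefficient.
#'
#' @param theta layer coordinate(s), `theta <= 0`.
#' @return Profile value(s) `f(theta)` in `[0, 1)`, with attribute `b`.
#' @export
interior_layer_f <- function(theta) {
  if (any(theta > 0)) stop("theta must be <= 0 (inside the front)", call. = FALSE)
  structure(1 - exp(theta / sqrt(2)), b = 1 / sqrt(2))
}

#' Large-T forms for general initial data
#'
#' Whatever the initial cell distribution, solutions of the transformed
#' system converge to
#' `N(x, T) ~ 1/T - m cosh(x/sqrt(2)) T^(-3/2)` and
#' `L(T) ~ sqrt(2) acosh(sqrt(T)/m)`,
#' where the single constant `m > 0` carries the memory of the initial data.
#' `m` shifts the front by a constant (`sqrt(2) ln(m2/m1)` between two
#' values) but never changes the logarithmic front speed. For cosh-ansatz
#' initial data `m = sqrt(2/alpha)`.
#'
#' @param T stretched time(s), `T > m^2`.
#' @param m general-initial-data constant (> 0).
#' @param x optional position(s); when given, `N` is evaluated there (vector
#'   `T` then must have length 1).
#' @return List with `L` and (if `x` given) `N`, else `N0` (the centre
#'   value `1/T - m T^(-3/2)`).
#' @export
general_ic_forms <- function(T, m, x = NULL) {
  stopifnot(m > 0)
  if (any(sqrt(T) / m < 1))
    stop("general_ic_forms requires T > m^2 (front beyond the origin)", call. = FALSE)
  L <- sqrt(2) * acosh(sqrt(T) / m)
  if (is.null(x)) {
    list(L = L, N0 = 1 / T - m * T^(-1.5))
  } else {
    if (length(T) != 1L) stop("supply a single T when x is given", call. = FALSE)
    list(L = L, N = pmax(1 / T - m * cosh(x / sqrt(2)) * T^(-1.5), 0))
  }
}

#' Fit the general-initial-data constant m from a trajectory
#'
#' Inverts the large-`T` front law on the tail of a marginal-growth
#' (`kappa = 0`) trajectory: since `cosh(L/sqrt(2)) = sqrt(T)/m` exactly
#' along the limiting form, `m` is estimated by a deterministic linear
#' regression (through the origin) of `cosh(L/sqrt(2))` on `sqrt(T)`.
#'
#' @param tr a `"trajectory"` from a `kappa = 0` run of
#'   [solve_moving_boundary()] or from [solve_transformed()] (report times
#'   are then already the stretched time).
#' @param window tail window in `T`; defaults to the last decade of the run.
#' @return List with `m`, `residual` (relative RMS misfit of `L` over the
#'   window) and `n_points`.
#' @export
fit_m <- function(tr, window = NULL) {
  stopifnot(inherits(tr, "trajectory"))
  if (!tr$transformed && tr$params$kappa != 0)
    stop("fit_m applies to kappa = 0 (or transformed-system) trajectories",
         call. = FALSE)
  Tmax <- max(tr$times)
  if (is.null(window)) window <- c(Tmax / 10, Tmax)
  sel <- tr$times >= window[1] & tr$times <= window[2]
  if (sum(sel) < 3L)
    warning("fewer than 3 report times in the fit window: tail too short")
  Tt <- tr$times[sel]; LL <- tr$L_values[sel]
  y <- cosh(LL / sqrt(2)); u <- sqrt(Tt)
  m_hat <- sum(u * u) / sum(u * y)     # slope of y ~ u through 0 is 1/m
  Lpred <- sqrt(2) * acosh(pmax(u / m_hat, 1))
  list(m = m_hat, residual = sqrt(mean((Lpred - LL)^2)) / mean(LL),
       n_points = sum(sel))
}
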