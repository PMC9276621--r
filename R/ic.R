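# Initial-condition families for the moving-boundary solver. Profiles are
# expressed in the boundary-fixed coordinate xi = x / L0 on [0, 1] and must
# vanish at the tissue edge xi = 1.

#' Construct an initial condition for the moving-boundary solver
#'
#' Low-level constructor: wraps a profile function of the fixed coordinate
#' `xi in [0, 1]` together with the initial front position `L0`. The profile
#' must vanish at `xi = 1` (the cell fraction is identically zero at the
#' tissue edge) and stay within `[0, 1 - s)`. Most users should call
#' [make_ic_quadratic()] or [make_ic_cosh()] instead.
#'
#' @param profile function of `xi` returning the initial cell fraction.
#' @param L0 initial front position (> 0).
#' @param s scaffold fraction used for the upper-bound check.
#' @param descriptor character tag recording the generator family.
#' @return An object of class `"initial_condition"` with fields `profile`,
#'   `L0`, `descriptor`.
#' @export
initial_condition <- function(profile, L0, s, descriptor = "custom") {
  stopifnot(is.function(profile), is.numeric(L0), length(L0) == 1L, L0 > 0)
  xi_chk <- seq(0, 1, length.out = 101L)
  v <- profile(xi_chk)
  if (length(v) != length(xi_chk) || any(!is.finite(v)))
    stop("profile must be vectorised over xi and finite on [0, 1]", call. = FALSE)
  if (abs(v[length(v)]) > 1e-12)
    stop("profile(1) must be 0: the cell fraction vanishes at the tissue edge",
         call. = FALSE)
  if (any(v < -1e-12) || any(v >= 1 - s))
    stop("profile values must lie in [0, 1 - s)", call. = FALSE)
  structure(list(profile = profile, L0 = as.numeric(L0),
                 descriptor = descriptor),
            class = "initial_condition")
}

#' @export
print.initial_condition <- function(x, ...) {
  cat(sprintf("Initial condition [%s]: L0 = %g, n(0) = %g\n",
              x$descriptor, x$L0, x$profile(0)))
  invisible(x)
}

#' Quadratic initial cell distribution
#'
#' The standard seeding profile `n0(xi) = omega (1 - xi^2)`: cell fraction
#' `omega` at the tissue centre, decaying to zero at the edge. With the
#' default `L0 = 1` the initial total cell mass is `2 omega / 3`.
#'
#' @param omega peak cell fraction at the centre (`0 < omega < 1 - s`).
#' @param L0 initial front position (> 0), default 1.
#' @param s scaffold fraction (bounds check only).
#' @return An [initial_condition()] object.
#' @export
#' @examples
#' ic <- make_ic_quadratic(omega = 0.03, L0 = 1, s = 0.2)
#' ic$profile(c(0, 1))  # 0.03, 0
make_ic_quadratic <- function(omega, L0 = 1, s = 0.2) {
  stopifnot(is.numeric(omega), length(omega) == 1L)
  if (omega <= 0 || omega >= 1 - s)
    stop("omega must lie in (0, 1 - s)", call. = FALSE)
  force(omega)
  initial_condition(function(xi) omega * (1 - xi^2), L0 = L0, s = s,
                    descriptor = "quadratic")
}

#' Cosh-ansatz initial cell distribution
#'
#' The initial profile `n(x, 0) = A0 - B0 cosh(x / sqrt(2))` on
#' `0 <= x <= L0`, with the front placed where the profile vanishes,
#' `L0 = sqrt(2) acosh(A0 / B0)`. This is the `T = 0` member of the
#' cosh-ansatz family that solves the small-growth-rate transformed problem
#' exactly, so solver runs started from it can be compared directly with the
#' closed-form asymptotic solutions (see [alpha_beta()], [solve_L_implicit()]).
#'
#' @param A0 uniform amplitude (`0 < B0 < A0 << 1`).
#' @param B0 cosh-mode amplitude.
#' @param s scaffold fraction (bounds check only).
#' @return An [initial_condition()] object; its `L0` equals
#'   `sqrt(2) * acosh(A0/B0)` and `profile(1) = 0` exactly.
#' @export
#' @examples
#' ic <- make_ic_cosh(A0 = 0.05, B0 = 0.01)
#' ic$L0            # sqrt(2) acosh(5) = 3.24198
#' ic$profile(0)    # A0 - B0 = 0.04
make_ic_cosh <- function(A0, B0, s = 0.2) {
  stopifnot(is.numeric(A0), is.numeric(B0), length(A0) == 1L, length(B0) == 1L)
  if (!(B0 > 0 && A0 > B0))
    stop("amplitudes must satisfy 0 < B0 < A0", call. = FALSE)
  if (A0 >= 1 - s)
    stop("A0 must stay below 1 - s", call. = FALSE)
  L0 <- sqrt(2) * acosh(A0 / B0)
  force(A0); force(B0)
  profile <- function(xi) {
    v <- A0 - B0 * cosh(xi * L0 / sqrt(2))
    # clamp the edge node: cosh(acosh(A0/B0)) reproduces A0/B0 to rounding only
    v[xi == 1] <- 0
    pmax(v, 0)
  }
  initial_condition(profile, L0 = L0, s = s, descriptor = "cosh")
}

#' Initial condition from tabulated values
#'
#' Builds an [initial_condition()] by monotone-in-x interpolation of a
#' two-column table `(xi, n)` with `xi in [0, 1]`; used by the command-line
#' interface for custom seeding profiles.
#'
#' @param tab data frame or matrix with columns `xi` and `n`.
#' @param L0 initial front position (> 0).
#' @param s scaffold fraction (bounds check only).
#' @return An [initial_condition()] object.
#' @export
make_ic_table <- function(tab, L0 = 1, s = 0.2) {
  tab <- as.data.frame(tab)
  if (!all(c("xi", "n") %in% names(tab)))
    stop("table must have columns 'xi' and 'n'", call. = FALSE)
  fn <- stats::splinefun(tab$xi, tab$n, method = "hyman")
  initial_condition(function(xi) pmax(fn(xi), 0), L0 = L0, s = s,
                    descriptor = "custom")
}
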