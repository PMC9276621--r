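# Shared fixtures: the standard parameter sets and initial conditions used
# throughout the suite (scaffold fraction 0.2, unit viscosity/interaction
# ratios, quadratic seeding with omega = 0.03, cosh seeding with
# A0 = 0.05, B0 = 0.01).

unit_dim_params <- function(r_a = 0, s = 0.2, mu_w = 1, nu = 1, chi = 0) {
  dim_params(r_m = 1, r_a = r_a, K = 1, mu_n = 1, mu_w = mu_w,
             delta = 1, nu = nu, chi = chi, s = s)
}

std_nondim <- function(kappa, s = 0.2, mu = 1, eta = 1) {
  nondim_params(kappa = kappa, s = s, mu = mu, eta = eta)
}

std_quad_ic <- function() make_ic_quadratic(omega = 0.03, L0 = 1, s = 0.2)
std_cosh_ic <- function() make_ic_cosh(A0 = 0.05, B0 = 0.01)

# random admissible dimensionless parameter sets for property-style loops
random_nondim <- function(n_sets, seed = 42L) {
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    s <- runif(1, 0.05, 0.7)
    nondim_params(kappa = runif(1, -0.5, 1 - s),
                  s = s,
                  mu = exp(runif(1, -2, 2)),
                  eta = exp(runif(1, -2, 2)))
  })
}

# log-spaced report times with a linear start, for long runs
logspaced_times <- function(t_end, t_lin = 100, n_lin = 21L, n_log = 101L) {
  sort(unique(c(seq(0, min(t_lin, t_end), length.out = n_lin),
                10^seq(log10(min(t_lin, t_end)), log10(t_end),
                       length.out = n_log))))
}
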