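# Closed-form small-|kappa| machinery: time stretch, cosh-ansatz closure,
# front laws, interior layer, and the general-initial-data constant.

test_that("stretched time handles both signs and the kappa -> 0 crossover", {
  expect_equal(transform_time(1000, 0.001), (exp(1) - 1) / 0.001)  # 1718.28
  expect_equal(transform_time(5, 0), 5)
  # series branch agrees with the exact formula across the crossover
  t0 <- 1
  for (k in c(1e-9, 1e-7, 1e-5)) {
    expect_equal(transform_time(t0, k), expm1(k * t0) / k, tolerance = 1e-12)
  }
  # kappa < 0 saturates at 1/|kappa|
  expect_equal(transform_time(1e7, -0.001), 1000, tolerance = 1e-9)
  expect_error(transform_time(-1, 0.1), ">= 0")
})

test_that("ansatz constants match their closed forms", {
  ap <- alpha_beta(0.05, 0.01)
  expect_equal(ap$alpha, 2e4 * 0.0024^1.5)              # 2.35151
  expect_equal(ap$L0, sqrt(2) * acosh(5))               # 3.24198
  # beta via cosh(2u) = 2 cosh^2(u) - 1: sinh(sqrt2 L0) = sqrt(cosh(2u)^2-1)
  expect_equal(ap$beta, sqrt((2 * 25 - 1)^2 - 1) - 2 * acosh(5))  # 44.4049
  expect_equal(ap$beta, 10 * sqrt(24) - 2 * acosh(5))
  expect_equal(ap$m, sqrt(2 / ap$alpha))
  # round trip: A0 = B0 cosh(L0/sqrt2)
  expect_equal(0.01 * cosh(ap$L0 / sqrt(2)), 0.05)
  expect_error(alpha_beta(0.01, 0.05), "B0 < A0")
})

test_that("implicit front law is solved exactly and agrees with its large-T inversion", {
  ap <- alpha_beta(0.05, 0.01)
  expect_equal(solve_L_implicit(0, ap), ap$L0, tolerance = 1e-10)
  Ts <- c(1, 10, 1e2, 1e3, 1e4)
  L <- solve_L_implicit(Ts, ap)
  # direct substitution residual of sinh(sqrt2 L) - sqrt2 L = alpha T + beta
  resid <- sinh(sqrt(2) * L) - sqrt(2) * L - (ap$alpha * Ts + ap$beta)
  expect_lt(max(abs(resid) / (ap$alpha * Ts + ap$beta)), 1e-10)
  expect_true(all(diff(L) > 0))
  # two-term inversion closes in on the exact root
  expect_equal(L_largeT(1e4, ap) / solve_L_implicit(1e4, ap), 1, tolerance = 1e-3)
  expect_equal(L_largeT(1e6, ap) / solve_L_implicit(1e6, ap), 1, tolerance = 1e-5)
  expect_error(L_largeT(1e-3, ap), "2 \\* alpha \\* T > 1")
})

test_that("cosh-ansatz closure is exact: (A, B) from the implicit solution satisfy the amplitude ODEs", {
  ap <- alpha_beta(0.05, 0.01)
  Tg <- exp(seq(log(1e-3), log(1e4), length.out = 300))
  L <- solve_L_implicit(Tg, ap)
  u <- L / sqrt(2)
  B <- (ap$alpha / 2) / sinh(u)^3
  A <- B * cosh(u)
  # chain rule through the implicit law gives dA/dT, dB/dT analytically
  dLdT <- ap$alpha / (sqrt(2) * (cosh(sqrt(2) * L) - 1))
  dBdL <- -(3 / sqrt(2)) * (ap$alpha / 2) * cosh(u) / sinh(u)^4
  dAdL <- dBdL * cosh(u) + B * sinh(u) / sqrt(2)
  expect_lt(max(abs(dAdL * dLdT - (-A^2 - B^2 / 2))), 1e-8)
  expect_lt(max(abs(dBdL * dLdT - (-1.5 * A * B))), 1e-8)
  # profile form: N(L) = 0 and N peaks at the centre with value A - B
  expect_equal(N_profile(L[100], L[100], ap), 0)
  expect_equal(N_profile(0, L[100], ap), A[100] - B[100])
})

test_that("numerical amplitude integration reproduces the implicit solution and its limits", {
  ap <- alpha_beta(0.05, 0.01)
  ab <- integrate_AB(0.05, 0.01, 1e4)
  expect_true(all(diff(ab$A) < 0) && all(diff(ab$B) < 0))
  expect_true(all(ab$B < ab$A))                         # invariant cone
  sel <- ab$T > 0
  expect_lt(max(abs(ab$L[sel] - solve_L_implicit(ab$T[sel], ap)) /
                  solve_L_implicit(ab$T[sel], ap)), 1e-6)
  # B0 -> 0 collapses dA/dT = -A^2 onto A(T) = A0/(1 + A0 T)
  ab0 <- integrate_AB(0.05, 1e-12, 100, T_out = c(0, 10, 100))
  expect_equal(ab0$A, 0.05 / (1 + 0.05 * ab0$T), tolerance = 1e-8)
})

test_that("front laws in original time: linear for kappa > 0, stationary for kappa < 0", {
  ap <- alpha_beta(0.05, 0.01)
  # kappa > 0: slope approaches kappa/sqrt(2)
  tt <- c(2e4, 4e4)
  Lp <- L_smallkappa(tt, 0.001, ap)
  expect_equal(diff(Lp) / diff(tt), 0.001 / sqrt(2), tolerance = 1e-3)
  # kappa -> 0 recovers the stretched-time law with T = t
  expect_equal(L_smallkappa(5e3, 0, ap), L_largeT(5e3, ap))
  # kappa < 0: approaches the stationary front position
  expect_equal(L_infinity(-0.001, ap$alpha),
               log(2 * ap$alpha / 0.001) / sqrt(2) * (1 + 0.001 / ap$alpha))
  expect_equal(L_infinity(-0.001, ap$alpha), 5.98181, tolerance = 1e-5)
  expect_equal(L_smallkappa(1e7, -0.001, ap), L_infinity(-0.001, ap$alpha),
               tolerance = 1e-3)
  # stationary front shrinks as decay strengthens
  Linf <- vapply(c(-0.001, -0.01, -0.05), function(k) L_infinity(k, ap$alpha),
                 numeric(1))
  expect_true(all(diff(Linf) < 0))
  expect_error(L_infinity(0.1, 1), "kappa < 0")
})

test_that("small-|kappa| profiles have the right large-time limits on both branches", {
  ap <- alpha_beta(0.05, 0.01)
  # kappa > 0: n -> kappa at fixed x as t -> Inf
  expect_equal(n_smallkappa(0, 1e6, 0.001, ap), 0.001, tolerance = 1e-6)
  n1 <- n_smallkappa(c(0, 1, 2), 1e4, 0.001, ap)
  expect_true(all(diff(n1) < 0))
  # kappa < 0: decay envelope of order exp(-|kappa| t)
  n2 <- n_smallkappa(0, 1e4, -0.001, ap)
  expect_lt(n2, 0.001 * exp(-10) / (1 - exp(-10)))
  expect_gt(n2, 0.9 * 0.001 * exp(-10))
  # kappa = 0 routes through the general-IC form with m = sqrt(2/alpha)
  expect_equal(n_smallkappa(1, 5e3, 0, ap),
               general_ic_forms(5e3, sqrt(2 / ap$alpha), x = 1)$N)
})

test_that("interior-layer profile solves its similarity ODE identically", {
  th <- seq(-8, 0, length.out = 401)
  f <- interior_layer_f(th)
  b <- attr(f, "b")
  expect_equal(b, 1 / sqrt(2))
  expect_equal(f[length(f)], 0)                          # f(0) = 0
  expect_equal(interior_layer_f(-sqrt(2) * log(2)), 0.5,
               ignore_attr = TRUE)
  expect_lt(abs(interior_layer_f(-30) - 1), 1e-9)        # f -> 1 far inside
  expect_true(all(diff(f) < 0))                          # decreasing towards the edge
  # exact derivatives: f' = -e^{th/sqrt2}/sqrt2, (f f')' = f'^2 + f f''
  e <- exp(th / sqrt(2))
  fp <- -e / sqrt(2); fpp <- -e / 2
  resid <- -b * fp - (fp^2 + (1 - e) * fpp) - (1 - e) * e
  expect_lt(max(abs(resid)), 1e-12)
  expect_error(interior_layer_f(0.1), "<= 0")
})

test_that("general-initial-data forms: m shifts the front but not its logarithmic speed", {
  Ts <- 10^seq(3, 4, length.out = 30)
  g1 <- general_ic_forms(Ts, 0.5)
  g2 <- general_ic_forms(Ts, 1.5)
  # slope d L / d ln T -> 1/sqrt(2) for any m
  s1 <- stats::coef(stats::lm(g1$L ~ log(Ts)))[2]
  s2 <- stats::coef(stats::lm(g2$L ~ log(Ts)))[2]
  expect_equal(unname(s1), 1 / sqrt(2), tolerance = 5e-3)
  expect_equal(unname(s2), 1 / sqrt(2), tolerance = 5e-3)
  # constant offset sqrt(2) ln(m2/m1) at matched large T
  expect_equal(g1$L - g2$L, rep(sqrt(2) * log(1.5 / 0.5), 30), tolerance = 1e-3)
  expect_error(general_ic_forms(1, 2), "T > m\\^2")
})

test_that("fit_m recovers a known constant and the cosh-family value", {
  # self-consistency on synthetic data generated from the front law
  Ts <- 10^seq(2, 4, length.out = 60)
  tr_fake <- structure(list(times = Ts,
                            L_values = sqrt(2) * acosh(sqrt(Ts) / 0.9),
                            params = list(kappa = 0), transformed = TRUE),
                       class = "trajectory")
  fm <- fit_m(tr_fake)
  expect_equal(fm$m, 0.9, tolerance = 1e-10)
  expect_lt(fm$residual, 1e-10)
  # parameter recovery stays sub-0.5% for a one-decade tail
  tr2 <- tr_fake; tr2$times <- 10^seq(3, 4, length.out = 30)
  tr2$L_values <- sqrt(2) * acosh(sqrt(tr2$times) / 1.7)
  expect_equal(fit_m(tr2)$m, 1.7, tolerance = 5e-3)
  # a kappa = 0 run from the cosh profile lands within a few percent of sqrt(2/alpha)
  ap <- alpha_beta(0.05, 0.01)
  st <- solver_settings(n_grid = 101, t_end = 2000,
                        output_times = logspaced_times(2000))
  tr <- solve_moving_boundary(std_nondim(0), std_cosh_ic(), st)
  fm3 <- fit_m(tr)
  expect_equal(fm3$m, sqrt(2 / ap$alpha), tolerance = 0.05)
  expect_error(fit_m(solve_moving_boundary(std_nondim(0.3), std_quad_ic(),
                                           solver_settings(n_grid = 51, t_end = 2))),
               "kappa = 0")
})
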