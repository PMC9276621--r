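# Moving-boundary solver: conservation structure, boundary handling,
# convergence, and regime diagnostics.

test_that("trajectory satisfies the structural invariants", {
  q <- std_nondim(0.3)
  tr <- solve_moving_boundary(q, std_quad_ic(),
                              solver_settings(n_grid = 101, t_end = 20))
  expect_equal(tr$n_values[, ncol(tr$n_values)], rep(0, length(tr$times)))  # edge pinned
  expect_true(all(tr$n_values < 1 - q$s))
  expect_true(min(tr$n_values) > -100 * tr$settings$abs_tol)  # positivity
  expect_true(all(tr$L_values > 0))
  expect_true(all(abs(diff(tr$L_values)) < 0.5))              # no front jumps
  # Stefan condition: stored dL/dt is -edge_gradient/L by construction
  for (at in tr$times[c(1, 51, 201)]) {
    k <- which(tr$times == at)
    expect_equal(-edge_gradient(tr, at) / tr$L_values[k], tr$dLdt_values[k])
  }
})

test_that("total mass starts at the exact integral of the seeding profile", {
  tr <- solve_moving_boundary(std_nondim(0.3), std_quad_ic(),
                              solver_settings(n_grid = 101, t_end = 1))
  # int_0^1 0.03 (1 - xi^2) dxi = 0.02; Euler-Maclaurin puts the composite
  # trapezoid at 0.02 + (h^2/12)(f'(1) - f'(0)) = 0.02 - 0.005 h^2, h = 1/100
  expect_equal(total_mass(tr, 0), 0.02, tolerance = 1e-4)
  expect_equal(total_mass(tr, 0), 0.02 - 0.005 * 0.01^2, tolerance = 1e-9)
})

test_that("mass is conserved without reaction and its budget closes with reaction", {
  q <- std_nondim(0.3)
  st_off <- solver_settings(n_grid = 101, t_end = 50, reaction_on = FALSE)
  tr <- solve_moving_boundary(q, std_quad_ic(), st_off)
  m <- vapply(tr$times, function(a) total_mass(tr, a), numeric(1))
  expect_lt(max(abs(m - m[1])) / m[1], 1e-4)
  # with the reaction on, d(mass)/dt tracks the integrated net growth
  st_on <- solver_settings(n_grid = 201, t_end = 5,
                           output_times = seq(0, 5, by = 0.05))
  tr2 <- solve_moving_boundary(q, std_quad_ic(), st_on)
  m2 <- vapply(tr2$times, function(a) total_mass(tr2, a), numeric(1))
  dm <- diff(m2) / diff(tr2$times)
  growth <- vapply(seq_along(tr2$times), function(k) {
    n <- tr2$n_values[k, ]
    h <- tr2$xi[2] - tr2$xi[1]
    tr2$L_values[k] * h * (sum(gamma_net(n, q$kappa)) -
                             0.5 * (gamma_net(n[1], q$kappa)))
  }, numeric(1))
  gmid <- (growth[-1] + growth[-length(growth)]) / 2
  expect_lt(max(abs(dm - gmid)) / max(abs(gmid)), 5e-3)
})

test_that("front position converges at second order under grid refinement", {
  q <- std_nondim(0.3)
  L_end <- vapply(c(26, 51, 101, 401), function(M) {
    tr <- solve_moving_boundary(q, std_quad_ic(),
                                solver_settings(n_grid = M, t_end = 10,
                                                output_times = c(0, 10)))
    tr$L_values[2]
  }, numeric(1))
  err <- abs(L_end[1:3] - L_end[4])
  orders <- log2(err[-3] / err[-1])
  expect_true(all(orders > 1.5 & orders < 2.5))
})

test_that("growing tissue forms a constant-speed front and decaying tissue stalls", {
  ic <- std_quad_ic()
  tr_pos <- solve_moving_boundary(std_nondim(0.3), ic,
                                  solver_settings(n_grid = 101, t_end = 50))
  fs <- front_speed(tr_pos, c(35, 50))
  expect_lt(fs$flatness, 0.05 * fs$speed)        # dL/dt settled
  expect_gt(fs$speed, 0.2)
  # max n approaches the carrying capacity kappa from the seeded 0.03
  expect_equal(max(tr_pos$n_values[length(tr_pos$times), ]), 0.3, tolerance = 5e-3)

  tr_neg <- solve_moving_boundary(std_nondim(-0.3), ic,
                                  solver_settings(n_grid = 101, t_end = 50))
  nmax <- apply(tr_neg$n_values, 1, max)
  late <- tr_neg$times > 5
  expect_true(all(diff(nmax[late]) < 0))         # monotone decay at late time
  expect_lt(abs(tr_neg$dLdt_values[length(tr_neg$times)]), 1e-6)
  expect_lt(diff(range(tr_neg$L_values[tr_neg$times > 25])), 1e-4)  # L settled
})

test_that("front_speed recovers the slope of synthetic linear growth and warns otherwise", {
  tr <- solve_moving_boundary(std_nondim(0.3), std_quad_ic(),
                              solver_settings(n_grid = 51, t_end = 10))
  fake <- tr
  fake$L_values <- 1.5 + 0.37 * fake$times
  fake$dLdt_values <- rep(0.37, length(fake$times))
  expect_equal(front_speed(fake, c(0, 10))$speed, 0.37)
  # early transient window is flagged as non-converged
  expect_warning(front_speed(tr, c(0, 2)), "not converged")
})

test_that("regime classification corroborates the sign rule over the kappa sweep", {
  ic <- std_quad_ic()
  for (k in c(0.3, 0.1, 0, -0.1, -0.3)) {
    q <- std_nondim(k)
    te <- if (k == 0) 50 else max(50, 10 / abs(k))
    tr <- solve_moving_boundary(q, ic, solver_settings(n_grid = 101, t_end = te))
    expected <- if (k > 0) "linear" else if (k < 0) "stationary" else "logarithmic"
    expect_identical(classify_regime(q, tr)$label, expected)
  }
})

test_that("classification reports a discrepancy on runs too short to leave the transient", {
  # decaying tissue still spreading diffusively: the edge has not stalled yet
  q <- std_nondim(-0.3)
  tr <- solve_moving_boundary(q, std_quad_ic(),
                              solver_settings(n_grid = 51, t_end = 2))
  expect_warning(cls <- classify_regime(q, tr), "sign rule")
  expect_identical(cls$label, "inconclusive")
  expect_identical(cls$sign_label, "stationary")
})

test_that("the transformed near-extinction system reproduces the exact ansatz front law", {
  ic <- std_cosh_ic()
  ap <- alpha_beta(0.05, 0.01)
  st <- solver_settings(n_grid = 101, t_end = 1000,
                        output_times = logspaced_times(1000))
  tr <- solve_transformed(ic, st)
  sel <- tr$times >= 10
  L_exact <- solve_L_implicit(tr$times[sel], ap)
  expect_lt(max(abs(tr$L_values[sel] - L_exact) / L_exact), 1e-3)
})

test_that("invalid solver inputs are rejected", {
  expect_error(solver_settings(n_grid = 2), "at least 3")
  expect_error(solver_settings(rel_tol = 0), "tolerances")
  expect_error(solver_settings(t_end = 10, output_times = c(0, 20)), "within")
  bad_ic <- list(profile = function(xi) rep(0.1, length(xi)), L0 = 1)
  expect_error(initial_condition(bad_ic$profile, 1, 0.2), "vanish")
})
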