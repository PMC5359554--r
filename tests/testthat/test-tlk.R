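test_that("the TLK right-hand side evaluates its three channels correctly", {
  p <- tlk_params()
  expect_equal(unname(tlk_rhs(0, 0, p)), c(0, 0, 0))
  # pure linear decay term
  p0 <- tlk_params(tau1_h = 0.25, eta_per_h = 0)
  expect_equal(unname(tlk_rhs(100, 0, p0))[1], -100 * log(2) / 0.25,
               tolerance = 1e-12)
  expect_equal(unname(tlk_rhs(100, 0, p0))[1], -277.259, tolerance = 1e-5)
  # generic state vs an independently written expression
  p2 <- tlk_params(tau1_h = 0.3, tau2_h = 6, beta1 = 0.002, beta2 = 0.04,
                   eta_per_h = 3e-4, lethal_pair_frac = 0.25)
  L1 <- 37.5; L2 <- 12.25
  l1 <- log(2) / 0.3; l2 <- log(2) / 6
  ref <- c(-l1 * L1 - 3e-4 * L1 * (L1 + L2),
           -l2 * L2 - 3e-4 * L2 * (L1 + L2),
           0.002 * l1 * L1 + 0.04 * l2 * L2 + 0.25 * 3e-4 * (L1 + L2)^2)
  expect_equal(unname(tlk_rhs(L1, L2, p2)), ref, tolerance = 1e-14)
  expect_error(tlk_rhs(-1, 0, p), "non-negative")
})

test_that("parameter validation enforces the physical ranges", {
  expect_error(tlk_params(tau1_h = 0), "tau1_h")
  expect_error(tlk_params(beta2 = 1.2), "beta2")
  expect_error(tlk_params(eta_per_h = -1), "eta_per_h")
  p <- tlk_params(tau1_h = 2)
  expect_equal(p$lambda1, log(2) / 2)
})

test_that("with eta = 0 the solver matches the closed-form kinetics to 1e-8", {
  p <- tlk_params(tau1_h = 0.25, tau2_h = 8, beta1 = 0.00026, beta2 = 0.011,
                  eta_per_h = 0)
  traj <- tlk_solve(c(100, 50), p, T_h = 24, dt_h = 1e-3)
  lam1 <- log(2) / 0.25; lam2 <- log(2) / 8
  t <- traj$time_h
  expect_equal(traj$L1, 100 * exp(-lam1 * t), tolerance = 1e-8)
  expect_equal(traj$L2, 50 * exp(-lam2 * t), tolerance = 1e-8)
  # exact finite-horizon lethal damage for the linear model
  ref_LL <- 0.00026 * 100 * (1 - exp(-lam1 * t)) +
    0.011 * 50 * (1 - exp(-lam2 * t))
  expect_equal(traj$L_lethal, ref_LL, tolerance = 1e-8)
  # one-hour benchmark: L1 halves four times
  traj1 <- tlk_solve(c(100, 0), tlk_params(tau1_h = 0.25, eta_per_h = 0),
                     T_h = 1, dt_h = 1e-3)
  expect_equal(traj1$L1[nrow(traj1)], 6.25, tolerance = 1e-8)
  # infinite-time limit beta1*L1(0) + beta2*L2(0), fast half-times
  pf <- tlk_params(tau1_h = 0.1, tau2_h = 0.5, beta1 = 0.01, beta2 = 0.2,
                   eta_per_h = 0)
  trajf <- tlk_solve(c(80, 40), pf, T_h = 24, dt_h = 1e-3)
  expect_equal(trajf$L_lethal[nrow(trajf)], 0.01 * 80 + 0.2 * 40,
               tolerance = 1e-8)
})

test_that("the RK4 solution agrees with a fine-step Euler oracle", {
  p <- tlk_params(tau1_h = 0.25, tau2_h = 8, beta1 = 0.00026, beta2 = 0.011,
                  eta_per_h = 1.6e-5)
  traj <- tlk_solve(c(60, 50), p, T_h = 24, dt_h = 0.005)
  ref <- euler_tlk(60, 50, p, T_h = 24, dt_h = 1e-4)
  got <- traj$L_lethal[nrow(traj)]
  expect_lt(abs(got - ref$L_lethal) / ref$L_lethal, 1e-3)
})

test_that("the solution is converged at the default steps", {
  p <- tlk_params()
  f1 <- tlk_final(tibble::tibble(L1_0 = 60, L2_0 = 50), p, T_h = 24,
                  dt_h = 0.005)
  f2 <- tlk_final(tibble::tibble(L1_0 = 60, L2_0 = 50), p, T_h = 24,
                  dt_h = 0.0025)
  expect_lt(abs(f1$L_lethal_T - f2$L_lethal_T) / f2$L_lethal_T, 1e-6)
  expect_lt(abs(f1$L1_T - f2$L1_T) / max(f2$L1_T, 1e-12), 1e-6)
})

test_that("trajectories satisfy the lesion-bookkeeping invariants", {
  p <- tlk_params(eta_per_h = 5e-4)  # strong interaction
  traj <- tlk_solve(c(150, 100), p, T_h = 24, dt_h = 0.005)
  expect_true(all(diff(traj$L1) <= 1e-12))
  expect_true(all(diff(traj$L2) <= 1e-12))
  expect_true(all(diff(traj$L_lethal) >= -1e-12))
  expect_true(all(traj$L1 >= 0 & traj$L2 >= 0))
  expect_lte(traj$L_lethal[nrow(traj)], 150 + 100)
})

test_that("batch finals equal the trajectory endpoint", {
  p <- tlk_params()
  states <- tibble::tibble(nucleus_id = 1:3, dose_gy = 1,
                           L1_0 = c(10, 60, 0), L2_0 = c(5, 50, 0),
                           oxygen_pct = 21)
  finals <- tlk_final(states, p, T_h = 24, dt_h = 0.005)
  for (i in 1:3) {
    traj <- tlk_solve(c(states$L1_0[i], states$L2_0[i]), p,
                      T_h = 24, dt_h = 0.005)
    expect_equal(finals$L_lethal_T[i], traj$L_lethal[nrow(traj)],
                 tolerance = 1e-12)
  }
  # per-nucleus half-times
  taus <- tibble::tibble(tau1_h = c(0.2, 0.3, 0.25), tau2_h = c(7, 9, 8))
  f <- tlk_final(states, p, T_h = 4, dt_h = 0.01, taus = taus)
  ref <- tlk_solve(c(10, 5), tlk_params(tau1_h = 0.2, tau2_h = 7),
                   T_h = 4, dt_h = 0.01)
  expect_equal(f$L_lethal_T[1], ref$L_lethal[nrow(ref)], tolerance = 1e-12)
})

test_that("survival probability is exp(-lethal damage) and monotone", {
  expect_identical(survival_probability(0), 1)
  expect_equal(survival_probability(1), exp(-1))
  expect_equal(survival_probability(1), 0.36788, tolerance = 1e-5)
  x <- seq(0, 5, by = 0.25)
  expect_true(all(diff(survival_probability(x)) < 0))
  expect_error(survival_probability(-0.1), "L_lethal")
})

test_that("a destabilising step size is rejected with advice", {
  p <- tlk_params(eta_per_h = 1)
  expect_error(tlk_solve(c(1000, 1000), p, T_h = 1, dt_h = 0.1), "reduce dt")
})

test_that("lethality integrals reproduce the integrated lethal damage", {
  # L_lethal(T) must equal beta1*I1 + beta2*I2 + frac*eta*J3 on the same grid
  p <- tlk_params(beta1 = 0.003, beta2 = 0.03, eta_per_h = 2e-4)
  states <- tibble::tibble(L1_0 = c(40, 90), L2_0 = c(30, 70))
  lam1 <- rep(p$lambda1, 2); lam2 <- rep(p$lambda2, 2)
  ints <- tlkcell:::tlk_lethality_integrals(states$L1_0, states$L2_0,
                                            lam1, lam2, p$eta_per_h, 24, 0.005)
  finals <- tlk_final(states, p, T_h = 24, dt_h = 0.005)
  recon <- p$beta1 * ints[, 1] + p$beta2 * ints[, 2] +
    p$lethal_pair_frac * p$eta_per_h * ints[, 3]
  expect_equal(finals$L_lethal_T, recon, tolerance = 1e-12)
})
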