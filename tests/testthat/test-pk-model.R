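test_that("zero input from a drug-naive state stays at zero", {
  times <- c(30, 240, 1440, 2880)
  conc <- simulate_dynamic(function(t) 0, pk_default, times)
  expect_equal(conc, rep(0, 4), tolerance = 1e-12)
})

test_that("negative input and bad time grids are rejected", {
  expect_error(simulate_dynamic(function(t) -0.1, pk_default, c(10, 20)),
               "negative input")
  expect_error(simulate_dynamic(function(t) 0.1, pk_default, c(20, 10)),
               "strictly increasing")
  expect_error(simulate_dynamic(function(t) 0.1, pk_default, c(10, 20),
                                initial = c(-1, 0, 0)),
               "non-negative")
})

test_that("with binding off the model matches the linear matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  p <- pk_parameters(k_on = 0)
  Vc <- p$V_c / 1000
  u0 <- 0.08
  # constant infusion into the 2-state linear system dx/dt = A x + b
  A <- matrix(c(-(p$k_el + p$k_pt), p$k_tp / Vc,
                p$k_pt * Vc, -p$k_tp), 2, 2, byrow = TRUE)
  b <- c(u0 / Vc, 0)
  oracle <- function(t) {
    E <- as.matrix(Matrix::expm(A * t))
    drop(solve(A, (E - diag(2)) %*% b))[1]
  }
  times <- c(5, 30, 120, 720, 2880)
  conc <- simulate_dynamic(function(t) u0, p, times,
                           rtol = 1e-10, atol = 1e-12)
  expect_equal(conc, vapply(times, oracle, numeric(1)),
               tolerance = 1e-6)
})

test_that("the algebraic steady state agrees with the stationarity root to 1e-10", {
  # A_T and RC are eliminated analytically at stationarity, leaving one
  # equation in C solved by uniroot as the independent oracle
  for (u in c(1e-4, 0.01, 0.05, 1, 50)) {
    root <- uniroot(function(C) u - invert_steady_state(C, pk_default),
                    c(0, 1e8), tol = 1e-15)$root
    expect_equal(steady_state_concentration(u, pk_default), root,
                 tolerance = 1e-10)
  }
  expect_equal(steady_state_concentration(0, pk_default), 0,
               tolerance = 1e-12)
  expect_error(steady_state_concentration(-1, pk_default),
               "non-negative")
})

test_that("steady-state concentration is strictly increasing and inverts cleanly", {
  u <- seq(0, 2, length.out = 100)
  cc <- steady_state_concentration(u, pk_default)
  expect_true(all(diff(cc) > 0))
  # round trip C -> u -> C
  conc <- c(0.1, 1, 25, 300, 5000)
  back <- steady_state_concentration(invert_steady_state(conc, pk_default),
                                     pk_default)
  expect_equal(back, conc, tolerance = 1e-10)
})

test_that("constant infusion converges to the algebraic steady state", {
  u0 <- 0.05
  t_inf <- 50 / pk_default$k_el
  conc <- simulate_dynamic(function(t) u0, pk_default, c(t_inf / 2, t_inf))
  expect_equal(conc[2], steady_state_concentration(u0, pk_default),
               tolerance = 1e-6)
})

test_that("cumulative input is fully accounted for by pools plus elimination", {
  u_fn <- function(t) test_input(t, tip_default)
  mb <- check_mass_balance(u_fn, pk_default, 2880)
  expect_equal(mb$accounted, mb$input, tolerance = 1e-6)
  # also over a long horizon where most of the dose has transited
  mb2 <- check_mass_balance(function(t) 0.05 * exp(-t / 2e4),
                            pk_default, 1e5)
  expect_equal(mb2$accounted, mb2$input, tolerance = 1e-6)
})

test_that("the receptor complex stays within [0, R_tot]", {
  out <- simulate_dynamic(function(t) 50, pk_default,
                          seq(10, 5e4, length.out = 60),
                          full_state = TRUE)
  expect_true(all(out$RC >= -1e-8))
  expect_true(all(out$RC <= pk_default$R_tot + 1e-8))
  expect_true(all(out$C >= 0) && all(out$A_T >= 0))
})

test_that("forward sensitivities match central finite differences", {
  b <- build_kl_basis(28.8, 2880, N = 200, m = 20)
  set.seed(42)
  cc <- input_coefficients(c(log(0.09) / b$B[1, 1], rnorm(19) * 0.5))
  times <- sampling_schedule("short", "sparse")$times
  sim <- simulate_with_sensitivities(b, cc, pk_default, times,
                                     rtol = 1e-11, atol = 1e-13)
  jpick <- c(1, 2, 3, 5, 8, 11, 14, 17, 20)
  J_fd <- sapply(jpick, function(j) {
    h <- 1e-4 * max(abs(cc$c[j]), 1)
    up <- cc; up$c[j] <- cc$c[j] + h
    dn <- cc; dn$c[j] <- cc$c[j] - h
    (simulate_dynamic(list(basis = b, coeffs = up), pk_default, times,
                      rtol = 1e-11, atol = 1e-13) -
     simulate_dynamic(list(basis = b, coeffs = dn), pk_default, times,
                      rtol = 1e-11, atol = 1e-13)) / (2 * h)
  })
  expect_lt(max(abs(sim$jac[, jpick] - J_fd)) / max(abs(J_fd)), 1e-4)
})

test_that("sensitivity to the constant coefficient reduces to B1 * C for a linear model", {
  # with k_on = 0 the model is linear, so scaling u scales C; in the log
  # domain dC/dc1 = B1 * C exactly
  p <- pk_parameters(k_on = 0)
  b <- basis_small
  cc <- input_coefficients(c(log(0.05) / b$B[1, 1], rep(0, 9)))
  times <- c(60, 600, 2000, 2880)
  sim <- simulate_with_sensitivities(b, cc, p, times,
                                     rtol = 1e-10, atol = 1e-12)
  expect_equal(sim$jac[, 1], b$B[1, 1] * sim$conc, tolerance = 1e-6)
})
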