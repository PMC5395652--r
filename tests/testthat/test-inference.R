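test_that("proportional-error log-likelihood matches its closed form", {
  f <- c(2, 10, 40)
  g <- noise_model("gaussian", sigma = 0.1)
  expect_equal(log_likelihood(f, f, g),
               sum(-0.5 * log(2 * pi) - log(0.1 * f)))
  # symmetry of the residual in both families
  for (nm in list(g, noise_model("student_t", 0.1, 4))) {
    up <- log_likelihood(f * 1.07, f, nm)
    dn <- log_likelihood(f * 0.93, f, nm)
    expect_equal(up, dn, tolerance = 1e-12)
  }
  # permutation invariance
  set.seed(2); idx <- sample(3)
  y <- f * (1 + 0.1 * c(-0.5, 1, 0.2))
  expect_equal(log_likelihood(y[idx], f[idx], g),
               log_likelihood(y, f, g))
})

test_that("a heavy outlier is less penalized under the t(4) likelihood", {
  f <- c(10, 20, 30)
  y <- f; y[2] <- f[2] * (1 + 0.1 * 5)   # 5-sigma-equivalent residual
  lt <- log_likelihood(y, f, noise_model("student_t", 0.1, 4))
  lg <- log_likelihood(y, f, noise_model("gaussian", 0.1))
  expect_gt(lt, lg)
  # and pointwise at the outlier itself
  expect_gt(dt(5, df = 4, log = TRUE), dnorm(5, log = TRUE))
})

test_that("non-positive predictions invalidate the likelihood with a flag", {
  ll <- log_likelihood(c(1, 2), c(1, -0.5), noise_model("gaussian", 0.1))
  expect_identical(unname(as.numeric(ll)), -Inf)
  expect_true(attr(ll, "bad_prediction"))
})

test_that("posterior gradient matches finite differences in steady-state mode", {
  ds <- quick_long$dataset
  b <- quick_long$basis
  nm <- noise_model("student_t", 0.1, 4)
  set.seed(5)
  cc <- input_coefficients(
    c(log(invert_steady_state(median(ds$conc), pk_default)) / b$B[1, 1],
      rnorm(11) * 0.4), lam = 30)
  lp <- log_posterior_and_gradient(ds, b, cc, pk_default, nm,
                                   mode = "steady_state")
  g_fd <- vapply(seq_along(cc$c), function(j) {
    h <- 1e-6 * max(abs(cc$c[j]), 1)
    up <- cc; up$c[j] <- cc$c[j] + h
    dn <- cc; dn$c[j] <- cc$c[j] - h
    (log_posterior_and_gradient(ds, b, up, pk_default, nm,
                                mode = "steady_state")$value -
     log_posterior_and_gradient(ds, b, dn, pk_default, nm,
                                mode = "steady_state")$value) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(lp$grad - g_fd)) / max(abs(g_fd)), 1e-4)
})

test_that("posterior gradient matches finite differences in dynamic mode", {
  sched <- sampling_schedule("short", "sparse")
  ds <- generate_dataset(tip_default, sched, pk_default, noise = NULL,
                         seed = 12)
  b <- basis_small
  nm <- noise_model("student_t", 0.1, 4)
  set.seed(6)
  cc <- input_coefficients(c(log(0.08) / b$B[1, 1], rnorm(9) * 0.3),
                           lam = 10)
  lp <- log_posterior_and_gradient(ds, b, cc, pk_default, nm,
                                   mode = "dynamic")
  jpick <- c(1, 2, 5, 10)
  g_fd <- vapply(jpick, function(j) {
    h <- 1e-5 * max(abs(cc$c[j]), 1)
    up <- cc; up$c[j] <- cc$c[j] + h
    dn <- cc; dn$c[j] <- cc$c[j] - h
    (log_posterior_and_gradient(ds, b, up, pk_default, nm,
                                mode = "dynamic")$value -
     log_posterior_and_gradient(ds, b, dn, pk_default, nm,
                                mode = "dynamic")$value) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(lp$grad[jpick] - g_fd)) / max(abs(g_fd)), 1e-3)
})

test_that("the SMMALA metric is symmetric positive definite", {
  ds <- quick_long$dataset
  b <- quick_long$basis
  nm <- noise_model("student_t", 0.1, 4)
  set.seed(7)
  for (k in 1:5) {
    cc <- input_coefficients(
      c(log(0.03) / b$B[1, 1], rnorm(11) * 0.5), lam = runif(1, 1, 1e4))
    G <- log_posterior_and_gradient(ds, b, cc, pk_default, nm,
                                    mode = "steady_state")$G
    expect_equal(G, t(G), tolerance = 1e-10)
    expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
              0)
  }
})

test_that("steady-state and dynamic predictions agree on long but not short timescales", {
  # slow input on a weekly grid: discrepancy of the order of 1%
  expect_lt(steady_state_discrepancy(pk_default, tip_default), 3)
  # constant input over the first hours: the dynamic system is far from
  # its steady state early on
  b <- basis_small
  cc <- input_coefficients(c(log(0.1) / b$B[1, 1], rep(0, 9)))
  ds <- er_dataset(c(30, 60, 240, 2880), rep(1, 4), timescale = "short")
  dyn <- predict_concentration(ds, b, cc, pk_default, mode = "dynamic")
  ss <- suppressWarnings(
    predict_concentration(ds, b, cc, pk_default, mode = "steady_state"))
  expect_gt(max(abs(dyn - ss) / ss), 0.10)
  expect_warning(
    predict_concentration(ds, b, cc, pk_default, mode = "steady_state"),
    "short")
})

test_that("steady-state posterior evaluation is much cheaper than dynamic", {
  sched <- sampling_schedule("long", "dense")
  ds <- generate_dataset(tip_default, sched, pk_default, noise = NULL,
                         seed = 31)
  b <- build_kl_basis(min(ds$times), max(ds$times), N = 200, m = 20)
  nm <- noise_model("student_t", 0.1, 4)
  cc <- input_coefficients(
    c(log(invert_steady_state(median(ds$conc), pk_default)) / b$B[1, 1],
      rep(0, 19)), lam = 10)
  t_dyn <- system.time(
    log_posterior_and_gradient(ds, b, cc, pk_default, nm,
                               mode = "dynamic"))[3]
  t_ss <- system.time(
    for (i in 1:20) log_posterior_and_gradient(ds, b, cc, pk_default, nm,
                                               mode = "steady_state"))[3]
  expect_gt(t_dyn / (t_ss / 20), 10)
})
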