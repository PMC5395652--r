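# posterior callbacks for an analytic Gaussian target N(mu, Sigma),
# Sigma^{-1} = P: value/grad exact, metric = P (constant)
gaussian_target <- function(mu, P) {
  function(cvec) {
    r <- cvec - mu
    list(value = -0.5 * drop(r %*% P %*% r),
         grad = -drop(P %*% r),
         G = P)
  }
}

run_smmala <- function(target, c0, eps, n, seed = 1) {
  set.seed(seed)
  state <- smmala_state(c0, target)
  draws <- matrix(NA_real_, n, length(c0))
  acc <- 0L
  for (i in seq_len(n)) {
    st <- smmala_step(state, target, eps)
    state <- st$state
    acc <- acc + st$accepted
    draws[i, ] <- state$c
  }
  list(draws = draws, acc = acc / n)
}

test_that("SMMALA recovers the moments of a standard Gaussian target", {
  m <- 3
  target <- gaussian_target(rep(0, m), diag(m))
  out <- run_smmala(target, rep(2, m), eps = 1.4, n = 50000, seed = 4)
  keep <- out$draws[-(1:2000), ]
  # conservative MC standard error using an effective sample size that
  # discounts autocorrelation
  for (j in 1:m) {
    rho <- acf(keep[, j], lag.max = 1, plot = FALSE)$acf[2]
    neff <- nrow(keep) * (1 - rho) / (1 + rho)
    expect_lt(abs(mean(keep[, j])), 3 / sqrt(neff))
  }
  expect_equal(unname(diag(cov(keep))), rep(1, m), tolerance = 0.05)
  expect_lt(max(abs(cov(keep)[upper.tri(diag(m))])), 0.05)
})

test_that("acceptance approaches one as the step size vanishes", {
  target <- gaussian_target(rep(0, 2), diag(2))
  out <- run_smmala(target, c(0.3, -0.2), eps = 1e-4, n = 300, seed = 9)
  expect_equal(out$acc, 1)
})

test_that("chains replay identically under the same seed", {
  target <- gaussian_target(rep(0, 4), diag(4))
  a <- run_smmala(target, rep(1, 4), eps = 1, n = 500, seed = 123)
  b <- run_smmala(target, rep(1, 4), eps = 1, n = 500, seed = 123)
  expect_identical(a$draws, b$draws)

  cfg <- sampler_config(n_samples = 300, seed = 77)
  s1 <- run_mcmc(quick_long$dataset, quick_long$basis, pk_default,
                 noise_model("student_t", 0.1, 4), cfg)
  s2 <- run_mcmc(quick_long$dataset, quick_long$basis, pk_default,
                 noise_model("student_t", 0.1, 4), cfg)
  expect_identical(s1$C_samples, s2$C_samples)
  expect_identical(s1$lam_samples, s2$lam_samples)
})

test_that("SMMALA with a correlated metric matches the conjugate analytic posterior", {
  # linear-Gaussian model: y = X c + eps, known noise and prior precision;
  # posterior is N((X'X/s2 + P0)^{-1} X'y/s2, (X'X/s2 + P0)^{-1})
  set.seed(15)
  n <- 40; m <- 4; s2 <- 0.25
  X <- matrix(rnorm(n * m), n, m)
  ctrue <- c(1, -0.5, 0.2, 0)
  y <- drop(X %*% ctrue) + rnorm(n, sd = sqrt(s2))
  P0 <- diag(c(0.5, 1, 2, 4))
  Ppost <- crossprod(X) / s2 + P0
  mupost <- drop(solve(Ppost, crossprod(X, y) / s2))
  target <- function(cvec) {
    r <- y - drop(X %*% cvec)
    list(value = -0.5 * sum(r^2) / s2 -
           0.5 * drop(cvec %*% P0 %*% cvec),
         grad = drop(crossprod(X, r)) / s2 - drop(P0 %*% cvec),
         G = Ppost)
  }
  out <- run_smmala(target, rep(0, m), eps = 1.3, n = 40000, seed = 5)
  keep <- out$draws[-(1:2000), ]
  Sig <- solve(Ppost)
  for (j in 1:m) {
    rho <- acf(keep[, j], lag.max = 1, plot = FALSE)$acf[2]
    neff <- nrow(keep) * (1 - rho) / (1 + rho)
    expect_lt(abs(mean(keep[, j]) - mupost[j]),
              3 * sqrt(Sig[j, j] / neff))
  }
  expect_equal(cov(keep), Sig, tolerance = 0.1)
})

test_that("the Gibbs conditional for lambda is the analytic Gamma", {
  b <- basis_small
  m <- ncol(b$B); r <- m - 2
  # null-space-only coefficients: conditional is Gamma(alpha + r/2, beta)
  set.seed(33)
  d0 <- replicate(5000, gibbs_update_lambda(c(5, -2, rep(0, m - 2)), b,
                                            alpha = 2, beta = 3))
  expect_equal(mean(d0), (2 + r / 2) / 3, tolerance = 0.03)

  # generic coefficients: mean and full distribution
  set.seed(34)
  cc <- rnorm(m) * 2
  pen <- sum(b$d[3:m] * cc[3:m]^2)
  draws <- replicate(10000, gibbs_update_lambda(cc, b,
                                                alpha = 1e-3,
                                                beta = 1e-3))
  shape <- 1e-3 + r / 2
  rate <- 1e-3 + pen / 2
  expect_equal(mean(draws), shape / rate, tolerance = 0.02)
  ks <- suppressWarnings(
    ks.test(draws, "pgamma", shape = shape, rate = rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("a likelihood-free chain samples the smoothness prior", {
  # two-block Gibbs on the joint prior: exact conditional draw of the
  # penalized coefficients c | lambda ~ N(0, (lambda d)^-1) alternated
  # with the package's lambda update; at equilibrium the sampled
  # second-derivative energy satisfies E[lambda * sum d_j c_j^2] = r
  b <- basis_small
  m <- ncol(b$B); r <- m - 2
  set.seed(55)
  lam <- 1
  vals <- numeric(6000)
  cvec <- rep(0, m)
  for (i in seq_along(vals)) {
    cvec[3:m] <- rnorm(r) / sqrt(lam * b$d[3:m])
    lam <- gibbs_update_lambda(cvec, b, alpha = 2, beta = 2)
    vals[i] <- lam * sum(b$d[3:m] * cvec[3:m]^2)
  }
  expect_equal(mean(vals[-(1:500)]), r, tolerance = 0.10)
})

test_that("t(4) inference resists a gross outlier better than Gaussian", {
  ds <- quick_long$dataset
  conc <- ds$conc
  conc[4] <- conc[4] * 3       # one gross outlier
  ds_out <- er_dataset(ds$times, conc, timescale = "long",
                       dose_mg = ds$dose_mg)
  b <- quick_long$basis
  truth <- function(t) test_input(t, tip_default)
  cfg <- sampler_config(n_samples = 1500, seed = 10)
  s_t <- run_mcmc(ds_out, b, pk_default,
                  noise_model("student_t", 0.1, 4), cfg)
  s_g <- run_mcmc(ds_out, b, pk_default,
                  noise_model("gaussian", 0.1), cfg)
  rmse_t <- rmse_vs_truth(s_t, b, truth, "pmol_per_week")
  rmse_g <- rmse_vs_truth(s_g, b, truth, "pmol_per_week")
  expect_lt(rmse_t, rmse_g)
})

test_that("Raftery-Lewis reproduces the iid floor and flags degeneracy", {
  expect_error(raftery_lewis(rnorm(100), q = 0.025, r = 0.02, s = 0.95),
               "too short")

  set.seed(61)
  iid <- rnorm(20000)
  res <- raftery_lewis(iid, q = 0.025, r = 0.02, s = 0.95)
  # closed-form iid floor ceil(qnorm(0.975)^2 q (1-q) / r^2)
  expect_equal(res$N_min, 235)
  expect_lt(abs(res$N - res$N_min) / res$N_min, 0.20)

  const <- rep(1, 20000)
  res2 <- raftery_lewis(const, q = 0.025, r = 0.02, s = 0.95)
  expect_true(is.na(res2$N))
})

test_that("run_mcmc output obeys its structural contract", {
  cfg <- sampler_config(n_samples = 400, burn_in = 0.25, seed = 3)
  s <- run_mcmc(quick_long$dataset, quick_long$basis, pk_default,
                noise_model("student_t", 0.1, 4), cfg)
  expect_equal(nrow(s$C_samples), 300)
  expect_equal(length(s$lam_samples), 300)
  expect_true(all(s$lam_samples > 0))
  expect_identical(s$mode, "steady_state")
  expect_gt(s$acceptance, 0.01)
})
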