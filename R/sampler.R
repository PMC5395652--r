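#' MCMC sampler configuration
#'
#' @param n_samples total chain length (default 10000)
#' @param burn_in burn-in fraction in (0, 1), discarded (default 0.2)
#' @param eps initial SMMALA step size; adapted during burn-in toward an
#'   acceptance rate in `target_acc`, frozen afterwards to preserve
#'   detailed balance
#' @param target_acc acceptance-rate window for step-size adaptation
#' @param alpha,beta Gamma hyperprior on the regularization parameter
#'   (default 1e-3, 1e-3)
#' @param seed RNG seed, recorded with the samples
#' @param mode prediction mode passed to the likelihood ("auto":
#'   steady-state for long timescales, dynamic for short)
#' @return object of class `sampler_config`
#' @export
sampler_config <- function(n_samples = 10000, burn_in = 0.2, eps = 0.5,
                           target_acc = c(0.5, 0.7),
                           alpha = 1e-3, beta = 1e-3, seed = 1,
                           mode = "auto") {
  if (n_samples <= 0) stop("n_samples must be positive")
  if (burn_in <= 0 || burn_in >= 1) stop("burn_in must be in (0, 1)")
  structure(list(n_samples = as.integer(n_samples), burn_in = burn_in,
                 eps = eps, target_acc = target_acc, alpha = alpha,
                 beta = beta, seed = as.integer(seed), mode = mode),
            class = "sampler_config")
}

#' Initialize SMMALA state at a coefficient vector
#'
#' @param c coefficient vector
#' @param posterior function(c) returning a list with `value`, `grad`,
#'   `G` (positive-definite metric), and optionally extra cached parts
#' @return state list usable with [smmala_step()]
#' @export
smmala_state <- function(c, posterior) {
  p <- posterior(c)
  if (!is.finite(p$value)) stop("posterior not finite at the start point")
  c(list(c = c), p, list(R = robust_chol(p$G)))
}

# upper-triangular Cholesky with escalating jitter; NULL if hopeless
robust_chol <- function(G) {
  scale <- mean(diag(G))
  for (j in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    R <- tryCatch(chol(G + diag(j * scale, nrow(G))),
                  error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  NULL
}

#' One SMMALA update
#'
#' Proposal N(c + (eps^2/2) G^{-1} grad, eps^2 G^{-1}) with the full
#' Metropolis-Hastings correction using the position-dependent proposal
#' densities on both sides.
#'
#' @param state from [smmala_state()]
#' @param posterior as in [smmala_state()]
#' @param eps step size
#' @return list(state, accepted)
#' @export
smmala_step <- function(state, posterior, eps) {
  m <- length(state$c)
  R <- state$R
  if (is.null(R)) return(list(state = state, accepted = FALSE))
  mu <- state$c + (eps^2 / 2) * chol_solve(R, state$grad)
  prop <- mu + eps * backsolve(R, rnorm(m))

  p2 <- posterior(prop)
  if (!is.finite(p2$value)) return(list(state = state, accepted = FALSE))
  R2 <- robust_chol(p2$G)
  if (is.null(R2)) return(list(state = state, accepted = FALSE))
  mu2 <- prop + (eps^2 / 2) * chol_solve(R2, p2$grad)

  lq_fwd <- smmala_lq(prop, mu, R, eps)
  lq_rev <- smmala_lq(state$c, mu2, R2, eps)
  log_a <- p2$value - state$value + lq_rev - lq_fwd
  if (is.finite(log_a) && log(runif(1)) < log_a) {
    list(state = c(list(c = prop), p2, list(R = R2)), accepted = TRUE)
  } else {
    list(state = state, accepted = FALSE)
  }
}

chol_solve <- function(R, b) backsolve(R, backsolve(R, b, transpose = TRUE))

# log N(x | mu, eps^2 G^{-1}) up to the dimension constant, G = R'R
smmala_lq <- function(x, mu, R, eps) {
  d <- R %*% (x - mu)
  -sum(d^2) / (2 * eps^2) + sum(log(diag(R))) - length(x) * log(eps)
}

#' Gibbs update of the regularization parameter
#'
#' The Gamma(alpha, beta) hyperprior is conjugate to the Gaussian
#' smoothness prior: lambda | c ~ Gamma(alpha + r/2,
#' beta + sum_j d_j c_j^2 / 2) over the r penalized coefficients.
#'
#' @param c coefficient vector
#' @param basis [build_kl_basis()]
#' @param alpha,beta hyperprior parameters
#' @return one draw of lambda
#' @export
gibbs_update_lambda <- function(c, basis, alpha = 1e-3, beta = 1e-3) {
  r <- length(basis$d) - basis$n_null
  rgamma(1, shape = alpha + r / 2,
         rate = beta + penalty_energy(c, basis) / 2)
}

#' Sample the posterior over input coefficients and lambda
#'
#' Alternates one SMMALA update of the basis coefficients with one Gibbs
#' update of the regularization parameter.  The step size adapts during
#' burn-in toward the configured acceptance window and is frozen
#' afterwards.  Initialization: constant input u0 obtained by inverting
#' the steady-state relation at the median observed concentration (long
#' timescale) or from a dose-scaled heuristic (short timescale).
#'
#' @param dataset [er_dataset()]
#' @param basis [build_kl_basis()]
#' @param params [pk_parameters()]
#' @param noise [noise_model()]
#' @param config [sampler_config()]
#' @return object of class `posterior_samples`: list with `C_samples`
#'   (kept draws x m), `lam_samples`, `acceptance`, `eps`, `seed`,
#'   `mode`, `basis`, and `raftery_lewis` (diagnostic on the kept
#'   chains)
#' @export
run_mcmc <- function(dataset, basis, params = pk_parameters(),
                     noise = noise_model(), config = sampler_config()) {
  set.seed(config$seed)
  mode <- resolve_mode(config$mode, dataset)
  lik <- make_loglik_parts(dataset, basis, params, noise, mode)
  m <- length(basis$d)

  c0 <- init_coefficients(dataset, basis, params)
  # warm start from the Gaussian-likelihood mode: the quadratic score
  # pulls globally even when the start misfits every point, where the
  # redescending t score would plateau (the usual least-squares start
  # of robust fitting)
  lik_warm <- if (noise$family == "gaussian") lik else
    make_loglik_parts(dataset, basis, params,
                      noise_model("gaussian", sigma = noise$sigma),
                      mode)
  warm <- map_warmup(lik_warm, c0, basis, config$alpha, config$beta)
  if (noise$family != "gaussian")   # polish at the target likelihood
    warm <- map_warmup(lik, warm$c, basis, config$alpha, config$beta,
                       lam0 = warm$lam)
  c0 <- warm$c
  lam <- warm$lam
  posterior <- function(cvec)
    assemble_posterior(lik(cvec), cvec, lam, basis,
                       config$alpha, config$beta)
  state <- smmala_state(c0, posterior)
  if (is.null(state$R))
    state$R <- chol(diag(pmax(lam * basis$d, 1e-6), m))

  n <- config$n_samples
  n_burn <- floor(n * config$burn_in)
  eps <- config$eps
  keep_C <- matrix(NA_real_, n - n_burn, m)
  keep_lam <- numeric(n - n_burn)
  acc_window <- 0L; acc_total <- 0L
  window <- 50L

  for (i in seq_len(n)) {
    step <- smmala_step(state, posterior, eps)
    state <- step$state
    if (step$accepted) {
      acc_window <- acc_window + 1L
      if (i > n_burn) acc_total <- acc_total + 1L
    }
    # Gibbs lambda, then refresh cached posterior parts at the new lambda
    lam <- gibbs_update_lambda(state$c, basis, config$alpha, config$beta)
    state <- c(list(c = state$c),
               assemble_posterior(state$parts, state$c, lam, basis,
                                  config$alpha, config$beta),
               list(R = NULL))
    state$R <- robust_chol(state$G)
    if (is.null(state$R)) {
      # fall back to the prior-precision metric so the chain can move
      state$R <- chol(diag(pmax(lam * basis$d, 1e-6), m))
    }

    if (i <= n_burn && i %% window == 0L) {
      rate <- acc_window / window
      if (rate > config$target_acc[2]) eps <- eps * 1.25
      else if (rate < 0.2) eps <- eps * 0.5
      else if (rate < config$target_acc[1]) eps <- eps * 0.8
      acc_window <- 0L
    }
    if (i > n_burn) {
      keep_C[i - n_burn, ] <- state$c
      keep_lam[i - n_burn] <- lam
    }
  }
  acceptance <- acc_total / (n - n_burn)
  if (acceptance < 0.01)
    stop("chain rejected essentially all proposals (acceptance ",
         signif(100 * acceptance, 2), "%); check step size and metric")

  rl <- tryCatch(raftery_lewis(keep_lam), error = function(e) NULL)
  structure(list(C_samples = keep_C, lam_samples = keep_lam,
                 acceptance = acceptance, eps = eps,
                 seed = config$seed, mode = mode, basis = basis,
                 raftery_lewis = rl),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(
    "<posterior_samples> %d kept draws x %d coefficients (%s mode)\n",
    nrow(x$C_samples), ncol(x$C_samples), x$mode))
  cat(sprintf("  acceptance %.2f, step size %.3g, lambda median %.3g\n",
              x$acceptance, x$eps, median(x$lam_samples)))
  invisible(x)
}

# Gauss-Newton ascent to the joint mode before sampling: Newton steps
# G^{-1} grad with backtracking on the coefficients, alternated with the
# conditional-mean update of lambda.  Starting the chain near the mode
# matters particularly for the heavy-tailed likelihood, whose score
# nearly vanishes when every observation is a gross outlier (a flat
# start far from the data is exactly such a plateau).
map_warmup <- function(lik, c0, basis, alpha = 1e-3, beta = 1e-3,
                       lam0 = 1, n_outer = 30, n_inner = 5) {
  r <- length(basis$d) - basis$n_null
  lam <- lam0
  cvec <- c0
  post <- assemble_posterior(lik(cvec), cvec, lam, basis, alpha, beta)
  if (!is.finite(post$value)) return(list(c = c0, lam = lam))
  for (outer in seq_len(n_outer)) {
    moved <- FALSE
    for (inner in seq_len(n_inner)) {
      R <- robust_chol(post$G)
      if (is.null(R)) break
      dir <- chol_solve(R, post$grad)
      step <- 1
      improved <- FALSE
      while (step >= 1e-4) {
        cand <- cvec + step * dir
        cp <- assemble_posterior(lik(cand), cand, lam, basis,
                                 alpha, beta)
        if (is.finite(cp$value) && cp$value > post$value + 1e-10) {
          cvec <- cand; post <- cp; improved <- TRUE; moved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!improved) break
    }
    lam_new <- (alpha + r / 2) /
      (beta + penalty_energy(cvec, basis) / 2)
    if (!is.finite(lam_new) || lam_new <= 0) break
    converged <- abs(log(lam_new / lam)) < 1e-3 && !moved
    lam <- lam_new
    post <- assemble_posterior(post$parts, cvec, lam, basis,
                               alpha, beta)
    if (converged) break
  }
  # final polish of c at the settled lambda so the chain starts at a
  # point whose gradient is essentially zero under its own metric
  for (inner in seq_len(n_inner)) {
    R <- robust_chol(post$G)
    if (is.null(R)) break
    dir <- chol_solve(R, post$grad)
    step <- 1
    improved <- FALSE
    while (step >= 1e-4) {
      cand <- cvec + step * dir
      cp <- assemble_posterior(lik(cand), cand, lam, basis, alpha, beta)
      if (is.finite(cp$value) && cp$value > post$value + 1e-10) {
        cvec <- cand; post <- cp; improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
  }
  list(c = cvec, lam = lam)
}

init_coefficients <- function(dataset, basis, params) {
  u0 <- if (dataset$timescale == "long" || is.na(dataset$dose_mg)) {
    invert_steady_state(median(dataset$conc), params)
  } else {
    # ~1% of the dose absorbed over the short window, spread uniformly
    0.01 * dose_pmol(dataset$dose_mg) / dataset$bodyweight_kg /
      max(dataset$times)
  }
  c0 <- numeric(length(basis$d))
  c0[1] <- log(max(u0, 1e-12)) / basis$B[1, 1]
  c0
}

#' Raftery-Lewis chain-length diagnostic
#'
#' Two-state Markov-chain diagnostic: for each quantile q, the chain is
#' reduced to the indicator of falling below the empirical q-quantile,
#' thinned until first-order Markov dependence is adequate (BIC
#' comparison against a second-order chain), and the thinned chain's
#' transition probabilities give the burn-in and the number of
#' iterations N required to estimate q to within +/- r with probability
#' s.  Also reports the iid floor N_min.
#'
#' @param chain numeric vector of MCMC draws
#' @param q quantiles of interest
#' @param r required precisions (same length as q)
#' @param s coverage probability
#' @return data.frame with columns q, r, s, thin, burn_in, N, N_min,
#'   dependence_factor; attribute `N_required` holds max(N)
#' @export
raftery_lewis <- function(chain,
                          q = c(0.025, 0.25, 0.5, 0.75, 0.975),
                          r = c(0.02, 0.05, 0.06, 0.05, 0.02),
                          s = 0.95) {
  stopifnot(length(q) == length(r))
  phi <- qnorm((1 + s) / 2)
  nmin <- ceiling(phi^2 * q * (1 - q) / r^2)
  if (length(chain) < max(nmin))
    stop("chain too short for the Raftery-Lewis pilot estimate: need ",
         max(nmin), " draws, have ", length(chain))
  rows <- lapply(seq_along(q), function(i)
    rl_single(chain, q[i], r[i], s, phi))
  out <- do.call(rbind, rows)
  attr(out, "N_required") <- suppressWarnings(max(out$N, na.rm = TRUE))
  out
}

rl_single <- function(chain, q, r, s, phi) {
  nmin <- ceiling(phi^2 * q * (1 - q) / r^2)
  z <- as.integer(chain <= quantile(chain, q, names = FALSE))
  if (length(unique(z)) < 2)   # degenerate indicator (constant chain)
    return(data.frame(q = q, r = r, s = s, thin = NA, burn_in = NA,
                      N = NA, N_min = nmin, dependence_factor = NA))
  thin <- 1L
  repeat {
    zt <- z[seq(1L, length(z), by = thin)]
    if (length(zt) < 50 || rl_bic(zt) <= 0) break
    thin <- thin + 1L
  }
  zt <- z[seq(1L, length(z), by = thin)]
  n01 <- sum(zt[-length(zt)] == 0 & zt[-1] == 1)
  n0 <- sum(zt[-length(zt)] == 0)
  n10 <- sum(zt[-length(zt)] == 1 & zt[-1] == 0)
  n1 <- sum(zt[-length(zt)] == 1)
  a <- n01 / max(n0, 1); b <- n10 / max(n1, 1)
  if (a <= 0 || b <= 0 || a + b >= 2)
    return(data.frame(q = q, r = r, s = s, thin = thin, burn_in = NA,
                      N = NA, N_min = nmin, dependence_factor = NA))
  eps0 <- 1e-3
  burn <- ceiling(log(eps0 * (a + b) / max(a, b)) /
                    log(abs(1 - a - b))) * thin
  N <- ceiling((2 - a - b) * a * b / (a + b)^3 * (phi / r)^2) * thin
  data.frame(q = q, r = r, s = s, thin = thin, burn_in = max(burn, 0),
             N = N, N_min = nmin, dependence_factor = N / nmin)
}

# BIC of second-order vs first-order Markov dependence of a binary
# chain: positive values favor the second-order model (more thinning
# needed)
rl_bic <- function(z) {
  n <- length(z) - 2L
  tab <- table(factor(z[1:n], 0:1), factor(z[2:(n + 1)], 0:1),
               factor(z[3:(n + 2)], 0:1))
  g2 <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    o <- tab[i, j, k]
    if (o > 0) {
      e <- sum(tab[i, j, ]) * sum(tab[, j, k]) / max(sum(tab[, j, ]), 1)
      g2 <- g2 + 2 * o * log(o / e)
    }
  }
  g2 - 2 * log(n)
}
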