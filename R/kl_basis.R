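#' Karhunen-Loeve basis for the log-domain input function
#'
#' Discretizes the unknown log-input on a uniform grid of `N` nodes and
#' builds the m-function basis associated with a squared-second-derivative
#' smoothness penalty: the discrete penalty matrix
#' \eqn{K = D_2^T D_2 / \Delta s^3} (which discretizes
#' \eqn{\int (v'')^2 ds} on the span-normalized time s in [0, 1]) is
#' eigendecomposed; the basis consists of an
#' orthonormalized null space (constant and linear functions, zero
#' penalty) followed by the eigenvectors of smallest positive penalty
#' eigenvalue.  Truncating at `m` functions keeps the estimation problem
#' low-dimensional while retaining the smoothest directions, the
#' finite-dimensional analogue of a Karhunen-Loeve expansion of the
#' smoothness prior.
#'
#' @param t_min,t_end grid limits (minutes), `t_end > t_min >= 0`
#' @param N number of grid nodes (default 200)
#' @param m number of basis functions (default 20)
#' @return object of class `kl_basis`: list with `grid` (length N),
#'   `B` (N x m, orthonormal columns), `d` (length m penalty eigenvalues,
#'   ascending, first `n_null` exactly zero), `n_null = 2`
#' @export
#' @examples
#' b <- build_kl_basis(0, 2880, N = 100, m = 10)
#' crossprod(b$B)[1:3, 1:3]  # identity
build_kl_basis <- function(t_min, t_end, N = 200, m = 20) {
  if (m > N) stop("m must not exceed N")
  if (m < 3) stop("need at least 3 basis functions")
  if (t_end <= t_min || t_min < 0) stop("require t_end > t_min >= 0")
  grid <- seq(t_min, t_end, length.out = N)

  # second-difference operator, (N-2) x N; the penalty discretizes
  # int (v'')^2 ds with time normalized to the unit interval, so the
  # regularization parameter lives on a comparable scale across
  # timescales and the Gamma hyperprior stays effectively scale-free
  ds <- 1 / (N - 1)
  D2 <- matrix(0, N - 2, N)
  for (i in seq_len(N - 2)) D2[i, i + 0:2] <- c(1, -2, 1)
  K <- crossprod(D2) / ds^3

  # exact null space (constant and linear), orthonormalized, and its
  # orthogonal complement; eigendecomposing the penalty deflated onto
  # the complement keeps the basis exactly orthogonal to the null space
  # even though the smallest positive eigenvalues are nearly degenerate
  Qfull <- qr.Q(qr(cbind(1, grid)), complete = TRUE)
  nullb <- Qfull[, 1:2, drop = FALSE]
  if (nullb[1, 1] < 0) nullb[, 1] <- -nullb[, 1]
  if (nullb[N, 2] < nullb[1, 2]) nullb[, 2] <- -nullb[, 2]
  Qc <- Qfull[, -(1:2), drop = FALSE]

  eig <- eigen(crossprod(Qc, K %*% Qc), symmetric = TRUE)
  ord <- order(eig$values)            # ascending
  vals <- eig$values[ord]
  vecs <- Qc %*% eig$vectors[, ord, drop = FALSE]

  smooth <- vecs[, seq_len(m - 2), drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(ncol(smooth))) {
    k <- which.max(abs(smooth[, j]))
    if (smooth[k, j] < 0) smooth[, j] <- -smooth[, j]
  }
  B <- cbind(nullb, smooth)
  d <- c(0, 0, vals[seq_len(m - 2)])
  structure(list(grid = grid, B = B, d = d, n_null = 2L, K = K),
            class = "kl_basis")
}

#' @export
print.kl_basis <- function(x, ...) {
  cat(sprintf(
    "Karhunen-Loeve input basis: %d functions on [%g, %g] min (%d nodes)\n",
    ncol(x$B), x$grid[1], x$grid[length(x$grid)], length(x$grid)))
  cat(sprintf("  penalty eigenvalues: %d null, range of rest [%.3g, %.3g]\n",
              x$n_null, min(x$d[-seq_len(x$n_null)]), max(x$d)))
  invisible(x)
}

#' Coefficient vector with regularization parameter
#'
#' @param c length-m numeric vector of log-domain basis coefficients
#' @param lam regularization parameter lambda (> 0): the precision of the
#'   smoothness prior, trading data fit against smoothness
#' @return object of class `input_coefficients`
#' @export
input_coefficients <- function(c, lam = 1) {
  if (lam <= 0) stop("lam must be positive")
  structure(list(c = as.numeric(c), lam = lam),
            class = "input_coefficients")
}

# basis rows at arbitrary times: linear interpolation between grid nodes,
# constant extrapolation outside (mirrors the compiled RHS)
basis_at <- function(basis, t) {
  N <- length(basis$grid)
  x <- (t - basis$grid[1]) / (basis$grid[2] - basis$grid[1])
  x <- pmin(pmax(x, 0), N - 1)
  i <- pmin(floor(x), N - 2)
  w <- x - i
  (1 - w) * basis$B[i + 1, , drop = FALSE] +
    w * basis$B[i + 2, , drop = FALSE]
}

#' Evaluate the reconstructed input function
#'
#' u(t) = exp(B(t) c): strictly positive by construction (the
#' non-negativity constraint is imposed by modeling in the log domain).
#'
#' @param basis [build_kl_basis()]
#' @param coeffs [input_coefficients()]
#' @param t evaluation times (minutes) within the basis support
#' @param extrapolate allow t outside `[t_min, t_end]` (constant
#'   extrapolation of the boundary node); default FALSE (error)
#' @return u(t), pmol/min/kg
#' @export
evaluate_input <- function(basis, coeffs, t, extrapolate = FALSE) {
  rng <- range(basis$grid)
  if (!extrapolate && (any(t < rng[1] - 1e-9) || any(t > rng[2] + 1e-9)))
    stop("t outside basis support [", rng[1], ", ", rng[2], "]")
  as.numeric(exp(basis_at(basis, t) %*% coeffs$c))
}

#' Log prior density of coefficients and regularization parameter
#'
#' The smoothness prior puts c_j ~ N(0, 1/(lambda d_j)) on the penalized
#' coefficients, an improper flat prior on the null-space (constant and
#' linear) coefficients, and a Gamma(alpha, beta) hyperprior on lambda.
#' Returns, up to an additive constant,
#' \deqn{(r/2)\log\lambda - (\lambda/2)\sum_{j>n_0} d_j c_j^2
#'       + (\alpha-1)\log\lambda - \beta\lambda}
#' with r the number of penalized coefficients.
#'
#' @param coeffs [input_coefficients()]
#' @param basis [build_kl_basis()]
#' @param alpha,beta Gamma hyperprior parameters (default 1e-3, 1e-3)
#' @return log density (scalar, up to constant)
#' @export
log_prior_density <- function(coeffs, basis, alpha = 1e-3, beta = 1e-3) {
  lam <- coeffs$lam
  if (lam <= 0) stop("lam must be positive")
  pen <- penalty_energy(coeffs$c, basis)
  r <- length(basis$d) - basis$n_null
  (r / 2) * log(lam) - (lam / 2) * pen + (alpha - 1) * log(lam) - beta * lam
}

# sum_{j > n_null} d_j c_j^2, the discrete second-derivative energy
penalty_energy <- function(c, basis) {
  j <- seq.int(basis$n_null + 1, length(basis$d))
  sum(basis$d[j] * c[j]^2)
}

#' Serialize / restore a basis to JSON
#'
#' @param basis [build_kl_basis()]
#' @param path output (input) file
#' @return `read_basis_json` returns a `kl_basis`
#' @export
write_basis_json <- function(basis, path) {
  jsonlite::write_json(
    list(grid = basis$grid, B = basis$B, d = basis$d,
         n_null = basis$n_null),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_basis_json
#' @export
read_basis_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(grid = x$grid, B = x$B, d = x$d,
                 n_null = as.integer(x$n_null)),
            class = "kl_basis")
}
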