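#' Simulate the TMDD system for an arbitrary absorption input
#'
#' Integrates the two-compartment TMDD model
#' \deqn{dC/dt = u/V_c - (k_{el}+k_{pt}) C + k_{tp} A_T/V_c
#'       - k_{on}(R_{tot}-RC) C + k_{off} RC}
#' \deqn{dA_T/dt = k_{pt} C V_c - k_{tp} A_T}
#' \deqn{dRC/dt = k_{on}(R_{tot}-RC) C - (k_{off}+k_{int}) RC}
#' with a stiff (lsoda) solver and returns the central concentration at
#' the requested times.
#'
#' @param input_fn the absorption rate u(t) in pmol/min/kg: either an R
#'   function of time (minutes), a [test_input_params()] object, or a
#'   list with elements `basis` ([build_kl_basis()]) and `coeffs`
#'   ([input_coefficients()]) for the log-domain basis representation
#' @param params [pk_parameters()]
#' @param times strictly increasing observation times (minutes, >= 0)
#' @param initial initial state `c(C, A_T, RC)`; default drug-naive
#'   `c(0, 0, 0)`
#' @param rtol,atol solver tolerances
#' @param full_state return all three states instead of C only
#' @return numeric vector C(t) in pM (or a data.frame of all states)
#' @export
#' @examples
#' p <- pk_parameters()
#' simulate_dynamic(function(t) 0.05 * exp(-t / 500), p, times = c(60, 120))
simulate_dynamic <- function(input_fn, params, times,
                             initial = c(0, 0, 0),
                             rtol = 1e-8, atol = 1e-10,
                             full_state = FALSE) {
  check_times(times)
  if (any(initial < 0)) stop("initial state must be non-negative")

  if (is.function(input_fn)) {
    fn <- function(t) {
      u <- input_fn(t)
      if (any(u < 0)) stop("negative input u(t) encountered at t = ",
                           t[which(u < 0)[1]])
      u
    }
    out <- solve_tmdd_r(fn, params, times, initial, rtol, atol)
  } else if (inherits(input_fn, "test_input_params")) {
    .Call(C_set_pk, pk_vector(params))
    .Call(C_set_input_test, test_input_vector(input_fn))
    out <- solve_tmdd_c(times, initial, rtol, atol)
  } else if (is.list(input_fn) && !is.null(input_fn$basis)) {
    .Call(C_set_pk, pk_vector(params))
    b <- input_fn$basis
    .Call(C_set_input_basis, b$grid[1], b$grid[2] - b$grid[1], b$B,
          as.numeric(input_fn$coeffs$c), FALSE)
    out <- solve_tmdd_c(times, initial, rtol, atol)
  } else {
    stop("unsupported input_fn")
  }
  if (full_state) out else out$C
}

#' Simulate with forward sensitivities to the basis coefficients
#'
#' Appends the forward-sensitivity system d(state)/dc_j to the TMDD ODEs
#' and integrates everything jointly, giving the Jacobian of the
#' predicted concentrations with respect to the log-domain basis
#' coefficients (needed by the SMMALA gradient and metric).
#'
#' @inheritParams simulate_dynamic
#' @param basis [build_kl_basis()]
#' @param coeffs [input_coefficients()]
#' @return list with `conc` (length n) and `jac` (n x m matrix
#'   dC(t_i)/dc_j)
#' @export
simulate_with_sensitivities <- function(basis, coeffs, params, times,
                                        rtol = 1e-8, atol = 1e-10) {
  check_times(times)
  m <- ncol(basis$B)
  .Call(C_set_pk, pk_vector(params))
  .Call(C_set_input_basis, basis$grid[1], basis$grid[2] - basis$grid[1],
        basis$B, as.numeric(coeffs$c), TRUE)
  y0 <- numeric(3 + 3 * m)
  tt <- c(0, times)
  sol <- deSolve::lsoda(y0, tt, func = "tmdd_derivs",
                        parms = numeric(0), dllname = "erdeconv",
                        initfunc = "tmdd_init", rtol = rtol, atol = atol,
                        maxsteps = 50000)
  check_solution(sol, tt)
  sol <- sol[-1, , drop = FALSE]
  conc <- sol[, 2]
  jac <- sol[, 3 * seq_len(m) + 2, drop = FALSE]  # dC/dc_j columns
  dimnames(jac) <- NULL
  list(conc = conc, jac = jac)
}

#' Algebraic steady-state concentration for a constant absorption rate
#'
#' Closed-form stationary central concentration of the TMDD system: with
#' all derivatives set to zero, the peripheral and complex equations are
#' eliminated and the remaining quadratic in C is solved for its
#' non-negative root.  Valid as a model for slowly varying inputs (weekly
#' timescales), where the plasma concentration tracks the current
#' absorption rate.
#'
#' @param u absorption rate(s), pmol/min/kg, >= 0
#' @param params [pk_parameters()]
#' @return steady-state concentration(s), pM; strictly increasing in u
#' @export
steady_state_concentration <- function(u, params) {
  if (any(u < 0)) stop("u must be non-negative")
  with(params, {
    Vc <- vc_L(params)
    inside <- R_tot^2 * Vc^2 * k_int^2 * k_on^2 +
      2 * R_tot * Vc^2 * k_el * k_int^2 * k_on +
      2 * R_tot * Vc^2 * k_el * k_int * k_off * k_on -
      2 * R_tot * Vc * u * k_int * k_on^2 +
      Vc^2 * k_el^2 * k_int^2 +
      2 * Vc^2 * k_el^2 * k_int * k_off +
      Vc^2 * k_el^2 * k_off^2 +
      2 * Vc * u * k_el * k_int * k_on +
      2 * Vc * u * k_el * k_off * k_on +
      u^2 * k_on^2
    (-R_tot * Vc * k_int * k_on - Vc * k_el * k_int - Vc * k_el * k_off +
       u * k_on + sqrt(inside)) / (2 * Vc * k_el * k_on)
  })
}

# derivative dC_ss/du of the steady-state relation (chain rule for the
# algebraic-model Jacobian)
steady_state_dCdu <- function(u, params) {
  with(params, {
    Vc <- vc_L(params)
    inside <- R_tot^2 * Vc^2 * k_int^2 * k_on^2 +
      2 * R_tot * Vc^2 * k_el * k_int^2 * k_on +
      2 * R_tot * Vc^2 * k_el * k_int * k_off * k_on -
      2 * R_tot * Vc * u * k_int * k_on^2 +
      Vc^2 * k_el^2 * k_int^2 +
      2 * Vc^2 * k_el^2 * k_int * k_off +
      Vc^2 * k_el^2 * k_off^2 +
      2 * Vc * u * k_el * k_int * k_on +
      2 * Vc * u * k_el * k_off * k_on +
      u^2 * k_on^2
    dinside <- -2 * R_tot * Vc * k_int * k_on^2 +
      2 * Vc * k_el * k_int * k_on +
      2 * Vc * k_el * k_off * k_on +
      2 * u * k_on^2
    (k_on + dinside / (2 * sqrt(inside))) / (2 * Vc * k_el * k_on)
  })
}

#' Invert the steady-state relation: absorption rate from concentration
#'
#' At stationarity the complex concentration is
#' \eqn{RC = k_{on} R_{tot} C / (k_{on} C + k_{off} + k_{int})} and mass
#' balance gives \eqn{u = V_c (k_{el} C + k_{int} RC)}.
#'
#' @param conc steady-state concentration(s), pM, >= 0
#' @param params [pk_parameters()]
#' @return absorption rate(s) u, pmol/min/kg
#' @export
invert_steady_state <- function(conc, params) {
  if (any(conc < 0)) stop("conc must be non-negative")
  with(params, {
    RC <- k_on * R_tot * conc / (k_on * conc + k_off + k_int)
    vc_L(params) * (k_el * conc + k_int * RC)
  })
}

#' Mass-balance audit of a simulated trajectory
#'
#' Integrates the TMDD system with auxiliary cumulative states and
#' returns the terms of the balance: cumulative input versus drug held
#' in the three pools plus cumulative elimination (linear clearance and
#' complex internalization), all per kg bodyweight.
#'
#' @inheritParams simulate_dynamic
#' @param t_end end of the audited window (minutes)
#' @return list with `input` (pmol/kg absorbed) and `accounted`
#'   (pmol/kg in pools + eliminated); the two agree to solver tolerance
#' @export
check_mass_balance <- function(input_fn, params, t_end,
                               rtol = 1e-10, atol = 1e-12) {
  Vc <- vc_L(params)
  rhs <- function(t, y, parms) {
    u <- input_fn(t)
    C <- y[1]; AT <- y[2]; RC <- y[3]
    with(params, list(c(
      u / Vc - (k_el + k_pt) * C + k_tp * AT / Vc -
        k_on * (R_tot - RC) * C + k_off * RC,
      k_pt * C * Vc - k_tp * AT,
      k_on * (R_tot - RC) * C - (k_off + k_int) * RC,
      u,            # cumulative input
      C,            # int C dt
      RC            # int RC dt
    )))
  }
  sol <- deSolve::lsoda(numeric(6), c(0, t_end), rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 200000)
  s <- unname(sol[nrow(sol), -1])
  list(input = s[4],
       accounted = Vc * s[1] + s[2] + Vc * s[3] +
         Vc * (params$k_el * s[5] + params$k_int * s[6]))
}

check_times <- function(times) {
  if (length(times) < 1 || any(times < 0) || any(diff(times) <= 0))
    stop("times must be non-negative and strictly increasing")
}

solve_tmdd_c <- function(times, initial, rtol, atol) {
  tt <- if (times[1] > 0) c(0, times) else times
  sol <- deSolve::lsoda(initial, tt, func = "tmdd_derivs",
                        parms = numeric(0), dllname = "erdeconv",
                        initfunc = "tmdd_init", rtol = rtol, atol = atol,
                        maxsteps = 50000)
  check_solution(sol, tt)
  if (times[1] > 0) sol <- sol[-1, , drop = FALSE]
  data.frame(time = sol[, 1], C = sol[, 2], A_T = sol[, 3], RC = sol[, 4])
}

solve_tmdd_r <- function(input_fn, params, times, initial, rtol, atol) {
  Vc <- vc_L(params)
  rhs <- function(t, y, parms) {
    u <- input_fn(t)
    C <- y[1]; AT <- y[2]; RC <- y[3]
    with(params, list(c(
      u / Vc - (k_el + k_pt) * C + k_tp * AT / Vc -
        k_on * (R_tot - RC) * C + k_off * RC,
      k_pt * C * Vc - k_tp * AT,
      k_on * (R_tot - RC) * C - (k_off + k_int) * RC
    )))
  }
  tt <- if (times[1] > 0) c(0, times) else times
  sol <- deSolve::lsoda(initial, tt, rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  check_solution(sol, tt)
  if (times[1] > 0) sol <- sol[-1, , drop = FALSE]
  data.frame(time = sol[, 1], C = sol[, 2], A_T = sol[, 3], RC = sol[, 4])
}

check_solution <- function(sol, times) {
  if (nrow(sol) < length(times) || anyNA(sol))
    stop("ODE integration failed near t = ",
         signif(sol[nrow(sol), 1], 6),
         " min (tolerance not met)")
  invisible(sol)
}
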