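#' Parameters of the synthetic extended-release test input
#'
#' The validation input function is the sum of two Erlang-shaped peaks
#' (the slow release phases, weeks apart) and a bi-exponential initial
#' burst (the fast release of surface-bound drug):
#' \deqn{u_i(t) = a_i k_{tr,i}^{n_i} t^{n_i-1} e^{-k_{tr,i} t}/(n_i-1)!,
#'   \quad i = 1, 2}
#' \deqn{u_3(t) = r_1 e^{-k_1 t} + r_2 e^{-k_2 t}}
#' \deqn{u(t) = u_1(t) + u_2(t) + u_3(t).}
#' Defaults emulate a 10 mg extended-release exenatide dose.
#'
#' @param n1,n2 Erlang shape integers (>= 1)
#' @param a1,a2 peak masses (pmol/kg)
#' @param ktr1,ktr2 Erlang rate constants (1/min)
#' @param r1,r2 burst coefficients (pmol/min/kg)
#' @param k1,k2 burst decay rates (1/min)
#' @return object of class `test_input_params`
#' @export
test_input_params <- function(n1 = 10, a1 = 2700, ktr1 = 1.5e-4,
                              n2 = 4, a2 = 800, ktr2 = 1.8e-4,
                              r1 = 0.12, k1 = 7.64e-3,
                              r2 = 0.02, k2 = 4.76e-4) {
  if (n1 != round(n1) || n2 != round(n2) || n1 < 1 || n2 < 1)
    stop("Erlang shapes n1, n2 must be positive integers")
  p <- list(n1 = as.integer(n1), a1 = a1, ktr1 = ktr1,
            n2 = as.integer(n2), a2 = a2, ktr2 = ktr2,
            r1 = r1, k1 = k1, r2 = r2, k2 = k2)
  if (any(unlist(p[-c(1, 4)]) <= 0))
    stop("all masses and rates must be strictly positive")
  structure(p, class = "test_input_params")
}

test_input_vector <- function(p) {
  c(p$n1, p$a1, p$ktr1, p$n2, p$a2, p$ktr2, p$r1, p$k1, p$r2, p$k2)
}

#' Evaluate the synthetic test input
#'
#' @param t time(s), minutes, >= 0
#' @param p [test_input_params()]
#' @param components which terms to include: any subset of
#'   `c("u1", "u2", "u3")` (the long-timescale input of the steady-state
#'   comparison uses `c("u1", "u2")`)
#' @return absorption rate u(t), pmol/min/kg
#' @export
#' @examples
#' test_input(0, test_input_params())  # r1 + r2 = 0.14
test_input <- function(t, p = test_input_params(),
                       components = c("u1", "u2", "u3")) {
  if (any(t < 0)) stop("t must be non-negative")
  erlang <- function(a, n, ktr, t) {
    out <- numeric(length(t))
    pos <- t > 0
    out[pos] <- exp(log(a) + n * log(ktr) + (n - 1) * log(t[pos]) -
                      ktr * t[pos] - lgamma(n))
    if (n == 1) out[!pos] <- a * ktr
    out
  }
  u <- numeric(length(t))
  if ("u1" %in% components) u <- u + erlang(p$a1, p$n1, p$ktr1, t)
  if ("u2" %in% components) u <- u + erlang(p$a2, p$n2, p$ktr2, t)
  if ("u3" %in% components) u <- u + p$r1 * exp(-p$k1 * t) +
      p$r2 * exp(-p$k2 * t)
  u
}

#' Sampling schedules for the validation study
#'
#' Dense: 100 equally spaced points on the open-left interval (0, T]
#' (t = 0 is excluded because C(0) = 0 makes proportional noise
#' degenerate).  Sparse short: a reconstructed 12-point clinical schedule
#' within the first 48 h.  Sparse long: the 48 h point plus weekly
#' samples, weeks 1-12.
#'
#' @param timescale "short" (48 h horizon) or "long" (12 weeks)
#' @param label "dense" or "sparse"
#' @return object of class `sampling_schedule`: list with `label`,
#'   `timescale`, `times` (minutes)
#' @export
sampling_schedule <- function(timescale = c("short", "long"),
                              label = c("dense", "sparse")) {
  timescale <- match.arg(timescale)
  label <- match.arg(label)
  t_end <- if (timescale == "short") 48 * 60 else 12 * 7 * 24 * 60
  times <- if (label == "dense") {
    seq_len(100) * t_end / 100
  } else if (timescale == "short") {
    c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 24, 36, 48) * 60
  } else {
    c(48 * 60, seq_len(12) * 7 * 24 * 60)
  }
  structure(list(label = label, timescale = timescale, times = times),
            class = "sampling_schedule")
}

#' Generate a synthetic validation dataset
#'
#' Pushes the test input through the TMDD system, samples the resulting
#' concentration curve at the schedule times, and (optionally) applies
#' proportional noise y_i = f_i (1 + sigma eps_i).  Non-positive noisy
#' observations are redrawn (count recorded in the metadata) so the
#' nominal noise model holds for the bulk of the data.
#'
#' @param p [test_input_params()]
#' @param schedule [sampling_schedule()]
#' @param params [pk_parameters()]
#' @param noise [noise_model()] or NULL for noise-free data
#' @param seed RNG seed (recorded in the dataset metadata)
#' @param dose_mg,bodyweight_kg dose bookkeeping for downstream
#'   bioavailability reporting
#' @return [er_dataset()] with the generating truth attached
#' @export
generate_dataset <- function(p = test_input_params(),
                             schedule = sampling_schedule("short", "dense"),
                             params = pk_parameters(),
                             noise = NULL, seed = 1,
                             dose_mg = 10, bodyweight_kg = 90) {
  f <- simulate_dynamic(p, params, schedule$times)
  y <- f
  redraws <- 0L
  if (!is.null(noise)) {
    set.seed(seed)
    draw_eps <- function(n) {
      if (noise$family == "student_t") rt(n, df = noise$df) else rnorm(n)
    }
    y <- f * (1 + noise$sigma * draw_eps(length(f)))
    while (any(y <= 0)) {
      bad <- which(y <= 0)
      redraws <- redraws + length(bad)
      y[bad] <- f[bad] * (1 + noise$sigma * draw_eps(length(bad)))
    }
  }
  er_dataset(schedule$times, y, timescale = schedule$timescale,
             dose_mg = dose_mg, bodyweight_kg = bodyweight_kg,
             truth = p,
             meta = list(schedule = schedule$label, seed = seed,
                         noise = if (is.null(noise)) "none" else
                           unclass(noise),
                         n_redraws = redraws))
}

#' Analytic total mass of the test input
#'
#' \eqn{\int_0^\infty u\,dt = a_1 + a_2 + r_1/k_1 + r_2/k_2} (pmol/kg).
#'
#' @param p [test_input_params()]
#' @export
test_input_total_mass <- function(p = test_input_params()) {
  p$a1 + p$a2 + p$r1 / p$k1 + p$r2 / p$k2
}
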