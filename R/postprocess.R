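#' Dose in pmol from mg and molar mass
#'
#' @param dose_mg dose (mg)
#' @param molar_mass molar mass (g/mol); default 4186.6, exenatide
#' @export
dose_pmol <- function(dose_mg, molar_mass = 4186.6) {
  dose_mg / molar_mass * 1e9
}

# draws of u on the basis grid: N x n_draws matrix
reconstruct_inputs <- function(samples, basis) {
  exp(basis$B %*% t(samples$C_samples))
}

unit_factor <- function(units) {
  switch(units,
         pmol_per_min = 1,
         pmol_per_h = 60,
         pmol_per_week = 7 * 24 * 60,
         stop("unknown units: ", units,
              " (use pmol_per_min, pmol_per_h or pmol_per_week)"))
}

#' Mean posterior RMSE of the input function against a known truth
#'
#' One RMSE is computed per posterior draw (reconstructed u versus the
#' true input on the basis grid) and the values are averaged, so the
#' score penalizes both bias and posterior spread.
#'
#' @param samples [run_mcmc()] result
#' @param basis [build_kl_basis()]
#' @param truth true input: a function of t (minutes) returning
#'   pmol/min/kg, or a [test_input_params()] object
#' @param units reporting units: "pmol_per_h" (short timescale),
#'   "pmol_per_week" (long) or "pmol_per_min"
#' @return mean RMSE in the requested units (per kg bodyweight)
#' @export
rmse_vs_truth <- function(samples, basis, truth,
                          units = c("pmol_per_h", "pmol_per_week",
                                    "pmol_per_min")) {
  units <- match.arg(units)
  fac <- unit_factor(units)
  ut <- truth_on_grid(truth, basis$grid)
  U <- reconstruct_inputs(samples, basis)
  mean(sqrt(colMeans((U - ut)^2))) * fac
}

truth_on_grid <- function(truth, grid) {
  if (inherits(truth, "test_input_params")) test_input(grid, truth)
  else if (is.function(truth)) truth(grid)
  else stop("truth must be a function or test_input_params")
}

#' Pointwise 95% credible-band coverage of a known truth
#'
#' @inheritParams rmse_vs_truth
#' @param exclude_before drop grid points earlier than this time
#'   (minutes), e.g. to exclude the initial burst region that the
#'   smoothness prior cannot represent on the long timescale
#' @return fraction of (retained) grid points whose pointwise 2.5-97.5%
#'   interval contains the truth
#' @export
coverage_vs_truth <- function(samples, basis, truth,
                              exclude_before = NULL) {
  keep <- if (is.null(exclude_before)) rep(TRUE, length(basis$grid))
          else basis$grid >= exclude_before
  ut <- truth_on_grid(truth, basis$grid)[keep]
  U <- reconstruct_inputs(samples, basis)[keep, , drop = FALSE]
  lo <- apply(U, 1, quantile, 0.025)
  hi <- apply(U, 1, quantile, 0.975)
  mean(ut >= lo & ut <= hi)
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))
}

#' Fraction-absorbed curves from posterior draws
#'
#' Per draw, the cumulative integral of the absorption rate (times
#' bodyweight) divided by the administered dose in pmol: the fraction of
#' the dose absorbed by time t.  The terminal value of each curve is a
#' draw of the bioavailability F.
#'
#' @inheritParams rmse_vs_truth
#' @param dose_mg administered dose (mg)
#' @param bodyweight_kg subject bodyweight (kg)
#' @param molar_mass drug molar mass (g/mol)
#' @return list with `grid` (minutes), `curves` (grid x draws,
#'   non-decreasing in t), `F_samples` (terminal fractions)
#' @export
fraction_absorbed <- function(samples, basis, dose_mg,
                              bodyweight_kg = 90, molar_mass = 4186.6) {
  if (dose_mg <= 0) stop("dose must be positive")
  U <- reconstruct_inputs(samples, basis)
  dp <- dose_pmol(dose_mg, molar_mass)
  curves <- apply(U, 2, function(u)
    cumtrapz(basis$grid, u) * bodyweight_kg / dp)
  list(grid = basis$grid, curves = curves,
       F_samples = curves[nrow(curves), ])
}

#' Kernel density estimate of bioavailability
#'
#' Gaussian kernel with Silverman's bandwidth; reports the mean and the
#' central 95% interval alongside the density.
#'
#' @param F_samples bioavailability draws (terminal fractions absorbed)
#' @return list with `density` (a [stats::density()] object, or NULL for
#'   degenerate samples), `mean`, `ci` (2.5/97.5 percentiles),
#'   `point_mass` flag
#' @export
bioavailability_kde <- function(F_samples) {
  if (length(F_samples) < 100)
    stop("need at least 100 draws for a density estimate")
  if (sd(F_samples) == 0) {
    return(list(density = NULL, mean = F_samples[1],
                ci = c(F_samples[1], F_samples[1]), point_mass = TRUE))
  }
  list(density = density(F_samples, bw = "nrd0"),
       mean = mean(F_samples),
       ci = unname(quantile(F_samples, c(0.025, 0.975))),
       point_mass = FALSE)
}

#' Posterior summary of the estimated input function
#'
#' @inheritParams rmse_vs_truth
#' @param truth optional known truth for RMSE/coverage reporting
#' @param dose_mg,bodyweight_kg,molar_mass optional dose bookkeeping;
#'   when `dose_mg` is given, fraction-absorbed curves and
#'   bioavailability draws are included
#' @return object of class `summary_result`: grid, posterior mean input
#'   and pointwise 95% bands (pmol/min/kg), optional mean RMSE, fraction
#'   absorbed and F draws
#' @export
summarize_posterior <- function(samples, basis, truth = NULL,
                                units = "pmol_per_h",
                                dose_mg = NA, bodyweight_kg = 90,
                                molar_mass = 4186.6) {
  U <- reconstruct_inputs(samples, basis)
  out <- list(grid = basis$grid,
              mean = rowMeans(U),
              lower = apply(U, 1, quantile, 0.025),
              upper = apply(U, 1, quantile, 0.975),
              units = units,
              rmse = if (!is.null(truth))
                rmse_vs_truth(samples, basis, truth, units),
              lambda_median = median(samples$lam_samples),
              acceptance = samples$acceptance)
  if (!is.na(dose_mg)) {
    fa <- fraction_absorbed(samples, basis, dose_mg, bodyweight_kg,
                            molar_mass)
    out$fraction_absorbed_mean <- rowMeans(fa$curves)
    out$F_samples <- fa$F_samples
    out$F_mean <- mean(fa$F_samples)
    out$F_ci <- unname(quantile(fa$F_samples, c(0.025, 0.975)))
  }
  structure(out, class = "summary_result")
}

#' @export
print.summary_result <- function(x, ...) {
  cat("<summary_result>\n")
  cat(sprintf("  grid: %d points on [%.3g, %.3g] min\n",
              length(x$grid), min(x$grid), max(x$grid)))
  if (!is.null(x$rmse))
    cat(sprintf("  mean RMSE vs truth: %.4g %s\n", x$rmse, x$units))
  if (!is.null(x$F_mean))
    cat(sprintf("  bioavailability F: mean %.4g, 95%% CI [%.4g, %.4g]\n",
                x$F_mean, x$F_ci[1], x$F_ci[2]))
  invisible(x)
}

#' Write a posterior summary as tidy CSV + JSON
#'
#' @param summary [summarize_posterior()]
#' @param stem output path stem: writes `<stem>.csv` (trajectory) and
#'   `<stem>.json` (scalars)
#' @export
write_summary <- function(summary, stem) {
  write.csv(data.frame(time_min = summary$grid,
                       u_mean = summary$mean,
                       u_lo95 = summary$lower,
                       u_hi95 = summary$upper),
            paste0(stem, ".csv"), row.names = FALSE)
  scalars <- summary[c("units", "rmse", "lambda_median", "acceptance",
                       "F_mean", "F_ci")]
  scalars <- scalars[!vapply(scalars, is.null, logical(1))]
  jsonlite::write_json(scalars, paste0(stem, ".json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(stem)
}
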