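# erdeconv

Non-parametric Bayesian input estimation for extended-release
pharmacokinetics.

## The problem

During extended-release (ER) formulation development the central
unknown is the in vivo absorption-rate profile u(t) — the rate at which
drug reaches the systemic circulation — and its integral, the
bioavailability F. What is actually measured is the plasma
concentration C(t) at a handful of timepoints. When the
pharmacokinetics are linear and effectively stationary, recovering u
from C is classical deconvolution; for drugs with non-linear
(target-mediated) disposition, such as the GLP-1 receptor agonist
exenatide, the general *input estimation* problem must be solved: u(t)
is an unknown input to a known ODE system.

`erdeconv` solves this problem for single-dose ER data:

* **PK model.** A two-compartment model with target-mediated drug
  disposition (TMDD): central concentration C, peripheral amount A_T,
  and drug–receptor complex RC, with complex internalization as an
  extra elimination route. On weekly timescales the package can replace
  ODE integration with the exact algebraic steady-state solution of the
  system (orders of magnitude cheaper inside MCMC; the two agree to the
  order of 1% for slowly varying inputs).
* **Input model.** u(t) = exp(Σ c_j B_j(t)): non-negative by
  construction. The 20 basis functions B_j are the truncated
  Karhunen–Loève basis of a second-derivative smoothness prior; the
  regularization parameter λ gets a Gamma(10⁻³, 10⁻³) hyperprior and is
  estimated with everything else.
* **Observation model.** Proportional error, y = f(1 + σ ε), with
  ε Gaussian or Student-t(4); the heavy-tailed default makes the fit
  robust to outliers.
* **Inference.** MCMC alternating SMMALA (manifold-MALA with the
  Gauss–Newton Fisher metric; gradients from forward-sensitivity ODEs
  in compiled code) on the coefficients with conjugate Gibbs updates of
  λ, started at the joint mode found by Gauss–Newton warmup.
  Chain-length adequacy is assessed with a built-in Raftery–Lewis
  diagnostic.
* **Reporting.** Posterior input trajectories with credible bands,
  fraction-absorbed curves, and kernel-density summaries of
  bioavailability.

## Worked example

Generate a realistic synthetic dataset — the built-in test input (two
Erlang release peaks plus a bi-exponential initial burst, emulating a
10 mg ER exenatide dose) pushed through the TMDD model, sampled at a
sparse clinical-style schedule with 10% proportional t(4) noise — then
recover the input and bioavailability:

```r
library(erdeconv)

params <- pk_parameters()                 # published TMDD constants
truth  <- test_input_params()             # synthetic 10 mg profile
ds <- generate_dataset(truth, sampling_schedule("long", "sparse"),
                       params, noise = noise_model("student_t", 0.10, 4),
                       seed = 42)
basis <- build_kl_basis(min(ds$times), max(ds$times))
post  <- run_mcmc(ds, basis, params, noise_model("student_t", 0.10, 4),
                  sampler_config(n_samples = 10000, seed = 42))
summ  <- summarize_posterior(post, basis,
                             truth = function(t) test_input(t, truth),
                             units = "pmol_per_week", dose_mg = 10)
summ
```

```
<summary_result>
  grid: 200 points on [2.88e+03, 1.21e+05] min
  mean RMSE vs truth: 77.35 pmol_per_week
  bioavailability F: mean 0.1473, 95% CI [0.1314, 0.1646]
```

Read: averaged over posterior draws, the reconstructed absorption-rate
trajectory differs from the true input by ~77 pmol/week (per kg) for
this noisy sparse realization — a profile whose release peaks reach
several hundred pmol/week — and an estimated 14.7% of the 10 mg dose
reaches circulation (the true fraction for this input is 13.4%), with
a credible interval that reflects the sparse weekly sampling.

`cli_estimate()` wraps the same pipeline for any CSV with columns
`time_min,conc_pM` (see `inst/extdata/synthetic_dose_*.csv` for
packaged examples with their JSON truth sidecars), and
`inst/cli/erdeconv` exposes `simulate` / `estimate` / `validate`
commands for shell use.

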