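# shared fixtures, built once per test run
pk_default <- pk_parameters()
tip_default <- test_input_params()

# small short-timescale basis reused across files
basis_small <- build_kl_basis(28.8, 2880, N = 100, m = 10)

# coefficients whose reconstruction roughly tracks the short-timescale
# burst, for tests needing a "realistic" point in coefficient space
coef_burst <- local({
  target <- log(test_input(basis_small$grid, tip_default))
  input_coefficients(drop(crossprod(basis_small$B, target)), lam = 100)
})

# a quick long-timescale sparse dataset + basis (steady-state mode is
# cheap, so several tests can afford a small MCMC run on this)
quick_long <- local({
  ds <- generate_dataset(tip_default, sampling_schedule("long", "sparse"),
                         pk_default, noise = NULL, seed = 99)
  list(dataset = ds,
       basis = build_kl_basis(min(ds$times), max(ds$times),
                              N = 80, m = 12))
})
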