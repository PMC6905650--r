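# Shared fixtures: small descriptors and configs used across tests.

fx_cfg <- cohort_config("clean")

fx_naive_src <- source_descriptor("exp_decay", c(S0 = 1e7, nu = 0.003),
                                  t_ref = 66)

fx_chi_src <- source_descriptor("gen_logistic",
  c(lower = 0, upper = 0.9, rate = 0.035, midpoint = 70, shape = 1))

# constant-chimerism descriptor (a degenerate generalised logistic)
fx_chi_const <- function(c0) {
  source_descriptor("gen_logistic",
    c(lower = c0, upper = c0, rate = 1, midpoint = 0, shape = 1))
}

# quick synthetic timecourse for fitting tests
fx_cohort <- function(model = "homogeneous", n_mice = 60, seed = 1,
                      sigma_x = 0.15, sigma_y = 0.05, subset = "tcm",
                      facility = "clean",
                      truth = homogeneous_params(2.5e5, 1e-3, 0.01)) {
  sc <- sim_config(facility, subset, model, truth, n_mice = n_mice,
                   seed = seed, sigma_x = sigma_x, sigma_y = sigma_y)
  obs <- simulate_cohort(sc)
  list(config = sc,
       data = suppressMessages(
         extract_timecourse(obs, subset, cohort_config(facility))))
}
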