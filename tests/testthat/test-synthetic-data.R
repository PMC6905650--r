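test_that("noiseless cohorts lie exactly on the truth trajectory", {
  truth <- homogeneous_params(2.5e5, 1e-3, 0.01)
  sc <- sim_config("clean", "tcm", "homogeneous", truth, n_mice = 20,
                   sigma_x = 1e-12, sigma_y = 1e-12, seed = 3)
  obs <- simulate_cohort(sc)
  dat <- suppressMessages(extract_timecourse(obs, "tcm", fx_cfg))
  pred <- vapply(seq_len(nrow(dat)), function(i) {
    tr <- solve_homogeneous(truth, sc$source_truth, sc$chi_source_truth,
                            fx_cfg, dat$bmt_age_days[i], dat$obs_age_days[i],
                            h = 0.5)
    c(tr$total, tr$chi_norm)
  }, numeric(2))
  expect_equal(dat$count, pred[1, ], tolerance = 1e-6)
  expect_equal(dat$chi_norm, pred[2, ], tolerance = 1e-6)
})

test_that("simulated noise magnitudes match the configured SDs", {
  truth <- homogeneous_params(2.5e5, 1e-3, 0.01)
  sc <- sim_config("clean", "tcm", "homogeneous", truth, n_mice = 2000,
                   seed = 11, h = 1)
  obs <- simulate_cohort(sc)
  dat <- suppressMessages(extract_timecourse(obs, "tcm", fx_cfg))
  ctx <- memdyn:::make_ctx(sc$source_truth, sc$chi_source_truth, fx_cfg,
                           dat$bmt_age_days, dat$obs_age_days, h = 1)
  pr <- memdyn:::predict_cohort(truth, ctx)
  rx <- log(dat$count) - log(pr$total)
  expect_lt(abs(sd(rx) / sc$sigma_x - 1), 0.05)
})

test_that("cohorts are reproducible from their seed and differ across seeds", {
  truth <- homogeneous_params(2.5e5, 1e-3, 0.01)
  sc1 <- sim_config("clean", "tcm", "homogeneous", truth, n_mice = 25,
                    seed = 5)
  a <- simulate_cohort(sc1)
  b <- simulate_cohort(sc1)
  attr(a, "truth") <- attr(b, "truth") <- NULL
  expect_identical(a, b)
  sc2 <- sim_config("clean", "tcm", "homogeneous", truth, n_mice = 25,
                    seed = 6)
  expect_false(identical(simulate_cohort(sc2)$count_tcm, a$count_tcm))
})

test_that("back-transformed chimerism stays within [0, 1] of the DP1 reference", {
  truth <- homogeneous_params(2.5e5, 1e-3, 0.01)
  sc <- sim_config("clean", "tcm", "homogeneous", truth, n_mice = 500,
                   sigma_y = 0.4, seed = 7, h = 1)
  obs <- simulate_cohort(sc)
  expect_true(all(obs$chi_tcm >= 0 & obs$chi_tcm <= obs$chi_dp1 + 1e-12))
  expect_true(all(obs$chi_dp1 >= 0.6 & obs$chi_dp1 <= 0.95))
})

test_that("clean-facility naive source declines with a 228-day half-life", {
  src <- default_source_truth("clean", "naive")
  expect_equal(src$params[["nu"]], log(2) / 228)
  expect_equal(default_source_truth("dirty", "naive")$params[["nu"]],
               log(2) / 143)
})

test_that("published point estimates populate the truth configurations", {
  sc <- default_truth("clean", "tcm", "age_dep")
  expect_equal(sc$truth_params$lam0, 2.2e-2)
  expect_equal(sc$truth_params$A, 150)
  expect_equal(sc$truth_params$n, 3)
  expect_equal(default_truth("dirty", "tcm", "two_phase")$truth_params$lam_slow,
               4.8e-3)
  # transition rate backed out of the percentage surviving to slow memory
  tp <- default_truth("clean", "tcm", "two_phase")$truth_params
  expect_equal(tp$gamma, 0.082 * 0.034 / (1 - 0.034), tolerance = 1e-10)
  expect_equal(100 * tp$gamma / (tp$lam_fast + tp$gamma), 3.4,
               tolerance = 1e-10)
  # the slow-pool initial size is calibrated to the reported slow fraction
  d <- derived_quantities(tp, default_source_truth("clean", "naive"),
                          cohort_config("clean"))
  expect_equal(d$prop_slow_tstar, 0.25, tolerance = 1e-6)
})

test_that("unidentifiable published rows are refused", {
  expect_error(default_truth("dirty", "tem", "age_dep"), "poorly constrained")
})

test_that("round trip: fitting recovers the generating parameters", {
  # large cohort, modest noise: estimates land within a few percent of truth
  truth <- homogeneous_params(2.5e5, 1e-3, 0.01)
  sc <- sim_config("clean", "tcm", "homogeneous", truth, n_mice = 300,
                   sigma_x = 0.05, sigma_y = 0.02, seed = 13, h = 1)
  obs <- simulate_cohort(sc)
  dat <- suppressMessages(extract_timecourse(obs, "tcm", fx_cfg))
  fit <- fit_model(dat, "homogeneous", sc$source_truth, sc$chi_source_truth,
                   fx_cfg, starts = 3, seed = 1, h = 1)
  expect_lt(abs(fit$params$M0 / truth$M0 - 1), 0.1)
  expect_lt(abs(fit$params$phi / truth$phi - 1), 0.15)
  expect_lt(abs(fit$params$lam - truth$lam), 0.005)
})
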