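times_fx <- c(100, 150, 250, 400)

test_that("homogeneous model with no influx decays exponentially, chimerism stays zero", {
  p <- homogeneous_params(M0 = 1e6, phi = 0, lam = 0.01)
  tr <- solve_homogeneous(p, fx_naive_src, fx_chi_src, fx_cfg, 56, times_fx)
  expect_equal(tr$total, 1e6 * exp(-0.01 * (times_fx - 66)), tolerance = 1e-10)
  expect_equal(tr$chi_norm, rep(0, 4))
})

test_that("semi-analytic homogeneous solution matches the stiff ODE solver", {
  p <- homogeneous_params(M0 = 1e6, phi = 1e-3, lam = 0.01)
  a <- solve_homogeneous(p, fx_naive_src, fx_chi_src, fx_cfg, 56, times_fx)
  b <- solve_homogeneous(p, fx_naive_src, fx_chi_src, fx_cfg, 56, times_fx,
                         method = "ode")
  expect_equal(a$total, b$total, tolerance = 1e-6)
  expect_lt(max(abs(a$chi_norm - b$chi_norm)), 1e-5)
})

test_that("the lam = nu removable singularity is handled in the closed form", {
  nu <- fx_naive_src$params[["nu"]]
  p <- homogeneous_params(M0 = 1e6, phi = 1e-3, lam = nu)
  a <- solve_homogeneous(p, fx_naive_src, fx_chi_src, fx_cfg, 56, times_fx)
  b <- solve_homogeneous(p, fx_naive_src, fx_chi_src, fx_cfg, 56, times_fx,
                         method = "ode")
  expect_true(all(is.finite(a$total)))
  expect_equal(a$total, b$total, tolerance = 1e-6)
})

test_that("memory chimerism converges to a constant source chimerism when nu < lam", {
  # with influx declining more slowly than memory is lost, memory chimerism
  # climbs all the way to the source's plateau
  p <- homogeneous_params(M0 = 2e5, phi = 1e-3, lam = 0.05)
  tr <- solve_homogeneous(p, fx_naive_src, fx_chi_const(0.6), fx_cfg, 56,
                          c(400, 900, 1500))
  expect_lt(abs(tr$chi_norm[3] - 0.6), 0.01)
  expect_true(all(diff(tr$chi_norm) > 0) || tr$chi_norm[1] > 0.59)
})

test_that("two-phase model degenerates to homogeneous when gamma = 0, Mslow0 = 0", {
  lam <- 0.05; phi <- 1e-3
  tp <- two_phase_params(Mslow0 = 0, phi = phi, lam_fast = lam,
                         lam_slow = 0.01, gamma = 0)
  hm <- homogeneous_params(M0 = phi * 1e7 / lam, phi = phi, lam = lam)
  a <- solve_two_phase(tp, fx_naive_src, fx_chi_src, fx_cfg, 56, times_fx)
  b <- solve_homogeneous(hm, fx_naive_src, fx_chi_src, fx_cfg, 56, times_fx)
  expect_equal(a$total, b$total, tolerance = 1e-6)
  expect_equal(a$chi_norm, b$chi_norm, tolerance = 1e-6)
})

test_that("two-phase totals with equal loss rates sum to the homogeneous equation", {
  lam <- 0.05; phi <- 1e-3; gam <- 0.02
  tp <- two_phase_params(Mslow0 = 2e5, phi = phi, lam_fast = lam,
                         lam_slow = lam, gamma = gam)
  hm <- homogeneous_params(M0 = phi * 1e7 / (lam + gam) + 2e5, phi = phi,
                           lam = lam)
  a <- solve_two_phase(tp, fx_naive_src, fx_chi_src, fx_cfg, 56, times_fx)
  b <- solve_homogeneous(hm, fx_naive_src, fx_chi_src, fx_cfg, 56, times_fx)
  expect_equal(a$total, b$total, tolerance = 1e-4)
})

test_that("two-phase subsets approach their fixed points under a constant source", {
  S_const <- source_descriptor("exp_decay", c(S0 = 1e7, nu = 0), t_ref = 66)
  phi <- 1e-3; lf <- 0.1; ls <- 0.02; g <- 0.03
  tp <- two_phase_params(Mslow0 = 1e4, phi = phi, lam_fast = lf,
                         lam_slow = ls, gamma = g)
  tr <- solve_two_phase(tp, S_const, fx_chi_src, fx_cfg, 56, c(900, 1200))
  Mf_star <- phi * 1e7 / (lf + g)
  Ms_star <- g * Mf_star / ls
  expect_equal(tr$fast[2], Mf_star, tolerance = 1e-6)
  expect_equal(tr$slow[2], Ms_star, tolerance = 1e-4)
})

test_that("two-phase quasi-equilibrium initialisation rejects lam_fast + gamma <= 0", {
  expect_error(two_phase_params(1e5, 1e-3, -0.02, 0.01, 0.01),
               "quasi-equilibrium")
})

test_that("resistant model with no incumbents equals the homogeneous model", {
  rp <- resistant_params(M0 = 1e6, I0 = 0, phi = 1e-3, lam = 0.01)
  hm <- homogeneous_params(M0 = 1e6, phi = 1e-3, lam = 0.01)
  a <- solve_resistant(rp, fx_naive_src, fx_chi_src, fx_cfg, 56, times_fx)
  b <- solve_homogeneous(hm, fx_naive_src, fx_chi_src, fx_cfg, 56, times_fx)
  expect_equal(a$total, b$total, tolerance = 1e-4)
  expect_equal(a$chi_norm, b$chi_norm, tolerance = 1e-4)
})

test_that("with no influx only incumbents persist in the resistant model", {
  rp <- resistant_params(M0 = 1e6, I0 = 3e5, phi = 0, lam = 0.05)
  tr <- solve_resistant(rp, fx_naive_src, fx_chi_src, fx_cfg, 56, c(400, 900))
  expect_lt(abs(tr$total[2] / 3e5 - 1), 1e-6)
  expect_equal(tr$chi_norm, c(0, 0))
})

test_that("incumbents dilute total chimerism below the displaceable compartment's", {
  # chi_norm(total) < chi_norm(displaceable) whenever I0 > 0, across a grid
  for (lam in c(0.005, 0.02, 0.1)) {
    for (I0 in c(1e5, 5e5)) {
      rp <- resistant_params(M0 = 5e5, I0 = I0, phi = 1e-3, lam = lam)
      hm <- homogeneous_params(M0 = 5e5, phi = 1e-3, lam = lam)
      a <- solve_resistant(rp, fx_naive_src, fx_chi_src, fx_cfg, 56, times_fx)
      b <- solve_homogeneous(hm, fx_naive_src, fx_chi_src, fx_cfg, 56,
                             times_fx)
      expect_true(all(a$chi_norm[-1] < b$chi_norm[-1]))
    }
  }
})

test_that("age-dependent model with constant loss reduces to homogeneous", {
  pp <- 0.01; lam0 <- 0.022; phi <- 1e-3
  ad <- age_dep_params(phi = phi, p = pp, lam0 = lam0, A = Inf)
  M0 <- phi * 1e7 * (exp(pp * 66) - 1) / pp
  hm <- homogeneous_params(M0 = M0, phi = phi, lam = lam0)
  a <- solve_age_dep(ad, fx_naive_src, fx_chi_src, fx_cfg, 56, times_fx)
  b <- solve_homogeneous(hm, fx_naive_src, fx_chi_src, fx_cfg, 56, times_fx)
  expect_equal(a$total, b$total, tolerance = 1e-4)
  expect_equal(a$chi_norm, b$chi_norm, tolerance = 1e-4)
})

test_that("p -> 0 limit of the initial pool size is phi S(t0) t0", {
  phi <- 1e-3
  ad <- age_dep_params(phi = phi, p = 0, lam0 = 0.022, A = 150, n = 3)
  tr <- solve_age_dep(ad, fx_naive_src, fx_chi_src, fx_cfg, 40, 66)
  # at t = t0 no influx has accumulated and no initial cell has decayed away
  # beyond the survival-free integral, so total(t0) = integral of g = phi S t0
  expect_equal(tr$total, phi * 1e7 * 66, tolerance = 1e-6)
})

test_that("cohort survival matches adaptive quadrature to high precision", {
  lam0 <- 0.022; A <- 150; n <- 3
  p <- age_dep_params(phi = 1e-3, p = 0, lam0 = lam0, A = A, n = n)
  Lam <- memdyn:::age_loss_cum(p, 600)
  for (a in c(10, 100, 500)) {
    expect_equal(exp(-Lam(a)), survival_quadrature(a, lam0, A, n),
                 tolerance = 1e-8)
  }
})

test_that("host + donor decomposition conserves totals", {
  # solving host and donor compartments separately (deSolve) and summing
  # equals the package's total solution
  p <- homogeneous_params(M0 = 1e6, phi = 1e-3, lam = 0.01)
  bmt <- 56; t_start <- bmt + fx_cfg$bmt_lag
  deriv <- function(t, y, parms) {
    S <- eval_source(fx_naive_src, t)
    chs <- eval_source(fx_chi_src, max(t - bmt, 0))   # normalised
    list(c(p$phi * S * (1 - chs) - p$lam * y[1],
           p$phi * S * chs - p$lam * y[2]))
  }
  # start at t_start with all-host memory propagated from t0
  M_T <- solve_homogeneous(p, fx_naive_src, fx_chi_src, fx_cfg, bmt,
                           t_start)$total
  out <- deSolve::lsoda(c(host = M_T, donor = 0),
                        c(t_start, times_fx), deriv, rtol = 1e-10, atol = 1e-4)
  tot_split <- rowSums(out[-1, c("host", "donor")])
  tr <- solve_homogeneous(p, fx_naive_src, fx_chi_src, fx_cfg, bmt, times_fx)
  expect_equal(unname(tot_split), tr$total, tolerance = 1e-7)
  # and the donor fraction reproduces the chimerism solution
  expect_equal(unname(out[-1, "donor"] / tot_split), tr$chi_norm,
               tolerance = 1e-4)
})

test_that("mice with different BMT ages lie on the same total-numbers curve", {
  p <- two_phase_params(Mslow0 = 2e5, phi = 1e-3, lam_fast = 0.1,
                        lam_slow = 5e-3, gamma = 0.01)
  tt <- c(160, 250, 400)   # past the later mouse's post-BMT lag
  a <- solve_two_phase(p, fx_naive_src, fx_chi_src, fx_cfg, 40, tt)
  b <- solve_two_phase(p, fx_naive_src, fx_chi_src, fx_cfg, 120, tt)
  expect_equal(a$total, b$total, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(a$chi_norm, b$chi_norm)))
})

test_that("chimerism is nondecreasing when source chimerism is nondecreasing", {
  set.seed(11)
  tt <- seq(95, 500, by = 15)
  for (i in 1:5) {
    p <- homogeneous_params(M0 = 10^runif(1, 5, 6.5),
                            phi = 10^runif(1, -4, -2.5),
                            lam = runif(1, -0.01, 0.1))
    tr <- solve_homogeneous(p, fx_naive_src, fx_chi_src, fx_cfg, 56, tt)
    expect_true(all(diff(tr$chi_norm) > -1e-10))
  }
})

test_that("derived quantities reproduce the published half-life arithmetic", {
  src <- fx_naive_src
  tp <- two_phase_params(Mslow0 = 1e5, phi = 1.2, lam_fast = 0.23,
                         lam_slow = 2.5e-3, gamma = 4.2e-3)
  d <- derived_quantities(tp, src, fx_cfg)
  expect_equal(signif(d$half_life_fast, 2), 3.0)    # ln2 / 0.23
  tp2 <- two_phase_params(1e5, 1e-3, 0.1, 4.8e-3, 0.005)
  expect_equal(signif(derived_quantities(tp2, src,
                                         fx_cfg)$half_life_slow, 2), 140)
  # gamma = lam_fast means half of fast memory survives to the slow pool
  tp3 <- two_phase_params(1e5, 1e-3, 0.1, 5e-3, 0.1)
  expect_equal(derived_quantities(tp3, src, fx_cfg)$pct_to_slow, 50)
  # non-positive loss has no half-life
  hm <- homogeneous_params(1e5, 1e-3, -0.01)
  expect_true(is.na(derived_quantities(hm, src, fx_cfg)$half_life))
})

test_that("trajectory preconditions are enforced", {
  p <- homogeneous_params(1e6, 1e-3, 0.01)
  expect_error(solve_homogeneous(p, fx_naive_src, fx_chi_src, fx_cfg, 56, 70),
               "post-BMT")
  expect_error(solve_homogeneous(p, fx_naive_src, fx_chi_src, fx_cfg, 20, 200),
               "baseline age")
})
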