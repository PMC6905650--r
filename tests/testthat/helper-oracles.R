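# Independent oracles used by the tests. These deliberately avoid the
# package's own integrators.

# Brute-force solution of the age-structured transport equation
#   dM/dt + dM/da = -lambda(a) M,  M(t, 0) = phi S(t),
#   M(t0, a) = g(a) = phi S(t0) e^{p a} on [0, t0],
# by first-order upwind discretisation on a lattice with da = dt. Cohorts are
# advected one age bin per step and decremented by their exact per-step
# survival; totals are accumulated by the rectangle rule.
upwind_age_dep_totals <- function(params, source, t0, t_end, dt = 0.25) {
  lam <- memdyn:::age_loss_rate(params)
  phi <- params$phi; p <- params$p
  S0 <- eval_source(source, t0)
  n_init <- floor(t0 / dt)
  ages <- (seq_len(n_init) - 0.5) * dt    # bin-centre ages at t0
  dens <- phi * S0 * exp(p * ages)
  times <- seq(t0, t_end, by = dt)
  totals <- numeric(length(times))
  totals[1] <- sum(dens) * dt
  for (i in seq_along(times)[-1]) {
    surv <- exp(-lam(ages) * dt)
    dens <- dens * surv
    # advect: every cohort ages by dt; a new age-0 cohort enters
    ages <- ages + dt
    ages <- c(0.5 * dt, ages)
    dens <- c(phi * eval_source(source, times[i]), dens)
    totals[i] <- sum(dens) * dt
  }
  data.frame(times = times, total = totals)
}

# High-precision survival of an age-a cohort under the sigmoid loss rate,
# via adaptive quadrature of the cumulative hazard.
survival_quadrature <- function(a, lam0, A, n) {
  H <- stats::integrate(function(s) lam0 / (1 + (s / A)^n), 0, a,
                        rel.tol = 1e-12, abs.tol = 0)$value
  exp(-H)
}

# Unprofiled joint log-likelihood with explicit error SDs,
#   ln L = -n ln(2 pi sigma_x) - n ln(2 pi sigma_y)
#          - SSRx / (2 sigma_x^2) - SSRy / (2 sigma_y^2).
# Its maximum over (sigma_x, sigma_y) equals the profiled form
# -(n/2) ln(SSRx SSRy) - 2n up to the sigma-independent constant
#   C(n) = n ln n - 2 n ln(2 pi) - n + 2n,
# which the profiled convention drops.
loglik_unprofiled <- function(ssr_x, ssr_y, n, sigma_x, sigma_y) {
  -n * log(2 * pi * sigma_x) - n * log(2 * pi * sigma_y) -
    ssr_x / (2 * sigma_x^2) - ssr_y / (2 * sigma_y^2)
}

profiling_constant <- function(n) n * log(n) - 2 * n * log(2 * pi) - n + 2 * n
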