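#' Facility-level cohort configuration
#'
#' Bundles the timing constants of a busulfan-chimera cohort: the baseline
#' host age `t0` from which all models are solved (the age at which donor
#' chimerism in memory can be taken as zero for the youngest-BMT mouse and
#' DP1 thymocyte chimerism has stabilised), the post-BMT lag `bmt_lag` before
#' chimerism observations are informative, and the reference age `t_star`
#' at which derived quantities (daily influx, proportion slow) are reported.
#'
#' Defaults follow the study design: `t0 = 66` d with a 26 d lag for the clean
#' facility, `t0 = 84` d with a 28 d lag for the dirty facility, and
#' `t_star = 140` d (20 weeks) for both.
#'
#' @param facility `"clean"` or `"dirty"`.
#' @param t0,bmt_lag,t_star optional overrides in days.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(facility = c("clean", "dirty"), t0 = NULL,
                          bmt_lag = NULL, t_star = 140) {
  facility <- match.arg(facility)
  t0 <- t0 %||% switch(facility, clean = 66, dirty = 84)
  bmt_lag <- bmt_lag %||% switch(facility, clean = 26, dirty = 28)
  stopifnot(t0 > 0, bmt_lag > 0, t_star > 0)
  structure(list(facility = facility, t0 = t0, bmt_lag = bmt_lag,
                 t_star = t_star),
            class = "cohort_config")
}

# ---------------------------------------------------------------------------
# model parameter containers
# ---------------------------------------------------------------------------

#' Model parameter containers
#'
#' Constructors for the unknowns of the four candidate models of memory
#' dynamics. All rates are per day, population sizes in cells.
#'
#' \describe{
#'   \item{homogeneous}{a single kinetically homogeneous pool:
#'     \eqn{dM/dt = \varphi S(t) - \lambda M}. `M0` is the pool size at the
#'     baseline age `t0`, `phi` the force of recruitment (per-capita daily
#'     recruitment from the source times any net expansion on entry), and
#'     `lam` the net loss rate (death plus onward differentiation minus
#'     self-renewal; may be negative).}
#'   \item{two-phase}{fast and slow subpopulations; cells enter the fast pool
#'     at rate \eqn{\varphi S(t)}, transition fast to slow at rate `gamma`,
#'     and the subsets are lost at `lam_fast` and `lam_slow`. The fast pool at
#'     `t0` is initialised in quasi-equilibrium with its source,
#'     \eqn{M_{fast}(t_0) = \varphi S(t_0) / (\lambda_{fast} + \gamma)},
#'     unless `Mfast0` is supplied (free-initialisation variant); the slow
#'     pool starts at `Mslow0`.}
#'   \item{age-dependent loss}{the loss rate depends on cell age `a` (time
#'     since the cell or its ancestor entered memory):
#'     \eqn{\lambda(a) = \lambda_0 / (1 + (a/A)^n)} (sigmoid, `n` in
#'     1, 2, 3, 5, 10) or \eqn{\lambda_0 e^{-a/A}} (`form = "exponential"`).
#'     The host cells present at `t0` have age density
#'     \eqn{g(a) = \varphi S(t_0) e^{p a}} on \eqn{[0, t_0]}, so `p` (any
#'     sign) and `phi` fix the initial pool size
#'     \eqn{\varphi S(t_0)(e^{p t_0} - 1)/p}.}
#'   \item{resistant}{a displaceable pool with homogeneous kinetics plus an
#'     incumbent host-only population of initial size `I0` that is never
#'     supplemented and is stable in number (its loss rate is fixed at 0).}
#' }
#'
#' @param M0,Mslow0,Mfast0,I0 initial population sizes (cells) at `t0`.
#' @param phi force of recruitment (per day).
#' @param lam,lam_fast,lam_slow net loss rates (per day, unconstrained sign).
#' @param gamma fast-to-slow transition rate (per day, non-negative).
#' @param p initial age-distribution exponent (per day, any sign).
#' @param lam0 net loss rate of newly made memory (per day).
#' @param A cell-age threshold in days (may be `Inf` for a constant loss rate).
#' @param n sigmoid exponent.
#' @param form `"sigmoid"` or `"exponential"` age-dependence of the loss rate.
#' @return a list with class `c("<model>_params", "model_params")`.
#' @name model_params
NULL

#' @rdname model_params
#' @export
homogeneous_params <- function(M0, phi, lam) {
  stopifnot(M0 > 0, phi >= 0)
  structure(list(M0 = M0, phi = phi, lam = lam),
            class = c("homogeneous_params", "model_params"))
}

#' @rdname model_params
#' @export
two_phase_params <- function(Mslow0, phi, lam_fast, lam_slow, gamma,
                             Mfast0 = NULL) {
  stopifnot(Mslow0 >= 0, phi >= 0, gamma >= 0)
  if (lam_fast + gamma <= 0)
    stop("two_phase_params: lam_fast + gamma must be positive (quasi-",
         "equilibrium initialisation of the fast subset is undefined)")
  structure(list(Mslow0 = Mslow0, phi = phi, lam_fast = lam_fast,
                 lam_slow = lam_slow, gamma = gamma, Mfast0 = Mfast0),
            class = c("two_phase_params", "model_params"))
}

#' @rdname model_params
#' @export
age_dep_params <- function(phi, p, lam0, A, n = 3,
                           form = c("sigmoid", "exponential")) {
  form <- match.arg(form)
  stopifnot(phi >= 0, A > 0)
  if (form == "sigmoid" && !(n %in% c(1, 2, 3, 5, 10)))
    stop("age_dep_params: n must be one of 1, 2, 3, 5, 10")
  structure(list(phi = phi, p = p, lam0 = lam0, A = A, n = n, form = form),
            class = c("age_dep_params", "model_params"))
}

#' @rdname model_params
#' @export
resistant_params <- function(M0, I0, phi, lam) {
  stopifnot(M0 >= 0, I0 >= 0, phi >= 0)
  structure(list(M0 = M0, I0 = I0, phi = phi, lam = lam, lam_I = 0),
            class = c("resistant_params", "model_params"))
}

model_name <- function(params) {
  sub("_params$", "", class(params)[1])
}

# loss rate as a function of cell age, and its cumulative integral
age_loss_rate <- function(params) {
  lam0 <- params$lam0; A <- params$A
  if (is.infinite(A)) return(function(a) rep(lam0, length(a)))
  if (params$form == "exponential") return(function(a) lam0 * exp(-a / A))
  n <- params$n
  function(a) lam0 / (1 + (a / A)^n)
}

# cumulative integral Lambda(a) = int_0^a lambda(s) ds as a fast function.
# Exponential form has a closed form; the sigmoid is integrated once on a
# fine grid (Simpson) and evaluated through a spline.
age_loss_cum <- function(params, a_max, h = 0.25) {
  lam0 <- params$lam0; A <- params$A
  if (is.infinite(A)) return(function(a) lam0 * a)
  if (params$form == "exponential")
    return(function(a) lam0 * A * (1 - exp(-a / A)))
  lam <- age_loss_rate(params)
  ag <- time_grid(0, max(a_max, 1), h)
  stats::splinefun(ag, cum_simpson(ag, lam(ag)), method = "natural")
}

# ---------------------------------------------------------------------------
# prediction engine
#
# All models share a "context": a fine time grid from t0, the source size S(t)
# on that grid, and a per-mouse matrix of normalised source chimerism
# (a function of time since each mouse's BMT). Totals are solved once on the
# grid (they do not depend on BMT age); chimerism is marched per mouse from
# its own start (BMT + lag), where it is zero by construction.
# ---------------------------------------------------------------------------

make_ctx <- function(source, chi_source, cfg, bmt_age, obs_age, h = 0.5) {
  stopifnot(length(bmt_age) == length(obs_age))
  t_start <- bmt_age + cfg$bmt_lag
  if (any(t_start < cfg$t0 - 1e-9))
    stop("BMT age + bmt_lag precedes the baseline age t0; t0 is defined as ",
         "the youngest BMT age plus the post-BMT lag")
  if (any(obs_age < t_start - 1e-9))
    stop("observations earlier than ", cfg$bmt_lag, " d post-BMT are not ",
         "modelled (donor chimerism has not stabilised)")
  tmax <- max(obs_age, cfg$t0 + 1)
  tt <- time_grid(cfg$t0, tmax, h)
  S <- eval_source(source, tt)
  if (any(!is.finite(S)) || any(S <= 0))
    stop("source size must be positive over the integration window")
  tau <- outer(tt, bmt_age, "-")
  tau[tau < 0] <- 0
  CHI <- matrix(eval_source(chi_source, as.vector(tau)), nrow = length(tt))
  list(tt = tt, S = S, CHI = CHI, t_start = t_start, obs_age = obs_age,
       bmt_age = bmt_age, cfg = cfg, source = source, chi_source = chi_source,
       h = h)
}

phi1r <- function(z) ifelse(abs(z) < 1e-8, 1 + z / 2, expm1(z) / z)

# closed-form homogeneous total when the source decays exponentially
homog_total_closed <- function(t, M0, phi, lam, S0, nu, t0) {
  d <- t - t0
  M0 * exp(-lam * d) + phi * S0 * d * exp(-lam * d) * phi1r((lam - nu) * d)
}

interp_grid <- function(tt, v, t) stats::approx(tt, v, xout = t)$y

predict_cohort <- function(params, ctx) UseMethod("predict_cohort")

#' @export
predict_cohort.homogeneous_params <- function(params, ctx) {
  tt <- ctx$tt; m <- length(tt)
  if (ctx$source$kind == "exp_decay" &&
      abs(ctx$source$t_ref - ctx$cfg$t0) < 1e-9) {
    p <- ctx$source$params
    Mg <- homog_total_closed(tt, params$M0, params$phi, params$lam,
                             p[["S0"]], p[["nu"]], ctx$cfg$t0)
    Mobs <- homog_total_closed(ctx$obs_age, params$M0, params$phi, params$lam,
                               p[["S0"]], p[["nu"]], ctx$cfg$t0)
  } else {
    Mg <- march_affine_path(tt, rep(params$lam, m), params$phi * ctx$S,
                            params$M0)
    Mobs <- interp_grid(tt, Mg, ctx$obs_age)
  }
  if (any(!is.finite(Mg)) || any(Mg <= 0)) return(NULL)
  k <- params$phi * ctx$S / Mg
  chi <- march_affine_at(tt, k, k * ctx$CHI, ctx$t_start, ctx$obs_age)
  list(total = Mobs, chi = chi, grid = list(tt = tt, total = Mg))
}

#' @export
predict_cohort.two_phase_params <- function(params, ctx) {
  tt <- ctx$tt; m <- length(tt)
  kf_rate <- params$lam_fast + params$gamma
  if (kf_rate <= 0) return(NULL)
  Mf0 <- params$Mfast0 %||% (params$phi * ctx$S[1] / kf_rate)
  Mf <- march_affine_path(tt, rep(kf_rate, m), params$phi * ctx$S, Mf0)
  Ms <- march_affine_path(tt, rep(params$lam_slow, m), params$gamma * Mf,
                          params$Mslow0)
  Mg <- Mf + Ms
  if (any(!is.finite(Mg)) || any(Mg <= 0) || any(Mf <= 0)) return(NULL)
  kf <- params$phi * ctx$S / Mf
  ks <- params$gamma * Mf / pmax(Ms, 1e-12)
  ch <- march_two_at(tt, kf, kf * ctx$CHI, ks, ctx$t_start, ctx$obs_age)
  Mf_obs <- interp_grid(tt, Mf, ctx$obs_age)
  Ms_obs <- interp_grid(tt, Ms, ctx$obs_age)
  chi <- (ch[, 1] * Mf_obs + ch[, 2] * Ms_obs) / (Mf_obs + Ms_obs)
  list(total = Mf_obs + Ms_obs, chi = chi,
       fast = Mf_obs, slow = Ms_obs, chi_fast = ch[, 1], chi_slow = ch[, 2],
       grid = list(tt = tt, total = Mg, fast = Mf, slow = Ms))
}

#' @export
predict_cohort.resistant_params <- function(params, ctx) {
  tt <- ctx$tt; m <- length(tt)
  Md <- march_affine_path(tt, rep(params$lam, m), params$phi * ctx$S,
                          params$M0)
  Mg <- Md + params$I0
  if (any(!is.finite(Mg)) || any(Mg <= 0)) return(NULL)
  # normalised donor numbers: d(Mdon/chiDP1)/dt = phi chi_sn(t) S(t) - lam *
  Dn <- march_affine_at(tt, rep(params$lam, m),
                        params$phi * ctx$S * ctx$CHI,
                        ctx$t_start, ctx$obs_age)
  Mobs <- interp_grid(tt, Mg, ctx$obs_age)
  list(total = Mobs, chi = Dn / Mobs,
       grid = list(tt = tt, total = Mg, displaceable = Md))
}

#' @export
predict_cohort.age_dep_params <- function(params, ctx) {
  t0 <- ctx$cfg$t0
  tmax <- max(ctx$obs_age)
  Lam <- age_loss_cum(params, tmax)
  gl <- gl_unit(64)
  u <- gl$x; w <- gl$w
  phi <- params$phi; p <- params$p
  S_t0 <- eval_source(ctx$source, t0)

  # initial host cohort: int_0^{t0} g(a) exp(-(Lam(a + d) - Lam(a))) da
  a0 <- u * t0                     # 64 nodes on [0, t0]
  g0 <- phi * S_t0 * exp(p * a0)
  L0 <- Lam(a0)
  d <- ctx$obs_age - t0
  E1 <- matrix(exp(L0 - Lam(as.vector(outer(a0, d, "+")))), nrow = 64)
  M_init <- t0 * as.vector(crossprod(w * g0, E1))

  # post-t0 influx: phi int_0^{d} S(t - a) exp(-Lam(a)) da
  Ad <- outer(u, d)                # cell-age nodes, 64 x n
  Snew <- matrix(eval_source(ctx$source,
                             as.vector(rep(ctx$obs_age, each = 64) - Ad)),
                 nrow = 64)
  E2 <- Snew * matrix(exp(-Lam(as.vector(Ad))), nrow = 64)
  M_new <- phi * d * as.vector(crossprod(w, E2))
  Mobs <- M_init + M_new
  if (any(!is.finite(Mobs)) || any(Mobs <= 0)) return(NULL)

  # normalised donor numbers per mouse: influx restricted to post-BMT entry
  L <- ctx$obs_age - ctx$t_start
  AL <- outer(u, L)                # 64 x n cell-age nodes on [0, t - T]
  t_entry <- rep(ctx$obs_age, each = 64) - AL
  tau_entry <- t_entry - rep(ctx$bmt_age, each = 64)
  integ <- eval_source(ctx$chi_source, as.vector(pmax(tau_entry, 0))) *
    eval_source(ctx$source, as.vector(t_entry)) * exp(-Lam(as.vector(AL)))
  Dn <- phi * L * as.vector(crossprod(w, matrix(integ, nrow = 64)))
  list(total = Mobs, chi = Dn / Mobs, grid = NULL)
}

# ---------------------------------------------------------------------------
# public solvers
# ---------------------------------------------------------------------------

solve_common <- function(params, source, chi_source, cfg, bmt_age, times, h,
                         extra = character()) {
  stopifnot(length(bmt_age) == 1)
  ctx <- make_ctx(source, chi_source, cfg, rep(bmt_age, length(times)),
                  times, h = h)
  pr <- predict_cohort(params, ctx)
  if (is.null(pr)) stop("model unsolvable at these parameters")
  out <- data.frame(times = times, total = pr$total, chi_norm = pr$chi)
  for (e in extra) out[[e]] <- pr[[e]]
  rownames(out) <- NULL
  attr(out, "model") <- model_name(params)
  class(out) <- c("memdyn_trajectory", "data.frame")
  out
}

#' Solve a memory-dynamics model for one mouse
#'
#' Produce the model-predicted total cell numbers and normalised donor
#' chimerism of a memory subset over host age, for a mouse that underwent BMT
#' at `bmt_age`. Totals are propagated from the facility baseline age
#' `cfg$t0`; normalised chimerism starts at zero at `bmt_age + cfg$bmt_lag`
#' (the point at which DP1 thymocyte chimerism has stabilised).
#'
#' `solve_homogeneous()` and `solve_two_phase()` accept `method = "ode"` to
#' integrate the coupled number/chimerism ODE system directly with a
#' stiff-capable adaptive solver (deSolve's lsoda, relative tolerance 1e-8) --
#' useful as a cross-check of the default semi-analytic integrator. The
#' age-dependent loss model is solved along characteristics with fixed-order
#' Gauss-Legendre quadrature (64 nodes) of the cell-age integrals.
#'
#' @param params model parameters from [homogeneous_params()] and friends.
#' @param source a [source_descriptor()] for the precursor population size
#'   \eqn{S(t)} (host age, days).
#' @param chi_source a [source_descriptor()] for the normalised source
#'   chimerism as a function of time since BMT.
#' @param cfg a [cohort_config()].
#' @param bmt_age host age at BMT in days.
#' @param times host ages (days) at which to report the trajectory; must not
#'   precede `bmt_age + cfg$bmt_lag`.
#' @param h grid step in days for the semi-analytic integrator.
#' @param method `"semianalytic"` (default) or `"ode"`.
#' @return a data frame with columns `times`, `total`, `chi_norm` (and, for
#'   the two-phase model, `fast`, `slow`, `chi_fast`, `chi_slow`).
#' @examples
#' cfg <- cohort_config("clean")
#' src <- source_descriptor("exp_decay", c(S0 = 2e7, nu = log(2) / 228), t_ref = 66)
#' chi <- source_descriptor("gen_logistic",
#'   c(lower = 0, upper = 0.9, rate = 0.035, midpoint = 70, shape = 1))
#' solve_homogeneous(homogeneous_params(M0 = 2.5e5, phi = 1e-3, lam = 0.01),
#'                   src, chi, cfg, bmt_age = 56, times = c(100, 200, 400))
#' @export
solve_homogeneous <- function(params, source, chi_source, cfg, bmt_age, times,
                              h = 0.25, method = c("semianalytic", "ode")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "homogeneous_params"))
  if (method == "ode")
    return(solve_homog_ode(params, source, chi_source, cfg, bmt_age, times))
  solve_common(params, source, chi_source, cfg, bmt_age, times, h)
}

#' @rdname solve_homogeneous
#' @export
solve_two_phase <- function(params, source, chi_source, cfg, bmt_age, times,
                            h = 0.25, method = c("semianalytic", "ode")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "two_phase_params"))
  if (method == "ode")
    return(solve_two_phase_ode(params, source, chi_source, cfg, bmt_age, times))
  solve_common(params, source, chi_source, cfg, bmt_age, times, h,
               extra = c("fast", "slow", "chi_fast", "chi_slow"))
}

#' @rdname solve_homogeneous
#' @export
solve_age_dep <- function(params, source, chi_source, cfg, bmt_age, times,
                          h = 0.25) {
  stopifnot(inherits(params, "age_dep_params"))
  solve_common(params, source, chi_source, cfg, bmt_age, times, h)
}

#' @rdname solve_homogeneous
#' @export
solve_resistant <- function(params, source, chi_source, cfg, bmt_age, times,
                            h = 0.25) {
  stopifnot(inherits(params, "resistant_params"))
  solve_common(params, source, chi_source, cfg, bmt_age, times, h)
}

# deSolve reference routes ---------------------------------------------------

solve_homog_ode <- function(params, source, chi_source, cfg, bmt_age, times,
                            rtol = 1e-8) {
  t_start <- bmt_age + cfg$bmt_lag
  if (any(times < t_start - 1e-9)) stop("times must be >= bmt_age + bmt_lag")
  deriv_tot <- function(t, y, parms) {
    list(params$phi * eval_source(source, t) - params$lam * y[1])
  }
  MT <- deSolve::lsoda(c(M = params$M0), c(cfg$t0, t_start), deriv_tot,
                       rtol = rtol, atol = 1e-2)
  M_T <- MT[nrow(MT), "M"]
  deriv <- function(t, y, parms) {
    S <- eval_source(source, t)
    chs <- eval_source(chi_source, max(t - bmt_age, 0))
    dM <- params$phi * S - params$lam * y[1]
    dchi <- params$phi * S / y[1] * (chs - y[2])
    list(c(dM, dchi))
  }
  tt <- sort(unique(c(t_start, times)))
  out <- deSolve::lsoda(c(M = unname(M_T), chi = 0), tt, deriv,
                        rtol = rtol, atol = c(1e-2, 1e-10))
  out <- as.data.frame(out)[match(times, tt), ]
  res <- data.frame(times = times, total = out$M, chi_norm = out$chi)
  attr(res, "model") <- "homogeneous"
  class(res) <- c("memdyn_trajectory", "data.frame")
  res
}

solve_two_phase_ode <- function(params, source, chi_source, cfg, bmt_age,
                                times, rtol = 1e-8) {
  t_start <- bmt_age + cfg$bmt_lag
  if (any(times < t_start - 1e-9)) stop("times must be >= bmt_age + bmt_lag")
  kf_rate <- params$lam_fast + params$gamma
  Mf0 <- params$Mfast0 %||% (params$phi * eval_source(source, cfg$t0) / kf_rate)
  deriv_tot <- function(t, y, parms) {
    S <- eval_source(source, t)
    list(c(params$phi * S - kf_rate * y[1],
           params$gamma * y[1] - params$lam_slow * y[2]))
  }
  MT <- deSolve::lsoda(c(Mf = unname(Mf0), Ms = params$Mslow0),
                       c(cfg$t0, t_start), deriv_tot, rtol = rtol, atol = 1e-2)
  yT <- MT[nrow(MT), c("Mf", "Ms")]
  deriv <- function(t, y, parms) {
    S <- eval_source(source, t)
    chs <- eval_source(chi_source, max(t - bmt_age, 0))
    dMf <- params$phi * S - kf_rate * y[1]
    dMs <- params$gamma * y[1] - params$lam_slow * y[2]
    dchf <- params$phi * S / y[1] * (chs - y[3])
    dchs <- params$gamma * y[1] / max(y[2], 1e-12) * (y[3] - y[4])
    list(c(dMf, dMs, dchf, dchs))
  }
  tt <- sort(unique(c(t_start, times)))
  out <- deSolve::lsoda(c(Mf = unname(yT[1]), Ms = unname(yT[2]),
                          chf = 0, chs = 0), tt, deriv,
                        rtol = rtol, atol = c(1e-2, 1e-2, 1e-10, 1e-10))
  out <- as.data.frame(out)[match(times, tt), ]
  chi <- (out$chf * out$Mf + out$chs * out$Ms) / (out$Mf + out$Ms)
  res <- data.frame(times = times, total = out$Mf + out$Ms, chi_norm = chi,
                    fast = out$Mf, slow = out$Ms, chi_fast = out$chf,
                    chi_slow = out$chs)
  attr(res, "model") <- "two_phase"
  class(res) <- c("memdyn_trajectory", "data.frame")
  res
}

# ---------------------------------------------------------------------------
# derived quantities
# ---------------------------------------------------------------------------

half_life <- function(lam) {
  # undefined (reported as NA) for non-positive net loss: a stable or growing
  # clone has no half-life
  ifelse(is.finite(lam) & lam > 0, log(2) / lam, NA_real_)
}

#' Derived quantities of a fitted model
#'
#' Computes the field's standard summaries from a model's parameters: clonal
#' half-lives \eqn{\ln(2)/\lambda} for each applicable loss rate (reported as
#' `NA` when \eqn{\lambda \le 0}), the daily cell influx from the source at
#' the reference age `cfg$t_star` (\eqn{\varphi S(t^*)}), the percentage of
#' fast memory surviving to transition to the slow pool
#' (\eqn{100\gamma/(\lambda_{fast} + \gamma)}) and the proportion of the pool
#' that is slow at `t_star` (two-phase model), and the clonal half-life as a
#' function of cell age (age-dependent loss model).
#'
#' @param params a `model_params` object.
#' @param source the source-size [source_descriptor()].
#' @param cfg a [cohort_config()].
#' @param age_grid cell ages (days) for the age-dependent half-life curve.
#' @return a named list of scalars; the age-dependent model additionally
#'   carries a `half_life_curve` data frame.
#' @export
derived_quantities <- function(params, source, cfg,
                               age_grid = c(0, 7, 14, 30, 60, 90, 150, 210,
                                            300, 450)) {
  UseMethod("derived_quantities")
}

#' @export
derived_quantities.homogeneous_params <- function(params, source, cfg, ...) {
  list(half_life = half_life(params$lam),
       influx_tstar = params$phi * eval_source(source, cfg$t_star))
}

#' @export
derived_quantities.resistant_params <- function(params, source, cfg, ...) {
  list(half_life = half_life(params$lam),
       influx_tstar = params$phi * eval_source(source, cfg$t_star))
}

#' @export
derived_quantities.two_phase_params <- function(params, source, cfg, ...) {
  tt <- time_grid(cfg$t0, max(cfg$t_star, cfg$t0 + 1), 0.25)
  S <- eval_source(source, tt)
  kf_rate <- params$lam_fast + params$gamma
  Mf0 <- params$Mfast0 %||% (params$phi * S[1] / kf_rate)
  Mf <- march_affine_path(tt, rep(kf_rate, length(tt)), params$phi * S, Mf0)
  Ms <- march_affine_path(tt, rep(params$lam_slow, length(tt)),
                          params$gamma * Mf, params$Mslow0)
  i <- length(tt)
  list(half_life_fast = half_life(params$lam_fast),
       half_life_slow = half_life(params$lam_slow),
       pct_to_slow = 100 * params$gamma / (params$lam_fast + params$gamma),
       prop_slow_tstar = Ms[i] / (Mf[i] + Ms[i]),
       influx_tstar = params$phi * eval_source(source, cfg$t_star))
}

#' @export
derived_quantities.age_dep_params <- function(params, source, cfg,
                                              age_grid = c(0, 7, 14, 30, 60,
                                                           90, 150, 210, 300,
                                                           450)) {
  lam <- age_loss_rate(params)
  list(half_life_new = half_life(params$lam0),
       influx_tstar = params$phi * eval_source(source, cfg$t_star),
       half_life_curve = data.frame(age = age_grid,
                                    half_life = half_life(lam(age_grid))))
}
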