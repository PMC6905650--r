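# Joint maximum-likelihood fitting of count + chimerism timecourses.
#
# Counts enter the likelihood on the log scale and normalised chimerism on the
# arcsin-square-root scale; both transformed variables are assumed to carry
# iid Gaussian errors with constant (unknown) variances. Profiling out the two
# error variances analytically reduces the log-likelihood to
#   ln L = -(n/2) ln(SSRx * SSRy) - 2n,
# with n the number of mice (each mouse contributes one count and one
# chimerism measurement for the subset under study).

SSR_FLOOR <- 1e-30

K_PER_FACILITY <- c(homogeneous = 3, two_phase = 5, age_dep = 4, resistant = 4)

#' Transform observations to the fitting scales
#'
#' Counts are log-transformed and normalised chimerism is
#' arcsin-square-root-transformed. Records with non-positive counts are
#' rejected with a warning; chimerism values outside \eqn{[0, 1]} (the DP1
#' normalisation can overshoot 1 slightly) are clipped with a warning.
#'
#' @param counts total cell counts (cells).
#' @param chi normalised donor chimerism values.
#' @return a data frame with columns `x` (= `log(count)`) and `y`
#'   (= `asin(sqrt(chi))`, radians, in \eqn{[0, \pi/2]}); an attribute
#'   `n_rejected` records dropped rows and `n_clipped` clipped chimerism
#'   values.
#' @export
transform_observations <- function(counts, chi) {
  stopifnot(length(counts) == length(chi))
  bad <- !is.finite(counts) | counts <= 0 | !is.finite(chi)
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive counts or non-finite ",
            "chimerism rejected")
    counts <- counts[!bad]; chi <- chi[!bad]
  }
  clipped <- chi < 0 | chi > 1
  if (any(clipped)) {
    warning(sum(clipped), " chimerism value(s) outside [0, 1] clipped ",
            "before transforming")
    chi <- clip(chi, 0, 1)
  }
  out <- data.frame(x = log(counts), y = asin(sqrt(chi)))
  attr(out, "n_rejected") <- sum(bad)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

loglik_from_ssr <- function(ssr_x, ssr_y, n) {
  -(n / 2) * log(max(ssr_x, SSR_FLOOR) * max(ssr_y, SSR_FLOOR)) - 2 * n
}

#' Profiled joint log-likelihood of a parameter set
#'
#' Evaluates \eqn{\ln L = -(n/2)\ln(SSR_x \times SSR_y) - 2n}, the joint
#' Gaussian log-likelihood of the transformed counts and chimerism values
#' after substituting the maximum-likelihood estimates
#' \eqn{\hat\sigma_x^2 = SSR_x/n}, \eqn{\hat\sigma_y^2 = SSR_y/n} of the two
#' error variances. Returns `-Inf` (a rejected point) if the model cannot be
#' solved at `params`.
#'
#' @param params a `model_params` object.
#' @param data a timecourse data frame with columns `bmt_age_days`,
#'   `obs_age_days`, `count`, `chi_norm` (one row per mouse; see
#'   [extract_timecourse()]).
#' @param source,chi_source source [source_descriptor()]s.
#' @param cfg a [cohort_config()].
#' @param h integrator grid step (days).
#' @return the profiled log-likelihood (scalar).
#' @export
profiled_loglik <- function(params, data, source, chi_source, cfg, h = 0.5) {
  ctx <- make_ctx(source, chi_source, cfg, data$bmt_age_days,
                  data$obs_age_days, h = h)
  tr <- transform_observations(data$count, data$chi_norm)
  pr <- predict_cohort(params, ctx)
  if (is.null(pr)) return(-Inf)
  X <- log(pr$total)
  Y <- asin(sqrt(clip(pr$chi, 0, 1)))
  n <- nrow(tr)
  loglik_from_ssr(sum((tr$x - X)^2), sum((tr$y - Y)^2), n)
}

# ---------------------------------------------------------------------------
# model registry: parameterisation of each model for optimisation.
# Positive-constrained quantities are optimised on the log scale; net loss
# rates and the age-distribution exponent p are unconstrained.
# ---------------------------------------------------------------------------

# The two-phase model in quasi-equilibrium mode is optimised in terms of the
# fast-pool size at t0 (logMfast0) instead of log(phi): the data pin down the
# pool sizes directly while phi and lam_fast are strongly correlated along a
# likelihood ridge, so this coordinate system is far better conditioned.
# phi = Mfast0 (lam_fast + gamma) / S(t0) is recovered exactly.
model_def <- function(model, init = "qe", n = 3, form = "sigmoid",
                      S_t0 = NULL) {
  switch(model,
    homogeneous = list(
      theta_names = c("logM0", "logphi", "lam"),
      to_params = function(th) homogeneous_params(exp(th[1]), exp(th[2]), th[3]),
      from_params = function(p) c(log(p$M0), log(p$phi), p$lam),
      center = function(hint) c(log(hint$mx), log(0.05 * hint$mx / hint$S_mid),
                                0.03),
      draw = function(center) c(center[1] + runif(1, -1.5, 1.5),
                                center[2] + runif(1, -4.6, 4.6),
                                runif(1, -0.02, 0.4))),
    two_phase = if (init == "free") list(
      theta_names = c("logMslow0", "logphi", "lam_fast", "lam_slow", "loggamma",
                      "logMfast0"),
      to_params = function(th) two_phase_params(exp(th[1]), exp(th[2]), th[3],
        th[4], exp(th[5]), Mfast0 = exp(th[6])),
      from_params = function(p) c(log(p$Mslow0), log(p$phi), p$lam_fast,
        p$lam_slow, log(p$gamma), log(p$Mfast0)),
      center = function(hint) c(log(hint$mx / 2),
                                log(0.2 * hint$mx / (2 * hint$S_mid)),
                                0.2, 5e-3, log(0.01), log(hint$mx / 2)),
      draw = function(center) c(center[1] + runif(1, -2, 1),
                                center[2] + runif(1, -4.6, 4.6),
                                runif(1, 0.02, 0.6),
                                runif(1, -0.005, 0.02),
                                center[5] + runif(1, -2.3, 2.3),
                                center[6] + runif(1, -2, 1))
    ) else list(
      theta_names = c("logMslow0", "logMfast0", "lam_fast", "lam_slow",
                      "loggamma"),
      to_params = function(th) {
        g <- exp(th[5])
        if (th[3] + g <= 0) stop("lam_fast + gamma must be positive")
        two_phase_params(exp(th[1]), exp(th[2]) * (th[3] + g) / S_t0, th[3],
                         th[4], g)
      },
      from_params = function(p) c(log(p$Mslow0),
                                  log(p$phi * S_t0 / (p$lam_fast + p$gamma)),
                                  p$lam_fast, p$lam_slow, log(p$gamma)),
      center = function(hint) c(log(hint$mx / 2), log(hint$mx / 2),
                                0.2, 5e-3, log(0.01)),
      draw = function(center) c(center[1] + runif(1, -2, 1),
                                center[2] + runif(1, -2, 1),
                                runif(1, 0.02, 0.6),
                                runif(1, -0.005, 0.02),
                                center[5] + runif(1, -2.3, 2.3))),
    age_dep = list(
      theta_names = c("logphi", "p", "lam0", "logA"),
      to_params = function(th) age_dep_params(exp(th[1]), th[2], th[3],
                                              exp(th[4]), n = n, form = form),
      from_params = function(p) c(log(p$phi), p$p, p$lam0, log(p$A)),
      center = function(hint) c(log(hint$mx / (hint$S_t0 * hint$t0)),
                                -0.01, 0.02, log(100)),
      draw = function(center) c(center[1] + runif(1, -4.6, 4.6),
                                runif(1, -0.06, 0.03),
                                runif(1, 0.001, 0.05),
                                log(100) + runif(1, -1.5, 1.5))),
    resistant = list(
      theta_names = c("logM0", "logI0", "logphi", "lam"),
      to_params = function(th) resistant_params(exp(th[1]), exp(th[2]),
                                                exp(th[3]), th[4]),
      from_params = function(p) c(log(p$M0), log(p$I0), log(p$phi), p$lam),
      center = function(hint) c(log(hint$mx / 2), log(hint$mx / 2),
                                log(0.05 * hint$mx / (2 * hint$S_mid)), 0.05),
      draw = function(center) c(center[1] + runif(1, -1.5, 1.5),
                                center[2] + runif(1, -3, 1),
                                center[3] + runif(1, -4.6, 4.6),
                                runif(1, -0.02, 0.4))),
    stop("unknown model '", model, "'")
  )
}

# Precomputed, parameter-independent quadrature node data for the
# age-dependent loss objective: Gauss-Legendre nodes over the initial-cohort
# ages, per-observation cell-age nodes, and the source size / chimerism
# evaluated at every entry-time node.
age_dep_nodes <- function(ctx) {
  gl <- gl_unit(64)
  u <- gl$x; w <- gl$w
  t0 <- ctx$cfg$t0
  nk <- length(u)
  d <- ctx$obs_age - t0
  a0 <- u * t0
  Ad <- outer(u, d)
  Snew <- matrix(eval_source(ctx$source,
                             as.vector(rep(ctx$obs_age, each = nk) - Ad)),
                 nrow = nk)
  L <- ctx$obs_age - ctx$t_start
  AL <- outer(u, L)
  t_entry <- rep(ctx$obs_age, each = nk) - AL
  tau_entry <- pmax(t_entry - rep(ctx$bmt_age, each = nk), 0)
  list(gw = w, a0 = a0, d = d, Snew = Snew, Ad = Ad, L = L,
       SN = matrix(eval_source(ctx$source, as.vector(t_entry)), nrow = nk),
       CN = matrix(eval_source(ctx$chi_source, as.vector(tau_entry)),
                   nrow = nk),
       AL = AL, S_t0 = eval_source(ctx$source, t0), t0 = t0)
}

# Compiled profiled-negative-log-likelihood closure for a model given fixed
# transformed data (x, y). The R predict_cohort() path is the reference; the
# suite checks the two against each other.
make_negll <- function(model, ctx, x, y, init = "qe", nexp = 3,
                       form = "sigmoid") {
  tt <- ctx$tt; S <- ctx$S; CHI <- ctx$CHI
  ts <- ctx$t_start; te <- ctx$obs_age
  switch(model,
    homogeneous = function(th)
      negll_homog_cpp(c(exp(th[1]), exp(th[2]), th[3]), tt, S, CHI, ts, te,
                      x, y),
    two_phase = if (init == "free") function(th)
      negll_two_phase_cpp(c(exp(th[1]), exp(th[2]), th[3], th[4], exp(th[5]),
                            exp(th[6])),
                          tt, S, CHI, ts, te, x, y)
    else function(th) {
      g <- exp(th[5])
      negll_two_phase_cpp(c(exp(th[1]), exp(th[2]) * (th[3] + g) / S[1],
                            th[3], th[4], g, NA_real_),
                          tt, S, CHI, ts, te, x, y)
    },
    resistant = function(th)
      negll_resistant_cpp(c(exp(th[1]), exp(th[2]), exp(th[3]), th[4]),
                          tt, S, CHI, ts, te, x, y),
    age_dep = {
      nd <- age_dep_nodes(ctx)
      function(th)
        negll_age_dep_cpp(c(exp(th[1]), th[2], th[3], exp(th[4])),
                          as.integer(nexp), identical(form, "exponential"),
                          nd$t0, nd$S_t0, nd$gw, nd$a0, nd$d, nd$Snew, nd$Ad,
                          nd$L, nd$SN, nd$CN, nd$AL, x, y)
    },
    stop("unknown model '", model, "'"))
}

# numeric parameter vector for bootstrap summaries
params_to_vector <- function(params) {
  keep <- vapply(params, function(v) is.numeric(v) && length(v) == 1,
                 logical(1))
  unlist(params[keep])
}

#' Fit a memory-dynamics model by profiled maximum likelihood
#'
#' Maximises the profiled joint log-likelihood of the log counts and
#' arcsin-square-root chimerism values with respect to the model parameters,
#' using a fixed multi-start schedule: the first start is a data-driven
#' heuristic, the remaining `starts - 1` are log-uniform perturbations of it
#' spanning roughly four orders of magnitude for positive parameters (the
#' likelihood surfaces, especially for the age-dependent loss model, are
#' multimodal). Each start is optimised with Nelder-Mead; the best start is
#' refined with BFGS. Fully reproducible given `seed`.
#'
#' @param data timecourse data frame (columns `bmt_age_days`, `obs_age_days`,
#'   `count`, `chi_norm`; one row per mouse), e.g. from
#'   [extract_timecourse()].
#' @param model one of `"homogeneous"`, `"two_phase"`, `"age_dep"`,
#'   `"resistant"`.
#' @param source,chi_source source [source_descriptor()]s (size over host age;
#'   normalised chimerism over time post-BMT).
#' @param cfg a [cohort_config()].
#' @param starts number of multi-starts (>= 1).
#' @param seed seed for the multi-start schedule.
#' @param h integrator grid step in days.
#' @param init two-phase initialisation: `"qe"` (fast subset in
#'   quasi-equilibrium with its source at `t0`; the default) or `"free"`
#'   (fast pool size at `t0` is an extra free parameter).
#' @param n,form sigmoid exponent / functional form of the age-dependent loss
#'   rate (age-dependent model only).
#' @param control list with optional elements `maxit_nm`, `maxit_bfgs`,
#'   `reltol`.
#' @return an object of class `memdyn_fit`: maximum-likelihood `params`, the
#'   profiled `loglik`, sums of squared residuals (`ssr_x`, `ssr_y`), profiled
#'   error SDs (`sigma_x`, `sigma_y`), fitted values, residuals, and
#'   bookkeeping (`n_obs`, `converged`, `n_starts_used`).
#' @export
fit_model <- function(data, model = c("homogeneous", "two_phase", "age_dep",
                                      "resistant"),
                      source, chi_source, cfg, starts = 20, seed = 1,
                      h = 0.5, init = c("qe", "free"), n = 3,
                      form = c("sigmoid", "exponential"), control = list()) {
  model <- match.arg(model)
  init <- match.arg(init)
  form <- match.arg(form)
  ctx <- make_ctx(source, chi_source, cfg, data$bmt_age_days,
                  data$obs_age_days, h = h)
  def <- model_def(model, init = init, n = n, form = form, S_t0 = ctx$S[1])
  npar <- length(def$theta_names)
  if (nrow(data) < npar + 2)
    stop("fit_model: need at least ", npar + 2, " mice for the ", model,
         " model")
  stopifnot(starts >= 1)
  maxit_nm <- control$maxit_nm %||% 600
  maxit_bfgs <- control$maxit_bfgs %||% 200
  reltol <- control$reltol %||% 1e-10
  tr <- transform_observations(data$count, data$chi_norm)
  nobs <- nrow(tr)

  negll <- make_negll(model, ctx, tr$x, tr$y, init = init, nexp = n,
                      form = form)

  hint <- list(mx = exp(mean(tr$x)),
               S_mid = eval_source(source, stats::median(data$obs_age_days)),
               S_t0 = ctx$S[1], t0 = cfg$t0)
  center <- def$center(hint)
  set.seed(seed)
  start_list <- c(list(center),
                  lapply(seq_len(starts - 1), function(i) def$draw(center)))

  best <- NULL; n_used <- 0L
  for (th0 in start_list) {
    o <- try(stats::optim(th0, negll, method = "Nelder-Mead",
                          control = list(maxit = maxit_nm, reltol = reltol)),
             silent = TRUE)
    if (inherits(o, "try-error") || !is.finite(o$value) || o$value >= 1e10)
      next
    n_used <- n_used + 1L
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("fit_model: no start converged for the ", model, " model")
  ref <- try(stats::optim(best$par, negll, method = "BFGS",
                          control = list(maxit = maxit_bfgs,
                                         reltol = 1e-12)), silent = TRUE)
  if (!inherits(ref, "try-error") && is.finite(ref$value) &&
      ref$value <= best$value) best <- ref

  params <- def$to_params(best$par)
  pr <- predict_cohort(params, ctx)
  X <- log(pr$total)
  Y <- asin(sqrt(clip(pr$chi, 0, 1)))
  ssr_x <- sum((tr$x - X)^2)
  ssr_y <- sum((tr$y - Y)^2)
  structure(list(
    model = model, params = params, theta = best$par,
    theta_names = def$theta_names,
    loglik = loglik_from_ssr(ssr_x, ssr_y, nobs),
    ssr_x = ssr_x, ssr_y = ssr_y,
    sigma_x = sqrt(ssr_x / nobs), sigma_y = sqrt(ssr_y / nobs),
    n_obs = nobs, converged = TRUE, n_starts_used = n_used,
    fitted = data.frame(X = X, Y = Y),
    resid = data.frame(rx = tr$x - X, ry = tr$y - Y),
    transformed = tr, data = data,
    source = source, chi_source = chi_source, cfg = cfg, h = h,
    init = init, n = n, form = form, seed = seed
  ), class = "memdyn_fit")
}

#' @export
print.memdyn_fit <- function(x, ...) {
  cat("<memdyn_fit>", x$model, "model,", x$n_obs, "mice,",
      "lnL =", format(x$loglik, digits = 6), "\n")
  pv <- params_to_vector(x$params)
  print(signif(pv, 3))
  cat("sigma_x =", signif(x$sigma_x, 3), " sigma_y =", signif(x$sigma_y, 3),
      "\n")
  invisible(x)
}

#' Corrected Akaike information criterion
#'
#' \eqn{AICc = -2 \ln L + 2K + 2K(K+1)/(N - K - 1)}, where `K` is the total
#' number of estimated parameters and `N` the total number of observations
#' (two per mouse: a count and a chimerism value).
#'
#' @param loglik combined maximised log-likelihood.
#' @param K total parameter count.
#' @param N total observation count; must exceed `K + 1`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, K, N) {
  if (N <= K + 1) stop("aicc undefined: N must exceed K + 1")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (N - K - 1)
}

#' Fit and rank every model/source combination
#'
#' Fits each candidate model with each candidate source to the clean-facility
#' data (and the dirty-facility data when supplied), combines the facility
#' log-likelihoods (\eqn{\ln L_{combined} = \ln L_{clean} + \ln L_{dirty}};
#' parameters are estimated separately per facility so `K` doubles), and ranks
#' the combinations by AICc. Differences of 10 or more are conventionally
#' considered strong evidence against the higher-AICc model.
#'
#' @param data_clean,data_dirty timecourse data frames (see [fit_model()]);
#'   `data_dirty` may be `NULL` for a single-facility comparison.
#' @param sources_clean,sources_dirty named lists of source options; each
#'   element is a `list(size = <descriptor>, chi = <descriptor>)` and its name
#'   (e.g. `"naive"`, `"tcm"`) labels the source population.
#' @param models character vector of models to include.
#' @param cfg_clean,cfg_dirty [cohort_config()]s.
#' @param starts,seed,h passed to [fit_model()].
#' @return a data frame of class `memdyn_comparison` with one row per
#'   (model, source): `K`, `N`, `loglik`, `aicc`, `delta_aicc` (0 for the
#'   best-supported combination), `converged`; fitted objects are attached as
#'   attribute `fits`.
#' @export
compare_models <- function(data_clean, data_dirty = NULL, sources_clean,
                           sources_dirty = NULL,
                           models = c("homogeneous", "two_phase", "age_dep",
                                      "resistant"),
                           cfg_clean = cohort_config("clean"),
                           cfg_dirty = cohort_config("dirty"),
                           starts = 20, seed = 1, h = 0.5) {
  stopifnot(length(sources_clean) >= 1, !is.null(names(sources_clean)))
  if (!is.null(data_dirty) && is.null(sources_dirty))
    stop("sources_dirty must be supplied with data_dirty")
  grid <- expand.grid(model = models, source = names(sources_clean),
                      stringsAsFactors = FALSE)
  nfac <- 1L + !is.null(data_dirty)
  N <- 2L * nrow(data_clean) + if (is.null(data_dirty)) 0L else
    2L * nrow(data_dirty)
  fits <- vector("list", nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mod <- grid$model[i]; src <- grid$source[i]
    lnl <- 0; ok <- TRUE; fl <- list()
    fc <- try(fit_model(data_clean, mod, sources_clean[[src]]$size,
                        sources_clean[[src]]$chi, cfg_clean,
                        starts = starts, seed = seed, h = h), silent = TRUE)
    if (inherits(fc, "try-error")) ok <- FALSE else {
      lnl <- lnl + fc$loglik; fl$clean <- fc
    }
    if (ok && !is.null(data_dirty)) {
      fd <- try(fit_model(data_dirty, mod, sources_dirty[[src]]$size,
                          sources_dirty[[src]]$chi, cfg_dirty,
                          starts = starts, seed = seed, h = h), silent = TRUE)
      if (inherits(fd, "try-error")) ok <- FALSE else {
        lnl <- lnl + fd$loglik; fl$dirty <- fd
      }
    }
    K <- unname(K_PER_FACILITY[mod]) * nfac
    fits[[i]] <<- fl
    data.frame(model = mod, source = src, K = K, N = N,
               loglik = if (ok) lnl else NA_real_,
               aicc = if (ok) aicc(lnl, K, N) else NA_real_,
               converged = ok)
  })
  out <- do.call(rbind, rows)
  out$delta_aicc <- out$aicc - min(out$aicc, na.rm = TRUE)
  out <- out[order(out$aicc), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("memdyn_comparison", "data.frame")
  out
}

#' Residual-bootstrap confidence intervals
#'
#' Resamples the (x-residual, y-residual) pairs jointly with replacement, adds
#' them to the fitted predictions on the transformed scales, refits the model
#' to each replicate (warm-started from the original optimum plus a few
#' perturbed starts), and returns type-7 (2.5%, 97.5%) quantiles of the
#' replicate estimates for every parameter and derived quantity.
#'
#' @param fit a [fit_model()] result.
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed.
#' @param starts_extra perturbed warm starts per replicate in addition to the
#'   original optimum.
#' @param maxit Nelder-Mead iteration cap per replicate refit.
#' @param refit `"nm"` (Nelder-Mead then BFGS polish; default, robust for the
#'   ridge-prone two-phase and age-dependent models) or `"bfgs"`
#'   (quasi-Newton only; fast and adequate for the well-conditioned
#'   homogeneous and resistant models).
#' @param h integrator grid step for replicate refits (defaults to the fit's).
#' @return a list with elements `ci` (matrix with rows = quantities, columns
#'   `lo`, `hi`), `estimates` (point estimates for the same quantities),
#'   `replicates` (data frame of per-replicate values) and `n_failed`.
#'   A warning is issued if more than 10% of replicates fail to refit.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000, seed = 1, starts_extra = 3,
                         maxit = 300, refit = c("nm", "bfgs"), h = NULL) {
  refit <- match.arg(refit)
  stopifnot(inherits(fit, "memdyn_fit"), isTRUE(fit$converged))
  h <- h %||% fit$h
  ctx <- make_ctx(fit$source, fit$chi_source, fit$cfg,
                  fit$data$bmt_age_days, fit$data$obs_age_days, h = h)
  def <- model_def(fit$model, init = fit$init, n = fit$n, form = fit$form,
                   S_t0 = ctx$S[1])
  nobs <- fit$n_obs
  X <- fit$fitted$X; Y <- fit$fitted$Y
  # fitted residuals are deflated by the degrees of freedom the model
  # consumes; inflate by the standard sqrt(n / (n - p)) factor before
  # resampling so replicate noise has the right scale
  infl <- sqrt(nobs / (nobs - length(fit$theta)))
  rx <- fit$resid$rx * infl
  ry <- fit$resid$ry * infl
  qty <- function(params) {
    dv <- derived_quantities(params, fit$source, fit$cfg)
    dv <- dv[vapply(dv, function(v) is.numeric(v) && length(v) == 1,
                    logical(1))]
    c(params_to_vector(params), unlist(dv))
  }
  point <- qty(fit$params)
  # data-driven heuristic start (as used by fit_model): when the optimum sits
  # on a likelihood ridge, replicates need a start on the other side of it
  hint <- list(mx = exp(mean(X)),
               S_mid = eval_source(fit$source,
                                   stats::median(fit$data$obs_age_days)),
               S_t0 = ctx$S[1], t0 = fit$cfg$t0)
  th_center <- def$center(hint)

  negll_for <- function(xb, yb) {
    make_negll(fit$model, ctx, xb, yb, init = fit$init, nexp = fit$n,
               form = fit$form)
  }

  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, length(point),
                 dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nobs, nobs, replace = TRUE)
    f <- negll_for(X + rx[idx], Y + ry[idx])
    best <- NULL
    for (s in 0:starts_extra) {
      th0 <- if (s == 0) fit$theta else if (s == 1) th_center else
        fit$theta + rnorm(length(fit$theta), 0, 0.15)
      o <- if (refit == "nm")
        try(stats::optim(th0, f, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-9)),
            silent = TRUE)
      else
        try(stats::optim(th0, f, method = "BFGS",
                         control = list(maxit = maxit, reltol = 1e-10)),
            silent = TRUE)
      if (inherits(o, "try-error") || !is.finite(o$value) || o$value >= 1e10)
        next
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) { n_failed <- n_failed + 1L; next }
    if (refit == "nm") {
      # quasi-Newton polish: replicate optima can sit along likelihood ridges
      # that the simplex traverses slowly
      ref <- try(stats::optim(best$par, f, method = "BFGS",
                              control = list(maxit = 60, reltol = 1e-10)),
                 silent = TRUE)
      if (!inherits(ref, "try-error") && is.finite(ref$value) &&
          ref$value <= best$value) best <- ref
    }
    reps[b, ] <- qty(def$to_params(best$par))
  }
  if (n_failed > 0.1 * n_boot)
    warning(n_failed, " of ", n_boot, " bootstrap replicates failed to refit")
  keep <- !is.na(reps[, 1])
  ci <- t(apply(reps[keep, , drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975), type = 7, na.rm = TRUE))
  colnames(ci) <- c("lo", "hi")
  list(ci = ci, estimates = point,
       replicates = as.data.frame(reps[keep, , drop = FALSE]),
       n_failed = n_failed)
}
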