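# Early-life predictions: run an adult-fitted model forward from age 5 d
# (where young-mouse data begin) using an empirical young-mouse source curve,
# optionally with a fold-correction to the force of recruitment over the
# first 11 weeks of life.

#' Define an ontogeny scenario
#'
#' Bundles what is needed to predict the early-life accumulation of a memory
#' subset: the adult-fitted model parameters, a young-mouse source descriptor
#' (e.g. the sigmoid fit to naive T cell numbers in young clean mice), the
#' presumed subset size at age 5 d, and a fold-correction `phi_scale` applied
#' to the force of recruitment from age 5 d up to `horizon` days (11 weeks by
#' default), after which the force reverts to its adult value. Predictions are
#' insensitive to `M_init`, which is small and rapidly outnumbered by influx.
#'
#' @param model_params adult-fitted `model_params`.
#' @param source_desc young-mouse source [source_descriptor()] covering ages
#'   from 5 d upward.
#' @param M_init cells at age 5 d.
#' @param phi_scale dimensionless fold-correction to the force of recruitment
#'   over `[5, horizon]` days.
#' @param horizon age in days up to which `phi_scale` applies (default 77 d =
#'   11 weeks).
#' @param t_start age at which the forward solution starts (5 d, where data
#'   begin).
#' @return an object of class `ontogeny_scenario`.
#' @export
ontogeny_scenario <- function(model_params, source_desc, M_init = 0,
                              phi_scale = 1, horizon = 77, t_start = 5) {
  stopifnot(inherits(model_params, "model_params"),
            inherits(source_desc, "source_descriptor"),
            phi_scale > 0, M_init >= 0, horizon > t_start)
  structure(list(model_params = model_params, source_desc = source_desc,
                 M_init = M_init, phi_scale = phi_scale, horizon = horizon,
                 t_start = t_start),
            class = "ontogeny_scenario")
}

# influx phi_eff(t) * S(t) on a grid, with the fold-correction up to horizon
scaled_influx <- function(scenario, tt) {
  phi <- scenario$model_params$phi
  scale <- ifelse(tt <= scenario$horizon, scenario$phi_scale, 1)
  phi * scale * eval_source(scenario$source_desc, tt)
}

#' Predict early-life accumulation of a memory subset
#'
#' Solves the scenario's model forward from age `t_start` (5 d) with influx
#' `phi_scale * phi * S(t)` up to the horizon and `phi * S(t)` thereafter.
#' Only total numbers are produced: chimerism is undefined before BMT. For the
#' two-phase model the initial cells are placed in the fast compartment (newly
#' generated memory is fast); for the age-dependent loss model they are
#' treated as age-zero cells at `t_start`, so the initial cohort decays with
#' the new-memory survival curve. For a chained prediction
#' (naive to T_CM to T_EM) wrap the predicted T_CM trajectory with
#' [source_from_trajectory()] and use it as the T_EM scenario's source.
#'
#' @param scenario an [ontogeny_scenario()].
#' @param ages host ages (days, all >= `t_start`) at which to report totals.
#' @param h integrator grid step in days.
#' @return a data frame with columns `times` and `total`.
#' @export
predict_early <- function(scenario, ages, h = 0.25) {
  stopifnot(inherits(scenario, "ontogeny_scenario"))
  t1 <- scenario$t_start
  if (any(ages < t1)) stop("ages must be >= ", t1, " d")
  p <- scenario$model_params
  # split the grid exactly at the horizon: the influx correction switches off
  # there and quadrature panels must not straddle the jump
  tmax <- max(ages, t1 + 1)
  tt <- sort(unique(c(time_grid(t1, tmax, h),
                      if (tmax > scenario$horizon) scenario$horizon)))
  b <- scaled_influx(scenario, tt)
  m <- length(tt)

  total <- switch(model_name(p),
    homogeneous = {
      M <- march_affine_path(tt, rep(p$lam, m), b, scenario$M_init)
      interp_grid(tt, M, ages)
    },
    resistant = {
      M <- march_affine_path(tt, rep(p$lam, m), b, scenario$M_init)
      interp_grid(tt, M, ages) + p$I0
    },
    two_phase = {
      Mf <- march_affine_path(tt, rep(p$lam_fast + p$gamma, m), b,
                              scenario$M_init)
      Ms <- march_affine_path(tt, rep(p$lam_slow, m), p$gamma * Mf, 0)
      interp_grid(tt, Mf + Ms, ages)
    },
    age_dep = {
      Lam <- age_loss_cum(p, tmax - t1)
      gl <- gl_unit(64)
      init <- scenario$M_init * exp(-Lam(ages - t1))
      # influx integral int_{t1}^{t} b(s) exp(-Lam(t - s)) ds, split at the
      # horizon so each Gauss-Legendre panel sees a smooth integrand
      seg <- function(lo, hi, t) {
        if (hi <= lo) return(0)
        s <- lo + gl$x * (hi - lo)
        (hi - lo) * sum(gl$w * scaled_influx(scenario, s) * exp(-Lam(t - s)))
      }
      infl <- vapply(ages, function(t) {
        brk <- min(t, scenario$horizon)
        seg(t1, brk, t) + seg(brk, t, t)
      }, numeric(1))
      init + infl
    },
    stop("unsupported model for ontogeny prediction")
  )
  out <- data.frame(times = ages, total = total)
  attr(out, "model") <- model_name(p)
  class(out) <- c("memdyn_trajectory", "data.frame")
  out
}

#' Estimate the fold-correction to the force of recruitment
#'
#' Finds the scalar multiplying the adult force of recruitment over
#' `[t_start, horizon]` days such that the predicted subset size at the
#' horizon equals `target_mean` (typically the mean subset size observed at
#' ages 10-28 weeks, over which memory numbers are approximately stable).
#' Solved by bracketed root-finding on the log scale; the horizon prediction
#' is monotone increasing in the scaling.
#'
#' @param scenario an [ontogeny_scenario()] (its `phi_scale` is ignored).
#' @param target_mean target subset size (cells) at the horizon.
#' @param horizon override of the scenario horizon (days).
#' @param bracket search interval for the scaling.
#' @param tol relative tolerance of the root.
#' @return the estimated `phi_scale` (scalar).
#' @export
estimate_phi_scaling <- function(scenario, target_mean, horizon = NULL,
                                 bracket = c(1e-3, 1e3), tol = 1e-8) {
  stopifnot(target_mean > 0)
  if (!is.null(horizon)) scenario$horizon <- horizon
  g <- function(ls) {
    sc <- scenario
    sc$phi_scale <- exp(ls)
    log(predict_early(sc, scenario$horizon)$total / target_mean)
  }
  lo <- log(bracket[1]); hi <- log(bracket[2])
  if (g(lo) > 0 || g(hi) < 0)
    stop("estimate_phi_scaling: target not reachable within the bracket")
  exp(stats::uniroot(g, c(lo, hi), tol = tol)$root)
}
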