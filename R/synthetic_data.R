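# Synthetic busulfan-chimera cohorts with the statistical structure the
# analysis assumes: cross-sectional terminal harvests, staggered BMT ages,
# lognormal noise on counts and Gaussian noise on the arcsin-sqrt scale of
# normalised chimerism, and per-mouse DP1 conditioning efficiency.

#' Default source-size truths per facility
#'
#' Returns the synthetic-truth descriptor of a precursor population's size.
#' Naive CD4 T cell numbers decline exponentially from the facility baseline
#' age with half-lives of 228 d (clean) and 143 d (dirty); central-memory
#' sources follow a sigmoid (clean; the pool is still growing) or a slow
#' exponential decline (dirty). Scales are chosen so that the daily influx
#' \eqn{\varphi S(t^*)} at 20 weeks is of the magnitude reported for adult
#' mice (naive pool ~1.6e7 cells, T_CM pool ~3e5 clean / ~7.5e5 dirty at 20
#' weeks).
#'
#' @param facility `"clean"` or `"dirty"`.
#' @param source `"naive"` or `"tcm"`.
#' @return a [source_descriptor()].
#' @export
default_source_truth <- function(facility = c("clean", "dirty"),
                                 source = c("naive", "tcm")) {
  facility <- match.arg(facility)
  source <- match.arg(source)
  if (source == "naive") {
    if (facility == "clean")
      source_descriptor("exp_decay", c(S0 = 2.0e7, nu = log(2) / 228),
                        t_ref = 66)
    else
      source_descriptor("exp_decay", c(S0 = 2.2e7, nu = log(2) / 143),
                        t_ref = 84)
  } else {
    if (facility == "clean")
      source_descriptor("sigmoid_growth", c(Smax = 3.1e5, Smin = 2e4, r = 0.06))
    else
      source_descriptor("exp_decay", c(S0 = 8.0e5, nu = 1e-3), t_ref = 84)
  }
}

#' Default normalised source-chimerism truths
#'
#' Generalised-logistic curves of normalised donor chimerism as a function of
#' time since BMT: zero at transplant, rising towards a plateau below 1. The
#' naive pool turns over faster through thymic export and plateaus high; the
#' central-memory pool (as a source of effector memory) equilibrates more
#' slowly and at a lower level.
#'
#' @param source `"naive"` or `"tcm"`.
#' @return a [source_descriptor()] of kind `gen_logistic` (argument: days
#'   post-BMT).
#' @export
default_chi_source_truth <- function(source = c("naive", "tcm")) {
  source <- match.arg(source)
  if (source == "naive")
    source_descriptor("gen_logistic",
      c(lower = 0, upper = 0.9, rate = 0.035, midpoint = 70, shape = 1))
  else
    source_descriptor("gen_logistic",
      c(lower = 0, upper = 0.45, rate = 0.02, midpoint = 120, shape = 1))
}

#' Young-mouse source descriptors for ontogeny scenarios
#'
#' Sigmoid descriptors of naive and central-memory CD4 T cell numbers in
#' young (5 d - 15 wk) clean-facility mice, of the functional form fitted to
#' young wild-type timecourses: near `Smin` at birth, saturating at `Smax` by
#' adulthood.
#'
#' @param source `"naive"` or `"tcm"`.
#' @return a [source_descriptor()] of kind `sigmoid_growth`.
#' @export
default_young_source <- function(source = c("naive", "tcm")) {
  source <- match.arg(source)
  if (source == "naive")
    source_descriptor("sigmoid_growth", c(Smax = 2.4e7, Smin = 4e5, r = 0.15))
  else
    source_descriptor("sigmoid_growth", c(Smax = 2.6e5, Smin = 2e3, r = 0.10))
}

# Point estimates of the two-phase and age-dependent loss models in adult
# mice (force of recruitment per day, loss rates per day, ages in days);
# the age-dependent T_EM/dirty cell-age threshold was not identifiable.
TABLE2 <- list(
  two_phase = list(
    tcm_clean = list(phi = 1.4e-3, lam_fast = 0.082, lam_slow = 5.9e-3,
                     pct_to_slow = 3.4, prop_slow_tstar = 0.25),
    tcm_dirty = list(phi = 1.5e-3, lam_fast = 0.10, lam_slow = 4.8e-3,
                     pct_to_slow = 5.0, prop_slow_tstar = 0.61),
    tem_clean = list(phi = 1.2, lam_fast = 0.23, lam_slow = 2.5e-3,
                     pct_to_slow = 1.8, prop_slow_tstar = 0.36),
    tem_dirty = list(phi = 1.1, lam_fast = 0.39, lam_slow = 4.8e-3,
                     pct_to_slow = 9.1, prop_slow_tstar = 0.72)
  ),
  age_dep = list(
    tcm_clean = list(phi = 0.43e-3, lam0 = 2.2e-2, A = 150, n = 3, p = -0.02),
    tcm_dirty = list(phi = 0.26e-3, lam0 = 1.2e-2, A = 190, n = 3, p = -0.02),
    tem_clean = list(phi = 0.10, lam0 = 1.2e-2, A = 150, n = 3, p = -0.06)
  )
)

#' Synthetic-cohort configuration
#'
#' Collects everything needed to generate a synthetic busulfan-chimera
#' cohort: the facility timing constants, the generating ("truth") model and
#' its parameters, source-size and source-chimerism truths, noise SDs on the
#' fitting scales, cohort size and design windows. Noise is applied on the
#' fitting scales (log counts; arcsin-sqrt normalised chimerism), so the
#' fitted likelihood is exactly correctly specified for generated cohorts.
#'
#' @param facility `"clean"` or `"dirty"`.
#' @param subset `"tcm"` or `"tem"` -- which memory subset the truth model
#'   generates.
#' @param truth_model name of the generating model.
#' @param truth_params `model_params` of the generating model.
#' @param source_truth,chi_source_truth source [source_descriptor()]s
#'   (defaults: facility/subset-appropriate descriptors).
#' @param source name of the source population (`"naive"` for T_CM, `"tcm"`
#'   for T_EM by default).
#' @param sigma_x SD of log-count noise (default 0.15).
#' @param sigma_y SD of arcsin-sqrt chimerism noise (default 0.05).
#' @param n_mice cohort size (one terminal observation per mouse).
#' @param bmt_age_range host ages at BMT, days (uniform). The default runs
#'   from `t0 - bmt_lag` (40 d clean, 56 d dirty -- the facility baseline age
#'   is defined as the youngest BMT age plus the post-BMT lag) to 182 d
#'   (26 weeks).
#' @param obs_window_post_bmt observation times post-BMT, days (uniform;
#'   default 28-448 d, i.e. 4-64 weeks).
#' @param dp1_range range of the per-mouse stabilised DP1 thymocyte donor
#'   fraction (uniform; emulates variable conditioning efficiency).
#' @param seed RNG seed for [simulate_cohort()].
#' @param h integrator grid step for the truth trajectory.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(facility = c("clean", "dirty"),
                       subset = c("tcm", "tem"),
                       truth_model, truth_params,
                       source_truth = NULL, chi_source_truth = NULL,
                       source = NULL,
                       sigma_x = 0.15, sigma_y = 0.05, n_mice = 150,
                       bmt_age_range = NULL,
                       obs_window_post_bmt = c(28, 448),
                       dp1_range = c(0.6, 0.95), seed = 1, h = 0.5) {
  facility <- match.arg(facility)
  subset <- match.arg(subset)
  cfg <- cohort_config(facility)
  bmt_age_range <- bmt_age_range %||% c(cfg$t0 - cfg$bmt_lag, 182)
  stopifnot(inherits(truth_params, "model_params"),
            sigma_x > 0, sigma_y > 0, n_mice >= 1,
            bmt_age_range[1] <= bmt_age_range[2],
            obs_window_post_bmt[1] <= obs_window_post_bmt[2])
  if (bmt_age_range[1] + cfg$bmt_lag < cfg$t0)
    stop("BMT ages younger than t0 - bmt_lag are inconsistent with the ",
         "facility baseline age")
  source <- source %||% if (subset == "tcm") "naive" else "tcm"
  if (obs_window_post_bmt[1] < cfg$bmt_lag)
    stop("observations before the post-BMT lag are excluded from fitting; ",
         "set obs_window_post_bmt[1] >= ", cfg$bmt_lag)
  structure(list(
    facility = facility, subset = subset, truth_model = truth_model,
    truth_params = truth_params,
    source_truth = source_truth %||% default_source_truth(facility, source),
    chi_source_truth = chi_source_truth %||% default_chi_source_truth(source),
    source = source, sigma_x = sigma_x, sigma_y = sigma_y, n_mice = n_mice,
    bmt_age_range = bmt_age_range, obs_window_post_bmt = obs_window_post_bmt,
    dp1_range = dp1_range, seed = seed, h = h, cfg = cfg
  ), class = "sim_config")
}

#' Table-of-estimates truth configurations
#'
#' Builds a [sim_config()] whose generating parameters are the published
#' adult point estimates for the requested facility, memory subset and model
#' (two-phase or age-dependent loss). For the two-phase model the transition
#' rate is backed out of the reported percentage of memory transitioning to
#' slow, \eqn{\gamma = \lambda_{fast} \, q/(1 - q)} with
#' \eqn{q = \%/100}, and the slow pool size at `t0` is calibrated so that the
#' proportion of slow cells at 20 weeks matches the reported value. The
#' age-dependent loss estimates for T_EM in dirty mice are refused: the loss
#' rate of new memory was indistinguishable from zero there and the cell-age
#' threshold was not identifiable.
#'
#' @param facility `"clean"` or `"dirty"`.
#' @param subset `"tcm"` or `"tem"`.
#' @param model `"two_phase"` or `"age_dep"`.
#' @param ... passed on to [sim_config()] (e.g. `n_mice`, `seed`).
#' @return a [sim_config()].
#' @export
default_truth <- function(facility = c("clean", "dirty"),
                          subset = c("tcm", "tem"),
                          model = c("two_phase", "age_dep"), ...) {
  facility <- match.arg(facility)
  subset <- match.arg(subset)
  model <- match.arg(model)
  key <- paste(subset, facility, sep = "_")
  tab <- TABLE2[[model]][[key]]
  if (is.null(tab))
    stop("no usable point estimates for ", model, " / ", key,
         " (the cell-age threshold A was poorly constrained)")
  source <- if (subset == "tcm") "naive" else "tcm"
  src <- default_source_truth(facility, source)
  cfg <- cohort_config(facility)

  if (model == "age_dep") {
    params <- age_dep_params(phi = tab$phi, p = tab$p, lam0 = tab$lam0,
                             A = tab$A, n = tab$n)
  } else {
    q <- tab$pct_to_slow / 100
    gamma <- tab$lam_fast * q / (1 - q)
    # calibrate Mslow(t0) so the slow fraction at t* matches the estimate
    prop_at_tstar <- function(Mslow0) {
      p <- two_phase_params(Mslow0, tab$phi, tab$lam_fast, tab$lam_slow, gamma)
      derived_quantities(p, src, cfg)$prop_slow_tstar
    }
    f <- function(lM) prop_at_tstar(exp(lM)) - tab$prop_slow_tstar
    r <- stats::uniroot(f, c(log(1), log(1e9)), tol = 1e-10)
    params <- two_phase_params(exp(r$root), tab$phi, tab$lam_fast,
                               tab$lam_slow, gamma)
  }
  sim_config(facility = facility, subset = subset, truth_model = model,
             truth_params = params, source_truth = src, source = source, ...)
}

#' Generate a synthetic busulfan-chimera cohort
#'
#' Per mouse: a BMT age and a terminal observation age are drawn uniformly
#' from the configured windows; the truth model is evaluated at that design
#' point; the count is emitted as \eqn{\exp(\ln M + \epsilon_x)} with
#' \eqn{\epsilon_x \sim N(0, \sigma_x^2)}; normalised chimerism receives
#' Gaussian noise on the arcsin-sqrt scale, is back-transformed (never leaving
#' \eqn{[0, 1]}) and de-normalised by a per-mouse DP1 donor fraction drawn
#' from the configured range. Source-population columns are filled from the
#' source truths with the same noise model; the remaining subset's columns
#' are `NA`. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a data frame with one row per mouse: `mouse_id`, `facility`,
#'   `bmt_age_days`, `obs_age_days`, `count_naive`, `count_tcm`, `count_tem`,
#'   `chi_naive`, `chi_tcm`, `chi_tem`, `chi_dp1`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_mice
  bmt <- runif(n, cfg$bmt_age_range[1], cfg$bmt_age_range[2])
  obs <- bmt + runif(n, cfg$obs_window_post_bmt[1], cfg$obs_window_post_bmt[2])

  ctx <- make_ctx(cfg$source_truth, cfg$chi_source_truth, cfg$cfg, bmt, obs,
                  h = cfg$h)
  pr <- predict_cohort(cfg$truth_params, ctx)
  if (is.null(pr) || any(pr$total <= 0))
    stop("simulate_cohort: truth trajectory non-positive; check the config")

  noisy_count <- function(m) exp(log(m) + rnorm(n, 0, cfg$sigma_x))
  noisy_chi <- function(ch) {
    y <- asin(sqrt(clip(ch, 0, 1))) + rnorm(n, 0, cfg$sigma_y)
    sin(clip(y, 0, pi / 2))^2
  }
  dp1 <- runif(n, cfg$dp1_range[1], cfg$dp1_range[2])

  count_sub <- noisy_count(pr$total)
  chi_sub <- noisy_chi(pr$chi) * dp1

  src_size <- eval_source(cfg$source_truth, obs)
  src_chi <- eval_source(cfg$chi_source_truth, obs - bmt)
  count_src <- noisy_count(src_size)
  chi_src <- noisy_chi(src_chi) * dp1

  out <- data.frame(
    mouse_id = sprintf("m%03d", seq_len(n)),
    facility = cfg$facility,
    bmt_age_days = bmt, obs_age_days = obs,
    count_naive = NA_real_, count_tcm = NA_real_, count_tem = NA_real_,
    chi_naive = NA_real_, chi_tcm = NA_real_, chi_tem = NA_real_,
    chi_dp1 = dp1
  )
  out[[paste0("count_", cfg$subset)]] <- count_sub
  out[[paste0("chi_", cfg$subset)]] <- chi_sub
  out[[paste0("count_", cfg$source)]] <- count_src
  out[[paste0("chi_", cfg$source)]] <- chi_src
  attr(out, "truth") <- cfg
  out
}
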