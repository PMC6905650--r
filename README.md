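# memdyn

Dynamical models of memory CD4 T cell generation and loss in busulfan
chimeric mice.

## The problem

Mice accumulate memory-phenotype CD4 T cells — central memory (T_CM) and
effector memory (T_EM) — throughout life, even without overt infection. In a
busulfan chimera, host haematopoietic stem cells are partially replaced by
congenically marked donor marrow while peripheral T cells are untouched;
donor cells then flow through the thymus into the naive pool and onward into
memory. The rise of the donor fraction ("chimerism", normalised per mouse to
the donor fraction among DP1 thymocytes) within each memory subset, together
with total cell counts, identifies the rates at which memory is made and
lost. `memdyn` is for quantitative immunologists analysing such fate-mapping
timecourses.

The package implements four candidate models of a memory subset M(t) fed by
a precursor S(t) at total rate φS(t), where φ is the *force of recruitment*
and λ denotes *net* loss (death + onward differentiation − self-renewal):

* **homogeneous** — dM/dt = φS(t) − λM;
* **two-phase** — fast and slow subpopulations, influx into fast,
  fast→slow transition at rate γ, distinct loss rates;
* **age-dependent loss** — ∂M/∂t + ∂M/∂a = −λ(a)M with
  λ(a) = λ₀/(1+(a/A)ⁿ), solved along characteristics (a = time since entry
  into memory);
* **resistant memory** — a displaceable pool plus host-only incumbents
  established early in life and stable in number.

Models are fitted by joint maximum likelihood to log counts and
arcsin-√ chimerism with profiled error variances
(ln L = −(n/2)·ln(SSRx·SSRy) − 2n), compared across models and candidate
source populations by AICc, and equipped with residual-bootstrap confidence
intervals. An ontogeny module predicts early-life (5 d – 11 wk) accumulation
of memory from adult-fitted parameters and estimates environment-specific
fold-corrections to φ. A synthetic-cohort generator reproduces the
experiment's design (staggered BMT ages, one terminal observation per mouse,
per-mouse conditioning efficiency) so the entire pipeline is testable
without external data.

## Worked example

Simulate an effector-memory cohort at the published adult point estimates
(two-phase model, clean facility), refit it, and summarise:

```r
library(memdyn)
cfg  <- cohort_config("clean")                        # t0 = 66 d, lag = 26 d
sim  <- default_truth("clean", "tem", "two_phase", n_mice = 150, seed = 1)
obs  <- simulate_cohort(sim)                          # one row per mouse
tem  <- extract_timecourse(obs, "tem", cfg)           # counts + chi_norm
fit  <- fit_model(tem, "two_phase", sim$source_truth, sim$chi_source_truth,
                  cfg, starts = 8, seed = 1, h = 1)
print(fit)
#> <memdyn_fit> two_phase model, 150 mice, lnL = -330.39
#>   Mslow0      phi lam_fast lam_slow    gamma
#> 5.55e+05 5.91e-01 1.04e-01 2.34e-03 3.45e-03
#> sigma_x = 0.149  sigma_y = 0.0547
report_parameter_table(fit)
#>           quantity       value
#> 1           Mslow0  5.6 x 10^5
#> 2              phi        0.59
#> 3         lam_fast         0.1
#> 4         lam_slow 2.3 x 10^-3
#> 5            gamma 3.5 x 10^-3
#> 6   half_life_fast         6.7
#> 7   half_life_slow         300
#> 8      pct_to_slow         3.2
#> 9  prop_slow_tstar        0.33
#> 10    influx_tstar  1.8 x 10^5
```

Reading the output: the slow pool at the baseline age holds ~5.6×10⁵ cells
(the generating value); newly recruited ("fast") memory is lost with a
clonal half-life of days (ln2/λ_fast ≈ 6.7 d here), about 3% of it survives
the transition to slow memory (100γ/(λ_fast+γ)), and established slow
clones persist for months (half-life ≈ 300 d in this replicate — this
quantity has a wide sampling distribution, which the bootstrap makes
explicit). φ and λ_fast individually sit on a likelihood ridge; their CIs
from `bootstrap_ci(fit)` span roughly an order of magnitude, as expected for
this design. `sigma_x`/`sigma_y` recover the generating noise SDs
(0.15, 0.05).

`compare_models()` fits every model × source combination and emits the
AICc support table; `predict_early()` and `estimate_phi_scaling()` handle
the ontogeny analyses.

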