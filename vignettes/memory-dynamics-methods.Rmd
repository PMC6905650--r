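---
title: "Models and methods for memory CD4 T cell fate-mapping analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for memory CD4 T cell fate-mapping analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdyn)
```

## The biological problem

Laboratory mice accumulate circulating memory-phenotype CD4 T cells —
central memory (T~CM~, CD44^hi^CD62L^+^) and effector memory (T~EM~,
CD44^hi^CD62L^−^) — without overt infection. In busulfan chimeric mice,
host haematopoietic stem cells are partially replaced by congenically marked
donor marrow while the peripheral T cell pools are left intact. Donor-derived
cells then percolate through the thymus into the naive pool and onward into
memory, so the rise of the donor fraction ("chimerism") within each memory
subset is a clock that reports the rates of recruitment and loss. `memdyn`
implements the modelling side of such an experiment: candidate dynamical
models of a memory subset fed by a precursor population, joint likelihood
fitting to cell counts and chimerism, information-criterion model comparison,
bootstrap uncertainty, and early-life (ontogeny) predictions.

Chimerism is always *normalised*: each mouse's donor fraction in a memory
subset is divided by the donor fraction among its early double-positive (DP1)
thymocytes, which removes mouse-to-mouse variation in conditioning
efficiency. Because DP1 chimerism stabilises within 3–4 weeks of bone-marrow
transplant (BMT), its time derivative is dropped from the chimerism
dynamics, and observations earlier than the facility's post-BMT lag (26 d
clean, 28 d dirty) are excluded from fitting.

## Source descriptors

Each model needs the precursor population's size $S(t)$ (host age $t$, days)
and its normalised chimerism $\chi_{s}(\tau)$ (time since BMT $\tau$). These
are empirical parametric curves, fitted separately and held fixed during the
dynamical fits:

* exponential decline $S(t) = S_0 e^{-\nu (t - t_0)}$ for the adult naive
  pool (thymic involution; half-lives of 228 d in the clean facility and
  143 d in the dirty one) — anchored at the facility baseline age $t_0$ so
  that $S(t_0)$ is itself a parameter;
* logistic growth $S(t) = S_{max} / (1 + e^{-rt}(S_{max}-S_{min})/S_{min})$
  for growing pools (young-mouse naive and central-memory timecourses);
* a generalised (Richards) logistic
  $\chi_s(\tau) = lower + (upper-lower)\,(1 + e^{-rate(\tau - mid)})^{-1/shape}$
  for source chimerism, confined to $[0,1]$. The Richards form is the
  standard five-parameter generalisation of the logistic and nests the
  symmetric curve at $shape = 1$.

Size descriptors are fitted by least squares on log-transformed counts
(multiplicative noise); the chimerism descriptor is fitted on the natural
scale with bounds, since only count errors are log-normal in the observation
model. `exp_decay` is solved exactly by linear regression; the nonlinear
families use ten Nelder–Mead starts drawn log-uniformly over data-driven
ranges (fixed seed) with BFGS polish, best sum of squares winning.

## The four dynamical models

All models describe a memory subset of total size $M(t)$ receiving influx
$\varphi S(t)$ from its source, where $\varphi$ is the *force of
recruitment* — the per-capita daily recruitment rate times any clonal
expansion at entry. Loss is always a *net* rate (death plus onward
differentiation minus self-renewal), so it may be negative. Totals are
propagated from the facility baseline age $t_0$ (66 d clean, 84 d dirty; the
youngest BMT age plus the post-BMT lag). For a mouse transplanted at age
$t_B$, normalised chimerism starts at zero at $T = t_B + \text{lag}$, which
handles staggered BMT designs: all mice share one total-numbers curve but
each has its own chimerism clock.

**Homogeneous.** $dM/dt = \varphi S(t) - \lambda M$, with
$\chi'_M = \varphi S/M\,(\chi_s - \chi_M)$. With an exponentially declining
source the totals have a closed form, used both as a fast path and as the
oracle for the ODE integrator. When $\lambda$ equals the source decay rate
$\nu$ the closed form has a removable singularity, handled with an
$(e^z - 1)/z$ evaluation rather than the raw expression.

**Two-phase.** Fast and slow subpopulations with distinct net loss rates;
influx enters the fast pool, which feeds the slow pool at rate $\gamma$. The
fast pool at $t_0$ is initialised in quasi-equilibrium with its source,
$M_{f}(t_0) = \varphi S(t_0)/(\lambda_f + \gamma)$ (adult pools change
slowly); the slow pool size at $t_0$ is free. A free-initialisation variant
(`init = "free"`) estimates $M_f(t_0)$ at the cost of one parameter. Subset
chimerisms obey a chained pair of linear equations and combine as a
pool-size-weighted average.

**Age-dependent loss.** The loss rate depends on cell age $a$ (time since
the cell or its ancestor entered memory): a transport equation
$\partial_t M + \partial_a M = -\lambda(a) M$ with boundary influx
$\varphi S(t)$ and initial host age-density $g(a) = \varphi S(t_0)e^{pa}$ on
$[0, t_0]$, solved along characteristics. We use
$\lambda(a) = \lambda_0/(1+(a/A)^n)$ (sigmoid, $n = 3$ by default — the
best-performing exponent; 1, 2, 5, 10 and an exponential form are
available). The cell-age integrals are evaluated with fixed 64-node
Gauss–Legendre panels and a precomputed cumulative hazard
$\Lambda(a) = \int_0^a \lambda$, so results are deterministic and
reproducible. The $p \to 0$ initial pool size
$\varphi S(t_0)(e^{pt_0}-1)/p \to \varphi S(t_0) t_0$ needs no special-casing
because the pool is computed as a quadrature of $g$, not from the closed
form.

**Resistant (incumbent) memory.** A displaceable pool with homogeneous
kinetics plus a host-only incumbent population $I$ established early in life,
never supplemented, and stable in number ($\lambda_I = 0$). Incumbents dilute
the measured chimerism below that of the displaceable compartment.

### Numerics

The workhorse integrator is an exponential-midpoint scheme for scalar linear
ODEs $x' = b(t) - a(t)x$ on a fine grid (default step 0.25 d for
trajectories, 0.5–1 d inside likelihood optimisation, where discretisation
error is far below observation noise). The step is exact for constant
coefficients — which covers every totals equation, since their loss rates
are time-constant — and unconditionally stable, which matters because
candidate loss rates span $10^{-5}$–$10\ \mathrm{d^{-1}}$ during
optimisation. Chimerism equations are integrated directly in this form
rather than as ratios of separately integrated donor and total solutions,
avoiding cancellation at small chimerism; equivalence of the two
constructions is a test. A deSolve (lsoda, rtol $10^{-8}$) route cross-checks
the homogeneous and two-phase solvers, and a brute-force upwind
discretisation of the age-structured model ($\Delta a = \Delta t = 0.25$ d)
cross-checks the characteristics solver to 0.5%. Normalised chimerism may
overshoot 1 slightly through DP1 normalisation; values are clipped at 1
before transforming, with a warning.

## Likelihood, model comparison, uncertainty

Each mouse contributes one count and one chimerism value per subset
(cross-sectional terminal harvests). Counts enter as $x = \ln M$ and
chimerism as $y = \arcsin\sqrt{\chi}$, both assumed Gaussian with constant
variances. Profiling the two variances analytically
($\hat\sigma^2 = SSR/n$) gives
$\ln L = -\tfrac{n}{2}\ln(SSR_x \cdot SSR_y) - 2n$,
maximised over the model parameters with a multi-start scheme: a
data-driven heuristic start plus log-uniform perturbations spanning about
four orders of magnitude for positive parameters (20 starts by default; the
age-dependent surface is multimodal), Nelder–Mead per start, BFGS polish on
the best. Positive parameters are optimised on the log scale; net loss rates
and the age-distribution exponent $p$ are unconstrained. The two-phase model
is optimised in terms of the fast-pool size
$M_f(t_0) = \varphi S(t_0)/(\lambda_f+\gamma)$ rather than $\varphi$:
the data pin down pool sizes directly while $\varphi$ and $\lambda_f$ lie
along a likelihood ridge, and this coordinate change makes both the fit and
the bootstrap refits far better conditioned without changing the model.

Model/source combinations are ranked by
$AICc = -2\ln L + 2K + 2K(K+1)/(N-K-1)$ with $\ln L$ summed over facilities,
$K$ the total parameter count (3/5/4/4 per facility for the
homogeneous/two-phase/age-dependent/resistant models; the profiled error
variances are excluded, matching the published parameter counts) and $N$ the
total observation count (two per mouse). Differences of 10 or more are
treated as decisive.

Confidence intervals come from a residual bootstrap: the $(x, y)$ residual
*pairs* are resampled jointly per mouse (a package choice that preserves any
within-mouse error correlation), inflated by the standard $\sqrt{n/(n-p)}$
factor to undo the
degrees-of-freedom deflation of fitted residuals, added to the fitted
transformed predictions, and the model is refit per replicate, warm-started
from the original optimum (plus optional perturbed starts) with a
quasi-Newton polish so replicates can travel along likelihood ridges (for
the well-conditioned homogeneous and resistant models a pure quasi-Newton
refit, `refit = "bfgs"`, is adequate and much faster). Intervals are type-7 (2.5%, 97.5%) quantiles of the
replicate estimates, including derived quantities (clonal half-lives
$\ln 2/\lambda$, the percentage of fast memory surviving to the slow pool
$100\gamma/(\lambda_f+\gamma)$, the slow fraction and daily influx
$\varphi S(t^*)$ at the reference age $t^* = 140$ d). Half-lives of
non-positive net loss rates are reported as undefined.

## Ontogeny predictions

Adult-fitted parameters are run forward from age 5 d (where young-mouse data
begin) with the young-mouse source descriptor, starting from the (small)
observed subset size at 5 d; predictions at 11 weeks are insensitive to that
initial value. A scalar fold-correction to $\varphi$ applies over
[5 d, 77 d] and reverts to the adult force afterwards — a sharp switch,
since the shape of any ramp is not identifiable from a single matching
level; the correction is chosen by bracketed root-finding so the predicted
subset size at 11 weeks matches the mean size observed at ages 10–28 weeks
(a window over which memory numbers are roughly stable). Chained predictions
(naive → T~CM~ → T~EM~) wrap the predicted T~CM~ trajectory as an
interpolating source for the two-phase T~EM~ model. In the two-phase model
initial cells are seeded into the fast pool and in the age-dependent model
they are treated as age-zero at 5 d — in both cases they are rapidly
outnumbered by influx, which is what makes the predictions initial-condition
insensitive. For germ-free scenarios the clean-facility adult loss
parameters are reused, since no chimera-based estimates exist for germ-free
mice.

## The synthetic-cohort generator

`simulate_cohort()` emulates the busulfan-chimera design: per mouse a BMT
age uniform over 40–182 d (clean; 56–182 d dirty — the lower bound is the
facility baseline age minus the lag, by the definition of $t_0$), one
terminal observation 28–448 d post BMT, a stabilised DP1 donor fraction
uniform on 0.6–0.95 (variable conditioning efficiency), lognormal noise on
counts ($\sigma_x = 0.15$) and Gaussian noise on arcsin-√ normalised
chimerism ($\sigma_y = 0.05$). Noise is applied on the fitting scales, so
the fitted likelihood is *exactly* correctly specified for generated
cohorts — deliberate, because it makes coverage and consistency experiments
clean. The default noise SDs are plausible scatter values for flow-cytometry
cell counts and chimerism fractions, not estimates from any particular
dataset.

Truth configurations (`default_truth()`) use the published adult point
estimates for the two-phase and age-dependent models; quantities the table
does not pin down are completed as follows, once, as model-consistent
choices: the fast→slow transition rate is backed out of the reported
percentage transitioning ($\gamma = \lambda_f q/(1-q)$), the slow pool's
initial size is calibrated so the slow fraction at 20 weeks matches the
reported proportion, source scales are set so the daily influx
$\varphi S(t^*)$ has the reported magnitude (naive pool ≈ 1.6×10⁷ cells,
T~CM~ ≈ 3×10⁵ clean / 7.5×10⁵ dirty at 20 weeks), the age-distribution
exponent is $p = -0.02$ (T~CM~) / $-0.06$ (T~EM~), giving initial pools of
realistic size, and source chimerism plateaus at 0.9 (naive) / 0.45 (T~CM~)
with post-BMT midpoints of 70 / 120 d. The age-dependent estimates for
T~EM~ in dirty mice are refused: the new-memory loss rate there was
indistinguishable from zero and the age threshold unidentifiable. The
generator does not emulate flow-cytometry gating noise, per-organ
variation, longitudinal sampling (the design is cross-sectional), or any
homeostatic (density-dependent) regulation — so passing recovery tests shows
the inference machinery is correct and well calibrated *for the assumed
observation model*, not that real data meet those assumptions.

## Problem sizes used by the test suite

The recovery, selection and coverage experiments run at sizes chosen to
exercise the full pipeline on a single core: parameter recovery uses 10
replicate cohorts of 150 mice per model with 40-60 bootstrap replicates
each; selection power uses 10 replicates of 150 mice on one facility;
bootstrap coverage uses 70 cohorts of 150 mice with 150 bootstrap
replicates. Thresholds
(≥ 90% joint recovery, ΔAICc > 10 in ≥ 9/10, coverage in 90–99%) are
independent of these sizes. Production analyses should use the defaults
(20 multi-starts, 1000 bootstrap replicates, 0.25 d grids).

## Known limitations

* Only net loss rates are identified; division and death cannot be separated
  without proliferation data (e.g. Ki67), which is out of scope.
* The two heterogeneous models (two-phase, age-dependent) describe the data
  nearly equally well by design of the comparison; both express progressive
  clonal stabilisation and cannot always be distinguished at realistic n.
* The generalised-logistic chimerism descriptor and the source scales are
  synthetic-truth choices consistent with the published influx magnitudes;
  refits of real cohort data would replace them.
* AICc comparisons assume independent observations; repeated measures would
  require a different error model (the supported design is cross-sectional).
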