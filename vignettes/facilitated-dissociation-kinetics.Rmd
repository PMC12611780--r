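---
title: "Modelling and fitting facilitated-dissociation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and fitting facilitated-dissociation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdkin)
```

## The system

A host protein H binds a target T tightly (slow spontaneous dissociation,
rate constant $k_{off,T:H}$). An effector E can bind the target:host
complex and drive it into a strained ternary complex THE from which the
target leaves much faster ($k_{off,T:HE}$). The figure of merit of such a
facilitated-dissociation system is the **fold acceleration**
$k_{off,T:HE}/k_{off,T:H}$: how much faster the target is released when
effector is present, without sacrificing affinity when it is not.

`fdkin` implements three competition topologies as mass-action reaction
networks (`build_network()`, integrated with `simulate_network()`):

* **Mutually exclusive competition** — E binds only free host; no ternary
  complex. Exchange is limited by $k_{off,T:H}$.
* **Conformational selection** — the bound complex interconverts between a
  closed state TH~X~ and an open state TH~Y~ ($k_{switch}$,
  $k_{unswitch}$), and a rigid effector can bind only TH~Y~. The apparent
  effector on-rate saturates at $k_{switch}$.
* **Induced fit** — a flexible effector engages TH~X~ directly and commits
  to the strained ternary complex; the apparent on-rate grows linearly
  with [E]. The transient initial encounter is not microscopically
  resolved, so this step is modelled as one collapsed association carrying
  $k_{on,TH:E}$; that is a modelling convention, since no rates for the
  weak initial engagement are experimentally separable.

Units are fixed internally to seconds and molar everywhere; all I/O
declares units in column names (`time_s`, `conc_M`) or JSON unit strings.
No implicit nM/µM scaling is performed.

## Closed-form rate laws

Four closed forms carry the link between microscopic rates and
observables:

* `kapp_linear()`: $k_{app} = k_{on}[E] + k_{off}$, the induced-fit
  association law.
* `kapp_conformational_selection()`: the slow relaxation rate of the
  three-state system TH~X~ ⇌ TH~Y~ ⇌ THE under pseudo-first-order [E].
  It equals the smallest-magnitude nonzero eigenvalue of the 3×3 rate
  matrix (asserted against an eigenvalue oracle for 100 random parameter
  sets) and saturates at $k_{switch}$.
* `kapp_hyperbolic()`: $k = k_{max}\,c/(K_{1/2}+c) + k_{base}$, the
  saturating dependence of an effective rate on the driving
  concentration, used in both the forward (vs [E]) and reverse (vs [T])
  directions.
* `fraction_bound()`: the exact quadratic solution of the two-component
  binding isotherm, valid in the tight-binding regime where probe
  depletion matters. It is evaluated in the rationalized form
  $2[H]/(b+\sqrt{b^2-4[H][E]})$, $b=[H]+[E]+K_d$, which is numerically
  stable and yields the dilute-probe limit $[H]/([H]+K_d)$ continuously
  at $[E]=0$ (rather than NaN).

## Trace fitting

All exponential models are linear in baseline and amplitudes given the
rates, so fits are **separable**: the nonlinear search runs over
log-rates only (positivity without constraints) and the linear parameters
are profiled out exactly at each step. The default multi-start grid spans
$10^{-5}$–$10^{-1}$ s⁻¹ plus data-driven seeds at $\ln 2/\mathrm{span}$;
a multimodality warning is raised if a competing optimum (objective
within 2× of the best, rate differing more than 3-fold) exists.
Confidence information comes from the Jacobian-based covariance at the
optimum.

The double-exponential dissociation model accounts for two host
populations. The reported rate follows an explicit operationalization of
the "faster and higher amplitude" convention: the faster component is
reported if its amplitude share is ≥ 30%, otherwise the larger-amplitude
component; the rule applied is recorded in every fit result. When the two
components are indistinguishable (rate ratio < 3 or amplitude ratio >
20) the fit degrades to a single exponential with a warning. The 30%
threshold is this package's operationalization of a convention that is
otherwise qualitative.

`fit_dose_response()` fits the three rate laws with optional case
weights. `select_rate_law()` (mechanism discrimination) uses
$1/k_{app}^2$ weighting — relative least squares — because rate constants
recovered from exponential fits carry approximately proportional errors
and a dilution series spans decades; unweighted least squares lets the
top concentrations dominate and the hyperbola's extra parameter chase
their noise. Model choice is by small-sample-corrected AIC. During
conformational-selection law fits, $k_{off,TH:E}$ is box-bounded below
$10^{-4}$ s⁻¹, matching the observed very slow effector release from the
ternary complex.

Isotherm fits report `K_d < [probe]` instead of a point estimate whenever
the fitted $K_d$ falls below the probe concentration — below that bound
the titration carries no information about the affinity.

## The multi-cycle SPR model

Within one dissociation phase, with effector concentration held constant
by flow, the chip obeys the linear system

$$
\begin{aligned}
d[THE]/dt &= -k_{off,T:HE}[THE] + k_{on,TH:E}[TH][E] - k_{off,TH:E}[THE]\\
d[TH]/dt  &= -k_{off,T:H}[TH] - k_{on,TH:E}[TH][E] + k_{off,TH:E}[THE]\\
d[THn]/dt &= -k_{off,T:Hn}[THn]
\end{aligned}
$$

where THn is a host population unresponsive to effector that accumulates
over cycles. Cycle $n$ starts with $[THE]=0$, and the free capture sites
left by cycle $n-1$ are reloaded with host, a fraction $f_{responsive}$
entering TH and the rest THn (`propagate_cycles()`). The response is the
linear read-out $S = f_n(a_{TH}[TH] + a_{THE}[THE] + a_{THn}[THn])$ with
per-cycle amplitude factors $f_n$.

`global_fit()` fits this model jointly to the dissociation curves of all
cycles with Levenberg–Marquardt least squares. Choices made where the
procedure was genuinely open:

* **Gauge fixing.** The $f_n$ multiply the amplitudes, so one factor is
  redundant; $f_1 \equiv 1$ anchors the scale.
* **Bounds.** Rates are searched in log-space (off-rates effectively
  $10^{-22}$–$10^{22}$, clamped only to keep `exp()` finite);
  $f_{responsive}$ is confined to $[0.5, 1]$ through a scaled logistic.
* **Weighting.** Per-cycle residuals are equally weighted; no
  noise-variance weighting is applied.
* **Association phases** are summarized by their end state (full
  reloading of free sites), not fitted point-by-point; only dissociation
  curves enter the objective.
* **Identifiability.** $(k_{on,TH:E}, k_{off,TH:E})$ tightly covary when
  effector binding is fast — only their joint effect on the dissociation
  kinetics is constrained — and every result carries that flag. A warning
  is raised when the fitted $k_{off,TH:E}$ times the inter-cycle gap is
  below 3, i.e. when ternary complex may not clear between cycles and the
  $[THE]=0$ cycle-start assumption becomes doubtful.
* **Propagation.** The per-cycle system is linear, so the fit evaluates
  its closed-form eigen-solution rather than a numerical integrator;
  the synthetic generator deliberately uses the opposite route
  (stiff-capable numerical integration at rtol $10^{-8}$/atol
  $10^{-12}$), so round-trip tests cross-check two independent solvers.

`compute_keff()` defines the effective rate of the full process at a
given [E] through the half-time of total bound target on the simplified
two-species system ($[TH]_0=1$, $[THE]_0=0$, no THn):
$k_{eff} = \ln 2 / t_{1/2}$, with the half-time bracketed geometrically
and refined to $10^{-6}$ relative tolerance. `summarize_fd()` computes
$k_{eff}$ on a concentration grid, fits the hyperbola
$k_{eff} = k_{off,T:HE}[E]/(K_{1/2}+[E]) + k_{off,T:H}$ with the plateau
and base constrained to the globally fitted values (only $K_{1/2}$
free), and reports the fold acceleration. The half-time-defined
$k_{eff}$ is not exactly hyperbolic; the residual shape mismatch is
about 1.5% of the plateau rate independently of the binding speed, which
is why consistency tests bound it at 2%.

## Synthetic data: what it emulates, and what it does not

Because no raw kinetic traces are available to refit, every assay is
emulated by a generator with known ground truth, and the package is
validated by parameter recovery:

* `gen_cycleset()` — multi-cycle SPR with host capture, a twofold
  effector dilution series, accumulation of unresponsive host, per-cycle
  amplitude factors and additive Gaussian noise.
* `gen_fp_titration()` — FP titrations obeying the exact quadratic
  isotherm.
* `gen_competition_courses()` — exponential competition, reverse-FD,
  FRET-transfer (with sigmoid baseline drift) and luminescence courses.

Conditions are fixed to the assay regimes of the study and are not
tuning knobs: dissociation phases of 2 h; a twofold serial dilution of
effector with top concentration 5 µM (eight concentrations by default);
base target off-rate $10^{-5}$ s⁻¹ and $f_{responsive} = 0.95$ for the
cycle sets; additive Gaussian noise with $\sigma$ = 0.5% of full scale
(no noise statistics are reported for the original data; 0.5% makes 5%
recovery tolerances meaningful); per-cycle factors jittered by 2% around
1. One effector-free cycle precedes the dilution series — the protocol's
own base off-rate measurement — because when the facilitated flux
dominates every cycle, $k_{off,T:H}$ is unidentifiable without it. The
unresponsive-host off-rate is set equal to the base target off-rate
(unresponsiveness is to the effector, not to the target); sampling is
1 Hz in the full-scale acceptance runs and 0.1 Hz in the test suite and
analysis scripts, which leaves recovery quality unchanged (the slowest
phases carry ~700 points either way).

What the generators do **not** emulate, and hence what passing tests do
not demonstrate about real data: heteroscedastic or correlated
instrument noise, bulk refractive-index jumps, spikes, drift other than
the single sigmoid of the transfer assay, mass-transport limitation on
the chip, and surface-chemistry artefacts such as capture-tag
competition. Recovery results certify the inference machinery, not the
instruments.

All generators take a mandatory integer seed and restore the session RNG
state afterwards; a fixed seed gives byte-identical datasets.

## Worked example

```{r example, eval = FALSE}
truth <- list(k_off_T_H = 1e-5, k_off_T_HE = 2.4e-2,   # 2,400-fold
              k_on_TH_E = 1e5, k_off_TH_E = 1e-4, k_off_T_Hn = 1e-5,
              f_responsive = 0.95)
cs  <- gen_cycleset(truth, experiment_design(dt = 10),
                    noise_model(seed = 42))
rep <- characterize_forward(cs)
rep$fold_acceleration   # ~2400 (recovered within a few percent)
rep$K_half              # effector concentration of half-maximal k_eff
```

## Known limitations

* The accelerated off-rate is extrapolated (wide interval) when
  $K_{1/2}$ exceeds the top effector concentration — systems whose
  ternary complex dissociates faster than effector binding can saturate.
  The recovery sweep flags such sets rather than hiding them.
* $k_{off,T:Hn}$ and $k_{off,T:H}$ separate only through the
  accumulation of unresponsive host across cycles; with
  $f_{responsive}$ near 1 and few cycles they can trade off.
* The deterministic mass-action treatment assumes macroscopic copy
  numbers, which holds for all assays modelled here; no stochastic
  engine is provided.
* The chip model inherits the $[THE]=0$ cycle-start assumption; for very
  slow effector release the fit warns but cannot correct for carry-over.
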