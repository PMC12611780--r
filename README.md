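# fdkin

Kinetic modelling and inference for engineered **facilitated
dissociation** systems: protein assemblies in which an effector (E) binds
a target–host complex (TH), drives it into a strained ternary
intermediate (THE), and thereby accelerates release of the target (T) by
orders of magnitude over its spontaneous off-rate. The package is for
protein engineers and kineticists who need to simulate such systems,
discriminate their binding mechanism, and extract rate constants from
multi-cycle SPR sensorgrams, fluorescence-polarization titrations and
exponential time courses.

## What it computes

The central quantity is the **fold acceleration**

```
fold = k_off,T:HE / k_off,T:H
```

the ratio of the target's off-rate from the strained ternary complex to
its spontaneous off-rate. Around it the package provides:

* **Mass-action networks** for the three competition mechanisms —
  mutually exclusive, conformational selection (effector binds only the
  open state TH_Y, apparent on-rate saturating at `k_switch`), induced
  fit (flexible effector engages the closed state directly, linear
  apparent on-rate) — with stiff ODE simulation and conservation checks.
* **Closed-form rate laws**: linear and hyperbolic apparent-rate laws,
  the conformational-selection slow-relaxation rate (the slow eigenvalue
  of the 3-state system), and the exact quadratic binding isotherm.
* **Trace fitting**: separable multi-start single/double-exponential
  fits (with the faster-and-higher-amplitude reporting convention made
  explicit), dose–response law fits with AICc-based mechanism selection,
  tight-binding-aware FP isotherm fits, reverse facilitated dissociation,
  and sigmoid baseline-drift subtraction.
* **The multi-cycle SPR global fit**: the chip model
  `d[THE]/dt, d[TH]/dt, d[THn]/dt` with accumulation of an
  effector-unresponsive host population across cycles, per-cycle
  amplitude factors, and the initial-value reloading recursion — fitted
  jointly across all effector concentrations; then effective-rate
  extraction `k_eff = ln 2 / t_1/2` and the constrained hyperbolic
  summary `k_eff = k_off,T:HE [E]/(K_1/2 + [E]) + k_off,T:H`.
* **Synthetic-assay generators** with embedded ground truth and seeded
  noise, so every stage is validated by parameter recovery.

## Worked example

Generate a synthetic multi-cycle SPR experiment for a system with a true
2,400-fold acceleration (base off-rate 1e-5 s⁻¹, eight twofold effector
dilutions plus an effector-free baseline cycle, 0.5% noise), then
recover the kinetics with the global fit:

```r
library(fdkin)
truth <- list(k_off_T_H = 1e-5, k_off_T_HE = 2.4e-2,
              k_on_TH_E = 1e5, k_off_TH_E = 1e-4, k_off_T_Hn = 1e-5,
              f_responsive = 0.95)
cs  <- gen_cycleset(truth, experiment_design(dt = 10), noise_model(seed = 42))
rep <- characterize_forward(cs)
```

Output of this run:

```
fold_acceleration: 2411.6
K_half: 3.46e-07 M
k_off_T_H: 1e-05  k_off_T_HE: 0.0242  f_responsive: 0.951
rms: 0.005186
```

The fold acceleration is recovered within 0.5% of the generating truth;
`K_half` is the effector concentration at which half the maximal rate
increase is reached; the residual RMS matches the injected noise level
(0.5% of full scale), indicating the model accounts for the data down to
the noise floor. The `(k_on_TH_E, k_off_TH_E)` pair is reported with a
weak-identifiability flag — only its joint effect is constrained.

## Analysis workflow

The numbered scripts under `analysis/` run the full study on synthetic
data (from the repository root):

1. `01_simulate_assays.R` — generate cycle sets at 20×–5,700× fold
   acceleration, an FP titration, reverse-FD courses, a sensor trace.
2. `02_fit_traces.R` — closed-form trace fits at the characteristic rates.
3. `03_global_spr_fit.R` — global fits; all folds recovered within 2.3%.
4. `04_mechanism_discrimination.R` — linear vs hyperbolic law selection,
   40/40 replicates classified correctly.
5. `05_parameter_recovery.R` — random-truth recovery sweep, 94% of key
   parameters within 5%.

Each writes its table under `results/`; bulky datasets go to `scratch/`.

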