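---
title: "A delayed model of stress-feedback-limited recombinant protein production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A delayed model of stress-feedback-limited recombinant protein production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
```

```{r setup, message = FALSE}
library(rppfeedback)
library(dplyr)
library(ggplot2)
```

## The system

High-level expression of a recombinant protein stresses an *E. coli*
host: folding capacity is exhausted and a large share of the product is
deposited in insoluble inclusion bodies. `rppfeedback` models a synthetic
circuit that lets the cell throttle its own production: GFP is expressed
from a T7/TetO promoter (T7 polymerase itself induced by IPTG), while the
misfolded-protein-responsive promoter of the inclusion-body-binding
protein operon drives a degradation-tagged TetR repressor. Rising
aggregate load therefore feeds back negatively on transcription of the
product gene.

The model tracks eight species: mRNA and protein for T7 polymerase
(`m_T7`, `p_T7`) and TetR (`m_R`, `p_R`), GFP mRNA (`m_G`), and three GFP
protein pools — the folding intermediate `g_F` (which doubles as the
soluble-aggregate pool), natively folded fluorescent GFP `g_N`, and
inclusion-body GFP `g_I`. Regulation enters through three Hill terms:

* IPTG activation of T7-polymerase expression, with a basal (leaky)
  floor `basal_T7`;
* TetR repression of the product promoter, `1 / (1 + (p_R/K_tetR)^n)`;
* stress activation of the repressor promoter, driven by the
  misfolded + aggregated load `s = g_F + g_I` (the sensor operon binds
  inclusion bodies, so native GFP does not signal stress), again with a
  basal floor `basal_R`.

Transcription and translation are delayed by `tau_tx` and `tau_tl`
(shared across genes — the minimal delayed structure the biology
commits to), every species is diluted by growth at a constant rate
`mu0`, and first-order degradation acts per species, with a large `d_R`
representing the degradation tag on TetR. The folding intermediate
drains into the native pool at `k_fold` and into inclusions at `k_agg`;
inclusion-body protein is cleared at `k_ib_deg`. Only `g_N` fluoresces;
`fluorescence_equiv = g_N / c_fluor` is the quantity compared with
plate-reader fluorescence per OD600, while `total_gfp` corresponds to
gel-based quantification.

A *feedback variant* is a promoter-strength × RBS-strength pair
(`promoter_scale` on `k_tx_R` and `basal_R`, `rbs_scale` on `k_tl_R`).
Four presets ship with the package: `NO_FB` (control, no repressor),
`WT_STRONG` (wild-type stress promoter, strong RBS), `MUT_STRONG`
(weakened promoter mutant, strong RBS) and `MUT_WEAK` (weaker promoter
mutant, weak RBS).

## Simulating the standard batch experiment

History before `t = 0` is the uninduced steady state (computed by long
integration at growth rate `mu0` with a stagnation test; the default
burn-in horizon is `50 / mu0` hours, doubled on demand). The standard
protocol induces with 1 mM IPTG at 2 h and follows the culture for 12 h.

```{r simulate}
params <- circuit_params()
sched <- induction_schedule(iptg_conc = 1, t_induce = 2, t_end = 12)
panel <- simulate_variant_panel(params, variant_presets(), sched)
plot_variant_panel(panel$trajectories, "total_gfp")
```

```{r compare}
panel$comparison |>
  select(variant, total_gfp_end, soluble_fraction_8h, max_reduction_pct)
```

The calibrated canonical parameter set reproduces the experimental
signatures: the strongest feedback cuts GFP by roughly 70% relative to
the control, reductions order with feedback strength, and every feedback
variant shows an equal-or-higher soluble fraction at the 8-h
fractionation time. The solubility gain in this model arises from
timing: feedback front-loads production, and because inclusion-body GFP
turns over faster than native GFP (`k_ib_deg > d_G`), an older protein
population is more soluble. The gain is accordingly modest — a few
percentage points — smaller than measured fractionation differences,
consistent with the model not describing chaperone-capacity depletion.

## Numerical machinery

The delayed system is integrated with `deSolve::dede` (Adams/BDF with
interpolated solution history — the same method-of-steps family as
MATLAB's `dde23`, which this formulation targets). The induction switch
is a derivative discontinuity, so the event time and its delayed images
are forced onto the solver mesh. With both delays zero the model
dispatches to a plain stiff ODE solve. Default tolerances are
`rel_tol = 1e-8`, `abs_tol = 1e-12`; fitting-grade runs use `1e-6`/`1e-9`
since measurement noise dominates integration error there. Integration
round-off can leave concentrations infinitesimally negative; values in
`[-1e-9, 0]` are clamped to zero and anything below that range raises an
error rather than being masked.

Two independent verification routes guard the integrator: a hand-written
fixed-step Euler scheme with a dense history buffer (`euler_oracle`,
first-order, used only for cross-checks) and, in the zero-delay limit,
an implicit Runge-Kutta (radau) reference. Auxiliary cumulative fluxes
(translated, degraded, diluted GFP) are integrated alongside the state
so tests can close the mass balance exactly.

## What the synthetic data generator emulates

`generate_timecourse()` mimics a batch plate-reader experiment: four
biological replicates by default, sampled every 30 min over 12 h.
Clone-to-clone variability — a prominent experimental feature — enters
as lognormal multipliers (median 1) on stress-promoter strength, RBS
efficiency and growth rate; the default sigmas (0.25, 0.25, 0.08) are
conventions chosen to reproduce "high variability between clones", not
measured values. Measurement noise is multiplicative lognormal with unit
mean (default CV 10% on fluorescence, 5% on OD; replicate noise
magnitudes are likewise conventions). OD600 itself is synthesized as
exponential growth from inoculation density 0.1 capped at a stationary
ceiling, because the circuit model deliberately keeps `mu` constant —
fluorescence per OD is the fitted observable, so growth curve shape
never enters the likelihood. `generate_fraction_measurements()` emulates
the 8-h soluble/insoluble fractionation, reporting totals relative to
the mean no-feedback clone (reference content 1) and truncating noisy
fractions to [0, 1].

What passing tests on these data do **not** show: correctness under
burden-coupled growth (real cultures slow down as expression load
rises), resource competition between TetR and GFP synthesis,
higher-order aggregation kinetics (aggregation here is first-order in
the intermediate pool), or media effects beyond re-setting `mu0`.

## Fitting, identifiability and the two key knobs

`fit_parameters()` minimizes squared log-residuals on fluorescence
(matching the multiplicative noise) plus linear residuals on any
attached fraction table, weighted by the square root of the count ratio
so both data kinds contribute comparably. Optimization is bounded
Levenberg-Marquardt in log-parameter space. Two numerical choices proved
load-bearing:

* a Latin-hypercube *screening* phase scores candidates across the
  bounds and only the best are polished, because the log-residual
  landscape is multi-modal;
* the finite-difference Jacobian step (`epsfcn = 1e-6`, i.e. relative
  steps near `1e-3`) is held well above the integrator's noise floor —
  with machine-epsilon steps the Jacobian is garbage and the optimizer
  silently stalls at its start.

One structural identifiability fact matters when choosing free
parameters: only the ratio `p_R / K_tetR` reaches the product gene, and
the repressor level is linear in `k_tx_R` (and `k_tl_R`), so
`{k_tx_R, K_tetR}` freed jointly form an exact scaling ridge for *any*
GFP-based dataset — their ratio is recoverable, the individual values
are not. The recovery benchmark therefore frees the identifiable triple
`{k_tx_R, K_stress, k_agg}`. On 20 synthetic datasets at 5% noise the
median relative recovery error of each is well under 15%, with the
aggregation rate pinned most tightly and the two stress-arm parameters
showing the sloppiest (but bounded) directions.

`local_sensitivity()` ranks parameters by normalized central-difference
coefficients of end-point total GFP and soluble fraction; the top of the
ranking is stable across perturbation sizes, singling out the same small
set of processes (translation/folding of the product and the stress
arm's strength) as the levers that matter. `cross_validate()` refits on
leave-one-clone-out splits; with an honest model and 10% noise the
test/train error ratio stays near 1.

## Problem sizes and defaults used in checks

Automated checks simulate the four-variant panel at 0.25-h resolution,
verify the oracle at `dt = 1e-4` h over the 12-h horizon, run the
monotonicity grid over promoter/RBS scales in `[0, 1]` (the range the
constructed variants span; far beyond the wild-type strength the
basal-repression delay can shave fractions of a percent off the 8-h
soluble fraction), and use 20 recovery datasets with 2 polishing starts
over a 25-point screen. These sizes were chosen to characterize the
estimator honestly at interactive cost.

## Known limitations

* Growth is constant at `mu0`: no stationary-phase transition, no
  burden coupling (exposed as a single scenario parameter, not a
  dynamic state).
* Aggregation is first-order; crowding-accelerated inclusion growth
  would change the yield/solubility trade-off quantitatively.
* The soluble-aggregate pool of the protein-fate scheme is merged into
  `g_F`; with only soluble/insoluble end-point data a separate pool is
  unidentifiable.
* `c_fluor` is a configurable conversion constant, fittable in
  principle but perfectly confounded with overall expression scale
  unless absolute calibration data are supplied.
* TetR levels (Western-blot-like data) are modeled but not used in the
  default objective; adding them would break the `k_tx_R`/`K_tetR`
  ridge.
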