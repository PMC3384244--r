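# rppfeedback

Modeling a self-limiting recombinant protein production circuit in
*E. coli*: IPTG-induced T7 polymerase drives GFP expression from a
T7/TetO promoter, while the misfolded-protein stress promoter
P<sub>IbpAB</sub> expresses a degradation-tagged TetR repressor —
a negative feedback loop in which aggregate load throttles further
production, trading total yield for a higher soluble fraction.

The package is for systems/synthetic biologists who want to simulate,
calibrate and interrogate this class of circuit on plate-reader-style
data. The core is a delay differential equation model with eight
species (mRNA/protein for T7 polymerase and TetR; GFP mRNA; folding
intermediate, native and inclusion-body GFP pools):

```
m_T7'(t) = k_tx_T7 · H_act(IPTG(t−τ_tx); K_iptg, n, basal_T7) − (d_m + μ)·m_T7
p_T7'(t) = k_tl_T7 · m_T7(t−τ_tl) − (d_T7 + μ)·p_T7
m_G'(t)  = k_tx_G · p_T7(t−τ_tx) / (1 + (p_R(t−τ_tx)/K_tetR)^n_tetR) − (d_m + μ)·m_G
g_F'(t)  = k_tl_G · m_G(t−τ_tl) − (k_fold + k_agg + d_G + μ)·g_F
g_N'(t)  = k_fold·g_F − (d_G + μ)·g_N
g_I'(t)  = k_agg·g_F − (k_ib_deg + μ)·g_I
m_R'(t)  = k_tx_R · H_act(g_F + g_I at t−τ_tx; K_stress, n, basal_R) − (d_m + μ)·m_R
p_R'(t)  = k_tl_R · m_R(t−τ_tl) − (d_R + μ)·p_R
```

where `H_act(x; K, n, b) = b + (1−b)·xⁿ/(Kⁿ+xⁿ)`. Only native GFP
(`g_N`) fluoresces; the soluble fraction is `(g_F+g_N)/(g_F+g_N+g_I)`.
Around the model sit a pre-induction steady-state solver, a fixed-step
verification oracle, a synthetic data generator with clone-to-clone
variability, multi-start parameter estimation, local sensitivity
analysis, cross-validation, and variant comparison reporting. See the
vignette `vignettes/stress-feedback-model.Rmd` for the full account.

## Worked example

Simulate the four studied circuit variants under the standard protocol
(1 mM IPTG at 2 h, 12-h batch) and compare them against the no-feedback
control:

```r
library(rppfeedback)
library(dplyr)

panel <- simulate_variant_panel(circuit_params(), variant_presets(),
                                induction_schedule(iptg_conc = 1,
                                                   t_induce = 2,
                                                   t_end = 12))
panel$comparison |>
  select(variant, total_gfp_end, soluble_fraction_8h, max_reduction_pct)
#> # A tibble: 4 × 4
#>   variant    total_gfp_end soluble_fraction_8h max_reduction_pct
#>   <chr>              <dbl>               <dbl>             <dbl>
#> 1 NO_FB              2265.               0.631               0
#> 2 WT_STRONG           659.               0.652              71.5
#> 3 MUT_STRONG         1395.               0.635              38.1
#> 4 MUT_WEAK           1994.               0.632              11.8
```

Reading the table: the control accumulates ~2.3 µM total GFP by 12 h
with 63% of it soluble at the 8-h fractionation time. The strongest
feedback (wild-type stress promoter, strong RBS) cuts fluorescent GFP
by a maximum of ~71% relative to the control while raising the 8-h
soluble fraction; the weakened promoter/RBS variants interpolate, in
order of feedback strength. Generate matching synthetic plate-reader
data with `generate_paperlike_suite(seed = 1)`, fit parameters with
`fit_parameters()`, and run everything end-to-end from a config file
with `run_pipeline()` (a shell wrapper lives in
`inst/scripts/circuit-pipeline.R`; a demo config in
`inst/extdata/demo_config.yaml`).

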