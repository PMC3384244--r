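# shared fixtures: a short batch protocol and fitting-grade tolerances
# keep unit tests fast; full-length runs live in test-acceptance.R

quick_settings <- function() solver_settings(rel_tol = 1e-6, abs_tol = 1e-9)

short_schedule <- function() induction_schedule(iptg_conc = 1, t_induce = 1,
                                                t_end = 6)

# memoize the canonical trajectories used by several files
traj_cache <- new.env(parent = emptyenv())

cached_traj <- function(variant, schedule = short_schedule(),
                        settings = quick_settings(),
                        times = seq(0, schedule$t_end, by = 0.25)) {
  key <- paste(variant, schedule$t_end, sep = "_")
  if (is.null(traj_cache[[key]])) {
    traj_cache[[key]] <- simulate_circuit(circuit_params(), variant,
                                          schedule, settings, times = times)
  }
  traj_cache[[key]]
}

# random-but-reproducible parameter draws for property-style tests
random_params <- function(seed) {
  withr::with_seed(seed, {
    jitter <- function(x, f = 2) x * exp(stats::runif(1, -log(f), log(f)))
    p <- circuit_params()
    circuit_params(
      mu0 = jitter(p$mu0, 1.5), k_tx_T7 = jitter(p$k_tx_T7),
      K_iptg = jitter(p$K_iptg), basal_T7 = stats::runif(1, 0, 0.1),
      k_tx_G = jitter(p$k_tx_G), K_tetR = jitter(p$K_tetR),
      k_tx_R = jitter(p$k_tx_R), basal_R = stats::runif(1, 0, 0.1),
      K_stress = jitter(p$K_stress), k_tl_T7 = jitter(p$k_tl_T7),
      k_tl_G = jitter(p$k_tl_G), k_tl_R = jitter(p$k_tl_R),
      tau_tx = stats::runif(1, 0.05, 0.3), tau_tl = stats::runif(1, 0.05, 0.3),
      d_m = jitter(p$d_m, 1.5), d_T7 = jitter(p$d_T7),
      d_G = jitter(p$d_G), d_R = jitter(p$d_R),
      k_fold = jitter(p$k_fold), k_agg = jitter(p$k_agg),
      k_ib_deg = jitter(p$k_ib_deg)
    )
  })
}
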