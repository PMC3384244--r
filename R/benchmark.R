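#' Parameter-recovery benchmark
#'
#' Ground-truth recovery harness: repeatedly generates a synthetic
#' strong-feedback time course from the canonical parameters, then refits
#' a chosen free-parameter subset starting away from the truth (each free
#' parameter displaced by `displace`, plus Latin-hypercube restarts), and
#' reports per-dataset relative estimation errors.
#'
#' @param n_datasets number of independent synthetic datasets.
#' @param free parameters to estimate. The default triple (stress-promoter
#'   strength, stress half-activation constant, aggregation rate) is
#'   structurally identifiable from fluorescence data; note that
#'   `k_tx_R` and `K_tetR` cannot be freed jointly, since only the ratio
#'   of repressor level to `K_tetR` enters the GFP branch.
#' @param noise_cv fluorescence CV of the measurement noise.
#' @param n_clones replicates per dataset.
#' @param params true [circuit_params()].
#' @param variant variant generating the data.
#' @param schedule an [induction_schedule()].
#' @param sampling_times measurement grid (h).
#' @param displace multiplicative displacement of the optimizer's first
#'   start from the truth.
#' @param n_starts optimizer starts per dataset.
#' @param seed integer seed.
#' @return A tibble with one row per dataset and free parameter:
#'   `dataset`, `term`, `truth`, `estimate`, `rel_error`.
#' @export
recovery_benchmark <- function(n_datasets = 20,
                               free = c("k_tx_R", "K_stress", "k_agg"),
                               noise_cv = 0.05, n_clones = 4,
                               params = circuit_params(),
                               variant = "WT_STRONG",
                               schedule = induction_schedule(),
                               sampling_times = seq(0, 12, by = 0.5),
                               displace = 2.5, n_starts = 2, seed = 1) {
  truth <- vapply(free, function(nm) params[[nm]], numeric(1))
  init <- set_free(params, free, truth * displace)
  bounds <- lapply(stats::setNames(free, free),
                   function(nm) c(params[[nm]] / 10, params[[nm]] * 10))
  nm_model <- noise_model(fluor_cv = noise_cv, od_cv = 0, fraction_sd = 0)
  cv0 <- clone_variability(0, 0, 0)
  purrr::map_dfr(seq_len(n_datasets), function(i) {
    ds <- generate_timecourse(params, variant, schedule, sampling_times,
                              n_clones = n_clones, noise = nm_model,
                              clone_var = cv0, seed = seed + 1000L * i)
    fit <- fit_parameters(ds, init, free, bounds = bounds,
                          schedule = schedule, n_starts = n_starts,
                          seed = seed + i)
    tibble::tibble(dataset = i, term = free, truth = unname(truth),
                   estimate = unname(fit$estimates[free]),
                   rel_error = abs(unname(fit$estimates[free]) -
                                     unname(truth)) / unname(truth))
  })
}
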