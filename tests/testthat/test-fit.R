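test_that("fluorescence-molarity conversion is an exact linear inverse pair", {
  expect_equal(fluorescence_to_molarity(0, 100), 0)
  expect_equal(fluorescence_to_molarity(c(1, 2.5), 1), c(1, 2.5))
  p <- circuit_params()
  x <- c(0.3, 7, 42)
  expect_equal(fluorescence_to_molarity(x / p$c_fluor, p), x)
  expect_error(fluorescence_to_molarity(1, 0), "positive")
  expect_error(fluorescence_to_molarity(-1, 1), "nonnegative")
})

test_that("starting at the truth on noiseless data stays at the optimum", {
  p <- circuit_params()
  sched <- short_schedule()
  ds <- generate_timecourse(p, "WT_STRONG", sched,
                            sampling_times = seq(0, 6, 1), n_clones = 2,
                            noise = noise_model(0, 0, 0),
                            clone_var = clone_variability(0, 0, 0),
                            seed = 1, settings = quick_settings())
  fit <- fit_parameters(ds, p, free = c("k_tx_R", "K_tetR"),
                        schedule = sched, n_starts = 1, seed = 1)
  expect_lt(fit$objective, 1e-8)
  expect_equal(unname(fit$estimates["k_tx_R"]), p$k_tx_R, tolerance = 1e-3)
})

test_that("noiseless recovery from a displaced start lands within 5%", {
  p <- circuit_params()
  sched <- short_schedule()
  tight <- solver_settings(rel_tol = 1e-8, abs_tol = 1e-11)
  ds <- generate_timecourse(p, "WT_STRONG", sched,
                            sampling_times = seq(0, 6, 0.5), n_clones = 2,
                            noise = noise_model(0, 0, 0),
                            clone_var = clone_variability(0, 0, 0),
                            seed = 2, settings = tight)
  free <- c("k_tx_R", "K_stress", "k_agg")
  init <- update_params(p, k_tx_R = p$k_tx_R * 3, K_stress = p$K_stress / 3,
                        k_agg = p$k_agg * 2)
  bounds <- lapply(stats::setNames(free, free),
                   function(nm) c(p[[nm]] / 10, p[[nm]] * 10))
  fit <- fit_parameters(ds, init, free, bounds = bounds, schedule = sched,
                        settings = tight, n_starts = 2, seed = 3)
  for (nm in free) {
    expect_lt(abs(fit$estimates[[nm]] - p[[nm]]) / p[[nm]], 0.05)
  }
})

test_that("the repressor strength / repression constant pair is a scaling ridge", {
  # only p_R / K_tetR reaches the GFP branch: scaling k_tx_R and K_tetR
  # together leaves the observable unchanged, so the individual values are
  # unidentifiable from fluorescence while their ratio is recovered
  p <- circuit_params()
  sched <- short_schedule()
  ds <- generate_timecourse(p, "WT_STRONG", sched,
                            sampling_times = seq(0, 6, 0.5), n_clones = 2,
                            noise = noise_model(0, 0, 0),
                            clone_var = clone_variability(0, 0, 0),
                            seed = 2, settings = quick_settings())
  free <- c("k_tx_R", "K_tetR")
  init <- update_params(p, k_tx_R = p$k_tx_R * 5, K_tetR = p$K_tetR * 5)
  fit <- suppressWarnings(
    fit_parameters(ds, init, free, schedule = sched, n_starts = 1,
                   seed = 1)
  )
  # on the ridge: near-zero objective away from the individual truth
  expect_lt(fit$objective, 1e-4)
  expect_gt(fit$estimates[["k_tx_R"]], 2 * p$k_tx_R)
  expect_equal(fit$estimates[["k_tx_R"]] / fit$estimates[["K_tetR"]],
               p$k_tx_R / p$K_tetR, tolerance = 0.02)
})

test_that("an underdetermined fit request emits a rank diagnostic", {
  p <- circuit_params()
  sched <- short_schedule()
  ds <- generate_timecourse(p, "WT_STRONG", sched, sampling_times = 6,
                            n_clones = 2, noise = noise_model(0, 0, 0),
                            clone_var = clone_variability(0, 0, 0),
                            seed = 4, settings = quick_settings())
  w <- capture_warnings(
    fit_parameters(ds, p, free = c("k_tx_R", "K_tetR", "k_agg"),
                   schedule = sched, n_starts = 1, seed = 1)
  )
  expect_match(w, "underdetermined", all = FALSE)
})

test_that("the objective ignores record order and replicate relabeling", {
  p <- circuit_params()
  sched <- short_schedule()
  ds <- generate_timecourse(p, "WT_STRONG", sched,
                            sampling_times = seq(0, 6, 2), n_clones = 2,
                            seed = 6, settings = quick_settings())
  perm <- withr::with_seed(8, sample.int(nrow(ds)))
  shuffled <- tibble::as_tibble(ds)[perm, ]
  shuffled$clone_id <- sub("clone01", "cloneZZ", shuffled$clone_id)
  r1 <- rppfeedback:::dataset_residuals(p, ds, variant_presets(), sched,
                                        quick_settings())
  r2 <- rppfeedback:::dataset_residuals(p, shuffled, variant_presets(),
                                        sched, quick_settings())
  expect_equal(sum(r1^2), sum(r2^2), tolerance = 1e-12)
})

test_that("unknown free parameters and unmapped variants are rejected", {
  p <- circuit_params()
  ds <- generate_timecourse(p, "WT_STRONG", short_schedule(),
                            sampling_times = c(0, 3), n_clones = 1,
                            seed = 1, settings = quick_settings())
  expect_error(fit_parameters(ds, p, free = "k_magic"), "unknown")
  ds2 <- ds
  ds2$variant <- "mystery"
  expect_error(fit_parameters(ds2, p, free = "k_agg"), "mystery")
})
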