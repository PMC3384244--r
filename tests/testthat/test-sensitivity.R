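test_that("pure-rescaling and disconnected parameters have exact coefficients", {
  p <- circuit_params()
  sched <- short_schedule()
  # c_fluor only divides the fluorescence readout: S = -1 exactly
  rep_c <- local_sensitivity(p, "WT_STRONG", sched,
                             outputs = "fluorescence_equiv",
                             parameters = "c_fluor", perturbation = 0.01,
                             settings = quick_settings())
  expect_equal(rep_c$coefficient, -1, tolerance = 1e-3)
  # no path from the TetR arm to GFP without feedback
  rep_r <- local_sensitivity(p, "NO_FB", sched,
                             outputs = "total_gfp",
                             parameters = c("k_tx_R", "k_tl_R", "K_tetR"),
                             settings = quick_settings())
  expect_equal(rep_r$coefficient, rep(0, 3), tolerance = 1e-6)
})

test_that("coefficients converge as the perturbation shrinks", {
  p <- circuit_params()
  sched <- short_schedule()
  pars <- c("k_tl_G", "k_agg", "K_stress")
  s_big <- local_sensitivity(p, "WT_STRONG", sched, perturbation = 0.08,
                             parameters = pars,
                             settings = quick_settings())
  s_small <- local_sensitivity(p, "WT_STRONG", sched, perturbation = 0.02,
                               parameters = pars,
                               settings = quick_settings())
  # central differences: error drops ~16x for a 4x smaller step, so the
  # two estimates must already be close
  expect_equal(s_small$coefficient, s_big$coefficient, tolerance = 0.02)
})

test_that("the influence ranking is stable across perturbation sizes", {
  p <- circuit_params()
  sched <- short_schedule()
  r1 <- local_sensitivity(p, "WT_STRONG", sched, perturbation = 0.01,
                          settings = quick_settings())
  r5 <- local_sensitivity(p, "WT_STRONG", sched, perturbation = 0.05,
                          settings = quick_settings())
  expect_identical(sensitivity_ranking(r1)[1:2], sensitivity_ranking(r5)[1:2])
  expect_setequal(sensitivity_ranking(r1), names(p))
})

test_that("perturbation bounds are enforced", {
  expect_error(local_sensitivity(circuit_params(), perturbation = 0),
               "perturbation")
  expect_error(local_sensitivity(circuit_params(), perturbation = 0.9),
               "perturbation")
})
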