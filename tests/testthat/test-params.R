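test_that("parameter validation enforces the physical constraints", {
  expect_s3_class(circuit_params(), "circuit_params")
  expect_error(circuit_params(mu0 = -0.1), "nonnegative")
  expect_error(circuit_params(n_tetR = 0.5), ">= 1")
  expect_error(circuit_params(basal_T7 = 1.2), "\\[0, 1\\]")
  expect_error(update_params(circuit_params(), nope = 1), "unknown")
  p2 <- update_params(circuit_params(), k_agg = 3)
  expect_equal(p2$k_agg, 3)
  expect_equal(p2$k_fold, circuit_params()$k_fold)
})

test_that("variant presets cover the four studied circuits and NO_FB is inert", {
  pre <- variant_presets()
  expect_named(pre, c("NO_FB", "WT_STRONG", "MUT_STRONG", "MUT_WEAK"))
  expect_identical(pre$NO_FB$promoter_scale, 0)
  # custom NO_FB label forces zero promoter activity
  v <- feedback_variant("NO_FB", promoter_scale = 2, rbs_scale = 1)
  expect_identical(v$promoter_scale, 0)
  expect_error(feedback_variant("custom"), "required")
  expect_error(feedback_variant("x", promoter_scale = -1, rbs_scale = 1),
               "nonnegative")
})

test_that("applying a variant rescales only the TetR arm", {
  p <- circuit_params()
  pv <- apply_variant(p, feedback_variant("half", promoter_scale = 0.5,
                                          rbs_scale = 0.25))
  expect_equal(pv$k_tx_R, p$k_tx_R * 0.5)
  expect_equal(pv$basal_R, p$basal_R * 0.5)
  expect_equal(pv$k_tl_R, p$k_tl_R * 0.25)
  same <- setdiff(names(p), c("k_tx_R", "basal_R", "k_tl_R"))
  expect_identical(unclass(pv)[same], unclass(p)[same])
  p0 <- apply_variant(p, "NO_FB")
  expect_identical(p0$k_tx_R, 0)
  expect_identical(p0$basal_R, 0)
})

test_that("induction schedules are validated", {
  expect_error(induction_schedule(t_induce = 5, t_end = 3), "t_induce")
  expect_error(induction_schedule(iptg_conc = -1), "nonnegative")
  s <- induction_schedule()
  expect_equal(c(s$iptg_conc, s$t_induce, s$t_end), c(1, 2, 12))
})

test_that("config files round-trip parameters, variants and schedule", {
  cfg <- file.path(tempdir(), "cfg.yaml")
  writeLines(c(
    "parameters:", "  mu0: 0.4", "  K_tetR: 15",
    "variants:",
    "  - label: NO_FB", "    promoter_scale: 0", "    rbs_scale: 1",
    "  - label: custom", "    promoter_scale: 0.7", "    rbs_scale: 0.3",
    "schedule:", "  iptg_conc: 0.5", "  t_induce: 1", "  t_end: 8"
  ), cfg)
  parsed <- read_circuit_config(cfg)
  expect_equal(parsed$params$mu0, 0.4)
  expect_equal(parsed$params$K_tetR, 15)
  expect_equal(parsed$params$k_agg, circuit_params()$k_agg)
  expect_named(parsed$variants, c("NO_FB", "custom"))
  expect_equal(parsed$variants$custom$rbs_scale, 0.3)
  expect_equal(parsed$schedule$t_end, 8)
  expect_error(read_circuit_config("does_not_exist.yaml"), "not found")
})
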