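test_that("steady-state search handles the extinct and leaky circuits", {
  p_off <- circuit_params(basal_T7 = 0, basal_R = 0)
  ss <- find_preinduction_steady_state(p_off, quick_settings())
  expect_equal(max(abs(unclass(ss))), 0)
  # burn-in convergence: doubling the horizon does not move the state
  p <- apply_variant(circuit_params(), "WT_STRONG")
  ss1 <- find_preinduction_steady_state(p, quick_settings())
  ss_ref <- find_preinduction_steady_state(p, solver_settings(
    rel_tol = 1e-10, abs_tol = 1e-13, steady_state_tol = 1e-8))
  expect_equal(unclass(ss1)[1:8], unclass(ss_ref)[1:8], tolerance = 1e-4)
})

test_that("trajectories cover the batch horizon with the induction event", {
  traj <- cached_traj("WT_STRONG")
  expect_s3_class(traj, "circuit_trajectory")
  expect_equal(min(traj$time), 0)
  expect_equal(max(traj$time), short_schedule()$t_end)
  expect_true(all(diff(traj$time) > 0))
  ev <- attr(traj, "events")
  expect_equal(ev$time, short_schedule()$t_induce)
  expect_equal(ev$event, "induction")
  # state at t = 0 is the steady-state history value
  ss <- find_preinduction_steady_state(
    apply_variant(circuit_params(), "WT_STRONG"), quick_settings())
  expect_equal(unname(unlist(traj[1, c("p_T7", "g_N", "p_R")])),
               unname(unclass(ss)[c("p_T7", "g_N", "p_R")]),
               tolerance = 1e-6)
})

test_that("identical inputs give bit-identical trajectories", {
  a <- simulate_circuit(circuit_params(), "MUT_STRONG", short_schedule(),
                        quick_settings(), times = seq(0, 6, 0.5))
  b <- simulate_circuit(circuit_params(), "MUT_STRONG", short_schedule(),
                        quick_settings(), times = seq(0, 6, 0.5))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("all species stay nonnegative across random parameter draws", {
  for (seed in 1:6) {
    p <- random_params(seed)
    traj <- simulate_circuit(p, "WT_STRONG", short_schedule(),
                             quick_settings(), times = seq(0, 6, 0.5))
    sp <- c("m_T7", "p_T7", "m_G", "g_F", "g_N", "g_I", "m_R", "p_R")
    expect_true(all(as.matrix(traj[, sp]) >= 0),
                label = paste("nonnegativity, seed", seed))
  }
})

test_that("halving tolerances leaves end-point observables unchanged", {
  s1 <- solver_settings(rel_tol = 1e-6, abs_tol = 1e-9)
  s2 <- solver_settings(rel_tol = 5e-7, abs_tol = 5e-10)
  a <- simulate_circuit(circuit_params(), "WT_STRONG", short_schedule(),
                        s1, times = 6)
  b <- simulate_circuit(circuit_params(), "WT_STRONG", short_schedule(),
                        s2, times = 6)
  end_a <- a[nrow(a), c("total_gfp", "soluble_fraction")]
  end_b <- b[nrow(b), c("total_gfp", "soluble_fraction")]
  expect_lt(abs(end_a$total_gfp - end_b$total_gfp) / end_b$total_gfp, 1e-5)
  expect_lt(abs(end_a$soluble_fraction - end_b$soluble_fraction), 1e-5)
})

test_that("zero-delay dispatch matches an implicit stiff reference", {
  p0 <- update_params(circuit_params(), tau_tx = 0, tau_tl = 0)
  sched <- short_schedule()
  tt <- seq(0, 6, by = 0.5)
  tr <- simulate_circuit(p0, "WT_STRONG", sched,
                         solver_settings(rel_tol = 1e-10, abs_tol = 1e-12),
                         times = tt)
  pv <- apply_variant(p0, "WT_STRONG")
  y0 <- unclass(find_preinduction_steady_state(pv, quick_settings()))
  parms <- list(params = pv, schedule = sched, y0 = y0, t0 = 0)
  ref <- deSolve::ode(y = y0, times = sort(unique(c(tt, sched$t_induce))),
                      func = rppfeedback:::dede_func, parms = parms,
                      method = "radau", rtol = 1e-11, atol = 1e-13)
  ref <- ref[ref[, 1] %in% tt, ]
  sp <- c("m_T7", "p_T7", "m_G", "g_F", "g_N", "g_I", "m_R", "p_R")
  scale <- apply(abs(ref[, 2:9]), 2, max)
  err <- max(abs(as.matrix(tr[, sp]) - ref[, 2:9]) /
               rep(scale + 1e-12, each = length(tt)))
  expect_lt(err, 1e-6)
})

test_that("observables partition total GFP and invert the fluorescence map", {
  p <- circuit_params()
  s <- circuit_state(g_N = 3, g_F = 1, g_I = 4)
  ob <- observables(s, p)
  expect_equal(ob$total_gfp, 8)
  expect_equal(ob$soluble_fraction, 0.5)
  expect_equal(fluorescence_to_molarity(ob$fluorescence_equiv, p), 3)
  # empty cell convention
  expect_equal(observables(circuit_state(), p)$soluble_fraction, 1)
})
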