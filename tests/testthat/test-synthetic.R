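test_that("a noiseless single-clone dataset reproduces the model exactly", {
  p <- circuit_params()
  sched <- short_schedule()
  tt <- seq(0, 6, 1)
  ds <- generate_timecourse(p, "WT_STRONG", sched, sampling_times = tt,
                            n_clones = 1, noise = noise_model(0, 0, 0),
                            clone_var = clone_variability(0, 0, 0),
                            seed = 5, settings = quick_settings())
  traj <- simulate_circuit(p, "WT_STRONG", sched, quick_settings(),
                           times = tt)
  expect_equal(ds$fluorescence_per_od,
               traj$fluorescence_equiv[match(tt, traj$time)],
               tolerance = 1e-12)
  expect_equal(nrow(ds), length(tt))
})

test_that("datasets are reproducible from the seed", {
  args <- list(circuit_params(), "MUT_STRONG", short_schedule(),
               sampling_times = seq(0, 6, 1), n_clones = 3, seed = 11,
               settings = quick_settings())
  a <- do.call(generate_timecourse, args)
  b <- do.call(generate_timecourse, args)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- do.call(generate_timecourse, utils::modifyList(args, list(seed = 12)))
  expect_false(identical(a$fluorescence_per_od, c$fluorescence_per_od))
})

test_that("measurement noise is calibrated: empirical CV matches the model", {
  ds <- generate_timecourse(circuit_params(), "NO_FB", short_schedule(),
                            sampling_times = 6, n_clones = 200,
                            noise = noise_model(fluor_cv = 0.1, od_cv = 0,
                                                fraction_sd = 0),
                            clone_var = clone_variability(0, 0, 0),
                            seed = 3, settings = quick_settings())
  cv <- stats::sd(ds$fluorescence_per_od) / mean(ds$fluorescence_per_od)
  expect_gt(cv, 0.08)
  expect_lt(cv, 0.12)
})

test_that("sampling outside the horizon is refused", {
  expect_error(
    generate_timecourse(circuit_params(), "NO_FB", short_schedule(),
                        sampling_times = c(0, 7)),
    "within"
  )
})

test_that("fraction measurements are referenced to the no-feedback control", {
  p <- circuit_params()
  sched <- short_schedule()
  fr <- generate_fraction_measurements(
    p, variants = list("NO_FB", "WT_STRONG"), t_sample = 4, n_clones = 2,
    noise = noise_model(0, 0, 0), clone_var = clone_variability(0, 0, 0),
    seed = 7, schedule = sched, settings = quick_settings())
  expect_equal(fr$total_gfp_relative[fr$variant == "NO_FB"], c(1, 1))
  # zero noise: fractions equal the model's soluble fraction at t_sample
  traj <- simulate_circuit(p, "WT_STRONG", sched, quick_settings(),
                           times = 4)
  expect_equal(unique(fr$soluble_fraction[fr$variant == "WT_STRONG"]),
               traj$soluble_fraction[traj$time == 4], tolerance = 1e-10)
  expect_error(
    generate_fraction_measurements(p, variants = list("WT_STRONG"),
                                   t_sample = 4, schedule = sched),
    "NO_FB"
  )
  expect_error(
    generate_fraction_measurements(p, t_sample = 13, schedule = sched),
    "horizon"
  )
})

test_that("fraction noise respects the [0,1] truncation", {
  fr <- generate_fraction_measurements(
    circuit_params(), variants = list("NO_FB"), t_sample = 4,
    n_clones = 50, noise = noise_model(0, 0, 0.5),
    clone_var = clone_variability(0, 0, 0), seed = 2,
    schedule = short_schedule(), settings = quick_settings())
  expect_true(all(fr$soluble_fraction >= 0 & fr$soluble_fraction <= 1))
})

test_that("the canonical suite carries four clones of each variant", {
  ds <- generate_paperlike_suite(seed = 1, clone_var = clone_variability(),
                                 n_clones = 4)
  expect_s3_class(ds, "timecourse_dataset")
  counts <- table(unique(tibble::as_tibble(ds)[, c("variant",
                                                   "clone_id")])$variant)
  expect_equal(as.vector(counts[c("NO_FB", "WT_STRONG", "MUT_STRONG",
                                  "MUT_WEAK")]), rep(4L, 4))
  expect_true(all(ds$time >= 0 & ds$time <= 12))
  fr <- fraction_table(ds)
  expect_false(is.null(fr))
  expect_true(all(fr$soluble_fraction >= 0 & fr$soluble_fraction <= 1))
  expect_true(all(c("NO_FB", "WT_STRONG", "MUT_STRONG", "MUT_WEAK") %in%
                    fr$variant))
})

test_that("time-course CSV export round-trips with the fraction sidecar", {
  ds <- generate_timecourse(circuit_params(), "NO_FB", short_schedule(),
                            sampling_times = seq(0, 6, 2), n_clones = 2,
                            seed = 9, settings = quick_settings())
  path <- file.path(tempdir(), "tc.csv")
  write_timecourse(ds, path)
  back <- read_timecourse(path)
  expect_equal(data.frame(tibble::as_tibble(back)),
               data.frame(tibble::as_tibble(ds)), tolerance = 1e-12)
})
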