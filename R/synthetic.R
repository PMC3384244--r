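#' Measurement noise model
#'
#' Plate-reader-style measurement noise: multiplicative lognormal noise on
#' fluorescence and OD (parameterized by coefficient of variation, with
#' unit mean), and additive Gaussian noise on end-point soluble fractions,
#' truncated to `[0, 1]`.
#'
#' @param fluor_cv CV of the fluorescence-per-OD noise.
#' @param od_cv CV of the OD600 noise.
#' @param fraction_sd additive sd of soluble-fraction measurements.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(fluor_cv = 0.1, od_cv = 0.05, fraction_sd = 0.05) {
  if (fluor_cv < 0 || od_cv < 0 || fraction_sd < 0) {
    stop("noise magnitudes must be nonnegative", call. = FALSE)
  }
  structure(list(fluor_cv = fluor_cv, od_cv = od_cv,
                 fraction_sd = fraction_sd),
            class = "noise_model")
}

# unit-mean lognormal multipliers with the requested CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Clone-to-clone variability model
#'
#' Biological replicates (clones) differ in stress-promoter activity, RBS
#' efficiency and growth rate. Each clone draws independent lognormal
#' multipliers (median 1) on `promoter_scale`, `rbs_scale` and `mu0`.
#'
#' @param sigma_promoter,sigma_rbs,sigma_mu lognormal sigmas (sd of the
#'   log-multiplier) for the three clone-specific factors.
#' @return An object of class `clone_variability`.
#' @export
clone_variability <- function(sigma_promoter = 0.25, sigma_rbs = 0.25,
                              sigma_mu = 0.08) {
  if (sigma_promoter < 0 || sigma_rbs < 0 || sigma_mu < 0) {
    stop("sigmas must be nonnegative", call. = FALSE)
  }
  structure(list(sigma_promoter = sigma_promoter, sigma_rbs = sigma_rbs,
                 sigma_mu = sigma_mu),
            class = "clone_variability")
}

draw_clone_multipliers <- function(n_clones, clone_var) {
  tibble::tibble(
    clone = seq_len(n_clones),
    m_promoter = stats::rlnorm(n_clones, 0, clone_var$sigma_promoter),
    m_rbs = stats::rlnorm(n_clones, 0, clone_var$sigma_rbs),
    m_mu = stats::rlnorm(n_clones, 0, clone_var$sigma_mu)
  )
}

# simulate one clone: variant scales and growth rate perturbed by the
# clone's multipliers; memoized on the multiplier triple within one call
simulate_clone <- function(params, variant, schedule, settings, times,
                           mult, cache) {
  key <- paste(signif(c(mult$m_promoter, mult$m_rbs, mult$m_mu), 12),
               collapse = "_")
  if (!is.null(cache[[key]])) return(list(traj = cache[[key]], cache = cache))
  v <- feedback_variant(variant$label,
                        promoter_scale = variant$promoter_scale *
                          mult$m_promoter,
                        rbs_scale = variant$rbs_scale * mult$m_rbs)
  if (variant$promoter_scale == 0) v$promoter_scale <- 0
  p <- update_params(params, mu0 = params$mu0 * mult$m_mu)
  traj <- simulate_circuit(p, v, schedule, settings, times = times)
  cache[[key]] <- traj
  list(traj = traj, cache = cache)
}

#' Generate a synthetic fluorescence time-course dataset
#'
#' Emulates a batch plate-reader experiment: for each clone, draws
#' clone-specific multipliers, simulates the circuit, synthesizes an OD600
#' trace (exponential growth at the clone's growth rate, capped at a
#' stationary ceiling), converts native GFP to fluorescence per OD, and
#' applies multiplicative measurement noise. Fully reproducible from
#' `seed`.
#'
#' @param params true [circuit_params()].
#' @param variant a [feedback_variant()] or preset label.
#' @param schedule an [induction_schedule()].
#' @param sampling_times measurement times (h), within `[0, t_end]`.
#' @param n_clones number of biological replicates.
#' @param noise a [noise_model()].
#' @param clone_var a [clone_variability()].
#' @param seed integer seed.
#' @param settings a [solver_settings()].
#' @param od0 inoculation OD600; the protocol inoculates at 0.1.
#' @param od_max stationary-phase OD ceiling.
#' @return A `timecourse_dataset`: a tibble with columns `time`,
#'   `clone_id`, `variant`, `od600`, `fluorescence_per_od`, plus metadata
#'   attributes.
#' @export
generate_timecourse <- function(params, variant = "WT_STRONG",
                                schedule = induction_schedule(),
                                sampling_times = seq(0, 12, by = 0.5),
                                n_clones = 4,
                                noise = noise_model(),
                                clone_var = clone_variability(),
                                seed = 1,
                                settings = solver_settings(rel_tol = 1e-8,
                                                           abs_tol = 1e-10),
                                od0 = 0.1, od_max = 4) {
  variant <- as_variant(variant)
  if (any(sampling_times < 0) || any(sampling_times > schedule$t_end)) {
    stop("sampling_times must lie within [0, t_end]", call. = FALSE)
  }
  sampling_times <- sort(unique(sampling_times))
  withr::with_seed(seed, {
    mults <- draw_clone_multipliers(n_clones, clone_var)
    cache <- list()
    rows <- vector("list", n_clones)
    for (i in seq_len(n_clones)) {
      res <- simulate_clone(params, variant, schedule, settings,
                            sampling_times, mults[i, ], cache)
      cache <- res$cache
      traj <- res$traj
      sel <- match(sampling_times, traj$time)
      mu_i <- params$mu0 * mults$m_mu[i]
      od <- pmin(od0 * exp(mu_i * sampling_times), od_max)
      n_t <- length(sampling_times)
      rows[[i]] <- tibble::tibble(
        time = sampling_times,
        clone_id = sprintf("clone%02d", i),
        variant = variant$label,
        od600 = od * rlnorm_cv(n_t, noise$od_cv),
        fluorescence_per_od = traj$fluorescence_equiv[sel] *
          rlnorm_cv(n_t, noise$fluor_cv)
      )
    }
    new_timecourse(dplyr::bind_rows(rows),
                   metadata = list(n_replicates = n_clones, medium = "M9",
                                   seed = seed))
  })
}

new_timecourse <- function(tbl, fractions = NULL, metadata = list()) {
  validate_timecourse(tbl, fractions)
  structure(tbl, class = c("timecourse_dataset", class(tbl)),
            fractions = fractions, metadata = metadata)
}

#' Validate a time-course dataset
#'
#' Checks the header contract and invariants: nonnegative times and
#' fluorescence, at least one variant, soluble fractions in `[0, 1]`.
#'
#' @param tbl a data frame of time-course records.
#' @param fractions optional end-point fraction table.
#' @return `tbl`, invisibly; errors on violation.
#' @export
validate_timecourse <- function(tbl, fractions = NULL) {
  need <- c("time", "clone_id", "variant", "od600", "fluorescence_per_od")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop("time-course dataset lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(tbl$time < 0)) stop("times must be nonnegative", call. = FALSE)
  if (any(tbl$fluorescence_per_od < 0)) {
    stop("fluorescence must be nonnegative", call. = FALSE)
  }
  if (length(unique(tbl$variant)) < 1) {
    stop("at least one variant required", call. = FALSE)
  }
  if (!is.null(fractions) &&
      any(fractions$soluble_fraction < 0 | fractions$soluble_fraction > 1)) {
    stop("soluble fractions must lie in [0, 1]", call. = FALSE)
  }
  invisible(tbl)
}

#' End-point fraction table of a dataset
#'
#' @param data a `timecourse_dataset`.
#' @return The attached end-point soluble/insoluble fraction tibble, or
#'   `NULL`.
#' @export
fraction_table <- function(data) attr(data, "fractions")

#' Generate end-point fractionation measurements
#'
#' Emulates the cell-fractionation assay: at `t_sample` each clone's
#' soluble GFP fraction and total GFP amount are measured; total GFP is
#' reported relative to the mean of the no-feedback reference clones
#' (reference content = 1). Additive noise on fractions is truncated to
#' `[0, 1]`; total amounts get multiplicative lognormal noise.
#'
#' @param params true [circuit_params()].
#' @param variants a list of [feedback_variant()]s (or preset labels);
#'   must include `NO_FB` when `relative = TRUE`.
#' @param t_sample harvest time (h), at most `schedule$t_end`; the assay
#'   protocol harvests at 8 h.
#' @param n_clones clones per variant.
#' @param noise a [noise_model()].
#' @param clone_var a [clone_variability()].
#' @param seed integer seed.
#' @param schedule an [induction_schedule()].
#' @param settings a [solver_settings()].
#' @param relative report total GFP relative to the NO_FB mean.
#' @return A tibble with `clone_id`, `variant`, `soluble_fraction`,
#'   `total_gfp` and (if `relative`) `total_gfp_relative`.
#' @export
generate_fraction_measurements <- function(params,
                                           variants = variant_presets(),
                                           t_sample = 8, n_clones = 4,
                                           noise = noise_model(),
                                           clone_var = clone_variability(),
                                           seed = 1,
                                           schedule = induction_schedule(),
                                           settings =
                                             solver_settings(rel_tol = 1e-8,
                                                             abs_tol = 1e-10),
                                           relative = TRUE) {
  if (t_sample > schedule$t_end) {
    stop("t_sample must not exceed the schedule horizon", call. = FALSE)
  }
  variants <- lapply(variants, as_variant)
  labels <- vapply(variants, `[[`, character(1), "label")
  if (relative && !"NO_FB" %in% labels) {
    stop("relative totals need a NO_FB reference variant", call. = FALSE)
  }
  withr::with_seed(seed, {
    out <- purrr::map2_dfr(variants, labels, function(v, lab) {
      mults <- draw_clone_multipliers(n_clones, clone_var)
      cache <- list()
      purrr::map_dfr(seq_len(n_clones), function(i) {
        res <- simulate_clone(params, v, schedule, settings,
                              times = t_sample, mults[i, ], cache)
        cache <<- res$cache
        st <- res$traj[res$traj$time == t_sample, ]
        frac <- st$soluble_fraction +
          stats::rnorm(1, 0, noise$fraction_sd)
        tibble::tibble(
          clone_id = sprintf("clone%02d", i),
          variant = lab,
          soluble_fraction = min(1, max(0, frac)),
          total_gfp = st$total_gfp * rlnorm_cv(1, noise$fluor_cv)
        )
      })
    })
    if (relative) {
      ref <- mean(out$total_gfp[out$variant == "NO_FB"])
      out$total_gfp_relative <- out$total_gfp / ref
    }
    out
  })
}

#' Generate the canonical four-variant synthetic suite
#'
#' Produces one bundle mirroring the full characterization experiment:
#' the four shipped feedback variants (no feedback; wild-type stress
#' promoter with strong RBS; promoter mutant with strong RBS; promoter
#' mutant with weak RBS), four clones per variant, sampled every 0.5 h
#' over a 12-h batch induced with 1 mM IPTG at 2 h, plus an 8-h
#' fractionation table. The canonical parameter fixture is calibrated so
#' that end-point GFP is strictly ordered
#' `NO_FB > MUT_WEAK > MUT_STRONG > WT_STRONG` with the strongest
#' feedback cutting GFP by about 70%.
#'
#' @param seed integer seed.
#' @param params base [circuit_params()]; default the canonical fixture.
#' @param noise a [noise_model()].
#' @param clone_var a [clone_variability()].
#' @param n_clones clones per variant.
#' @return A `timecourse_dataset` spanning all four variants, with the
#'   8-h fraction table attached (see [fraction_table()]).
#' @export
generate_paperlike_suite <- function(seed = 1, params = circuit_params(),
                                     noise = noise_model(),
                                     clone_var = clone_variability(),
                                     n_clones = 4) {
  schedule <- induction_schedule(iptg_conc = 1, t_induce = 2, t_end = 12)
  presets <- variant_presets()
  tcs <- purrr::imap(presets, function(v, lab) {
    generate_timecourse(params, v, schedule,
                        sampling_times = seq(0, 12, by = 0.5),
                        n_clones = n_clones, noise = noise,
                        clone_var = clone_var,
                        seed = seed + match(lab, names(presets)))
  })
  fractions <- generate_fraction_measurements(
    params, presets, t_sample = 8, n_clones = n_clones, noise = noise,
    clone_var = clone_var, seed = seed + 101, schedule = schedule)
  new_timecourse(dplyr::bind_rows(lapply(tcs, tibble::as_tibble)),
                 fractions = fractions,
                 metadata = list(n_replicates = n_clones, medium = "M9",
                                 seed = seed))
}

#' Read / write time-course datasets
#'
#' Tidy CSV contract: columns `time` (h), `clone_id`, `variant`, `od600`,
#' `fluorescence_per_od` (linear scale). The optional end-point fraction
#' table travels as a sidecar `<stem>_fractions.csv`.
#'
#' @param data a `timecourse_dataset`.
#' @param path CSV path.
#' @return `write_timecourse()` returns `path` invisibly;
#'   `read_timecourse()` returns a validated `timecourse_dataset`.
#' @export
write_timecourse <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  fr <- fraction_table(data)
  if (!is.null(fr)) {
    readr::write_csv(fr, sub("\\.csv$", "_fractions.csv", path))
  }
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  fpath <- sub("\\.csv$", "_fractions.csv", path)
  fr <- if (file.exists(fpath)) {
    readr::read_csv(fpath, show_col_types = FALSE)
  } else {
    NULL
  }
  new_timecourse(tbl, fractions = fr,
                 metadata = list(n_replicates =
                                   length(unique(tbl$clone_id))))
}
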