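#' Compare feedback variants against the no-feedback control
#'
#' Builds the headline comparison table from one simulated trajectory per
#' variant: end-point total GFP and fluorescence, the soluble fraction at
#' the fractionation time (8 h), the end-point percent reduction relative
#' to the no-feedback control, and the maximal post-induction reduction
#' with the time at which it occurs. Reduction is computed on the measured
#' quantity (fluorescence), `100 * (1 - f_v(t) / f_NO_FB(t))`; the
#' total-GFP reduction is reported alongside.
#'
#' @param trajectories named list of `circuit_trajectory` objects sharing
#'   one schedule; must contain `"NO_FB"`.
#' @param t_frac time (h) at which the soluble fraction is reported
#'   (default 8, the fractionation harvest time).
#' @return A `comparison_table` tibble with one row per variant:
#'   `variant`, `total_gfp_end`, `fluorescence_end`, `soluble_fraction_8h`,
#'   `reduction_end_pct`, `reduction_total_end_pct`, `max_reduction_pct`,
#'   `t_max_reduction`.
#' @export
#' @examples
#' \donttest{
#' sched <- induction_schedule(t_end = 10)
#' trajs <- purrr::map(variant_presets()[c("NO_FB", "WT_STRONG")],
#'                     ~ simulate_circuit(circuit_params(), .x, sched))
#' compare_variants(trajs)
#' }
compare_variants <- function(trajectories, t_frac = 8) {
  if (!"NO_FB" %in% names(trajectories)) {
    stop("comparison requires a NO_FB trajectory", call. = FALSE)
  }
  scheds <- purrr::map(trajectories, ~ attr(.x, "schedule"))
  if (length(unique(purrr::map_chr(scheds, ~ paste(unlist(.x),
                                                   collapse = "_")))) != 1) {
    stop("all trajectories must share one induction schedule",
         call. = FALSE)
  }
  sched <- scheds[[1]]
  ref <- trajectories[["NO_FB"]]
  post <- function(traj) traj$time > sched$t_induce
  at <- function(traj, col, t) {
    stats::approx(traj$time, traj[[col]], xout = t, rule = 2)$y
  }
  purrr::imap_dfr(trajectories, function(traj, lab) {
    tt <- traj$time[post(traj)]
    ref_f <- at(ref, "fluorescence_equiv", tt)
    if (any(ref_f <= 0)) {
      warning("NO_FB fluorescence is zero at some evaluation times; ",
              "reduction undefined there", call. = FALSE)
    }
    red <- ifelse(ref_f > 0,
                  100 * (1 - traj$fluorescence_equiv[post(traj)] / ref_f),
                  NA_real_)
    i_max <- which.max(red)
    t_end <- max(traj$time)
    ref_tot_end <- at(ref, "total_gfp", t_end)
    tibble::tibble(
      variant = lab,
      total_gfp_end = at(traj, "total_gfp", t_end),
      fluorescence_end = at(traj, "fluorescence_equiv", t_end),
      soluble_fraction_8h = at(traj, "soluble_fraction",
                               min(t_frac, t_end)),
      reduction_end_pct = red[length(red)],
      reduction_total_end_pct = if (ref_tot_end > 0) {
        100 * (1 - at(traj, "total_gfp", t_end) / ref_tot_end)
      } else {
        NA_real_
      },
      max_reduction_pct = if (length(i_max)) red[i_max] else NA_real_,
      t_max_reduction = if (length(i_max)) tt[i_max] else NA_real_
    )
  }) |>
    (\(tbl) structure(tbl, class = c("comparison_table", class(tbl)),
                      schedule = sched, t_frac = t_frac))()
}

#' Simulate all variants and compare them
#'
#' Convenience wrapper: simulates every variant in `variants` under one
#' schedule and returns both the trajectories and the
#' [compare_variants()] table.
#'
#' @param params a [circuit_params()].
#' @param variants named list of [feedback_variant()]s (default the four
#'   shipped presets).
#' @param schedule an [induction_schedule()].
#' @param settings a [solver_settings()].
#' @param times output grid.
#' @return List with `trajectories` (named list) and `comparison`
#'   (`comparison_table`).
#' @export
simulate_variant_panel <- function(params, variants = variant_presets(),
                                   schedule = induction_schedule(),
                                   settings = solver_settings(),
                                   times = NULL) {
  trajs <- purrr::map(variants,
                      ~ simulate_circuit(params, .x, schedule, settings,
                                         times = times))
  list(trajectories = trajs, comparison = compare_variants(trajs))
}
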