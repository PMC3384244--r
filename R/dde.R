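#' Solver settings
#'
#' Numerical settings for the delayed-system integrator, the steady-state
#' search and the fixed-step verification oracle.
#'
#' @param rel_tol,abs_tol relative and absolute integration tolerances.
#' @param max_step maximal internal step (h); `Inf` leaves it to the solver.
#' @param history_interp interpolation used by the fixed-step oracle's
#'   delayed-state lookup, `"linear"` or `"cubic"` (the adaptive solver
#'   uses its own dense-output interpolant).
#' @param steady_state_tol maximal absolute derivative (nM/h) accepted as
#'   steady during the pre-induction burn-in.
#' @param oracle_dt default step (h) of the fixed-step oracle; must stay
#'   below the smallest nonzero delay.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(rel_tol = 1e-8, abs_tol = 1e-12, max_step = Inf,
                            history_interp = c("linear", "cubic"),
                            steady_state_tol = 1e-6, oracle_dt = 1e-4) {
  history_interp <- match.arg(history_interp)
  if (rel_tol <= 0 || abs_tol <= 0 || steady_state_tol <= 0 || oracle_dt <= 0) {
    stop("tolerances and oracle_dt must be positive", call. = FALSE)
  }
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 history_interp = history_interp,
                 steady_state_tol = steady_state_tol, oracle_dt = oracle_dt),
            class = "solver_settings")
}

# Clamp integration round-off: values in [-1e-9, 0] are set to 0; anything
# more negative is a genuine model/solver failure and raises an error.
clamp_nonnegative <- function(mat, context = "integration") {
  sp <- intersect(colnames(mat), species_names())
  vals <- mat[, sp, drop = FALSE]
  if (any(vals < -1e-9)) {
    worst <- min(vals)
    stop(context, " produced a negative concentration (", signif(worst, 3),
         "); reduce tolerances", call. = FALSE)
  }
  vals[vals < 0] <- 0
  mat[, sp] <- vals
  mat
}

# deSolve-facing rhs: delayed lookups through lagvalue(), with the
# constant pre-t0 history equal to the initial (steady) state.
dede_func <- function(t, y, parms) {
  p <- parms$params
  sched <- parms$schedule
  y0 <- parms$y0
  lag_at <- function(tl) {
    if (tl <= parms$t0) y0 else deSolve::lagvalue(tl)
  }
  y_tx <- if (p$tau_tx > 0) lag_at(t - p$tau_tx) else y
  y_tl <- if (p$tau_tl > 0) lag_at(t - p$tau_tl) else y
  list(rhs_core(pmax(y, 0), pmax(y_tx, 0), pmax(y_tl, 0), p,
                iptg_at(t - p$tau_tx, sched)))
}

integrate_circuit <- function(y0, times, params, schedule, settings) {
  parms <- list(params = params, schedule = schedule, y0 = y0,
                t0 = times[[1]])
  hmax <- if (is.finite(settings$max_step)) settings$max_step else NULL
  has_delay <- params$tau_tx > 0 || params$tau_tl > 0
  # the induction switch is a derivative discontinuity: force it (and its
  # delayed images) onto the mesh so the solver restarts cleanly there
  crit <- schedule$t_induce +
    c(0, params$tau_tx, params$tau_tl, params$tau_tx + params$tau_tl)
  crit <- unique(crit[crit > times[[1]] & crit < times[[length(times)]]])
  tt <- sort(unique(c(times, crit)))
  sol <- if (has_delay) {
    deSolve::dede(y = y0, times = tt, func = dede_func, parms = parms,
                  rtol = settings$rel_tol, atol = settings$abs_tol,
                  hmax = hmax,
                  control = list(mxhist = 1e5))
  } else {
    deSolve::ode(y = y0, times = tt, func = dede_func, parms = parms,
                 method = "lsoda", rtol = settings$rel_tol,
                 atol = settings$abs_tol, hmax = hmax)
  }
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failed near t = ", signif(utils::tail(sol[, 1], 1), 4),
         " h", call. = FALSE)
  }
  sol <- sol[sol[, 1] %in% times, , drop = FALSE]
  colnames(sol) <- c("time", state_names())
  clamp_nonnegative(sol)
}

#' Pre-induction steady state
#'
#' Integrates the uninduced circuit (no IPTG; only leaky T7 expression and
#' basal stress-promoter activity) from the empty state for an extended
#' burn-in at growth rate `mu0`, and accepts the end state once every
#' derivative magnitude falls below `settings$steady_state_tol`. The
#' burn-in horizon starts at `50 / mu0` hours and doubles (up to three
#' times) if the system is still drifting.
#'
#' @param params a [circuit_params()] object (variant already applied).
#' @param settings a [solver_settings()] object.
#' @return A named steady-state vector (class `circuit_state`), auxiliary
#'   cumulative fluxes zeroed.
#' @export
find_preinduction_steady_state <- function(params,
                                           settings = solver_settings()) {
  sched0 <- induction_schedule(iptg_conc = 0, t_induce = 0, t_end = 1)
  horizon <- 50 / max(params$mu0, 1e-3)
  y <- circuit_state()
  # constant-history solutions make the delayed terms equal the current
  # state, so the fixed point can be approached with the delays zeroed;
  # acceptance of the end state still checks the full delayed rhs below
  p_run <- update_params(params, tau_tx = 0, tau_tl = 0)
  for (attempt in 0:3) {
    tt <- c(0, horizon / 2, horizon)
    sol <- integrate_circuit(unclass(y), tt, p_run, sched0, settings)
    y_end <- sol[nrow(sol), state_names()]
    dy <- circuit_rhs(horizon, y_end, delayed = function(t) y_end,
                      params = params, schedule = sched0)
    dy <- dy[species_names()]
    if (max(abs(dy)) < settings$steady_state_tol) {
      y_end[c("cum_tl", "cum_deg", "cum_dil")] <- 0
      return(structure(y_end, class = c("circuit_state", "numeric")))
    }
    horizon <- horizon * 2
  }
  slowest <- names(dy)[which.max(abs(dy))]
  stop("pre-induction burn-in did not reach steady state within ",
       signif(horizon, 3), " h; slowest species: ", slowest,
       " (|d/dt| = ", signif(max(abs(dy)), 3), ")", call. = FALSE)
}

#' Simulate the circuit
#'
#' Integrates the delayed circuit model over a batch experiment. History
#' before `t = 0` is the constant pre-induction steady state; IPTG
#' switches on at `schedule$t_induce`. With both delays zero the system
#' is integrated as a plain stiff ODE.
#'
#' @param params a [circuit_params()] object (base parameters; the variant
#'   scales are applied internally).
#' @param variant a [feedback_variant()] or preset label; default the
#'   no-feedback control.
#' @param schedule an [induction_schedule()].
#' @param settings a [solver_settings()].
#' @param times output time grid (h); default every 0.05 h over the
#'   horizon.
#' @param y0 optional initial state overriding the computed steady state.
#' @return A `circuit_trajectory`: a tibble with `time`, the eight species
#'   columns, three cumulative-flux columns, and the derived observables
#'   `total_gfp`, `soluble_gfp`, `soluble_fraction`, `fluorescence_equiv`.
#'   Attributes carry the applied parameters, variant, schedule, settings
#'   and the induction event.
#' @export
#' @examples
#' traj <- simulate_circuit(circuit_params(), "NO_FB",
#'                          induction_schedule(t_end = 6),
#'                          times = seq(0, 6, by = 0.5))
#' dplyr::last(traj$total_gfp)
simulate_circuit <- function(params, variant = "NO_FB",
                             schedule = induction_schedule(),
                             settings = solver_settings(), times = NULL,
                             y0 = NULL) {
  variant <- as_variant(variant)
  pv <- apply_variant(params, variant)
  if (is.null(times)) {
    times <- seq(0, schedule$t_end, by = 0.05)
  }
  times <- sort(unique(c(0, times, schedule$t_end)))
  if (any(times < 0) || any(times > schedule$t_end)) {
    stop("output times must lie within [0, t_end]", call. = FALSE)
  }
  if (is.null(y0)) {
    y0 <- find_preinduction_steady_state(pv, settings)
  }
  sol <- integrate_circuit(unclass(y0)[state_names()], times, pv, schedule,
                           settings)
  traj <- tibble::as_tibble(as.data.frame(sol))
  traj <- add_observables(traj, pv)
  structure(traj,
            class = c("circuit_trajectory", class(traj)),
            params = pv, variant = variant, schedule = schedule,
            settings = settings,
            events = tibble::tibble(time = schedule$t_induce,
                                    event = "induction",
                                    iptg_conc = schedule$iptg_conc))
}

add_observables <- function(traj, params) {
  total <- traj$g_F + traj$g_N + traj$g_I
  soluble <- traj$g_F + traj$g_N
  traj$total_gfp <- total
  traj$soluble_gfp <- soluble
  traj$soluble_fraction <- ifelse(total > 0, soluble / total, 1)
  traj$fluorescence_equiv <- traj$g_N / params$c_fluor
  traj
}

#' Derived observables of a state
#'
#' @param state a [circuit_state()] (or any named vector with the GFP
#'   pools `g_F`, `g_N`, `g_I`).
#' @param params a [circuit_params()] object (for `c_fluor`).
#' @return A one-row tibble with `total_gfp`, `soluble_gfp`,
#'   `soluble_fraction` (1 by convention when no GFP is present) and
#'   `fluorescence_equiv` (only natively folded GFP fluoresces).
#' @export
observables <- function(state, params) {
  total <- unname(state[["g_F"]] + state[["g_N"]] + state[["g_I"]])
  soluble <- unname(state[["g_F"]] + state[["g_N"]])
  tibble::tibble(
    total_gfp = total,
    soluble_gfp = soluble,
    soluble_fraction = if (total > 0) soluble / total else 1,
    fluorescence_equiv = unname(state[["g_N"]]) / params$c_fluor
  )
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  v <- attr(x, "variant")
  cat(sprintf("<circuit_trajectory> variant %s, %d time points over [%g, %g] h\n",
              v$label, nrow(x), min(x$time), max(x$time)))
  NextMethod()
}

#' Long-format view of a trajectory
#'
#' @param trajectory a `circuit_trajectory`.
#' @return A tibble with columns `time`, `species`, `value`, `variant`.
#' @export
trajectory_long <- function(trajectory) {
  v <- attr(trajectory, "variant")$label
  tibble::as_tibble(trajectory[, c("time", species_names())]) |>
    tidyr::pivot_longer(-"time", names_to = "species",
                        values_to = "value") |>
    dplyr::mutate(variant = v)
}

#' Export a trajectory as tidy CSV
#'
#' Writes the long-format trajectory and a sidecar event log
#' (`<path stem>_events.csv`).
#'
#' @param trajectory a `circuit_trajectory`.
#' @param path output CSV path.
#' @param run_id identifier recorded in the `run_id` column.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, run_id = "run1") {
  out <- trajectory_long(trajectory) |> dplyr::mutate(run_id = run_id)
  readr::write_csv(out, path)
  ev <- attr(trajectory, "events")
  readr::write_csv(ev, sub("\\.csv$", "_events.csv", path))
  invisible(path)
}
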