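#' Fixed-step Euler reference integrator
#'
#' A brute-force explicit Euler integrator with a dense history buffer for
#' delayed-state lookups, sharing its derivative algebra with the adaptive
#' solver. It exists purely as an independent verification route for
#' [simulate_circuit()]: first-order, slow, and transparent.
#'
#' @param params a [circuit_params()] object (base parameters).
#' @param variant a [feedback_variant()] or preset label.
#' @param schedule an [induction_schedule()].
#' @param dt fixed step (h); must not exceed `settings$oracle_dt` nor the
#'   smallest nonzero delay.
#' @param settings a [solver_settings()]; `history_interp` selects linear
#'   or 4-point Lagrange (cubic) interpolation of the stored history.
#' @param times output grid (h); defaults to every 0.05 h. Each requested
#'   time is rounded to the nearest step.
#' @param y0 optional initial state; defaults to the pre-induction steady
#'   state computed by the adaptive route.
#' @return A `circuit_trajectory` tibble (same shape as
#'   [simulate_circuit()]).
#' @export
euler_oracle <- function(params, variant = "NO_FB",
                         schedule = induction_schedule(), dt = 1e-4,
                         settings = solver_settings(), times = NULL,
                         y0 = NULL) {
  variant <- as_variant(variant)
  pv <- apply_variant(params, variant)
  if (dt > settings$oracle_dt) {
    stop("dt exceeds settings$oracle_dt", call. = FALSE)
  }
  min_delay <- min(c(pv$tau_tx, pv$tau_tl)[c(pv$tau_tx, pv$tau_tl) > 0],
                   Inf)
  if (dt > min_delay) {
    stop("dt must not exceed the smallest nonzero delay (", min_delay, " h)",
         call. = FALSE)
  }
  if (is.null(times)) times <- seq(0, schedule$t_end, by = 0.05)
  times <- sort(unique(c(0, times, schedule$t_end)))
  if (is.null(y0)) y0 <- find_preinduction_steady_state(pv, settings)
  y0 <- unclass(y0)[state_names()]

  n_steps <- ceiling(schedule$t_end / dt)
  n_state <- length(y0)
  hist <- matrix(0, nrow = n_steps + 1, ncol = n_state)
  hist[1, ] <- y0
  cubic <- settings$history_interp == "cubic"

  # interpolated full-state lookup at continuous time tl (<= current step)
  lookup <- function(tl, k) {
    if (tl <= 0) return(y0)
    pos <- tl / dt
    i <- floor(pos)
    frac <- pos - i
    if (frac < 1e-12) return(hist[i + 1, ])
    if (!cubic || i < 1 || i + 2 > k) {
      return(hist[i + 1, ] * (1 - frac) + hist[i + 2, ] * frac)
    }
    # 4-point Lagrange on the uniform grid around the bracket
    x <- frac
    w0 <- -x * (x - 1) * (x - 2) / 6
    w1 <- (x + 1) * (x - 1) * (x - 2) / 2
    w2 <- -(x + 1) * x * (x - 2) / 2
    w3 <- (x + 1) * x * (x - 1) / 6
    hist[i, ] * w0 + hist[i + 1, ] * w1 + hist[i + 2, ] * w2 +
      hist[i + 3, ] * w3
  }

  tau_tx <- pv$tau_tx
  tau_tl <- pv$tau_tl
  y <- y0
  for (k in seq_len(n_steps)) {
    t_k <- (k - 1) * dt
    y_tx <- if (tau_tx > 0) lookup(t_k - tau_tx, k) else y
    y_tl <- if (tau_tl > 0) lookup(t_k - tau_tl, k) else y
    d <- rhs_core(y, y_tx, y_tl, pv, iptg_at(t_k - tau_tx, schedule))
    y <- y + dt * d
    y[y < 0 & y > -1e-9] <- 0
    hist[k + 1, ] <- y
  }

  idx <- pmin(round(times / dt), n_steps) + 1
  out <- hist[idx, , drop = FALSE]
  colnames(out) <- state_names()
  out <- clamp_nonnegative(out, "euler oracle")
  traj <- tibble::as_tibble(as.data.frame(out))
  traj <- tibble::add_column(traj, time = (idx - 1) * dt, .before = 1)
  traj <- add_observables(traj, pv)
  structure(traj,
            class = c("circuit_trajectory", class(traj)),
            params = pv, variant = variant, schedule = schedule,
            settings = settings,
            events = tibble::tibble(time = schedule$t_induce,
                                    event = "induction",
                                    iptg_conc = schedule$iptg_conc))
}
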