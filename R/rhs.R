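#' @keywords internal
"_PACKAGE"

# State vector layout. The first eight entries are the modeled species;
# the last three are auxiliary cumulative GFP fluxes used for mass-balance
# verification (translated, degraded, diluted), integrated alongside.
species_names <- function() {
  c("m_T7", "p_T7", "m_G", "g_F", "g_N", "g_I", "m_R", "p_R")
}

state_names <- function() {
  c(species_names(), "cum_tl", "cum_deg", "cum_dil")
}

#' Construct a circuit state vector
#'
#' @param m_T7,p_T7 T7-polymerase mRNA and protein (nM).
#' @param m_G GFP mRNA (nM).
#' @param g_F GFP folding intermediate / soluble aggregate pool (nM).
#' @param g_N natively folded (fluorescent) GFP (nM).
#' @param g_I insoluble inclusion-body GFP (nM).
#' @param m_R,p_R TetR mRNA and protein (nM).
#' @return A named numeric vector of class `circuit_state` (the three
#'   auxiliary cumulative-flux entries are initialized to zero).
#' @export
circuit_state <- function(m_T7 = 0, p_T7 = 0, m_G = 0, g_F = 0, g_N = 0,
                          g_I = 0, m_R = 0, p_R = 0) {
  s <- c(m_T7 = m_T7, p_T7 = p_T7, m_G = m_G, g_F = g_F, g_N = g_N,
         g_I = g_I, m_R = m_R, p_R = p_R,
         cum_tl = 0, cum_deg = 0, cum_dil = 0)
  if (any(!is.finite(s))) stop("state entries must be finite", call. = FALSE)
  if (any(s[species_names()] < 0)) {
    stop("species concentrations must be nonnegative", call. = FALSE)
  }
  structure(s, class = c("circuit_state", "numeric"))
}

# IPTG concentration seen by the cells at time t.
iptg_at <- function(t, schedule) {
  ifelse(t >= schedule$t_induce, schedule$iptg_conc, 0)
}

# Core derivative algebra, shared by the adaptive integrator, the
# zero-delay dispatch and the fixed-step oracle. `y` is the current state,
# `y_tx`/`y_tl` the states at t - tau_tx and t - tau_tl, `iptg_tx` the
# inducer concentration at t - tau_tx (transcription initiated then).
rhs_core <- function(y, y_tx, y_tl, p, iptg_tx) {
  mu <- p$mu0
  ind <- induction_factor(iptg_tx, p)
  rep_f <- repression_factor(max(y_tx[[8]], 0), p)
  stress <- stress_activation(max(y_tx[[4]], 0) + max(y_tx[[6]], 0), p)

  d_m_T7 <- p$k_tx_T7 * ind - (p$d_m + mu) * y[[1]]
  d_p_T7 <- p$k_tl_T7 * y_tl[[1]] - (p$d_T7 + mu) * y[[2]]
  d_m_G <- p$k_tx_G * y_tx[[2]] * rep_f - (p$d_m + mu) * y[[3]]
  tl_G <- p$k_tl_G * y_tl[[3]]
  d_g_F <- tl_G - (p$k_fold + p$k_agg + p$d_G + mu) * y[[4]]
  d_g_N <- p$k_fold * y[[4]] - (p$d_G + mu) * y[[5]]
  d_g_I <- p$k_agg * y[[4]] - (p$k_ib_deg + mu) * y[[6]]
  d_m_R <- p$k_tx_R * stress - (p$d_m + mu) * y[[7]]
  d_p_R <- p$k_tl_R * y_tl[[7]] - (p$d_R + mu) * y[[8]]

  c(d_m_T7, d_p_T7, d_m_G, d_g_F, d_g_N, d_g_I, d_m_R, d_p_R,
    tl_G,
    p$d_G * (y[[4]] + y[[5]]) + p$k_ib_deg * y[[6]],
    mu * (y[[4]] + y[[5]] + y[[6]]))
}

#' Right-hand side of the delayed circuit model
#'
#' Evaluates the state derivative at time `t` given a lookup function for
#' the delayed state. Transcription terms read promoter states (inducer,
#' active polymerase, repressor, stress load) at `t - tau_tx`; translation
#' terms read mRNA levels at `t - tau_tl`; first-order degradation and
#' growth dilution (rate `mu0`) act on every species at the current time.
#'
#' @param t time (h).
#' @param state current state vector (11 entries, see [circuit_state()]).
#' @param delayed function `(t)` returning the full state vector at an
#'   earlier time; must cover `t - tau_tx` and `t - tau_tl`.
#' @param params a [circuit_params()] object.
#' @param schedule an [induction_schedule()] object.
#' @return Named numeric derivative vector.
#' @export
circuit_rhs <- function(t, state, delayed, params, schedule) {
  if (any(state[seq_len(8)] < -1e-9)) {
    stop("negative species concentration at t = ", signif(t, 6), call. = FALSE)
  }
  y_tx <- if (params$tau_tx > 0) delayed(t - params$tau_tx) else state
  y_tl <- if (params$tau_tl > 0) delayed(t - params$tau_tl) else state
  d <- rhs_core(pmax(state, 0), pmax(y_tx, 0), pmax(y_tl, 0), params,
                iptg_at(t - params$tau_tx, schedule))
  stats::setNames(d, state_names())
}
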