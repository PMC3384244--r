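#' Promoter activity of the IPTG-inducible T7-polymerase gene
#'
#' Hill activation with a basal (leaky) floor:
#' `basal_T7 + (1 - basal_T7) * iptg^n / (K^n + iptg^n)`.
#' Monotone nondecreasing in `iptg`, bounded in `[basal_T7, 1]`.
#'
#' @param iptg IPTG concentration (mM), nonnegative; vectorized.
#' @param params a [circuit_params()] object.
#' @return Fractional promoter activity in `[basal_T7, 1]`.
#' @export
#' @examples
#' p <- circuit_params(basal_T7 = 0, n_iptg = 1)
#' induction_factor(p$K_iptg, p) # 0.5 at half-saturation
induction_factor <- function(iptg, params) {
  if (any(iptg < 0)) stop("iptg must be nonnegative", call. = FALSE)
  hill <- iptg^params$n_iptg /
    (params$K_iptg^params$n_iptg + iptg^params$n_iptg)
  hill[iptg == 0] <- 0 # guard 0/0 when K_iptg = 0
  params$basal_T7 + (1 - params$basal_T7) * hill
}

#' TetR repression of the T7/TetO promoter
#'
#' `1 / (1 + (tetR / K_tetR)^n_tetR)`: strictly decreasing in TetR, 1 with
#' no repressor, 0 in the limit of saturating repressor.
#'
#' @param tetR TetR protein concentration (nM), nonnegative; vectorized.
#' @param params a [circuit_params()] object.
#' @return Fractional residual promoter activity in `(0, 1]`.
#' @export
repression_factor <- function(tetR, params) {
  if (any(tetR < 0)) stop("tetR must be nonnegative", call. = FALSE)
  1 / (1 + (tetR / params$K_tetR)^params$n_tetR)
}

#' Stress-promoter activation by misfolded protein load
#'
#' The stress signal sensed by the inclusion-body-binding-protein promoter
#' is the misfolded plus aggregated GFP pool, `s = g_F + g_I`. Activity is
#' `basal_R + (1 - basal_R) * s^n / (K_stress^n + s^n)`.
#'
#' @param state a named state vector (or `circuit_state`) with `g_F` and
#'   `g_I` entries, or a single numeric stress load.
#' @param params a [circuit_params()] object.
#' @return Fractional promoter activity in `[basal_R, 1]`.
#' @export
stress_activation <- function(state, params) {
  s <- if (is.numeric(state) && is.null(names(state)) && length(state) == 1) {
    state
  } else {
    unname(state[["g_F"]] + state[["g_I"]])
  }
  if (any(s < 0)) stop("stress load must be nonnegative", call. = FALSE)
  hill <- s^params$n_stress /
    (params$K_stress^params$n_stress + s^params$n_stress)
  hill[s == 0] <- 0
  params$basal_R + (1 - params$basal_R) * hill
}
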