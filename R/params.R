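#' Circuit parameter set
#'
#' Constructs and validates the full kinetic parameter set of the
#' stress-feedback expression circuit: IPTG-inducible T7 polymerase
#' expression, T7-driven GFP expression repressible by TetR, and
#' stress-promoter-driven TetR expression. Concentrations are in nM
#' (except IPTG, in mM) and time is in hours.
#'
#' @param mu0 specific growth rate (per h); dilutes every intracellular
#'   species and sets the pre-induction batch growth rate.
#' @param k_tx_T7 maximal T7-polymerase mRNA transcription rate (nM/h).
#' @param K_iptg IPTG half-activation constant (mM).
#' @param n_iptg Hill coefficient of IPTG activation (>= 1).
#' @param basal_T7 leaky fraction of `k_tx_T7` without inducer, in [0, 1].
#' @param k_tx_G maximal GFP mRNA transcription rate per active T7
#'   polymerase (per h).
#' @param K_tetR TetR half-repression constant (nM).
#' @param n_tetR Hill coefficient of TetR repression (>= 1).
#' @param k_tx_R maximal TetR mRNA transcription rate of the stress
#'   promoter (nM/h); scaled by the feedback variant's promoter strength.
#' @param basal_R basal stress-promoter activity fraction, in [0, 1].
#' @param K_stress stress half-activation constant (nM of misfolded plus
#'   aggregated GFP).
#' @param n_stress Hill coefficient of stress activation (>= 1).
#' @param k_tl_T7,k_tl_G,k_tl_R translation rates (protein per mRNA per h);
#'   `k_tl_R` encodes the RBS strength of the feedback variant.
#' @param tau_tx,tau_tl transcription and translation delays (h), shared
#'   across genes.
#' @param d_m mRNA degradation rate (per h), shared across transcripts.
#' @param d_T7,d_G,d_R protein degradation rates (per h); `d_R` is large
#'   because TetR carries a degradation tag.
#' @param k_fold folding-intermediate to native-GFP rate (per h).
#' @param k_agg folding-intermediate to insoluble-inclusion rate (per h).
#' @param k_ib_deg inclusion-body GFP degradation rate (per h).
#' @param c_fluor fluorescence-to-molarity conversion factor (nM of native
#'   GFP per normalized fluorescence-per-OD unit).
#'
#' @return An object of class `circuit_params`: a validated named list.
#' @details Setting `k_tx_R = 0` and `basal_R = 0` removes all TetR
#'   production, reproducing the no-feedback control circuit exactly.
#'   Defaults are the package's canonical calibrated fixture, chosen so
#'   that the four shipped feedback variants reproduce the qualitative
#'   behaviour of the circuit: strongest feedback cuts end-point GFP by
#'   about 70% relative to no feedback while raising the soluble
#'   fraction.
#' @export
#' @examples
#' p <- circuit_params()
#' p$mu0
circuit_params <- function(mu0 = 0.6,
                           k_tx_T7 = 50, K_iptg = 0.05, n_iptg = 2,
                           basal_T7 = 0.02,
                           k_tx_G = 1, K_tetR = 20, n_tetR = 2,
                           k_tx_R = 80, basal_R = 0.05,
                           K_stress = 400, n_stress = 2,
                           k_tl_T7 = 20, k_tl_G = 30, k_tl_R = 12,
                           tau_tx = 0.15, tau_tl = 0.1,
                           d_m = 4, d_T7 = 0.2, d_G = 0.02, d_R = 2.5,
                           k_fold = 1.5, k_agg = 2, k_ib_deg = 0.45,
                           c_fluor = 100) {
  p <- list(
    mu0 = mu0, k_tx_T7 = k_tx_T7, K_iptg = K_iptg, n_iptg = n_iptg,
    basal_T7 = basal_T7, k_tx_G = k_tx_G, K_tetR = K_tetR,
    n_tetR = n_tetR, k_tx_R = k_tx_R, basal_R = basal_R,
    K_stress = K_stress, n_stress = n_stress, k_tl_T7 = k_tl_T7,
    k_tl_G = k_tl_G, k_tl_R = k_tl_R, tau_tx = tau_tx, tau_tl = tau_tl,
    d_m = d_m, d_T7 = d_T7, d_G = d_G, d_R = d_R, k_fold = k_fold,
    k_agg = k_agg, k_ib_deg = k_ib_deg, c_fluor = c_fluor
  )
  validate_circuit_params(p)
  structure(p, class = "circuit_params")
}

validate_circuit_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("circuit parameters must be finite numeric scalars; offending: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  neg <- vapply(p, function(x) x < 0, logical(1))
  if (any(neg)) {
    stop("all rates, constants and delays must be nonnegative; offending: ",
         paste(names(p)[neg], collapse = ", "), call. = FALSE)
  }
  for (h in c("n_iptg", "n_tetR", "n_stress")) {
    if (p[[h]] < 1) stop(h, " must be >= 1", call. = FALSE)
  }
  for (b in c("basal_T7", "basal_R")) {
    if (p[[b]] > 1) stop(b, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>\n")
  print(tibble::enframe(unlist(unclass(x)), name = "parameter"), n = Inf)
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params a [circuit_params()] object.
#' @param ... named scalar replacements, e.g. `k_agg = 3`.
#' @return A new `circuit_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "circuit_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  p <- unclass(params)
  p[names(repl)] <- repl
  validate_circuit_params(p)
  structure(p, class = "circuit_params")
}

#' Feedback variant
#'
#' A feedback variant is a promoter-strength x RBS-strength combination for
#' the TetR arm of the circuit. `promoter_scale` multiplies `k_tx_R` and
#' `basal_R`; `rbs_scale` multiplies `k_tl_R`. The label `"NO_FB"` forces
#' `promoter_scale = 0` (no repressor is ever made).
#'
#' @param label variant name; one of the shipped presets (`"NO_FB"`,
#'   `"WT_STRONG"`, `"MUT_STRONG"`, `"MUT_WEAK"`) or any user label.
#' @param promoter_scale nonnegative multiplier on stress-promoter strength.
#' @param rbs_scale nonnegative multiplier on TetR translation rate.
#' @return An object of class `feedback_variant`.
#' @export
#' @examples
#' feedback_variant("WT_STRONG")
#' feedback_variant("half", promoter_scale = 0.5, rbs_scale = 1)
feedback_variant <- function(label,
                             promoter_scale = NULL, rbs_scale = NULL) {
  presets <- variant_presets()
  if (label %in% names(presets) && is.null(promoter_scale) &&
      is.null(rbs_scale)) {
    return(presets[[label]])
  }
  if (is.null(promoter_scale) || is.null(rbs_scale)) {
    stop("promoter_scale and rbs_scale are required for non-preset variant '",
         label, "'", call. = FALSE)
  }
  if (promoter_scale < 0 || rbs_scale < 0) {
    stop("variant scales must be nonnegative", call. = FALSE)
  }
  if (identical(label, "NO_FB")) promoter_scale <- 0
  structure(list(label = label, promoter_scale = promoter_scale,
                 rbs_scale = rbs_scale),
            class = "feedback_variant")
}

#' Shipped feedback-variant presets
#'
#' The four circuit configurations studied experimentally: the no-feedback
#' control, the wild-type stress promoter with a strong RBS, a weakened
#' promoter mutant with a strong RBS, and a further weakened promoter
#' mutant with a weak RBS. Scales are the package's calibrated fixture.
#'
#' @return A named list of [feedback_variant()] objects.
#' @export
variant_presets <- function() {
  mk <- function(label, ps, rs) {
    structure(list(label = label, promoter_scale = ps, rbs_scale = rs),
              class = "feedback_variant")
  }
  list(
    NO_FB      = mk("NO_FB",      0,    1),
    WT_STRONG  = mk("WT_STRONG",  1,    1),
    MUT_STRONG = mk("MUT_STRONG", 0.30, 1),
    MUT_WEAK   = mk("MUT_WEAK",   0.25, 0.5)
  )
}

#' @export
print.feedback_variant <- function(x, ...) {
  cat(sprintf("<feedback_variant> %s (promoter_scale = %g, rbs_scale = %g)\n",
              x$label, x$promoter_scale, x$rbs_scale))
  invisible(x)
}

#' Apply a feedback variant to a parameter set
#'
#' @param params a [circuit_params()] object.
#' @param variant a [feedback_variant()] object or preset label.
#' @return A `circuit_params` object with the TetR arm rescaled.
#' @export
apply_variant <- function(params, variant) {
  variant <- as_variant(variant)
  update_params(params,
                k_tx_R = params$k_tx_R * variant$promoter_scale,
                basal_R = min(1, params$basal_R * variant$promoter_scale),
                k_tl_R = params$k_tl_R * variant$rbs_scale)
}

as_variant <- function(variant) {
  if (inherits(variant, "feedback_variant")) return(variant)
  if (is.character(variant) && length(variant) == 1) {
    return(feedback_variant(variant))
  }
  stop("variant must be a feedback_variant or a preset label", call. = FALSE)
}

#' Induction schedule
#'
#' Describes the batch experiment: inducer concentration, induction time
#' and simulation horizon. The default reproduces the experimental
#' protocol: 1 mM IPTG added at 2 h, 12 h total batch culture.
#'
#' @param iptg_conc IPTG concentration applied at induction (mM).
#' @param t_induce induction time (h) with `0 <= t_induce <= t_end`.
#' @param t_end end of the simulated batch (h).
#' @return An object of class `induction_schedule`.
#' @export
induction_schedule <- function(iptg_conc = 1, t_induce = 2, t_end = 12) {
  if (iptg_conc < 0) stop("iptg_conc must be nonnegative", call. = FALSE)
  if (t_induce < 0 || t_induce > t_end) {
    stop("need 0 <= t_induce <= t_end", call. = FALSE)
  }
  structure(list(iptg_conc = iptg_conc, t_induce = t_induce, t_end = t_end),
            class = "induction_schedule")
}

#' @export
print.induction_schedule <- function(x, ...) {
  cat(sprintf("<induction_schedule> %g mM IPTG at %g h, horizon %g h\n",
              x$iptg_conc, x$t_induce, x$t_end))
  invisible(x)
}

#' Read a circuit configuration file
#'
#' Reads a YAML (or JSON) configuration holding a flat `parameters` block
#' (any subset of [circuit_params()] fields), an optional list of
#' `variants` blocks (label, promoter_scale, rbs_scale) and an optional
#' `schedule` block (iptg_conc, t_induce, t_end).
#'
#' @param path path to a YAML or JSON file.
#' @return A list with elements `params`, `variants` (named list) and
#'   `schedule`.
#' @export
read_circuit_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  params <- do.call(circuit_params, as.list(cfg$parameters %||% list()))
  variants <- variant_presets()
  if (!is.null(cfg$variants)) {
    variants <- list()
    for (v in cfg$variants) {
      fv <- feedback_variant(v$label, promoter_scale = v$promoter_scale,
                             rbs_scale = v$rbs_scale)
      variants[[fv$label]] <- fv
    }
  }
  sched <- do.call(induction_schedule, as.list(cfg$schedule %||% list()))
  list(params = params, variants = variants, schedule = sched)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
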