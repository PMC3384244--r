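#' Local sensitivity analysis
#'
#' Normalized local sensitivity coefficients of end-point model outputs
#' with respect to each kinetic parameter, by central finite differences:
#' `S = (d output / output) / (d theta / theta)` with a symmetric relative
#' perturbation. Parameters whose nominal value is zero, or outputs whose
#' nominal value is zero, are reported on an absolute scale and flagged.
#'
#' @param params a [circuit_params()] object.
#' @param variant a [feedback_variant()] or preset label.
#' @param schedule an [induction_schedule()].
#' @param outputs character subset of `"total_gfp"`, `"soluble_fraction"`,
#'   `"fluorescence_equiv"`, evaluated at `t_eval`.
#' @param perturbation relative step size, in `(0, 0.5]`.
#' @param t_eval evaluation time (h); default the schedule end point.
#' @param parameters which parameters to perturb; default all.
#' @param settings a [solver_settings()].
#' @return A `sensitivity_report`: tibble with `parameter`, `output`,
#'   `coefficient`, `absolute_scale`; the attribute `"ranking"` holds the
#'   parameters ordered by mean |coefficient| across outputs (largest
#'   first).
#' @export
local_sensitivity <- function(params, variant = "WT_STRONG",
                              schedule = induction_schedule(),
                              outputs = c("total_gfp", "soluble_fraction"),
                              perturbation = 0.05, t_eval = NULL,
                              parameters = names(params),
                              settings = fit_settings()) {
  if (perturbation <= 0 || perturbation > 0.5) {
    stop("perturbation must lie in (0, 0.5]", call. = FALSE)
  }
  outputs <- match.arg(outputs,
                       c("total_gfp", "soluble_fraction",
                         "fluorescence_equiv"),
                       several.ok = TRUE)
  if (is.null(t_eval)) t_eval <- schedule$t_end
  eval_outputs <- function(p) {
    traj <- simulate_circuit(p, variant, schedule, settings,
                             times = t_eval)
    row <- traj[traj$time == t_eval, ]
    vapply(outputs, function(o) row[[o]], numeric(1))
  }
  base <- eval_outputs(params)
  rows <- purrr::map_dfr(parameters, function(nm) {
    theta <- params[[nm]]
    if (theta == 0) {
      h <- perturbation
      up <- eval_outputs(set_free(params, nm, h))
      coef <- (up - base) / h
      return(tibble::tibble(parameter = nm, output = outputs,
                            coefficient = unname(coef),
                            absolute_scale = TRUE))
    }
    h <- perturbation * theta
    up <- eval_outputs(set_free(params, nm, theta + h))
    dn <- eval_outputs(set_free(params, nm, theta - h))
    dout <- (up - dn) / (2 * h)
    coef <- ifelse(base != 0, dout * theta / base, dout * theta)
    tibble::tibble(parameter = nm, output = outputs,
                   coefficient = unname(coef),
                   absolute_scale = base == 0)
  })
  ranking <- rows |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(score = mean(abs(.data$coefficient)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score))
  structure(rows, class = c("sensitivity_report", class(rows)),
            ranking = ranking$parameter,
            perturbation = perturbation, t_eval = t_eval,
            variant = as_variant(variant)$label)
}

#' Parameter ranking of a sensitivity report
#'
#' @param report a `sensitivity_report`.
#' @return Character vector of parameters, most influential first.
#' @export
sensitivity_ranking <- function(report) attr(report, "ranking")

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> variant %s at t = %g h (step %g)\n",
              attr(x, "variant"), attr(x, "t_eval"),
              attr(x, "perturbation")))
  cat("  top parameters:",
      paste(utils::head(sensitivity_ranking(x), 5), collapse = ", "), "\n")
  NextMethod()
}
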