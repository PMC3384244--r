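#' Convert normalized fluorescence to molarity
#'
#' Linear conversion of fluorescence-per-OD readings into native-GFP
#' concentration, the exact inverse of the model's `fluorescence_equiv`
#' observable.
#'
#' @param fluor_per_od normalized fluorescence values, nonnegative.
#' @param c_fluor conversion factor (nM per fluorescence unit), positive;
#'   may also be a [circuit_params()] object.
#' @return Concentrations (nM).
#' @export
fluorescence_to_molarity <- function(fluor_per_od, c_fluor) {
  if (inherits(c_fluor, "circuit_params")) c_fluor <- c_fluor$c_fluor
  if (!is.numeric(c_fluor) || length(c_fluor) != 1 || c_fluor <= 0) {
    stop("c_fluor must be a positive scalar", call. = FALSE)
  }
  if (any(fluor_per_od < 0)) {
    stop("fluorescence must be nonnegative", call. = FALSE)
  }
  fluor_per_od * c_fluor
}

# fitting uses looser tolerances than reporting runs: the objective is
# dominated by measurement noise well above integration error
fit_settings <- function() solver_settings(rel_tol = 1e-6, abs_tol = 1e-9)

# Residual vector for a candidate parameter set against a dataset.
# Fluorescence enters on the log scale (multiplicative noise), end-point
# soluble fractions linearly, weighted sqrt(n_fluor/n_frac) so both data
# kinds contribute comparably to the sum of squares.
dataset_residuals <- function(params, data, variants, schedule, settings) {
  fr <- fraction_table(data)
  labels <- unique(data$variant)
  res <- numeric(0)
  n_fluor <- nrow(data)
  n_frac <- if (is.null(fr)) 0 else nrow(fr)
  w_frac <- if (n_frac > 0) sqrt(n_fluor / n_frac) else 0
  for (lab in labels) {
    d_v <- data[data$variant == lab, ]
    f_v <- if (is.null(fr)) NULL else fr[fr$variant == lab, ]
    tt <- sort(unique(c(d_v$time,
                        if (!is.null(f_v) && nrow(f_v)) 8 else NULL)))
    traj <- simulate_circuit(params, variants[[lab]], schedule, settings,
                             times = tt)
    model_f <- traj$fluorescence_equiv[match(d_v$time, traj$time)]
    res <- c(res, log(model_f + 1e-12) - log(d_v$fluorescence_per_od + 1e-12))
    if (!is.null(f_v) && nrow(f_v)) {
      m8 <- traj$soluble_fraction[which.min(abs(traj$time - 8))]
      res <- c(res, w_frac * (m8 - f_v$soluble_fraction))
    }
  }
  res
}

set_free <- function(params, free, values) {
  do.call(update_params, c(list(params), as.list(stats::setNames(values,
                                                                 free))))
}

#' Fit circuit parameters to time-course data
#'
#' Estimates a chosen subset of circuit parameters by minimizing the sum
#' of squared log-residuals between the model's fluorescence-per-OD
#' prediction and the observations (plus weighted linear residuals on any
#' attached 8-h soluble-fraction table), via multi-start
#' Levenberg-Marquardt: the first start is `init`, the remaining starts
#' are a Latin-hypercube draw over the (log-scale) bounds.
#'
#' @param data a `timecourse_dataset` (one or more variants).
#' @param init initial/fixed parameter values, a [circuit_params()].
#' @param free character vector of parameter names to estimate.
#' @param bounds optional named list of `c(lower, upper)` per free
#'   parameter; default `init/10` to `init*10`.
#' @param variants named list mapping each variant label in `data` to a
#'   [feedback_variant()]; defaults to [variant_presets()].
#' @param schedule an [induction_schedule()].
#' @param settings a [solver_settings()]; default uses fitting-grade
#'   tolerances.
#' @param n_starts number of Levenberg-Marquardt polishing runs
#'   (default 20): the supplied start plus the best-scoring screening
#'   candidates.
#' @param n_screen size of the Latin-hypercube screening draw whose
#'   objective is evaluated once per candidate before polishing.
#' @param seed integer seed for the start draw.
#' @return A `circuit_fit` object; see [tidy.circuit_fit()] and
#'   [glance.circuit_fit()].
#' @export
fit_parameters <- function(data, init, free, bounds = NULL,
                           variants = variant_presets(),
                           schedule = induction_schedule(),
                           settings = fit_settings(),
                           n_starts = 20, n_screen = 25, seed = 1) {
  validate_timecourse(data)
  stopifnot(inherits(init, "circuit_params"))
  bad <- setdiff(free, names(init))
  if (length(bad)) {
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  labels <- unique(data$variant)
  miss <- setdiff(labels, names(variants))
  if (length(miss)) {
    stop("no feedback variant mapped for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(bounds)) {
    bounds <- lapply(stats::setNames(free, free), function(nm) {
      v <- init[[nm]]
      if (v <= 0) c(1e-6, 1) else c(v / 10, v * 10)
    })
  }
  lower <- log10(vapply(bounds[free], `[[`, numeric(1), 1))
  upper <- log10(vapply(bounds[free], `[[`, numeric(1), 2))

  fr <- fraction_table(data)
  n_res <- nrow(data) +
    if (is.null(fr)) 0 else sum(fr$variant %in% labels)
  resid_fn <- function(ltheta) {
    p <- set_free(init, free, 10^ltheta)
    tryCatch(
      dataset_residuals(p, data, variants, schedule, settings),
      error = function(e) rep(1e6, n_res)
    )
  }

  # identifiability diagnostic: numeric Jacobian rank at the start point
  l0 <- pmin(pmax(log10(vapply(free, function(nm) init[[nm]], numeric(1))),
                  lower), upper)
  r0 <- resid_fn(l0)
  J <- vapply(seq_along(free), function(j) {
    lj <- l0
    lj[j] <- lj[j] + 1e-4
    (resid_fn(lj) - r0) / 1e-4
  }, numeric(length(r0)))
  rank <- qr(unique(round(J, 10)))$rank
  if (rank < length(free)) {
    warning("fit request looks underdetermined: residual Jacobian rank ",
            rank, " < ", length(free), " free parameters", call. = FALSE)
  }

  # basin screening: score a Latin-hypercube draw over the log-bounds and
  # polish only the most promising candidates (plus the supplied start)
  starts <- matrix(l0, nrow = 1)
  if (n_starts > 1) {
    cand <- withr::with_seed(seed,
                             lhs::randomLHS(max(n_screen, n_starts),
                                            length(free)))
    cand <- sweep(sweep(cand, 2, upper - lower, `*`), 2, lower, `+`)
    score <- apply(cand, 1, function(th) sum(resid_fn(th)^2))
    keep <- order(score)[seq_len(n_starts - 1)]
    starts <- rbind(starts, cand[keep, , drop = FALSE])
  }

  fits <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fits[[i]] <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         # epsfcn keeps the finite-difference Jacobian
                         # step well above the integration noise floor
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, ptol = 1e-10, ftol = 1e-10,
                           epsfcn = 1e-6)),
      error = function(e) NULL
    )
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all optimizer starts failed", call. = FALSE)
  dev <- vapply(fits, function(f) if (is.null(f)) Inf else f$deviance,
                numeric(1))
  best <- fits[[which.min(dev)]]
  est <- stats::setNames(10^best$par, free)
  p_hat <- set_free(init, free, est)

  resid_tbl <- tibble::tibble(
    variant = data$variant, clone_id = data$clone_id, time = data$time,
    residual = dataset_residuals(p_hat, data, variants, schedule,
                                 settings)[seq_len(nrow(data))]
  )
  structure(list(
    params = p_hat, estimates = est, free = free,
    objective = best$deviance, residuals = resid_tbl,
    converged = best$info %in% 1:4, info = best$info,
    message = best$message, bounds = bounds, n_starts = n_starts,
    seed = seed, n_obs = n_res
  ), class = "circuit_fit")
}

#' @export
print.circuit_fit <- function(x, ...) {
  cat("<circuit_fit>\n")
  cat(sprintf("  objective (SSR): %.6g over %d observations\n",
              x$objective, x$n_obs))
  cat(sprintf("  converged: %s (%s)\n", x$converged, x$message))
  for (nm in x$free) {
    cat(sprintf("  %-10s = %.5g\n", nm, x$estimates[[nm]]))
  }
  invisible(x)
}

#' Tidy a circuit fit
#'
#' @param x a `circuit_fit`.
#' @param ... unused.
#' @return One row per estimated parameter: `term`, `estimate`, `lower`,
#'   `upper`.
#' @method tidy circuit_fit
#' @export
tidy.circuit_fit <- function(x, ...) {
  tibble::tibble(
    term = x$free,
    estimate = unname(x$estimates[x$free]),
    lower = vapply(x$bounds[x$free], `[[`, numeric(1), 1),
    upper = vapply(x$bounds[x$free], `[[`, numeric(1), 2)
  )
}

#' Fit summary
#'
#' @param x a `circuit_fit`.
#' @param ... unused.
#' @return One-row tibble: objective, convergence flag, start count,
#'   observation count, seed.
#' @method glance circuit_fit
#' @export
glance.circuit_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$converged,
                 n_starts = x$n_starts, n_obs = x$n_obs, seed = x$seed)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
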