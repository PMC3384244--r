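#' Cross-validate a circuit fit
#'
#' K-fold cross-validation of the parameter fit: the hold-out unit is a
#' biological replicate (clone, the default) or a circuit variant. For
#' each fold the free parameters are refit on the training records and
#' the per-residual mean squared error is evaluated on the held-out
#' records, quantifying the generalization error of the calibrated model.
#'
#' @param data a `timecourse_dataset`.
#' @param init,free,bounds,variants,schedule,settings,n_starts passed to
#'   [fit_parameters()].
#' @param k number of folds (>= 2); capped at the number of units. With
#'   `k` equal to the unit count this is leave-one-unit-out.
#' @param unit `"clone"` or `"variant"`.
#' @param seed integer seed (fold shuffling and optimizer starts).
#' @return A `cv_report`: tibble with one row per fold (`fold`,
#'   `held_out`, `n_train`, `n_test`, `train_mse`, `test_mse`);
#'   [glance.cv_report()] summarizes mean/sd test error and the
#'   test/train ratio.
#' @export
cross_validate <- function(data, init, free, k = NULL,
                           unit = c("clone", "variant"),
                           bounds = NULL, variants = variant_presets(),
                           schedule = induction_schedule(),
                           settings = fit_settings(), n_starts = 3,
                           seed = 1) {
  unit <- match.arg(unit)
  validate_timecourse(data)
  key <- if (unit == "clone") {
    paste(data$variant, data$clone_id)
  } else {
    data$variant
  }
  units <- unique(key)
  if (is.null(k)) k <- length(units)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > length(units)) {
    stop("k = ", k, " exceeds the ", length(units), " available ", unit,
         " units", call. = FALSE)
  }
  fold_of <- withr::with_seed(seed, {
    stats::setNames(rep_len(seq_len(k), length(units))[sample.int(
      length(units))], units)
  })
  mse <- function(fit_params, d) {
    r <- dataset_residuals(fit_params, d, variants, schedule, settings)
    mean(r^2)
  }
  rows <- purrr::map_dfr(seq_len(k), function(fold) {
    test_units <- units[fold_of[units] == fold]
    train <- data[!key %in% test_units, ]
    test <- data[key %in% test_units, ]
    # fractions are dropped here: end-point rows of held-out units must
    # not leak into training, so CV scores the dynamic profiles only
    train_ds <- new_timecourse(tibble::as_tibble(train),
                               metadata = attr(data, "metadata"))
    fit <- fit_parameters(train_ds, init, free, bounds = bounds,
                          variants = variants, schedule = schedule,
                          settings = settings, n_starts = n_starts,
                          seed = seed + fold)
    test_ds <- new_timecourse(tibble::as_tibble(test))
    tibble::tibble(
      fold = fold,
      held_out = paste(test_units, collapse = ";"),
      n_train = nrow(train), n_test = nrow(test),
      train_mse = fit$objective / fit$n_obs,
      test_mse = mse(fit$params, test_ds)
    )
  })
  structure(rows, class = c("cv_report", class(rows)),
            unit = unit, k = k, free = free, seed = seed)
}

#' Cross-validation summary
#'
#' @param x a `cv_report`.
#' @param ... unused.
#' @return One-row tibble with mean/sd train and test error and their
#'   ratio.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    k = attr(x, "k"), unit = attr(x, "unit"),
    mean_train_mse = mean(x$train_mse), mean_test_mse = mean(x$test_mse),
    sd_test_mse = stats::sd(x$test_mse),
    test_train_ratio = mean(x$test_mse) / max(mean(x$train_mse), 1e-300)
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold by %s\n", attr(x, "k"), attr(x, "unit")))
  NextMethod()
}
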