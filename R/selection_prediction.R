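# Evidence-based model comparison and robust posterior prediction.

#' Bayes factor from two log-evidences
#'
#' Compares two models by the ratio of their evidences,
#' \eqn{B = \exp(E_2 - E_1)}, computed in log space so that extreme
#' evidence gaps do not overflow.
#'
#' @param e1,e2 Log-evidences of the two models (finite scalars).
#' @param labels Model labels, default `c("model1", "model2")`.
#' @return An object of class `"lj_model_comparison"`: `labels`,
#'   `log_evidences`, `log_bayes_factor` (`e2 - e1`), `bayes_factor`.
#' @examples
#' bayes_factor(-9.72, 2.81)  # strongly favors the second model
#' @export
bayes_factor <- function(e1, e2, labels = c("model1", "model2")) {
  stopifnot(is.finite(e1), is.finite(e2), length(labels) == 2L)
  structure(list(labels = labels,
                 log_evidences = c(e1, e2),
                 log_bayes_factor = e2 - e1,
                 bayes_factor = exp(e2 - e1)),
            class = "lj_model_comparison")
}

#' @export
print.lj_model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison: %s (logE = %.3f) vs %s (logE = %.3f)\n",
              x$labels[1], x$log_evidences[1], x$labels[2], x$log_evidences[2]))
  cat(sprintf("Bayes factor (%s / %s) = %.3g\n",
              x$labels[2], x$labels[1], x$bayes_factor))
  invisible(x)
}

#' Robust posterior prediction of an observable curve
#'
#' Propagates posterior parameter uncertainty into an observable: the
#' forward model is evaluated at the most probable value and at
#' `subsample` posterior draws (with replacement when `subsample` exceeds
#' the ensemble size), and the pointwise 5--95% quantiles across draws
#' summarize the predictive spread. Individual forward-model failures are
#' dropped and counted; more than 50% failures is an error.
#'
#' @param ensemble An `"lj_ensemble"` or `"lj_fit"` whose samples carry
#'   LJ parameter columns.
#' @param model An `"lj_forward_model"`.
#' @param condition An [lj_condition()].
#' @param r_grid Separations to predict on.
#' @param subsample Number of posterior draws (default 100).
#' @param seed Seed for the draw selection.
#' @param probs Quantile band (default `c(0.05, 0.95)`).
#' @return An object of class `"lj_prediction"`: `r_grid`, `mpv_curve`,
#'   `q05`, `q95`, `condition`, `n_failed`, `n_draws`.
#' @export
robust_predict <- function(ensemble, model, condition, r_grid,
                           subsample = 100, seed = NULL,
                           probs = c(0.05, 0.95)) {
  ens <- as_ensemble(ensemble)
  n <- nrow(ens$samples)
  if (n == 0L) stop("empty ensemble")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, subsample, replace = TRUE)
  params_at <- function(th) lj_params(th[["epsilon"]], th[["sigma"]],
                                      if ("p" %in% names(th)) th[["p"]] else 12)
  mpv_th <- mpv(ens)
  mpv_curve <- eval_forward_model(model, params_at(mpv_th), condition, r_grid)
  curves <- matrix(NA_real_, subsample, length(r_grid))
  failed <- 0L
  for (k in seq_len(subsample)) {
    th <- ens$samples[idx[k], ]
    curves[k, ] <- tryCatch(
      eval_forward_model(model, params_at(th), condition, r_grid),
      error = function(e) { failed <<- failed + 1L; rep(NA_real_, length(r_grid)) })
  }
  if (failed > subsample / 2)
    stop(sprintf("forward model failed for %d of %d posterior draws",
                 failed, subsample))
  ok <- stats::complete.cases(curves)
  qs <- apply(curves[ok, , drop = FALSE], 2L, stats::quantile,
              probs = probs, type = 7)
  structure(list(r_grid = r_grid, mpv_curve = mpv_curve,
                 q05 = qs[1, ], q95 = qs[2, ], probs = probs,
                 condition = condition, n_failed = failed,
                 n_draws = sum(ok)),
            class = "lj_prediction")
}

#' @export
print.lj_prediction <- function(x, ...) {
  cat(sprintf("<lj_prediction> '%s': %d grid points, %d posterior draws (%d failed)\n",
              x$condition$label, length(x$r_grid), x$n_draws, x$n_failed))
  invisible(x)
}

#' Relative squared prediction error
#'
#' The scalar error of a set of point predictions against reference
#' values, \eqn{\Delta g = \frac{1}{N}\sum_k ((g_k - r_k)/r_k)^2}, used to
#' compare predicted quantities of interest (density, diffusion, ...)
#' across thermodynamic conditions.
#'
#' @param predicted Predictions \eqn{g_k}.
#' @param reference Reference values \eqn{r_k}, all nonzero.
#' @return Scalar error.
#' @export
prediction_error <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(predicted) < 1L)
    stop("'predicted' and 'reference' must have equal length >= 1")
  if (any(reference == 0)) stop("reference values must be nonzero")
  mean(((predicted - reference) / reference)^2)
}

#' Mean-squared RDF error averaged over conditions
#'
#' @param predicted_curves List of predicted curves, one per condition.
#' @param reference_curves List of reference curves on matching grids.
#' @return Mean over conditions of the per-condition mean-squared error.
#' @export
rdf_error <- function(predicted_curves, reference_curves) {
  if (length(predicted_curves) != length(reference_curves) ||
      length(predicted_curves) < 1L)
    stop("matched non-empty lists of curves required")
  errs <- mapply(function(p, r) {
    if (length(p) != length(r)) stop("curve grid mismatch between conditions")
    mean((p - r)^2)
  }, predicted_curves, reference_curves)
  mean(errs)
}
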