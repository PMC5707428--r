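# The model-fitting front end: lj_calibrate() and its S3 methods.

# Build the (log_prior, log_lik) pair for one dataset under one model.
make_objective <- function(dataset, model, prior, forward) {
  has_p <- "p" %in% prior$names
  r <- dataset$r
  obs <- dataset$values
  cond <- dataset$condition
  log_lik <- function(theta) {
    pars <- lj_params(theta[["epsilon"]], theta[["sigma"]],
                      if (has_p) theta[["p"]] else 12)
    curve <- eval_forward_model(forward, pars, cond, r)
    log_likelihood(obs, curve, theta[["sigma_n"]])
  }
  if (!is.null(forward$evaluate_batch)) {
    n_d <- length(obs)
    log_lik <- function(theta) {
      curves <- forward$evaluate_batch(theta, cond, r)
      sse <- rowSums((curves - rep(obs, each = nrow(theta)))^2)
      sn <- theta[, "sigma_n"]
      -n_d / 2 * log(2 * pi * sn^2) - sse / (2 * sn^2)
    }
    attr(log_lik, "vectorized") <- TRUE
  }
  log_prior <- function(theta) log_prior_uniform(theta, prior)
  attr(log_prior, "vectorized") <- TRUE
  list(log_prior = log_prior, log_lik = log_lik)
}

#' Bayesian calibration of Lennard-Jones parameters
#'
#' Fits the generalized Lennard-Jones potential to one observable curve
#' by sampling the posterior of \eqn{\theta = (\epsilon, \sigma, [p],
#' \sigma_n)} with the transitional MCMC sampler [run_tmcmc()] under the
#' Gaussian curve likelihood [log_likelihood()] and a uniform box prior.
#' The classical model (`"lj6-12"`) fixes the repulsion exponent at 12
#' and infers three parameters; `"lj6-p"` infers the exponent as well.
#' The returned fit carries an equally-weighted posterior ensemble and
#' the model log-evidence used for selection between the two forms.
#'
#' @param data An [lj_dataset()].
#' @param model `"lj6-12"` or `"lj6-p"`.
#' @param prior Uniform box prior; defaults to [lj_prior()] for `model`.
#' @param control A [tmcmc_control()]; when omitted, the calibration
#'   defaults are used (2000 samples per stage for 6-12, 4000 for 6-p).
#' @param forward Forward model; defaults to the built-in model for the
#'   dataset kind ([dimer_energy_model()] untruncated for dimer scans,
#'   [dilute_rdf_model()] with the \eqn{3\sigma} cutoff for RDFs).
#' @param surrogate Optional [surrogate_control()].
#' @param seed Convenience override of `control$seed`.
#' @return An object of class `"lj_fit"` with components `ensemble`
#'   (`"lj_ensemble"`), `data`, `model`, `prior`, `forward`, plus the
#'   usual methods: [coef()][coef.lj_fit] (MPV), `confint` (5--95%
#'   quantiles), `summary`, `predict` (robust posterior prediction),
#'   `plot`, `residuals`, `simulate`, `logLik`.
#' @examples
#' d <- generate(synthetic_spec(
#'   c(epsilon = 0.238, sigma = 3.405, sigma_n = 0.01), "dimer_energy",
#'   lj_condition("demo"), r_min = 3.1, r_max = 8.5, n_points = 30, seed = 2))
#' fit <- lj_calibrate(d, "lj6-12",
#'                     control = tmcmc_control(n_samples = 300, seed = 1))
#' coef(fit)
#' @export
lj_calibrate <- function(data, model = c("lj6-12", "lj6-p"), prior = NULL,
                         control = NULL, forward = NULL, surrogate = NULL,
                         seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(data, "lj_dataset"))
  if (is.null(prior)) prior <- lj_prior(model)
  if (model == "lj6-12" && "p" %in% prior$names)
    stop("the 6-12 model takes a prior without 'p'")
  if (model == "lj6-p" && !"p" %in% prior$names)
    stop("the 6-p model needs a prior over 'p'")
  if (is.null(control))
    control <- tmcmc_control(n_samples = if (model == "lj6-p") 4000 else 2000)
  if (!is.null(seed)) control$seed <- seed
  if (is.null(forward)) forward <- builtin_forward_model(data$kind)
  obj <- make_objective(data, model, prior, forward)
  ens <- run_tmcmc(obj$log_prior, obj$log_lik, prior, control,
                   surrogate = surrogate)
  structure(list(ensemble = ens, data = data, model = model, prior = prior,
                 forward = forward, call = match.call()),
            class = "lj_fit")
}

#' @export
print.lj_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Lennard-Jones %s calibration of %s dataset '%s' (%d points)\n",
              if (x$model == "lj6-p") "6-p" else "6-12",
              x$data$kind, x$data$condition$label, length(x$data$r)))
  cat("Posterior most probable values:\n")
  print(round(mpv(x), digits))
  cat(sprintf("log-evidence: %.*f  (%d samples, %d stages)\n", digits,
              x$ensemble$log_evidence, nrow(x$ensemble$samples),
              length(x$ensemble$stage_exponents) - 1L))
  invisible(x)
}

#' Most probable parameter values of a fit
#'
#' @param object An `"lj_fit"`.
#' @param ... Unused.
#' @return Named vector: the posterior sample maximizing prior times
#'   likelihood (the MPV).
#' @export
coef.lj_fit <- function(object, ...) mpv(object)

#' @export
confint.lj_fit <- function(object, parm, level = 0.90, ...) {
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  q <- posterior_quantiles(object, probs)
  if (!missing(parm)) q <- q[parm, , drop = FALSE]
  q
}

#' @export
logLik.lj_fit <- function(object, ...) {
  i <- which.max(object$ensemble$log_priors + object$ensemble$log_liks)
  structure(object$ensemble$log_liks[i],
            df = ncol(object$ensemble$samples), class = "logLik")
}

#' Model log-evidence
#'
#' @param object An `"lj_fit"`, `"lj_ensemble"` or `"lj_hbfit"` (stage-2
#'   evidence).
#' @return The log model evidence \eqn{\log p(d | M)} estimated by the
#'   tempered sampler.
#' @export
log_evidence <- function(object) {
  if (inherits(object, "lj_hbfit")) return(object$hyper$log_evidence)
  as_ensemble(object)$log_evidence
}

#' @export
summary.lj_fit <- function(object, probs = c(0.05, 0.95), ...) {
  q <- posterior_quantiles(object, probs)
  tab <- cbind(MPV = mpv(object),
               mean = colMeans(object$ensemble$samples), q)
  structure(list(model = object$model, label = object$data$condition$label,
                 kind = object$data$kind, n_data = length(object$data$r),
                 table = tab, log_evidence = object$ensemble$log_evidence,
                 stages = length(object$ensemble$stage_exponents) - 1L,
                 acceptance = object$ensemble$acceptance_rates,
                 surrogate = object$ensemble$surrogate_stats),
            class = "summary.lj_fit")
}

#' @export
print.summary.lj_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Lennard-Jones %s calibration, %s '%s', N = %d\n",
              if (x$model == "lj6-p") "6-p" else "6-12",
              x$kind, x$label, x$n_data))
  print(round(x$table, digits))
  cat(sprintf("log-evidence %.3f over %d tempering stages (mean MH acceptance %.2f)\n",
              x$log_evidence, x$stages, mean(x$acceptance)))
  if (!is.null(x$surrogate))
    cat(sprintf("surrogate: %d calls, %d accepted, %d true evaluations\n",
                x$surrogate$calls, x$surrogate$accepted, x$surrogate$true_evals))
  invisible(x)
}

#' Robust posterior prediction from a fit
#'
#' @param object An `"lj_fit"`.
#' @param r_grid Grid to predict on; defaults to the data grid.
#' @param condition Condition to predict at; defaults to the data's.
#' @param subsample Posterior draws to propagate (default 100).
#' @param seed Seed for the draw selection.
#' @param ... Unused.
#' @return An `"lj_prediction"`; see [robust_predict()].
#' @export
predict.lj_fit <- function(object, r_grid = object$data$r,
                           condition = object$data$condition,
                           subsample = 100, seed = NULL, ...) {
  robust_predict(object$ensemble, object$forward, condition, r_grid,
                 subsample = subsample, seed = seed)
}

#' @export
residuals.lj_fit <- function(object, ...) {
  th <- mpv(object)
  pars <- lj_params(th[["epsilon"]], th[["sigma"]],
                    if ("p" %in% names(th)) th[["p"]] else 12)
  object$data$values -
    eval_forward_model(object$forward, pars, object$data$condition,
                       object$data$r)
}

#' Simulate datasets from the posterior predictive
#'
#' Draws parameter vectors from the posterior ensemble and generates new
#' noisy curves on the data grid under the fitted noise model.
#'
#' @param object An `"lj_fit"`.
#' @param nsim Number of datasets (default 1).
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of [lj_dataset()] objects.
#' @export
simulate.lj_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$ensemble$samples)
  idx <- sample.int(n, nsim, replace = TRUE)
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    th <- object$ensemble$samples[idx[k], ]
    pars <- lj_params(th[["epsilon"]], th[["sigma"]],
                      if ("p" %in% names(th)) th[["p"]] else 12)
    curve <- eval_forward_model(object$forward, pars, object$data$condition,
                                object$data$r)
    out[[k]] <- lj_dataset(object$data$kind, object$data$r,
                           curve + stats::rnorm(length(curve), 0, th[["sigma_n"]]),
                           object$data$condition)
  }
  out
}

#' Plot a calibration fit
#'
#' Data points with the MPV model curve and the pointwise 5--95%
#' posterior predictive band of the noiseless model curve.
#'
#' @param x An `"lj_fit"`.
#' @param subsample Posterior draws for the band (default 100).
#' @param seed Seed for the draw selection.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the `"lj_prediction"` used for the band.
#' @export
plot.lj_fit <- function(x, subsample = 100, seed = 1, ...) {
  pr <- predict(x, subsample = subsample, seed = seed)
  ylab <- if (x$data$kind == "rdf") "g(r)" else "E(r) [kcal/mol]"
  graphics::plot(x$data$r, x$data$values, pch = 16, cex = 0.6,
                 xlab = "r [Angstrom]", ylab = ylab,
                 ylim = range(x$data$values, pr$q05, pr$q95), ...)
  graphics::polygon(c(x$data$r, rev(x$data$r)), c(pr$q05, rev(pr$q95)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$data$r, pr$mpv_curve, col = "steelblue", lwd = 2)
  invisible(pr)
}
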