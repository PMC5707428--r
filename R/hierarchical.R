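# Two-level hierarchical inference: hyper-parameter posterior across
# datasets and refreshed per-dataset posteriors.

#' Hierarchical run settings
#'
#' @param stage1 A [tmcmc_control()] for the per-dataset runs (stage 1).
#' @param n_hyper Samples per stage for the hyper-parameter run (stage 2),
#'   default 1000.
#' @param n_psi Hyper-posterior draws marginalized over in the per-dataset
#'   refresh (stage 3), default 200.
#' @param n_theta Stage-1 posterior draws per dataset entering the
#'   importance-sampling hyper-likelihood (default 500); the refresh
#'   always reweights the full stage-1 ensembles.
#' @param ess_floor Effective-sample-size floor below which a refresh is
#'   flagged as degenerate (default 50).
#' @param seed Root seed; stage seeds are derived from it.
#' @return A list of class `"hb_control"`.
#' @export
hb_control <- function(stage1 = tmcmc_control(), n_hyper = 1000,
                       n_psi = 200, n_theta = 500, ess_floor = 50,
                       seed = NULL) {
  stopifnot(n_hyper >= 100, n_psi >= 10, n_theta >= 50, ess_floor > 0)
  structure(list(stage1 = stage1, n_hyper = as.integer(n_hyper),
                 n_psi = as.integer(n_psi), n_theta = as.integer(n_theta),
                 ess_floor = ess_floor, seed = seed),
            class = "hb_control")
}

#' Hyper-parameter log-likelihood
#'
#' The marginal likelihood of the hyper-parameters `psi` given all
#' datasets, estimated by importance sampling over the stage-1 posterior
#' ensembles obtained under the base (uniform) prior:
#' \deqn{\sum_i \Big[\log Z_i + \log \frac{1}{N_s}\sum_k
#'   \frac{p(\theta_i^{(k)} | \psi)}{p(\theta_i^{(k)} | base)}\Big],}
#' which equals \eqn{\sum_i \log p(d_i | \psi)} up to a `psi`-independent
#' constant. Re-running the forward model per `psi` is never needed. If a
#' `psi` is supported nowhere near a dataset's samples (all importance
#' ratios zero) the result is `-Inf`, with a warning.
#'
#' @param psi Hyper-parameter vector laid out as `family$psi_names`.
#' @param stage1 List of `"lj_ensemble"` / `"lj_fit"` objects, one per
#'   dataset, sampled under `family$base`.
#' @param family An [prior_family()].
#' @return Scalar log-density (up to a constant in `psi`).
#' @export
hyper_log_likelihood <- function(psi, stage1, family) {
  stopifnot(inherits(family, "lj_prior_family"), length(stage1) >= 1L)
  base <- family$base
  total <- 0
  for (ens in stage1) {
    ens <- as_ensemble(ens)
    lr <- conditional_log_prior(ens$samples, psi, family) -
      log_prior_uniform(ens$samples, base)
    lme <- logmeanexp(lr)
    if (!is.finite(lme)) {
      warning("psi support disjoint from a stage-1 ensemble; hyper-likelihood is -Inf")
      return(-Inf)
    }
    total <- total + ens$log_evidence + lme
  }
  total
}

#' Refresh one dataset's posterior under the hyper-posterior
#'
#' Reweights a stage-1 posterior ensemble by the ratio of its
#' hyper-marginalized conditional prior to the base prior,
#' \eqn{w_k \propto \frac{1}{N_\psi}\sum_j p(\theta^{(k)} | \psi^{(j)}) /
#' p(\theta^{(k)} | base)}, then resamples. The refreshed ensemble
#' therefore contains only stage-1 support points; the effective sample
#' size \eqn{(\sum w)^2 / \sum w^2} of the estimator is recorded.
#'
#' @param ensemble Stage-1 `"lj_ensemble"` (or `"lj_fit"`).
#' @param psi_mat Matrix of hyper-posterior draws (rows), laid out as
#'   `family$psi_names`.
#' @param family An [prior_family()].
#' @param ess_floor Warn when the ESS falls below this (default 50).
#' @return An `"lj_ensemble"` with resampled `samples`, `log_liks`,
#'   `log_priors`, plus `ess` and `weights`.
#' @export
hb_refresh <- function(ensemble, psi_mat, family, ess_floor = 50) {
  ens <- as_ensemble(ensemble)
  n <- nrow(ens$samples)
  base <- family$base
  lbase <- log_prior_uniform(ens$samples, base)
  lw_mat <- matrix(0, n, nrow(psi_mat))
  for (j in seq_len(nrow(psi_mat)))
    lw_mat[, j] <- conditional_log_prior(ens$samples, psi_mat[j, ], family) - lbase
  m <- apply(lw_mat, 1L, max)
  lw <- ifelse(is.finite(m), m + log(rowMeans(exp(lw_mat - m))), -Inf)
  w <- exp(lw - max(lw[is.finite(lw)]))
  w[!is.finite(lw)] <- 0
  if (sum(w) == 0) stop("all refresh weights are zero")
  w <- w / sum(w)
  ess <- 1 / sum(w^2)
  if (ess < ess_floor)
    warning(sprintf("refresh ESS %.1f below floor %g", ess, ess_floor))
  idx <- sample.int(n, n, replace = TRUE, prob = w)
  structure(list(samples = ens$samples[idx, , drop = FALSE],
                 log_liks = ens$log_liks[idx],
                 log_priors = ens$log_priors[idx],
                 log_evidence = ens$log_evidence,
                 stage_exponents = ens$stage_exponents,
                 weights = w, ess = ess, seed = ens$seed,
                 config = ens$config),
            class = "lj_ensemble")
}

#' Hierarchical Bayesian calibration across datasets
#'
#' Three stages: (1) an independent [lj_calibrate()] per dataset under the
#' base uniform prior; (2) a TMCMC run over the hyper-parameters `psi`
#' with [hyper_log_likelihood()] and a uniform hyperprior over the
#' family's hyper-box (locations range over the base box, scales over
#' `(1e-3 w, w)` per parameter); (3) a per-dataset refresh by
#' [hb_refresh()], marginalizing `psi` over its full posterior ensemble
#' rather than a point estimate. The noise scale `sigma_n` stays outside
#' the hierarchical tie: noise is condition-specific.
#'
#' @param datasets List of [lj_dataset()] objects (>= 1).
#' @param model `"lj6-12"` or `"lj6-p"`.
#' @param family `"truncnorm"` (default) or `"uniform"`; see
#'   [prior_family()].
#' @param prior Base prior box; defaults to [lj_prior()] for `model`.
#' @param control An [hb_control()].
#' @param seed Root seed (overrides `control$seed`).
#' @return An object of class `"lj_hbfit"`: `stage1` (list of
#'   `"lj_fit"`), `hyper` (`"lj_ensemble"` over psi), `refreshed` (list of
#'   `"lj_ensemble"`), `ess`, `family`, `warnings`.
#' @export
lj_hb <- function(datasets, model = c("lj6-12", "lj6-p"),
                  family = c("truncnorm", "uniform"),
                  prior = NULL, control = hb_control(), seed = NULL) {
  model <- match.arg(model)
  family_name <- match.arg(family)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, TRUE, "lj_dataset")))
  if (is.null(prior)) prior <- lj_prior(model)
  if (is.null(seed)) seed <- if (!is.null(control$seed)) control$seed else 1L
  fam <- prior_family(family_name, prior)

  stage1 <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    cfg <- control$stage1
    cfg$seed <- seed + 1000L * i
    stage1[[i]] <- lj_calibrate(datasets[[i]], model = model, prior = prior,
                                control = cfg)
  }

  hyper_box <- sampling_box(fam$hyper_box$lower, fam$hyper_box$upper)
  hwidth <- hyper_box$upper - hyper_box$lower
  hyper_lp <- function(psi) {
    if (all(psi >= hyper_box$lower & psi <= hyper_box$upper))
      -sum(log(hwidth)) else -Inf
  }
  ens1 <- lapply(stage1, as_ensemble)
  set.seed(seed + 333L)
  ens1_thin <- lapply(ens1, function(e) {
    n1 <- nrow(e$samples)
    if (n1 > control$n_theta) {
      keep <- sample.int(n1, control$n_theta)
      e$samples <- e$samples[keep, , drop = FALSE]
    }
    e
  })
  hyper_ll <- function(psi) hyper_log_likelihood(psi, ens1_thin, fam)
  hyper <- run_tmcmc(hyper_lp, hyper_ll, hyper_box,
                     tmcmc_control(n_samples = control$n_hyper,
                                   seed = seed + 777L))

  set.seed(seed + 555L)
  n_psi <- min(control$n_psi, nrow(hyper$samples))
  psi_mat <- hyper$samples[sample.int(nrow(hyper$samples), n_psi), ,
                           drop = FALSE]
  refreshed <- vector("list", length(datasets))
  warns <- character(0)
  for (i in seq_along(datasets)) {
    refreshed[[i]] <- withCallingHandlers(
      hb_refresh(stage1[[i]], psi_mat, fam, control$ess_floor),
      warning = function(w) {
        warns <<- c(warns, sprintf("dataset %d: %s", i, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  labels <- vapply(datasets, function(d) d$condition$label, "")
  names(stage1) <- names(refreshed) <- labels
  structure(list(stage1 = stage1, hyper = hyper, refreshed = refreshed,
                 ess = vapply(refreshed, function(r) r$ess, 0),
                 family = fam, datasets = datasets, seed = seed,
                 warnings = warns),
            class = "lj_hbfit")
}

#' @export
print.lj_hbfit <- function(x, ...) {
  cat(sprintf("Hierarchical LJ calibration: %d datasets, %s conditional prior\n",
              length(x$stage1), x$family$family))
  cat(sprintf("Hyper-posterior: %d samples, log-evidence %.3f\n",
              nrow(x$hyper$samples), x$hyper$log_evidence))
  cat("Refresh effective sample sizes:\n")
  print(round(x$ess, 1))
  if (length(x$warnings)) cat("Warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' @export
summary.lj_hbfit <- function(object, probs = c(0.05, 0.95), ...) {
  out <- lapply(names(object$refreshed), function(nm) {
    q1 <- posterior_quantiles(object$stage1[[nm]], probs)
    q2 <- posterior_quantiles(object$refreshed[[nm]], probs)
    list(label = nm, stage1 = q1, refreshed = q2,
         mpv_stage1 = mpv(object$stage1[[nm]]),
         mpv_refreshed = mpv(object$refreshed[[nm]]))
  })
  names(out) <- names(object$refreshed)
  structure(out, class = "summary.lj_hbfit")
}

#' @export
print.summary.lj_hbfit <- function(x, ...) {
  for (s in x) {
    cat(sprintf("-- %s --\n", s$label))
    cat("stage-1 MPV:  "); print(round(s$mpv_stage1, 4))
    cat("refreshed MPV:"); print(round(s$mpv_refreshed, 4))
  }
  invisible(x)
}
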