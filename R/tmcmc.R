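# Transitional Markov chain Monte Carlo: tempered posterior sampling with a
# model-evidence estimate per run.

#' TMCMC sampler settings
#'
#' @param n_samples Samples per tempering stage (>= 100). The calibration
#'   default is 2000 for the three-parameter 6-12 model and 4000 when the
#'   repulsion exponent is inferred.
#' @param target_cov Target coefficient of variation of the incremental
#'   importance weights that controls the tempering step (default 1.0).
#' @param beta Random-walk proposal scale: the proposal covariance is
#'   `beta^2` times the weighted sample covariance (default 0.2).
#' @param n_mh Metropolis-Hastings sweeps per stage (default 5). Each
#'   sweep proposes one move for every chain in parallel; extra sweeps
#'   decorrelate the resampled ensemble, which matters for sharply
#'   concentrated posteriors such as low-noise dimer fits.
#' @param max_stages Stage cap before a non-convergence error (default 50).
#' @param seed Integer seed; every random draw of the run derives from it.
#' @return A list of class `"tmcmc_control"`.
#' @export
tmcmc_control <- function(n_samples = 2000, target_cov = 1.0, beta = 0.2,
                          n_mh = 5, max_stages = 50, seed = NULL) {
  stopifnot(n_samples >= 100, target_cov > 0, beta > 0, beta <= 1,
            n_mh >= 1, max_stages >= 1)
  structure(list(n_samples = as.integer(n_samples), target_cov = target_cov,
                 beta = beta, n_mh = as.integer(n_mh),
                 max_stages = as.integer(max_stages), seed = seed),
            class = "tmcmc_control")
}

#' Generic box support for the sampler
#'
#' A plain rectangular support for [run_tmcmc()] when the parameters are
#' not LJ parameters (e.g. hyper-parameters, or test problems).
#'
#' @param lower,upper Named numeric vectors, `lower < upper`.
#' @return A list with `lower`, `upper`, `names`.
#' @export
sampling_box <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == length(upper), all(lower < upper))
  nm <- names(lower)
  if (is.null(nm)) nm <- paste0("x", seq_along(lower))
  list(lower = stats::setNames(as.numeric(lower), nm),
       upper = stats::setNames(as.numeric(upper), nm), names = nm)
}

as_support <- function(support) {
  if (inherits(support, "lj_prior"))
    list(lower = support$lower, upper = support$upper, names = support$names)
  else if (is.list(support) && all(c("lower", "upper", "names") %in% names(support)))
    support
  else stop("'support' must be an lj_prior or a sampling_box()")
}

logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(mean(exp(x - m)))
}

#' Next tempering exponent
#'
#' Finds the largest admissible increment of the tempering exponent: the
#' largest `dp <= 1 - current` such that the coefficient of variation of
#' the incremental weights `exp(dp * (l - max l))` does not exceed
#' `target_cov`, located by bisection to an absolute tolerance of 1e-10.
#' Returns 1 when even the full remaining step satisfies the bound (in
#' particular for identical log-likelihoods, whose weights have zero CoV).
#'
#' @param current Current exponent in `[0, 1)`.
#' @param log_likelihoods Log-likelihood values of the current ensemble;
#'   `-Inf` entries contribute zero weight.
#' @param target_cov Weight-CoV bound (default 1.0).
#' @return The next exponent in `(current, 1]`.
#' @export
next_exponent <- function(current, log_likelihoods, target_cov = 1.0) {
  stopifnot(current < 1, target_cov > 0)
  ll <- log_likelihoods
  m <- max(ll[is.finite(ll)])
  cov_at <- function(dp) {
    w <- exp(dp * (ll - m))
    w[!is.finite(ll)] <- 0
    mu <- mean(w)
    if (mu == 0) return(Inf)
    stats::sd(w) / mu
  }
  hi <- 1 - current
  if (cov_at(hi) <= target_cov) return(1)
  lo <- 0
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (cov_at(mid) <= target_cov) lo <- mid else hi <- mid
  }
  current + lo
}

weighted_cov <- function(X, w) {
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu, "-")
  t(Xc) %*% (Xc * w)
}

tmcmc_condition <- function(class, message, data = NULL) {
  structure(class = c(class, "error", "condition"),
            list(message = message, call = sys.call(-1), data = data))
}

#' Run the transitional MCMC sampler
#'
#' Samples the posterior `prior x likelihood` through the tempered
#' sequence \eqn{p_j(\theta) \propto p(\theta) L(\theta)^{q_j}} with
#' exponents \eqn{0 = q_0 < q_1 < ... < q_m = 1} chosen adaptively by
#' [next_exponent()]. Each stage reweights the ensemble by
#' \eqn{L^{q_{j+1}-q_j}}, accumulates the log-evidence as the log mean
#' incremental weight, resamples leaders multinomially, and moves every
#' chain through `n_mh` Metropolis-Hastings sweeps with a Gaussian
#' random-walk proposal whose covariance is `beta^2` times the weighted
#' sample covariance. Proposals leaving the support are rejected, so the
#' posterior is correctly truncated to the box. The final ensemble is an
#' equally-weighted posterior sample and `log_evidence` estimates
#' \eqn{\log p(d)}.
#'
#' All random draws of a sweep (resampling indices, proposal increments,
#' acceptance uniforms) are generated before any likelihood is evaluated,
#' so the sampled chain depends only on the seed and the sample indices,
#' not on the order in which likelihoods are computed within a sweep.
#'
#' @param log_prior Function: named parameter vector -> log prior density.
#' @param log_lik Function: named parameter vector -> log likelihood. A
#'   function carrying attribute `vectorized = TRUE` is instead called
#'   with a matrix (one row per point) and must return one value per row;
#'   the built-in calibration objectives are batched this way.
#' @param support An `"lj_prior"` or [sampling_box()]: the sampling box.
#' @param config A [tmcmc_control()].
#' @param sample_prior Optional function `n -> n x d matrix` drawing from
#'   the prior; defaults to uniform sampling over the support box (exact
#'   for the uniform calibration priors).
#' @param surrogate Optional [surrogate_control()]; when enabled, a local
#'   kriging surrogate of the log-likelihood stands in for true
#'   evaluations where its predicted error and quantile-band checks pass.
#' @return An object of class `"lj_ensemble"`: list with `samples` (n x d
#'   matrix), `log_liks`, `log_priors`, `log_evidence`,
#'   `stage_exponents` (from 0 to 1), `acceptance_rates`,
#'   `surrogate_stats`, `seed`, `config`.
#' @examples
#' box <- sampling_box(c(x = -8), c(x = 8))
#' fit <- run_tmcmc(function(th) dnorm(th[["x"]], log = TRUE),
#'                  function(th) dnorm(0, th[["x"]], 1, log = TRUE),
#'                  box, tmcmc_control(n_samples = 500, seed = 1),
#'                  sample_prior = function(n) matrix(rnorm(n), ncol = 1))
#' fit$log_evidence  # close to log(1 / sqrt(4 * pi))
#' @export
run_tmcmc <- function(log_prior, log_lik, support, config = tmcmc_control(),
                      sample_prior = NULL, surrogate = NULL) {
  sup <- as_support(support)
  d <- length(sup$names)
  n <- config$n_samples
  if (!is.null(config$seed)) set.seed(config$seed)

  eval_lp <- if (isTRUE(attr(log_prior, "vectorized")))
    function(X) as.numeric(log_prior(X))
  else function(X) apply(X, 1L, log_prior)
  batched <- isTRUE(attr(log_lik, "vectorized"))
  eval_ll_batch <- function(X) {
    if (batched) as.numeric(log_lik(X))
    else apply(X, 1L, function(x) log_lik(stats::setNames(x, sup$names)))
  }
  eval_ll_true <- function(x)
    eval_ll_batch(matrix(x, nrow = 1, dimnames = list(NULL, sup$names)))

  use_surr <- !is.null(surrogate) && isTRUE(surrogate$enabled)
  arch_X <- NULL; arch_y <- NULL
  surr_stats <- list(calls = 0L, accepted = 0L, rejected = 0L,
                     outside_box = 0L, true_evals = 0L,
                     reasons = c(error_gt_5pct = 0L, outside_quantile_band = 0L,
                                 too_few_points = 0L))

  if (is.null(sample_prior)) {
    X <- matrix(stats::runif(n * d, min = rep(sup$lower, each = n),
                             max = rep(sup$upper, each = n)),
                nrow = n, ncol = d)
  } else {
    X <- sample_prior(n)
    if (!is.matrix(X)) X <- matrix(X, ncol = d)
    stopifnot(nrow(X) == n, ncol(X) == d)
  }
  colnames(X) <- sup$names
  lp <- eval_lp(X)
  ll <- eval_ll_batch(X)
  surr_stats$true_evals <- surr_stats$true_evals + n
  if (use_surr) { arch_X <- X; arch_y <- ll }
  if (all(!is.finite(ll)))
    stop(tmcmc_condition("ljbayes_degenerate_likelihood",
                         "likelihood is -Inf at every prior sample"))

  q <- 0; logZ <- 0
  exponents <- 0; acc_rates <- numeric(0)
  stage <- 0L
  while (q < 1) {
    stage <- stage + 1L
    if (stage > config$max_stages) {
      partial <- list(samples = X, log_liks = ll, log_priors = lp,
                      stage_exponents = exponents, log_evidence = logZ)
      stop(tmcmc_condition("ljbayes_nonconvergence",
                           sprintf("tempering did not reach 1 in %d stages",
                                   config$max_stages),
                           data = partial))
    }
    q_new <- next_exponent(q, ll, config$target_cov)
    dq <- q_new - q
    lw <- dq * ll
    lw[!is.finite(ll)] <- -Inf
    logZ <- logZ + logmeanexp(lw)
    w <- exp(lw - max(lw[is.finite(lw)]))
    w[!is.finite(lw)] <- 0
    w <- w / sum(w)

    C <- config$beta^2 * weighted_cov(X, w)
    Lc <- tryCatch(chol(C + diag(1e-12 * (diag(C) + 1e-300), d)),
                   error = function(e) chol(diag(pmax(diag(C), 1e-12), d)))

    idx <- sample.int(n, n, replace = TRUE, prob = w)
    X <- X[idx, , drop = FALSE]
    lp <- lp[idx]; ll <- ll[idx]

    sweep_acc <- numeric(config$n_mh)
    for (s in seq_len(config$n_mh)) {
      # all randomness drawn up front: likelihood evaluation order is free
      Z <- matrix(stats::rnorm(n * d), n, d)
      U <- stats::runif(n)

      prop <- X + Z %*% Lc
      inside <- rep(TRUE, n)
      for (j in seq_len(d))
        inside <- inside & prop[, j] >= sup$lower[j] & prop[, j] <= sup$upper[j]
      lp_prop <- rep(-Inf, n)
      lp_prop[inside] <- eval_lp(prop[inside, , drop = FALSE])
      ll_prop <- rep(-Inf, n)

      need <- which(is.finite(lp_prop))
      if (use_surr && length(need)) {
        res <- surrogate_stage_eval(prop, seq_len(n), need, X, arch_X, arch_y,
                                    sup, surrogate, eval_ll_true)
        ll_prop[need] <- res$values
        arch_X <- res$arch_X; arch_y <- res$arch_y
        surr_stats <- accumulate_surr_stats(surr_stats, res$stats)
      } else if (length(need)) {
        ll_prop[need] <- eval_ll_batch(prop[need, , drop = FALSE])
        surr_stats$true_evals <- surr_stats$true_evals + length(need)
      }

      log_alpha <- (lp_prop + q_new * ll_prop) - (lp + q_new * ll)
      acc <- is.finite(log_alpha) & log(U) < log_alpha
      X[acc, ] <- prop[acc, , drop = FALSE]
      lp[acc] <- lp_prop[acc]; ll[acc] <- ll_prop[acc]
      sweep_acc[s] <- mean(acc)
    }

    q <- q_new
    exponents <- c(exponents, q)
    acc_rates <- c(acc_rates, mean(sweep_acc))
  }

  structure(list(samples = X, log_liks = ll, log_priors = lp,
                 log_evidence = logZ, stage_exponents = exponents,
                 acceptance_rates = acc_rates,
                 surrogate_stats = if (use_surr) surr_stats else NULL,
                 seed = config$seed, config = config),
            class = "lj_ensemble")
}

accumulate_surr_stats <- function(a, b) {
  a$calls <- a$calls + b$calls
  a$accepted <- a$accepted + b$accepted
  a$rejected <- a$rejected + b$rejected
  a$outside_box <- a$outside_box + b$outside_box
  a$true_evals <- a$true_evals + b$true_evals
  a$reasons <- a$reasons + b$reasons
  a
}

#' @export
print.lj_ensemble <- function(x, ...) {
  cat(sprintf("<lj_ensemble> %d samples of (%s), %d stages, log-evidence %.4f\n",
              nrow(x$samples), paste(colnames(x$samples), collapse = ", "),
              length(x$stage_exponents) - 1L, x$log_evidence))
  invisible(x)
}

#' Most probable value of an ensemble
#'
#' The posterior sample maximizing `log_prior + log_likelihood`; ties are
#' broken by the lowest sample index.
#'
#' @param ensemble An `"lj_ensemble"` (or `"lj_fit"`).
#' @return Named numeric parameter vector.
#' @export
mpv <- function(ensemble) {
  ensemble <- as_ensemble(ensemble)
  if (nrow(ensemble$samples) == 0L) stop("empty ensemble")
  i <- which.max(ensemble$log_priors + ensemble$log_liks)
  ensemble$samples[i, ]
}

as_ensemble <- function(x) {
  if (inherits(x, "lj_fit")) x$ensemble else x
}

#' Per-parameter posterior quantiles
#'
#' Empirical quantiles (linear interpolation, `type = 7`) of each
#' parameter of a posterior ensemble.
#'
#' @param ensemble An `"lj_ensemble"` or `"lj_fit"`.
#' @param probs Quantile levels in (0, 1); default the 5--95% band.
#' @return Matrix with one row per parameter, one column per level.
#' @export
posterior_quantiles <- function(ensemble, probs = c(0.05, 0.95)) {
  ensemble <- as_ensemble(ensemble)
  if (nrow(ensemble$samples) == 0L) stop("empty ensemble")
  stopifnot(all(probs > 0), all(probs < 1))
  t(apply(ensemble$samples, 2L, stats::quantile, probs = probs, type = 7))
}
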