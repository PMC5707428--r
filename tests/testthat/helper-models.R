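# Shared builders: conjugate Gaussian test problems and small synthetic
# datasets used across test files.

# 1-D conjugate model: prior N(0,1) truncated (negligibly) to [-8, 8],
# likelihood N(datum | x, lik_sd). Analytic log-evidence is the marginal
# N(datum | 0, 1 + lik_sd^2).
conjugate_problem <- function(lik_sd = 1, datum = 0) {
  list(
    box = sampling_box(c(x = -8), c(x = 8)),
    log_prior = function(th) stats::dnorm(th[["x"]], log = TRUE),
    log_lik = function(th) stats::dnorm(datum, th[["x"]], lik_sd, log = TRUE),
    sample_prior = function(n) matrix(stats::rnorm(n), ncol = 1),
    log_evidence = stats::dnorm(datum, 0, sqrt(1 + lik_sd^2), log = TRUE),
    post_mean = datum / (1 + lik_sd^2),
    post_sd = sqrt(lik_sd^2 / (1 + lik_sd^2)))
}

# Quick, low-noise dimer dataset for fit-interface tests.
small_dimer <- function(seed = 7, noise = 0.01, p = 12,
                        eps = 0.238, sig = 3.405, n = 30) {
  truth <- if (p == 12) c(epsilon = eps, sigma = sig, sigma_n = noise)
           else c(epsilon = eps, sigma = sig, p = p, sigma_n = noise)
  generate(synthetic_spec(truth, "dimer_energy", lj_condition("test"),
                          r_min = 0.92 * sig, r_max = 2.5 * sig,
                          n_points = n, noise = noise, seed = seed))
}

fast_control <- function(n_samples = 400, seed = 1, ...)
  tmcmc_control(n_samples = n_samples, seed = seed, ...)
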