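test_that("next_exponent clamps, solves the CoV equation, and matches a grid oracle", {
  expect_identical(next_exponent(0, rep(-3.2, 50)), 1)
  expect_identical(next_exponent(0.999, c(0, -500, -1000)), 1)

  ll <- c(0, -10)
  dp_star <- next_exponent(0, ll, target_cov = 1)
  # dense grid oracle: largest dp with CoV(exp(dp * (ll - max))) <= 1
  grid <- seq(1e-6, 1, length.out = 2e5)
  covs <- vapply(grid, function(dp) {
    w <- exp(dp * (ll - 0)); sd(w) / mean(w)
  }, 1)
  oracle <- max(grid[covs <= 1])
  expect_equal(dp_star, oracle, tolerance = 1e-4)
  # analytic check for two points: CoV = (1 - e^{-10 dp}) / (1 + e^{-10 dp}) * ...
  w <- exp(dp_star * (ll - 0))
  expect_equal(sd(w) / mean(w), 1, tolerance = 1e-8)
})

test_that("a constant likelihood leaves the prior intact and returns ln c", {
  box <- sampling_box(c(x = 0), c(x = 1))
  cfg <- tmcmc_control(n_samples = 2000, seed = 42)
  fit <- run_tmcmc(function(th) 0, function(th) -3.7, box, cfg)
  expect_equal(fit$log_evidence, -3.7, tolerance = 1e-6)
  expect_equal(fit$stage_exponents, c(0, 1))
  ks <- suppressWarnings(ks.test(fit$samples[, 1], "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("conjugate Gaussian evidence and posterior moments are recovered", {
  pr <- conjugate_problem()
  errs <- vapply(1:3, function(s) {
    fit <- run_tmcmc(pr$log_prior, pr$log_lik, pr$box,
                     tmcmc_control(n_samples = 1000, seed = s),
                     sample_prior = pr$sample_prior)
    fit$log_evidence - pr$log_evidence
  }, 1)
  expect_lt(mean(abs(errs)), 0.05)
  expect_equal(pr$log_evidence, -1.26551, tolerance = 1e-5)

  # sharper 2-D likelihood: posterior mean within 3 Monte-Carlo SEs
  box2 <- sampling_box(c(x = -8, y = -8), c(x = 8, y = 8))
  lp2 <- function(th) sum(dnorm(th, log = TRUE))
  ll2 <- function(th) sum(dnorm(c(1, -0.5), th, 1, log = TRUE))
  fit2 <- run_tmcmc(lp2, ll2, box2, tmcmc_control(n_samples = 2000, seed = 5),
                    sample_prior = function(n) matrix(rnorm(2 * n), ncol = 2))
  post_mean <- c(0.5, -0.25)  # datum / 2 under equal prior/likelihood precision
  for (j in 1:2) {
    mc_se <- sd(fit2$samples[, j]) / sqrt(nrow(fit2$samples))
    # the ensemble is correlated, so allow a generous effective-size factor
    expect_lt(abs(mean(fit2$samples[, j]) - post_mean[j]), 3 * mc_se * 5)
  }
})

test_that("MPV picks the highest-posterior sample and conjugate mode is matched", {
  ens <- structure(list(samples = matrix(c(1, 2, 3), ncol = 1,
                                         dimnames = list(NULL, "x")),
                        log_liks = c(-5, -1, -4), log_priors = c(0, 0, 0)),
                   class = "lj_ensemble")
  expect_equal(unname(mpv(ens)), 2)
  # ties broken by lowest index
  ens$log_liks <- c(-1, -1, -4)
  expect_equal(unname(mpv(ens)), 1)

  pr <- conjugate_problem()
  fit <- run_tmcmc(pr$log_prior, pr$log_lik, pr$box,
                   tmcmc_control(n_samples = 2000, seed = 3),
                   sample_prior = pr$sample_prior)
  expect_lt(abs(mpv(fit)[["x"]] - pr$post_mean), 3 * pr$post_sd)
})

test_that("posterior quantiles use linear interpolation and stay ordered", {
  ens <- structure(list(samples = matrix(rep(2.5, 10), ncol = 1,
                                         dimnames = list(NULL, "x"))),
                   class = "lj_ensemble")
  q <- posterior_quantiles(ens, c(0.05, 0.5, 0.95))
  expect_equal(unname(q[1, ]), c(2.5, 2.5, 2.5))

  ens$samples <- matrix(1:100, ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(unname(posterior_quantiles(ens, 0.5)[1, 1]), 50.5)
  q2 <- posterior_quantiles(ens, c(0.05, 0.95))
  expect_lt(q2[1, 1], q2[1, 2])
  expect_error(posterior_quantiles(ens, c(0, 0.5)))
})

test_that("identical seed and config give bit-identical ensembles", {
  pr <- conjugate_problem(lik_sd = 0.5)
  cfg <- tmcmc_control(n_samples = 300, seed = 77)
  f1 <- run_tmcmc(pr$log_prior, pr$log_lik, pr$box, cfg,
                  sample_prior = pr$sample_prior)
  f2 <- run_tmcmc(pr$log_prior, pr$log_lik, pr$box, cfg,
                  sample_prior = pr$sample_prior)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$log_evidence, f2$log_evidence)
  expect_identical(f1$stage_exponents, f2$stage_exponents)
})

test_that("shrinking a uniform prior around the mode shifts evidence by ln(volume ratio)", {
  ll <- function(th) dnorm(0, th[["x"]], 0.3, log = TRUE)
  ev <- function(halfw, seed) {
    box <- sampling_box(c(x = -halfw), c(x = halfw))
    run_tmcmc(function(th) -log(2 * halfw), ll, box,
              tmcmc_control(n_samples = 2000, seed = seed))$log_evidence
  }
  d <- mean(vapply(1:3, function(s) ev(2, s) - ev(8, s + 10), 1))
  expect_equal(d, log(16 / 4), tolerance = 0.1)
})

test_that("degenerate likelihoods and stage exhaustion raise typed errors", {
  box <- sampling_box(c(x = 0), c(x = 1))
  expect_error(run_tmcmc(function(th) 0, function(th) -Inf, box,
                         tmcmc_control(n_samples = 200, seed = 1)),
               class = "ljbayes_degenerate_likelihood")
  err <- tryCatch(
    run_tmcmc(function(th) 0,
              function(th) dnorm(0.5, th[["x"]], 1e-4, log = TRUE), box,
              tmcmc_control(n_samples = 200, max_stages = 1, seed = 1)),
    error = function(e) e)
  expect_s3_class(err, "ljbayes_nonconvergence")
  expect_true(is.list(err$data) && nrow(err$data$samples) == 200)
})

test_that("ensemble invariants hold on a calibration run", {
  d <- small_dimer(seed = 3, noise = 0.05)
  fit <- lj_calibrate(d, "lj6-12", control = fast_control(seed = 9))
  ens <- fit$ensemble
  expect_equal(ens$stage_exponents[1], 0)
  expect_equal(ens$stage_exponents[length(ens$stage_exponents)], 1)
  expect_true(all(diff(ens$stage_exponents) > 0))
  expect_true(is.finite(ens$log_evidence))
  inside <- rep(TRUE, nrow(ens$samples))
  for (nm in fit$prior$names)
    inside <- inside & ens$samples[, nm] >= fit$prior$lower[[nm]] &
      ens$samples[, nm] <= fit$prior$upper[[nm]]
  expect_true(all(inside))
})
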