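fake_ensemble <- function(samples, log_evidence = 0) {
  structure(list(samples = samples,
                 log_liks = rep(0, nrow(samples)),
                 log_priors = rep(0, nrow(samples)),
                 log_evidence = log_evidence,
                 stage_exponents = c(0, 1), seed = 1, config = NULL),
            class = "lj_ensemble")
}

sample_box_matrix <- function(n, base, seed) {
  set.seed(seed)
  m <- vapply(base$names, function(nm)
    runif(n, base$lower[[nm]], base$upper[[nm]]), numeric(n))
  colnames(m) <- base$names
  m
}

test_that("uniform family at the base box makes the hyper-likelihood the evidence sum", {
  base <- lj_prior("lj6-12")
  fam <- prior_family("uniform", base)
  mid <- (base$lower + base$upper)[fam$tied] / 2
  w <- (base$upper - base$lower)[fam$tied]
  psi <- c(mid, w)
  e1 <- fake_ensemble(sample_box_matrix(50, base, 1), log_evidence = -3.2)
  e2 <- fake_ensemble(sample_box_matrix(70, base, 2), log_evidence = 5.9)
  expect_equal(hyper_log_likelihood(psi, list(e1, e2), fam), -3.2 + 5.9,
               tolerance = 1e-12)
})

test_that("hyper-likelihood prefers psi centred on the sample cloud", {
  base <- lj_prior("lj6-12")
  fam <- prior_family("truncnorm", base)
  set.seed(8)
  cloud <- cbind(epsilon = rnorm(200, 0.9, 0.03),
                 sigma = rnorm(200, 3.4, 0.02),
                 sigma_n = runif(200, 0.05, 0.1))
  ens <- fake_ensemble(cloud, log_evidence = 2)
  centred <- hyper_log_likelihood(c(0.9, 3.4, 0.1, 0.1), list(ens), fam)
  displaced <- hyper_log_likelihood(c(2.8, 3.95, 0.1, 0.1), list(ens), fam)
  expect_gt(centred, displaced)
})

test_that("hyper-likelihood matches a two-point hand computation", {
  base <- lj_prior("lj6-12")
  fam <- prior_family("truncnorm", base)
  th <- rbind(c(epsilon = 0.5, sigma = 3.2, sigma_n = 0.3),
              c(epsilon = 1.5, sigma = 3.8, sigma_n = 0.7))
  ens <- fake_ensemble(th, log_evidence = 1.25)
  psi <- c(1.0, 3.5, 0.4, 0.25)
  # hand computation of the importance-sampling formula
  tn <- function(x, m, s, a, b)
    dnorm(x, m, s) / (pnorm(b, m, s) - pnorm(a, m, s))
  num <- function(i)
    tn(th[i, 1], psi[1], psi[3], 0.05, 3) * tn(th[i, 2], psi[2], psi[4], 3, 4) *
      (1 / (1 - 1e-6))
  den <- 1 / (2.95 * 1 * (1 - 1e-6))
  by_hand <- 1.25 + log(mean(c(num(1), num(2)) / den))
  expect_equal(hyper_log_likelihood(psi, list(ens), fam), by_hand,
               tolerance = 1e-12)
})

test_that("refresh under the base-box uniform psi keeps all weights equal", {
  base <- lj_prior("lj6-12")
  fam <- prior_family("uniform", base)
  mid <- (base$lower + base$upper)[fam$tied] / 2
  w <- (base$upper - base$lower)[fam$tied]
  psi_mat <- rbind(c(mid, w), c(mid, w))
  ens <- fake_ensemble(sample_box_matrix(300, base, 5))
  set.seed(1)
  ref <- hb_refresh(ens, psi_mat, fam)
  expect_equal(ref$weights, rep(1 / 300, 300), tolerance = 1e-12)
  expect_equal(ref$ess, 300, tolerance = 1e-9)
  # equal weights: the refresh is a plain bootstrap of the stage-1 ensemble
  expect_true(all(ref$samples[, "epsilon"] %in% ens$samples[, "epsilon"]))
})

test_that("hierarchical run ties identical datasets together symmetrically", {
  sp <- argon_presets()$Q
  # well-identified 3-parameter setting so run-to-run sampler noise is
  # small against the posterior spread
  sp$truth <- c(epsilon = 0.252, sigma = 3.370, sigma_n = 0.05)
  sp$noise <- 0.05
  d1 <- generate(sp)   # byte-identical pair
  d2 <- generate(sp)
  hb <- lj_hb(list(d1, d2), "lj6-12", "truncnorm",
              control = hb_control(stage1 = tmcmc_control(n_samples = 800),
                                   n_hyper = 300, n_psi = 50, n_theta = 300),
              seed = 3)
  m1 <- colMeans(hb$refreshed[[1]]$samples)
  m2 <- colMeans(hb$refreshed[[2]]$samples)
  for (nm in c("epsilon", "sigma")) {
    # identical data: refreshed means agree to within half the average
    # posterior spread (the two runs differ only by Monte-Carlo error)
    spread <- mean(c(diff(posterior_quantiles(hb$refreshed[[1]])[nm, ]),
                     diff(posterior_quantiles(hb$refreshed[[2]])[nm, ])))
    expect_lt(abs(m1[nm] - m2[nm]), 0.5 * spread)
  }
  # refreshed MPVs stay inside the base box
  for (r in hb$refreshed) {
    th <- mpv(r)
    expect_true(all(th >= hb$family$base$lower & th <= hb$family$base$upper))
  }
  expect_s3_class(summary(hb), "summary.lj_hbfit")
})

test_that("disjoint psi support yields -Inf with a warning", {
  base <- lj_prior("lj6-12")
  fam <- prior_family("uniform", base)
  cloud <- cbind(epsilon = runif(40, 0.1, 0.2), sigma = runif(40, 3.0, 3.1),
                 sigma_n = runif(40, 0.1, 0.2))
  ens <- fake_ensemble(cloud)
  # sub-box far from the cloud
  psi <- c(2.9, 3.95, 0.02, 0.02)
  expect_warning(v <- hyper_log_likelihood(psi, list(ens), fam), "disjoint")
  expect_identical(v, -Inf)
})
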