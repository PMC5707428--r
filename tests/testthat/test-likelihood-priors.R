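test_that("Gaussian log-likelihood matches direct formula evaluation", {
  # ln term cancels exactly when sigma_n = 1/sqrt(2 pi) and SSE = 0
  expect_equal(log_likelihood(1.7, 1.7, 1 / sqrt(2 * pi)), 0, tolerance = 1e-14)
  expect_equal(log_likelihood(1, 0, 1), -0.5 * log(2 * pi) - 0.5,
               tolerance = 1e-14)
  expect_equal(log_likelihood(c(1, 2), c(0, 0), 1), -log(2 * pi) - 2.5,
               tolerance = 1e-14)
  expect_error(log_likelihood(c(1, 2), 1, 0.1), "mismatch")
  expect_error(log_likelihood(1, 1, 0), "sigma_n")
  expect_error(log_likelihood(c(1, NA), c(1, 1), 1), "finite")
})

test_that("likelihood is maximized over sigma_n at the closed-form MLE", {
  set.seed(4)
  d <- rnorm(25); f <- rnorm(25)
  sn_star <- sqrt(mean((d - f)^2))
  o <- optimize(function(s) log_likelihood(d, f, s), c(1e-4, 10), maximum = TRUE)
  expect_equal(o$maximum, sn_star, tolerance = 1e-4)
})

test_that("uniform box prior is flat inside and impossible outside", {
  spec <- lj_prior("lj6-12")
  th1 <- c(epsilon = 0.3, sigma = 3.4, sigma_n = 0.05)
  th2 <- c(epsilon = 2.4, sigma = 3.9, sigma_n = 0.9)
  v <- -log(2.95) - log(1) - log(1 - 1e-6)
  expect_equal(log_prior_uniform(th1, spec), v, tolerance = 1e-12)
  expect_identical(log_prior_uniform(th1, spec), log_prior_uniform(th2, spec))
  expect_identical(log_prior_uniform(c(epsilon = 0.3, sigma = 4.5, sigma_n = 0.05),
                                     spec), -Inf)
})

test_that("default prior boxes carry the calibration bounds", {
  p12 <- lj_prior("lj6-12")
  expect_equal(unname(p12$lower), c(0.05, 3, 1e-6))
  expect_equal(unname(p12$upper), c(3, 4, 1))
  p6p <- lj_prior("lj6-p")
  expect_equal(unname(p6p$lower), c(0.05, 3, 6.01, 1e-6))
  expect_equal(unname(p6p$upper), c(10, 4, 15, 1))
  expect_error(prior_spec(c(epsilon = 1), c(epsilon = 0.5)), "lower < upper")
  expect_error(prior_spec(c(p = 5), c(p = 15)), "> 6")
})

test_that("uniform conditional family at the base box reduces to the base prior", {
  base <- lj_prior("lj6-p")
  fam <- prior_family("uniform", base)
  mid <- (base$lower + base$upper)[fam$tied] / 2
  w <- (base$upper - base$lower)[fam$tied]
  psi <- c(mid, w)  # half-width = full width clips back to the box
  set.seed(9)
  th <- cbind(epsilon = runif(5, 0.05, 10), sigma = runif(5, 3, 4),
              p = runif(5, 6.01, 15), sigma_n = runif(5, 1e-6, 1))
  expect_equal(conditional_log_prior(th, psi, fam),
               log_prior_uniform(th, base), tolerance = 1e-12)
})

test_that("wide truncated normals approach the uniform density", {
  base <- lj_prior("lj6-12")
  fam <- prior_family("truncnorm", base)
  mid <- (base$lower + base$upper)[fam$tied] / 2
  w <- (base$upper - base$lower)[fam$tied]
  psi <- c(mid, 1e3 * w)
  th <- c(epsilon = 1.2, sigma = 3.7, sigma_n = 0.4)
  expect_equal(conditional_log_prior(th, psi, fam),
               log_prior_uniform(th, base), tolerance = 0.01)
})

test_that("truncated normal density peaks at its location", {
  base <- lj_prior("lj6-12")
  fam <- prior_family("truncnorm", base)
  psi <- c(0.8, 3.5, 0.2, 0.1)  # loc_eps, loc_sigma, scale_eps, scale_sigma
  at_mode <- conditional_log_prior(c(epsilon = 0.8, sigma = 3.5, sigma_n = 0.5),
                                   psi, fam)
  set.seed(2)
  for (k in 1:20) {
    th <- c(epsilon = runif(1, 0.05, 3), sigma = runif(1, 3, 4), sigma_n = 0.5)
    expect_lte(conditional_log_prior(th, psi, fam), at_mode + 1e-12)
  }
  expect_error(conditional_log_prior(c(epsilon = 1, sigma = 3.5, sigma_n = 0.5),
                                     c(0.8, 3.5, -0.1, 0.1), fam),
               "inadmissible")
})

test_that("every conditional family integrates to one over the box", {
  # the joint factorizes as f(e, s, sn) = fe(e) fs(s) / w_sn, so the total
  # mass can be assembled from two 1-D quadratures and one density value:
  # (int fe)(int fs)(int 1/w_sn) = Ie * Is / f(ref) * w_sn with Ie, Is the
  # 1-D integrals of the joint along each tied coordinate at the reference.
  base <- lj_prior("lj6-12")
  for (family in c("truncnorm", "uniform")) {
    fam <- prior_family(family, base)
    for (psi in list(c(0.3, 3.2, 0.05, 0.4), c(2.9, 3.99, 2.0, 0.9))) {
      ref <- c(epsilon = psi[1], sigma = psi[2], sigma_n = 0.5)
      lims <- function(nm, j) {
        a <- base$lower[[nm]]; b <- base$upper[[nm]]
        if (family == "uniform")  # density vanishes outside the sub-box
          c(max(a, psi[j] - psi[j + 2]), min(b, psi[j] + psi[j + 2]))
        else c(a, b)
      }
      joint_along <- function(nm, x) vapply(x, function(xi) {
        th <- ref; th[nm] <- xi
        exp(conditional_log_prior(th, psi, fam))
      }, 1)
      le <- lims("epsilon", 1); ls <- lims("sigma", 2)
      Ie <- integrate(function(x) joint_along("epsilon", x), le[1], le[2],
                      rel.tol = 1e-10, subdivisions = 500L)$value
      Is <- integrate(function(x) joint_along("sigma", x), ls[1], ls[2],
                      rel.tol = 1e-10, subdivisions = 500L)$value
      at_ref <- exp(conditional_log_prior(ref, psi, fam))
      w_sn <- base$upper[["sigma_n"]] - base$lower[["sigma_n"]]
      expect_equal(Ie * Is / at_ref * w_sn, 1, tolerance = 1e-6)
    }
  }
})
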