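test_that("dimer model is the untruncated potential on the grid", {
  pars <- lj_params(0.5, 3.1, 12)
  expect_equal(dimer_energy_model(pars, 3.1), 0)
  expect_equal(dimer_energy_model(pars, 2^(1 / 6) * 3.1), -0.5,
               tolerance = 1e-12)
  # independent hand evaluation at the gas-phase posterior point
  pars_q <- lj_params(0.252, 3.370, 12.703)
  sr <- 3.370 / 4.0
  expect_equal(dimer_energy_model(pars_q, 4.0),
               4 * 0.252 * (sr^12.703 - sr^6), tolerance = 1e-14)
  # beyond 3 sigma the dimer model stays nonzero (no truncation)
  expect_true(dimer_energy_model(pars, 3.2 * 3.1) != 0)
})

test_that("dilute-gas RDF has the closed-form fixed points", {
  pars <- lj_params(0.3, 3.4, 12)
  cond <- lj_condition("t", temperature = 120)
  expect_equal(dilute_rdf_model(pars, cond, 3.4), 1)
  expect_equal(dilute_rdf_model(pars, cond, c(10.3, 12)), c(1, 1))
  # kB T = epsilon at the well bottom gives g = e
  Te <- 0.3 / ljbayes::kB
  g <- dilute_rdf_model(pars, lj_condition("t", Te), 2^(1 / 6) * 3.4)
  expect_equal(g, exp(1), tolerance = 1e-12)
  expect_error(dilute_rdf_model(pars, lj_condition("no_T"), 3), "temperature")
})

test_that("RDF is positive, clipped under deep wells, and peak grows with epsilon", {
  cond <- lj_condition("t", temperature = 100)
  r <- seq(2.6, 12, length.out = 100)
  g <- dilute_rdf_model(lj_params(9, 3.4, 6.2), cond, r)
  expect_true(all(g > 0) && all(is.finite(g)))
  peaks <- vapply(c(0.1, 0.3, 0.6, 1.2, 2.5),
                  function(e) max(dilute_rdf_model(lj_params(e, 3.4, 12), cond, r)),
                  1)
  expect_true(all(diff(peaks) > 0))
  # purity: repeated evaluation is bit-identical
  expect_identical(g, dilute_rdf_model(lj_params(9, 3.4, 6.2), cond, r))
})

test_that("batched curves agree with the scalar models", {
  set.seed(31)
  r <- seq(2.6, 11, length.out = 40)
  cond <- lj_condition("t", temperature = 130)
  theta <- cbind(epsilon = runif(20, 0.1, 5), sigma = runif(20, 3, 4),
                 p = runif(20, 6.1, 15), sigma_n = runif(20, 0.01, 1))
  fm_d <- builtin_forward_model("dimer_energy")
  fm_r <- builtin_forward_model("rdf")
  Bd <- fm_d$evaluate_batch(theta, cond, r)
  Br <- fm_r$evaluate_batch(theta, cond, r)
  for (i in c(1, 7, 20)) {
    pars <- lj_params(theta[i, 1], theta[i, 2], theta[i, 3])
    expect_equal(Bd[i, ], dimer_energy_model(pars, r), tolerance = 1e-10)
    expect_equal(Br[i, ], dilute_rdf_model(pars, cond, r), tolerance = 1e-10)
  }
  # 6-12 layout (no p column) fixes the exponent at 12
  th12 <- theta[, c("epsilon", "sigma", "sigma_n")]
  B12 <- fm_d$evaluate_batch(th12, cond, r)
  expect_equal(B12[3, ], dimer_energy_model(lj_params(theta[3, 1], theta[3, 2], 12), r),
               tolerance = 1e-10)
})

test_that("dataset container validates its grid", {
  expect_error(lj_dataset("rdf", c(3, 2), c(1, 1), lj_condition("x", 100)),
               "increasing")
  expect_error(lj_dataset("rdf", 3, 1, lj_condition("x", 100)), "length")
  expect_error(lj_dataset("rdf", c(3, 4), c(1, NA), lj_condition("x", 100)),
               "finite")
  d <- lj_dataset("dimer_energy", c(3, 4, 5), c(0.1, -0.2, -0.1))
  expect_s3_class(d, "lj_dataset")
})

test_that("external engine adapter round-trips a mock engine and flags bad output", {
  skip_on_os(c("windows"))
  mock <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh",
               "echo '# mock rdf'",
               "echo '3.0 1.00'", "echo '3.5 1.25'", "echo '4.0 1.10'"), mock)
  Sys.chmod(mock, "0755")
  fm <- register_external_engine(paste(mock, "{epsilon} {sigma} {p} {T}"))
  out <- eval_forward_model(fm, lj_params(1, 3.4, 12),
                            lj_condition("t", 100), c(3, 3.5, 4))
  expect_equal(out, c(1.00, 1.25, 1.10))
  expect_equal(fm$protocol$atoms, 666)
  # wrong grid length is an engine error naming the sizes
  expect_error(eval_forward_model(fm, lj_params(1, 3.4, 12),
                                  lj_condition("t", 100), c(3, 4)),
               "3 rows for a 2-point grid")
  expect_error(register_external_engine("no-such-engine-binary --x"),
               "not found")
})

test_that("engine output parser rejects malformed tables", {
  expect_error(parse_engine_table(character(0)), "no data rows")
  expect_error(parse_engine_table(c("1.0 2.0", "oops 3.0")), "not numeric")
  expect_error(parse_engine_table(c("1.0", "2.0")), "fewer than 2 columns")
  tab <- parse_engine_table(c("# c", "1 2", "", "3 4  # trailing"))
  expect_equal(tab, rbind(c(1, 2), c(3, 4)))
})
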