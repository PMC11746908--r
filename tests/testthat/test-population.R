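# population layer: covariate model, IIV sampling, residual error

test_that("individual parameters follow theta * (cov/ref)^beta * exp(eta)", {
  m <- kpd_reference_model()
  # identity at the covariate reference with eta = 0
  p0 <- individual_params(m, c(IGA = 1.15))
  expect_equal(as.numeric(p0), as.numeric(m$typical), tolerance = 1e-12)
  # doubling IgA scales ED50 by 2^1.39
  p2 <- individual_params(m, c(IGA = 2.30))
  expect_equal(p2[["ed50"]], 1.31 * 2^1.39, tolerance = 1e-12)
  expect_equal(p2[["ke"]], 0.049, tolerance = 1e-12)
  # eta_ke = ln 2 doubles Ke
  pk <- individual_params(m, c(IGA = 1.15), eta = c(ke = log(2)))
  expect_equal(pk[["ke"]], 0.098, tolerance = 1e-12)
  # missing covariate raises a named error
  expect_error(individual_params(m, c(BSA = 0.8)), "IGA",
               class = "kpd_missing_covariate")
  # beta = 0 is a no-op at any covariate value
  m0 <- m
  m0$covariates[[1]]$beta <- 0
  expect_equal(as.numeric(individual_params(m0, c(IGA = 3.7))),
               as.numeric(m0$typical), tolerance = 1e-12)
})

test_that("population sampling is reproducible and matches its moments", {
  m <- kpd_reference_model()
  # omega = 0 everywhere: all individuals identical to the typicals
  m0 <- kpd_model(m$typical, omega = NULL, residual = m$residual)
  s0 <- sample_individuals(m0, 25, seed = 7)
  expect_equal(as.numeric(s0$params),
               rep(as.numeric(m$typical), each = 25), tolerance = 1e-12)
  # same seed, same draws
  a <- sample_individuals(m, 50, covariate_sampler = c(IGA = 1.15), seed = 11)
  b <- sample_individuals(m, 50, covariate_sampler = c(IGA = 1.15), seed = 11)
  expect_identical(a$etas, b$etas)
  # large-sample SD of log Kin approaches omega_kin
  big <- sample_individuals(m, 1e5, covariate_sampler = c(IGA = 1.15),
                            seed = 3)
  expect_equal(sd(log(big$params[, "kin"])), 0.378, tolerance = 0.005)
  # log-normal median property: median of sampled ED50 -> typical * (cov/ref)^beta
  big2 <- sample_individuals(m, 1e5, covariate_sampler = c(IGA = 2.0),
                             seed = 4)
  expect_equal(median(big2$params[, "ed50"]), 1.31 * (2 / 1.15)^1.39,
               tolerance = 0.03)
})

test_that("residual error model composes and has the stated variance", {
  r <- residual_error("combined", sd_add = 2.56, sd_prop = 0.40)
  expect_identical(apply_residual(100, r, 0, 0), 100)
  expect_equal(apply_residual(100, r, 0.1, 2), 112)
  # additive/proportional kinds zero out the other component
  expect_equal(apply_residual(100, residual_error("additive", sd_add = 1),
                              eps_prop = 0.5, eps_add = 2), 102)
  expect_equal(apply_residual(100, residual_error("proportional",
                                                  sd_prop = 0.1),
                              eps_prop = 0.1, eps_add = 5), 110)
  # simulated variance at f matches f^2 sd_prop^2 + sd_add^2
  set.seed(99)
  f <- 100
  y <- apply_residual(f, r, rnorm(2e5, 0, r$sd_prop), rnorm(2e5, 0, r$sd_add))
  expect_equal(var(y), f^2 * 0.16 + 2.56^2, tolerance = 0.02 * (f^2 * 0.16))
  # negative outcomes are legal at this layer
  expect_lt(apply_residual(1, r, -0.5, -3), 0)
  # invalid specifications are rejected
  expect_error(residual_error("combined", sd_add = 0, sd_prop = 0.4),
               "combined")
})
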