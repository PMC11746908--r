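# model qualification: VPC, bootstrap, GOF tables

test_that("VPC is deterministic, validates bins, and is self-calibrated", {
  co <- generate_cohort(cohort_config(n_subjects = 30, seed = 9))
  m <- kpd_reference_model()
  # observed side simulated by the model itself (unclamped residuals)
  f0 <- kpd_fit(co$data, m, control = fast_control(), optimize = FALSE)
  dat <- simulate(f0, nsim = 1, seed = 90)[[1]]
  v1 <- kpd_vpc(dat, m, n_sim = 200, bins = 6, seed = 42)
  v2 <- kpd_vpc(dat, m, n_sim = 200, bins = 6, seed = 42)
  expect_identical(v1$observed, v2$observed)
  expect_identical(v1$band_lo, v2$band_lo)
  # ordered percentiles and ordered bands
  expect_true(all(v1$observed[, 1] <= v1$observed[, 2]))
  expect_true(all(v1$observed[, 2] <= v1$observed[, 3]))
  expect_true(all(v1$band_lo <= v1$band_hi))
  # self-VPC: data were generated from this model, so the observed median
  # should sit inside its simulated band in most bins
  inside <- v1$observed[, 2] >= v1$band_lo[, 2] &
    v1$observed[, 2] <= v1$band_hi[, 2]
  expect_gte(mean(inside), 0.8)
  # degenerate bin specification errors out with the offending interval
  expect_error(kpd_vpc(dat, m, n_sim = 100,
                       bins = c(0, 1000, 2000), seed = 1),
               "empty", class = "kpd_bin_error")
  expect_error(kpd_vpc(dat, m, n_sim = 50), "n_sim")
})

test_that("bootstrap keeps the resampling contract and is consistent", {
  # compact, well-specified scenario so 50 refits stay affordable
  truth <- kpd_model(ref_params(), omega = c(kin = 0.3),
                     residual = residual_error("combined", sd_add = 2.5,
                                               sd_prop = 0.2))
  co <- generate_cohort(cohort_config(n_subjects = 10, truth = truth,
                                      obs_interval = 40, seed = 77))
  fixed <- c("ke", "emax", "ed50", "gamma")
  fit <- kpd_fit(co$data, init = truth, fixed = fixed,
                 control = fast_control())
  bs <- kpd_bootstrap(co$data, fit$model, n_resample = 50, seed = 5,
                      fixed = fixed, control = fast_control(maxit = 60))
  # resample index sets: right shape, deterministic under the seed
  expect_identical(dim(bs$idx), c(10L, 50L))
  bs2_idx <- with_seed_idx <- kpd_bootstrap(co$data, fit$model,
                                            n_resample = 50, seed = 5,
                                            fixed = fixed,
                                            control = fast_control(
                                              maxit = 2))$idx
  expect_identical(bs$idx, bs2_idx)
  expect_lte(bs$n_converged, 50L)
  # medians near the point estimates for a well-specified model
  est <- coef(fit)
  for (p in c("kin", "kout")) {
    expect_lt(abs(bs$summary$median[bs$summary$parameter == p] - est[[p]]) /
                est[[p]], 0.15)
  }
  # median inside its own percentile interval
  expect_true(all(bs$summary$median >= bs$summary$lo95 &
                    bs$summary$median <= bs$summary$hi95))
  expect_error(kpd_bootstrap(co$data, fit$model, n_resample = 10), "50")
})

test_that("GOF tables line up with predictions and CWRES", {
  co <- generate_cohort(cohort_config(n_subjects = 12, seed = 19))
  fit <- kpd_fit(co$data, init = kpd_reference_model(),
                 control = fast_control(), optimize = FALSE)
  g <- gof_table(fit)
  expect_identical(nrow(g), sum(co$data$EVID == 0 & co$data$MDV == 0))
  expect_named(g, c("id", "time", "tad", "dv", "pred", "ipred", "cwres"))
  # cross-module equality with the estimation-side CWRES
  expect_equal(g$cwres, unname(cwres(fit)), tolerance = 1e-12)
  # tad is time since the most recent dose
  expect_true(all(g$tad[g$time > 7] <= g$time[g$time > 7] - 7 + 1e-9))
  # residuals() methods agree with the table
  expect_equal(unname(residuals(fit, type = "raw")), g$dv - g$ipred,
               tolerance = 1e-12)
  # predict() with type pred reproduces the table's population column
  pr <- predict(fit, type = "pred")
  expect_equal(pr$pred, g$pred, tolerance = 1e-12)
  # simulate() returns datasets in the input layout
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_identical(dim(sims[[1]]), dim(co$data))
  expect_false(identical(sims[[1]]$DV, co$data$DV))
})
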