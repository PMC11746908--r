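# regimen construction and Monte Carlo repletion exploration

test_that("textual dosing schedules parse to the right event tables", {
  r1 <- build_regimen("375 mg/m2 x2 weekly", bsa = 0.82)
  expect_equal(r1$time, c(0, 7))
  expect_equal(r1$amount, rep(307.5, 2), tolerance = 1e-12)
  r2 <- build_regimen("three 150 mg every 2 monthly")
  expect_equal(r2$time, c(0, 60, 120))
  expect_equal(r2$amount, rep(150, 3))
  r3 <- build_regimen("750 mg/m2 x1", bsa = 0.82, cap = 500)
  expect_equal(r3$amount, 500) # per-infusion cap
  r4 <- build_regimen("six monthly 100 mg")
  expect_equal(r4$time, (0:5) * 30)
  expect_error(build_regimen("banana split"), "parse",
               class = "kpd_spec_error")
  expect_error(build_regimen("375 mg/m2 x2 weekly"), "bsa",
               class = "kpd_spec_error")
  regs <- reference_regimens(bsa = 0.82)
  expect_length(regs, 10L)
  expect_equal(regs[["750 mg/m2 x1"]]$amount, 615)
})

test_that("regimen simulation collapses without IIV and orders with dose", {
  m <- kpd_reference_model()
  m0 <- kpd_model(m$typical, omega = NULL, covariates = m$covariates,
                  residual = m$residual)
  s0 <- simulate_regimen(m0, build_regimen("375 mg/m2 x2 weekly",
                                           bsa = 0.82), n = 100, seed = 1)
  expect_lt(s0$p95 - s0$p5, 0.05) # all individuals identical
  # typical-individual oracle for the same regimen
  rt_typ <- repletion_time(simulate_kpd(m$typical, std_doses(),
                                        times = seq(0, 300, 0.25)))
  expect_equal(s0$median, rt_typ, tolerance = 0.05)
  # larger single dose -> strictly later repletion
  s1 <- simulate_regimen(m0, regimen(0, 307.5), n = 100, seed = 2)
  s2 <- simulate_regimen(m0, regimen(0, 615), n = 100, seed = 2)
  expect_gt(s2$median, s1$median)
})

test_that("the regimen table is reproducible and covers its regimens", {
  m <- kpd_reference_model()
  expect_identical(nrow(regimen_table(list(), m)), 0L)
  regs <- list(build_regimen("100 mg x1"),
               build_regimen("375 mg/m2 x2 weekly", bsa = 0.82))
  t1 <- regimen_table(regs, m, n = 150, seed = 4)
  t2 <- regimen_table(regs, m, n = 150, seed = 4)
  expect_identical(t1, t2)
  expect_lt(t1$median[1], t1$median[2]) # 100 mg repletes before 375x2
  expect_true(all(t1$p5 <= t1$median & t1$median <= t1$p95))
})

test_that("IgA sweep orders the recovery curves as the covariate sign implies", {
  m <- kpd_reference_model()
  reg <- build_regimen("375 mg/m2 x2 weekly", bsa = 0.82)
  sw <- covariate_sweep(m, reg, values = c(0.11, 1.15, 2.26),
                        times = seq(0, 420, 0.25))
  # higher IgA -> larger ED50 -> weaker late stimulation -> earlier repletion
  expect_true(all(diff(sw$summary$repletion) < 0))
  # the reference value reproduces the typical trajectory exactly
  tr_ref <- simulate_kpd(m$typical, reg, times = seq(0, 420, 0.25))
  expect_equal(sw$trajectories[[2]]$bcell, tr_ref$bcell, tolerance = 1e-9)
  # with beta = 0 all curves coincide
  m0 <- m
  m0$covariates[[1]]$beta <- 0
  sw0 <- covariate_sweep(m0, reg, values = c(0.11, 1.15, 2.26),
                         times = seq(0, 200, 1))
  expect_equal(sw0$trajectories[[1]]$bcell, sw0$trajectories[[3]]$bcell,
               tolerance = 1e-12)
})

test_that("depletion-fraction curves behave at their limits", {
  m <- kpd_reference_model()
  reg <- build_regimen("three 100 mg every 2 monthly")
  ct <- population_trajectories(m, reg, n = 150,
                                times = seq(0, 400, 1), seed = 6)
  fr <- depletion_fraction(ct, threshold = 10)
  expect_equal(fr$fraction[fr$time == 0], 0) # pre-dose: nobody depleted
  # right after a large first dose essentially everyone is depleted
  big <- population_trajectories(m, build_regimen("375 mg/m2 x2 weekly",
                                                  bsa = 0.82),
                                 n = 150, times = seq(0, 10, 1), seed = 6)
  frb <- depletion_fraction(big, threshold = 10)
  # most individuals crash within days; the slow tail (low kout x emax
  # draws) needs about a week
  expect_gt(frb$fraction[frb$time == 3], 0.8)
  expect_gt(frb$fraction[frb$time == 7], 0.93)
  # single-crossing: non-increasing once recovery is underway
  post <- fr[fr$time >= 120, ]
  peak <- which.max(post$fraction)
  expect_true(all(diff(post$fraction[peak:nrow(post)]) <= 1e-12))
})

test_that("regimen medians are Monte Carlo stable across seeds", {
  m <- kpd_reference_model()
  reg <- build_regimen("375 mg/m2 x2 weekly", bsa = 0.82)
  a <- simulate_regimen(m, reg, n = 400, seed = 11)
  b <- simulate_regimen(m, reg, n = 400, seed = 12)
  expect_lt(abs(a$median - b$median), 5)
})
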