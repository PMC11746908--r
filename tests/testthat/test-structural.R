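# structural model: depot kinetics, Hill stimulation, trajectory
# integration, repletion-time extraction

test_that("depot superposition is exact against the analytic and ODE oracles", {
  p <- ref_params()
  # empty superposition
  expect_identical(depot_amount(NULL, ke = 0.049, t = c(0, 10)), c(0, 0))
  # one half-life halves a single bolus
  expect_equal(depot_amount(data.frame(time = 0, amount = 100), 0.049,
                            log(2) / 0.049), 50, tolerance = 1e-12)
  # two weekly doses just after the second dose
  got <- depot_amount(std_doses(), 0.049, 7)
  expect_equal(got, 307.5 * exp(-0.049 * 7) + 307.5, tolerance = 1e-12)
  # random dose sets vs numerical integration of dA1/dt with bolus events
  set.seed(42)
  for (rep in 1:5) {
    nd <- sample(1:5, 1)
    doses <- data.frame(time = sort(runif(nd, 0, 60)),
                        amount = runif(nd, 50, 500))
    ke <- runif(1, 0.01, 0.2)
    tt <- sort(runif(8, 0, 120))
    ev <- data.frame(var = "A1", time = doses$time, value = doses$amount,
                     method = "add")
    out <- deSolve::ode(c(A1 = 0), sort(unique(c(0, doses$time, tt))),
                        function(t, y, p) list(-ke * y), NULL,
                        events = list(data = ev), rtol = 1e-11, atol = 1e-11)
    ref <- out[match(tt, out[, "time"]), "A1"]
    expect_equal(depot_amount(doses, ke, tt), unname(ref),
                 tolerance = 1e-6)
  }
  expect_error(depot_amount(std_doses(), -0.1, 1), "positive")
  expect_error(depot_amount(std_doses(), 0.049, -1), "non-negative")
})

test_that("Hill stimulation has the exact sigmoid-Emax form", {
  expect_identical(hill_stimulation(0, 389.7, 1.31, 6.65), 0)
  expect_equal(hill_stimulation(1.31, 389.7, 1.31, 6.65), 389.7 / 2,
               tolerance = 1e-12)
  expect_equal(hill_stimulation(2 * 1.31, 389.7, 1.31, 6.65),
               389.7 * 2^6.65 / (2^6.65 + 1), tolerance = 1e-12)
  # monotone non-decreasing and bounded by emax
  a <- c(0, 10^seq(-3, 4, length.out = 40))
  s <- hill_stimulation(a, 389.7, 1.31, 6.65)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0 & s <= 389.7))
  # strictly below emax wherever the ratio is resolvable in double precision
  expect_true(all(hill_stimulation(c(1, 10, 100), 389.7, 1.31, 6.65) <
                    389.7))
})

test_that("trajectories match the stiff ODE oracle and preserve equilibrium", {
  p <- ref_params()
  # no doses: flat at baseline
  tr0 <- simulate_kpd(p, NULL, times = seq(0, 100, 5))
  expect_equal(tr0$bcell, rep(kpd_baseline(p), length(tr0$time)),
               tolerance = 1e-8)
  # standard course vs lsoda
  tt <- seq(0, 300, 2.5)
  tr <- simulate_kpd(p, std_doses(), times = tt)
  ref <- lsoda_oracle(p, std_doses(), tt)
  expect_equal(tr$bcell, unname(ref), tolerance = 1e-6)
  # depletion below 10 cells/uL within two days of a 307.5 mg dose
  tr1 <- simulate_kpd(p, data.frame(time = 0, amount = 307.5),
                      times = seq(0, 10, 0.25))
  expect_lt(tr1$bcell[tr1$time == 2], 10)
  # upward crossing of 10 between day 115 and 145 for the standard course
  rt <- repletion_time(simulate_kpd(p, std_doses(), times = seq(0, 300, 0.25)))
  expect_gt(rt, 115)
  expect_lt(rt, 145)
})

test_that("stimulation disabled or saturated gives the analytic limits", {
  p0 <- kpd_params(0.049, 4.14, 0.007, 1e-12, 1.31, 6.65) # emax ~ 0
  tr <- simulate_kpd(p0, std_doses(), times = seq(0, 200, 1))
  expect_equal(tr$bcell, rep(kpd_baseline(p0), 201), tolerance = 1e-6)
  # a huge depot clamps the Hill term at emax: E -> kin/(kout (1 + emax))
  p <- ref_params()
  trs <- simulate_kpd(p, data.frame(time = 0, amount = 1e9),
                      times = seq(0, 60, 1))
  lim <- p[["kin"]] / (p[["kout"]] * (1 + p[["emax"]]))
  expect_equal(trs$bcell[trs$time == 60], lim, tolerance = 1e-4)
})

test_that("trajectories are invariant under grid refinement", {
  p <- ref_params()
  tt <- seq(0, 250, 5)
  coarse <- simulate_kpd(p, std_doses(), times = tt)
  fine <- simulate_kpd(p, std_doses(), times = seq(0, 250, 0.5))
  expect_equal(coarse$bcell,
               fine$bcell[match(tt, fine$time)], tolerance = 1e-6)
})

test_that("repletion time is found, refined, and undefined when appropriate", {
  # always above threshold
  flat <- data.frame(time = 0:100, bcell = rep(500, 101))
  expect_true(is.na(repletion_time(flat, threshold = 10, after = 0)))
  # constructed piecewise-linear crossing at exactly day 100
  lin <- data.frame(time = seq(0, 200, 10),
                    bcell = pmax(0, (seq(0, 200, 10) - 90)))
  expect_equal(repletion_time(lin, threshold = 10, after = 0), 100,
               tolerance = 0.011)
  # bisection refinement agrees with an independent uniroot oracle
  p <- ref_params()
  tr <- simulate_kpd(p, std_doses(), times = seq(0, 300, 0.25))
  rt <- repletion_time(tr)
  root <- uniroot(function(t) lsoda_oracle(p, std_doses(), t) - 10,
                  c(100, 200), tol = 1e-4)$root
  expect_equal(rt, root, tolerance = 0.1)
  expect_error(repletion_time(data.frame(time = numeric(0),
                                         bcell = numeric(0))), "empty")
})

test_that("repletion time grows with the administered dose", {
  p <- ref_params()
  doses <- c(100, 200, 400, 800)
  rts <- vapply(doses, function(a) {
    repletion_time(simulate_kpd(p, data.frame(time = 0, amount = a),
                                times = seq(0, 400, 0.5)))
  }, numeric(1))
  expect_true(all(diff(rts) > 0))
  # approximate log-linearity in total dose for boluses >> ED50
  fit <- lm(rts ~ log(doses))
  expect_gt(summary(fit)$r.squared, 0.99)
})
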