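# approximate marginal likelihood, fitting, CWRES, shrinkage, stepwise

test_that("with no IIV the OFV equals the closed-form Gaussian -2LL", {
  m <- kpd_reference_model()
  m0 <- kpd_model(m$typical, omega = NULL, covariates = m$covariates,
                  residual = m$residual)
  co <- small_cohort(21, n = 8)
  ofv <- kpd_ofv(co$data, m0, method = "foce")
  # independent closed form using the same fixed-grid predictions
  subj <- bcellkpd:::kpd_split(co$data)
  fl <- bcellkpd:::kpd_flatten(subj)
  typ <- bcellkpd:::typ_matrix(m0, fl$covariates, length(subj))
  by_hand <- 0
  for (i in seq_along(subj)) {
    s <- subj[[i]]
    obs <- s$obs[s$obs$mdv == 0, ]
    p <- setNames(typ[i, ], bcellkpd:::.kpd_param_names)
    f <- bcellkpd:::kpd_solve_cpp(obs$time, p, s$doses$time, s$doses$amount,
                                  0, p[["kin"]] / p[["kout"]], 1e-6, 1e-8,
                                  0.25)
    g <- m0$residual$sd_add^2 + (m0$residual$sd_prop * f)^2
    by_hand <- by_hand + sum(log(2 * pi * g) + (obs$dv - f)^2 / g)
  }
  expect_equal(as.numeric(ofv), by_hand, tolerance = 1e-6)
  # doubling both sigmas changes the OFV in the closed-form direction
  m2 <- m0
  m2$residual$sd_add <- 2 * m2$residual$sd_add
  m2$residual$sd_prop <- 2 * m2$residual$sd_prop
  f_all <- unlist(lapply(seq_along(subj), function(i) {
    s <- subj[[i]]
    obs <- s$obs[s$obs$mdv == 0, ]
    p <- setNames(typ[i, ], bcellkpd:::.kpd_param_names)
    bcellkpd:::kpd_solve_cpp(obs$time, p, s$doses$time, s$doses$amount, 0,
                             p[["kin"]] / p[["kout"]], 1e-6, 1e-8, 0.25)
  }))
  g1 <- m0$residual$sd_add^2 + (m0$residual$sd_prop * f_all)^2
  r2 <- (fl$obs_y - f_all)^2
  predicted_change <- sum(log(4 * g1) - log(g1)) + sum(r2 / (4 * g1) - r2 / g1)
  ofv2 <- kpd_ofv(co$data, m2, method = "foce")
  expect_equal(as.numeric(ofv2 - ofv), predicted_change, tolerance = 1e-6)
})

test_that("Laplace OFV matches adaptive Gauss-Hermite on one-eta problems", {
  p <- ref_params()
  doses <- std_doses()
  times <- c(14, 40, 70, 100, 130, 160, 200)
  resid <- residual_error("combined", sd_add = 2.56, sd_prop = 0.40)
  for (cfg in list(list(which = "kin", omega = 0.378, seed = 1),
                   list(which = "kout", omega = 0.249, seed = 2),
                   list(which = "emax", omega = 0.578, seed = 3))) {
    set.seed(cfg$seed)
    pi_ <- as.numeric(p)
    names(pi_) <- names(ref_truth())
    pi_[cfg$which] <- pi_[cfg$which] * exp(rnorm(1, 0, cfg$omega))
    f <- bcellkpd:::kpd_solve_cpp(times, pi_, doses$time, doses$amount, 0,
                                  pi_[["kin"]] / pi_[["kout"]], 1e-10,
                                  1e-12, -1)
    y <- f * (1 + rnorm(length(f), 0, 0.40)) + rnorm(length(f), 0, 2.56)
    d <- rbind(
      data.frame(ID = 1, TIME = doses$time, AMT = doses$amount, DV = NA,
                 EVID = 1L, MDV = 1L),
      data.frame(ID = 1, TIME = times, AMT = NA, DV = y, EVID = 0L,
                 MDV = 0L))
    om <- setNames(cfg$omega, cfg$which)
    m <- kpd_model(p, omega = om, residual = resid)
    lap <- kpd_ofv(d, m, method = "laplace",
                   control = kpd_control(fixed_h = 0.05))
    ref <- agh_neg2ll(p, doses, times, y, cfg$which, cfg$omega, resid,
                      n_nodes = 15)
    expect_lt(abs(as.numeric(lap) - ref), 0.5)
  }
})

test_that("a nearly linear one-eta marginal matches the conjugate-Gaussian integral", {
  # small omega => f(eta) ~ f0 + J eta is accurate, and the marginal is the
  # Gaussian y ~ N(f0, J om^2 J' + diag(g))
  p <- ref_params()
  doses <- std_doses()
  times <- c(30, 60, 90, 120, 150)
  omega <- 0.02
  resid <- residual_error("additive", sd_add = 5)
  f0 <- bcellkpd:::kpd_solve_cpp(times, as.numeric(p), doses$time,
                                 doses$amount, 0, kpd_baseline(p), 1e-10,
                                 1e-12, -1)
  h <- 1e-5
  pk <- as.numeric(p); names(pk) <- names(ref_truth())
  pk["kin"] <- pk["kin"] * exp(h)
  fh <- bcellkpd:::kpd_solve_cpp(times, pk, doses$time, doses$amount, 0,
                                 pk[["kin"]] / pk[["kout"]], 1e-10, 1e-12,
                                 -1)
  J <- (fh - f0) / h
  set.seed(8)
  y <- f0 + J * rnorm(1, 0, omega) + rnorm(length(f0), 0, 5)
  C <- tcrossprod(J) * omega^2 + diag(25, length(f0))
  analytic <- as.numeric(
    length(f0) * log(2 * pi) + determinant(C)$modulus +
      t(y - f0) %*% solve(C, y - f0))
  d <- rbind(
    data.frame(ID = 1, TIME = doses$time, AMT = doses$amount, DV = NA,
               EVID = 1L, MDV = 1L),
    data.frame(ID = 1, TIME = times, AMT = NA, DV = y, EVID = 0L, MDV = 0L))
  m <- kpd_model(p, omega = c(kin = omega), residual = resid)
  got <- kpd_ofv(d, m, method = "laplace",
                 control = kpd_control(fixed_h = 0.05))
  expect_equal(as.numeric(got), analytic, tolerance = 0.05)
})

test_that("noiseless data with no IIV recover the typicals within 1%", {
  truth <- kpd_model(ref_params(), omega = NULL,
                     residual = residual_error("additive", sd_add = 0.01))
  co <- generate_cohort(cohort_config(n_subjects = 10, truth = truth,
                                      seed = 31))
  init <- kpd_model(kpd_params(0.049 * 1.05, 4.14 * 0.95, 0.007 * 1.05,
                               389.7 * 0.95, 1.31 * 1.05, 6.65 * 0.95),
                    omega = NULL,
                    residual = residual_error("additive", sd_add = 0.01))
  # fine likelihood grid: with near-noiseless data the discretization error
  # of the default grid would otherwise dominate the residual
  fit <- kpd_fit(co$data, init = init, fixed = "sigma_add",
                 control = fast_control(fixed_h = 0.05, maxit = 300,
                                        restarts = 3))
  est <- coef(fit)[names(ref_truth())]
  expect_true(all(abs(est - ref_truth()) / ref_truth() < 0.01))
})

test_that("fits never end above their starting objective", {
  co <- small_cohort(17, n = 12)
  m <- kpd_reference_model()
  fit <- kpd_fit(co$data, init = m, control = fast_control(maxit = 60))
  ofv_truth <- kpd_ofv(co$data, m, method = "foce")
  expect_lte(fit$ofv, as.numeric(ofv_truth) + 1e-6)
})

test_that("OFV is invariant to subject order and id relabeling", {
  co <- small_cohort(23, n = 10)
  m <- kpd_reference_model()
  o1 <- kpd_ofv(co$data, m, "foce")
  d2 <- co$data
  d2$ID <- paste0("S", d2$ID)           # relabel
  ids <- unique(d2$ID)
  d2 <- do.call(rbind, lapply(rev(ids), function(i) d2[d2$ID == i, ]))
  o2 <- kpd_ofv(d2, m, "foce")
  expect_equal(as.numeric(o1), as.numeric(o2), tolerance = 1e-8)
})

test_that("CWRES reduce to (y - f)/sqrt(g) with no IIV and are calibrated", {
  m <- kpd_reference_model()
  m0 <- kpd_model(m$typical, omega = NULL, covariates = m$covariates,
                  residual = m$residual)
  co <- small_cohort(41, n = 8)
  fit0 <- kpd_fit(co$data, init = m0, control = fast_control(),
                  optimize = FALSE)
  g <- gof_table(fit0)
  expect_equal(g$cwres,
               (g$dv - g$ipred) /
                 bcellkpd:::residual_sd(m0$residual, g$ipred),
               tolerance = 1e-8)
  expect_equal(g$pred, g$ipred, tolerance = 1e-10)
  # calibration at the generating model on a full-size cohort
  co2 <- generate_cohort(cohort_config(seed = 71))
  fit <- kpd_fit(co2$data, init = kpd_reference_model(),
                 control = fast_control(), optimize = FALSE)
  cw <- cwres(fit)
  expect_equal(length(cw), sum(co2$data$EVID == 0))
  # the generator's clamp-at-zero rule lifts observations at the depletion
  # nadir, so even at the generating model the mean sits slightly above 0
  expect_lt(abs(mean(cw)), 0.2)
  expect_gt(sd(cw), 0.85)
  expect_lt(sd(cw), 1.15)
})

test_that("eta shrinkage behaves at its limits", {
  co <- generate_cohort(cohort_config(n_subjects = 40, seed = 13))
  fit <- kpd_fit(co$data, init = kpd_reference_model(),
                 control = fast_control(), optimize = FALSE)
  shr <- eta_shrinkage(fit)
  expect_named(shr, c("ke", "kin", "kout", "emax", "ed50"))
  expect_true(all(shr <= 100 + 1e-6))
  # well-observed kin: modest shrinkage
  expect_lt(shr[["kin"]], 60)
  # a subject set with no informative observations collapses to eta = 0
  d <- co$data
  d <- d[d$EVID == 1 | d$TIME == 0, ] # keep only dosing + baseline
  fit2 <- kpd_fit(d, init = kpd_reference_model(),
                  control = fast_control(), optimize = FALSE)
  shr2 <- eta_shrinkage(fit2)
  expect_gt(shr2[["ed50"]], 85) # ED50 only acts post-dose: EBEs ~ 0
})

test_that("stepwise covariate machinery is deterministic and honest", {
  co <- small_cohort(3, n = 14)
  base <- kpd_reference_model()
  base$covariates <- list()
  # empty candidate list returns the base model unchanged
  sw0 <- kpd_stepwise(co$data, base, list(), control = fast_control(),
                      final_control = fast_control())
  expect_length(sw0$selected, 0)
  expect_equal(nrow(sw0$steps), 0L)
})

test_that("residual-model comparison ranks the generating error family first", {
  co <- generate_cohort(cohort_config(n_subjects = 25, seed = 37))
  base <- kpd_reference_model() # combined-error truth
  cmp <- compare_residual_models(co$data, base,
                                 control = fast_control(maxit = 80))
  expect_identical(cmp$kind[1], "combined")
  expect_identical(sort(cmp$n_par, decreasing = TRUE)[1],
                   cmp$n_par[cmp$kind == "combined"])
  # determinism: identical call, identical ranking
  cmp2 <- compare_residual_models(co$data, base,
                                  control = fast_control(maxit = 80))
  expect_identical(cmp$kind, cmp2$kind)
  expect_equal(cmp$ofv, cmp2$ofv, tolerance = 1e-9)
})
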