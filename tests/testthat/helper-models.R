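# shared fixtures and independent oracles

ref_params <- function() {
  kpd_params(ke = 0.049, kin = 4.14, kout = 0.007, emax = 389.7,
             ed50 = 1.31, gamma = 6.65)
}

ref_truth <- function() {
  c(ke = 0.049, kin = 4.14, kout = 0.007, emax = 389.7, ed50 = 1.31,
    gamma = 6.65)
}

std_doses <- function() data.frame(time = c(0, 7), amount = 307.5)

# independent trajectory oracle: deSolve::lsoda on the 2-state system with
# bolus events into the depot
lsoda_oracle <- function(params, doses, times, rtol = 1e-10, atol = 1e-10) {
  p <- as.numeric(params)
  names(p) <- c("ke", "kin", "kout", "emax", "ed50", "gamma")
  rhs <- function(t, y, parms) {
    a1 <- y[1]
    s <- if (a1 > 0) p[["emax"]] / (1 + (p[["ed50"]] / a1)^p[["gamma"]]) else 0
    list(c(-p[["ke"]] * a1,
           p[["kin"]] - p[["kout"]] * (1 + s) * y[2]))
  }
  ev <- data.frame(var = "A1", time = doses$time, value = doses$amount,
                   method = "add")
  tt <- sort(unique(c(0, doses$time, times)))
  out <- deSolve::ode(c(A1 = 0, E = p[["kin"]] / p[["kout"]]), tt, rhs,
                      NULL, events = list(data = ev), rtol = rtol,
                      atol = atol, method = "lsoda")
  out[match(times, out[, "time"]), "E"]
}

# Gauss-Hermite nodes/weights by Golub-Welsch (symmetric tridiagonal
# eigenproblem); weight function exp(-x^2)
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- diag(0, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  ev <- eigen(J, symmetric = TRUE)
  list(nodes = ev$values, weights = sqrt(pi) * ev$vectors[1, ]^2)
}

# adaptive Gauss-Hermite marginal -2 log-likelihood for a one-eta toy:
# subject with obs (times, y), eta acting multiplicatively on `which`
# parameter, centred and scaled at the joint mode
agh_neg2ll <- function(params, doses, times, y, which, omega, residual,
                       n_nodes = 15) {
  pred <- function(eta) {
    p <- as.numeric(params)
    names(p) <- names(ref_truth())
    p[which] <- p[which] * exp(eta)
    bcellkpd:::kpd_solve_cpp(times, p, doses$time, doses$amount, t0 = 0,
                  e0 = p[["kin"]] / p[["kout"]], rtol = 1e-10, atol = 1e-12,
                  fixed_h = -1)
  }
  nl_joint <- function(eta) { # -log p(y|eta) - log p(eta)
    f <- pred(eta)
    g <- residual$sd_add^2 + (residual$sd_prop * f)^2
    0.5 * sum(log(2 * pi * g) + (y - f)^2 / g) +
      0.5 * (log(2 * pi * omega^2) + eta^2 / omega^2)
  }
  opt <- optimize(nl_joint, c(-6, 6))
  mode <- opt$minimum
  h <- 1e-4
  hess <- (nl_joint(mode + h) - 2 * opt$objective + nl_joint(mode - h)) / h^2
  sdev <- 1 / sqrt(hess)
  gh <- gauss_hermite(n_nodes)
  z <- mode + sqrt(2) * sdev * gh$nodes
  lw <- log(gh$weights) + log(sqrt(2) * sdev) + gh$nodes^2 -
    vapply(z, nl_joint, numeric(1))
  m <- max(lw)
  -2 * (m + log(sum(exp(lw - m))))
}

# small synthetic cohort for estimation tests (cheaper than the default 59)
small_cohort <- function(seed, n = 20, truth = kpd_reference_model()) {
  generate_cohort(cohort_config(n_subjects = n, truth = truth, seed = seed))
}

fast_control <- function(...) {
  ctl <- kpd_control(hessian = FALSE)
  mod <- list(...)
  ctl[names(mod)] <- mod
  ctl
}
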