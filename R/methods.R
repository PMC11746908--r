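# S3 methods for kpd_fit + conditional weighted residuals and GOF tables

#' @export
print.kpd_fit <- function(x, ...) {
  cat("Population K-PD model fit (", x$method, ")\n", sep = "")
  cat(sprintf("  %d subjects, %d observations; OFV = %.3f; %s\n",
              x$n_subjects, x$n_obs, x$ofv,
              if (x$converged) "converged" else "NOT converged"))
  rse <- kpd_rse(x)
  shr <- eta_shrinkage(x)
  nat <- natural_scale(x$estimate)
  tab <- data.frame(estimate = signif(nat, 4),
                    `RSE%` = signif(rse, 3), check.names = FALSE)
  shr_col <- rep(NA_real_, nrow(tab))
  names(shr_col) <- rownames(tab)
  for (p in names(shr)) shr_col[paste0("omega_", p)] <- shr[[p]]
  tab$`shrinkage%` <- signif(shr_col, 3)
  print(tab)
  invisible(x)
}

#' @export
summary.kpd_fit <- function(object, ...) {
  structure(list(fit = object, rse = kpd_rse(object),
                 shrinkage = eta_shrinkage(object)),
            class = "summary.kpd_fit")
}

#' @export
print.summary.kpd_fit <- function(x, ...) {
  print(x$fit)
  cat("\nEstimated model:\n")
  print(x$fit$model)
  invisible(x)
}

#' @export
coef.kpd_fit <- function(object, ...) {
  natural_scale(object$estimate)
}

#' @export
vcov.kpd_fit <- function(object, ...) object$vcov

#' @export
logLik.kpd_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$estimate),
            nobs = object$n_obs, class = "logLik")
}

# per-subject predictions at given etas (diagnostic-quality adaptive solve)
subject_pred <- function(fit, s, typ_row, eta, times) {
  pars <- typ_row * exp(eta)
  kpd_solve_cpp(times, pars, s$doses$time, s$doses$amount, t0 = 0,
                e0 = pars[["kin"]] / pars[["kout"]],
                rtol = 1e-8, atol = 1e-10, fixed_h = -1)
}

#' Conditional weighted residuals
#'
#' First-order conditional linearization of each subject's model about its
#' empirical-Bayes etas: with Jacobian \eqn{J = \partial f/\partial\eta} at
#' the mode, the marginal mean is \eqn{f(\hat\eta) - J\hat\eta} and the
#' covariance \eqn{J\Omega J' + \mathrm{diag}(g)}; CWRES are the residuals
#' decorrelated by the Cholesky factor of that covariance.  With no IIV
#' this reduces exactly to \eqn{(y - f)/\sqrt{g}}.  Under a correct model
#' CWRES are approximately standard normal.
#'
#' @param fit a [kpd_fit()] result.
#' @return numeric vector, one value per non-missing observation (dataset
#'   order), with subject ids as names.
#' @export
cwres <- function(fit) {
  act <- which(fit$model$omega > 0)
  om2 <- fit$model$omega[act]^2
  res <- fit$model$residual
  out <- list()
  typm <- typ_matrix(fit$model, fit$flatten$covariates, fit$n_subjects)
  for (i in seq_along(fit$subjects)) {
    s <- fit$subjects[[i]]
    obs <- s$obs[s$obs$mdv == 0L, , drop = FALSE]
    if (nrow(obs) == 0L) next
    typ_row <- setNames(typm[i, ], .kpd_param_names)
    eta <- fit$etas[i, ]
    f <- subject_pred(fit, s, typ_row, eta, obs$time)
    g <- residual_sd(res, f)^2
    if (length(act) == 0L) {
      out[[i]] <- setNames((obs$dv - f) / sqrt(g), rep(s$id, nrow(obs)))
      next
    }
    J <- matrix(0, nrow(obs), length(act))
    h <- 1e-4
    for (k in seq_along(act)) {
      ek <- eta
      ek[act[k]] <- ek[act[k]] + h
      J[, k] <- (subject_pred(fit, s, typ_row, ek, obs$time) - f) / h
    }
    m <- f - drop(J %*% eta[act])
    C <- J %*% (om2 * t(J)) + diag(g, nrow(obs))
    L <- try(t(chol(C)), silent = TRUE)
    if (inherits(L, "try-error")) {
      warning("singular conditional covariance for subject ", s$id,
              "; falling back to individual weighted residuals")
      out[[i]] <- setNames((obs$dv - f) / sqrt(g), rep(s$id, nrow(obs)))
    } else {
      out[[i]] <- setNames(drop(forwardsolve(L, obs$dv - m)),
                           rep(s$id, nrow(obs)))
    }
  }
  unlist(out)
}

#' @param object a [kpd_fit()] result.
#' @param type \code{"cwres"} (conditional weighted), \code{"iwres"}
#'   (individual weighted \eqn{(y - f_i)/\sqrt{g}}) or \code{"raw"}
#'   (\eqn{y - f_i}).
#' @param ... unused.
#' @rdname cwres
#' @export
residuals.kpd_fit <- function(object, type = c("cwres", "iwres", "raw"),
                              ...) {
  type <- match.arg(type)
  if (type == "cwres") return(cwres(object))
  g <- gof_table(object)
  r <- g$dv - g$ipred
  if (type == "iwres") {
    r <- r / residual_sd(object$model$residual, g$ipred)
  }
  setNames(r, g$id)
}

#' Goodness-of-fit table
#'
#' One row per non-missing observation: time, time after the most recent
#' dose, observed value, population prediction (etas = 0), individual
#' prediction (empirical-Bayes etas) and CWRES.
#'
#' @param fit a [kpd_fit()] result.
#' @return data frame with columns \code{id, time, tad, dv, pred, ipred,
#'   cwres}.
#' @export
gof_table <- function(fit) {
  typm <- typ_matrix(fit$model, fit$flatten$covariates, fit$n_subjects)
  cw <- cwres(fit)
  rows <- list()
  pos <- 0L
  for (i in seq_along(fit$subjects)) {
    s <- fit$subjects[[i]]
    obs <- s$obs[s$obs$mdv == 0L, , drop = FALSE]
    if (nrow(obs) == 0L) next
    typ_row <- setNames(typm[i, ], .kpd_param_names)
    pred <- subject_pred(fit, s, typ_row, numeric(6), obs$time)
    ipred <- subject_pred(fit, s, typ_row, fit$etas[i, ], obs$time)
    tad <- vapply(obs$time, function(t) {
      prior <- s$doses$time[s$doses$time <= t]
      if (length(prior)) t - max(prior) else NA_real_
    }, numeric(1))
    rows[[i]] <- data.frame(id = s$id, time = obs$time, tad = tad,
                            dv = obs$dv, pred = pred, ipred = ipred,
                            cwres = cw[pos + seq_len(nrow(obs))])
    pos <- pos + nrow(obs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predictions from a fitted model
#'
#' @param object a [kpd_fit()] result.
#' @param newdata optional dataset (same layout as the fitting data); the
#'   default reuses the fitting data.  Subjects in \code{newdata} that were
#'   in the fit keep their empirical-Bayes etas; new subjects get etas = 0.
#' @param type \code{"ipred"} (individual) or \code{"pred"} (population).
#' @param ... unused.
#' @return data frame \code{id, time, pred}.
#' @export
predict.kpd_fit <- function(object, newdata = NULL,
                            type = c("ipred", "pred"), ...) {
  type <- match.arg(type)
  subjects <- if (is.null(newdata)) object$subjects else kpd_split(newdata)
  fl <- if (is.null(newdata)) object$flatten else kpd_flatten(subjects)
  typm <- typ_matrix(object$model, fl$covariates, length(subjects))
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    if (nrow(s$obs) == 0L) return(NULL)
    typ_row <- setNames(typm[i, ], .kpd_param_names)
    eta <- if (type == "pred") numeric(6) else {
      if (as.character(s$id) %in% rownames(object$etas)) {
        object$etas[as.character(s$id), ]
      } else numeric(6)
    }
    data.frame(id = s$id, time = s$obs$time,
               pred = subject_pred(object, s, typ_row, eta, s$obs$time))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new etas and residual errors at the design (subjects, dose
#' schedules, observation times, covariates) of the fitting data.
#'
#' @param object a [kpd_fit()] result.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of data frames in the input layout with simulated DV.
#' @export
simulate.kpd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sims <- simulate_design(object$model, object$subjects, object$flatten,
                          nsim, seed)
  lapply(seq_len(nsim), function(r) {
    d <- object$data
    obs_rows <- which(d$EVID == 0 & d$MDV == 0)
    d$DV[obs_rows] <- sims$y[, r]
    d
  })
}

# core design simulator: returns n_obs x nsim matrix of simulated DV
# (non-missing observation rows, dataset order) and the eta draws
simulate_design <- function(model, subjects, fl, nsim, seed = NULL) {
  n <- length(subjects)
  typm <- typ_matrix(model, fl$covariates, n)
  with_seed(seed, {
    y <- matrix(NA_real_, sum(fl$obs_len), nsim)
    etas <- array(0, c(n, 6, nsim))
    for (k in which(model$omega > 0)) {
      etas[, k, ] <- rnorm(n * nsim, 0, model$omega[[k]])
    }
    for (r in seq_len(nsim)) {
      pos <- 0L
      for (i in seq_len(n)) {
        s <- subjects[[i]]
        obs <- s$obs[s$obs$mdv == 0L, , drop = FALSE]
        if (nrow(obs) == 0L) next
        pars <- typm[i, ] * exp(etas[i, , r])
        f <- kpd_solve_cpp(obs$time, pars, s$doses$time, s$doses$amount,
                           t0 = 0, e0 = pars[2] / pars[3],
                           rtol = 1e-6, atol = 1e-8, fixed_h = -1)
        y[pos + seq_len(nrow(obs)), r] <- draw_residual(model$residual, f)
        pos <- pos + nrow(obs)
      }
    }
    list(y = y, etas = etas)
  })
}

#' Diagnostic plots for a fitted model
#'
#' Four-panel goodness-of-fit display: observed vs population and
#' individual predictions, CWRES vs population prediction and vs time
#' after dose.
#'
#' @param x a [kpd_fit()] result.
#' @param ... passed to [plot()].
#' @export
plot.kpd_fit <- function(x, ...) {
  g <- gof_table(x)
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(g$pred, g$dv, xlab = "Population prediction",
       ylab = "Observed (cells/uL)", main = "DV vs PRED", ...)
  abline(0, 1, col = 2)
  plot(g$ipred, g$dv, xlab = "Individual prediction",
       ylab = "Observed (cells/uL)", main = "DV vs IPRED", ...)
  abline(0, 1, col = 2)
  plot(g$pred, g$cwres, xlab = "Population prediction", ylab = "CWRES",
       main = "CWRES vs PRED", ...)
  abline(h = c(-2, 0, 2), lty = c(2, 1, 2), col = c(2, 1, 2))
  plot(g$tad, g$cwres, xlab = "Time after dose (days)", ylab = "CWRES",
       main = "CWRES vs TAD", ...)
  abline(h = c(-2, 0, 2), lty = c(2, 1, 2), col = c(2, 1, 2))
  invisible(g)
}
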