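# Model qualification: visual predictive check and nonparametric bootstrap

#' Visual predictive check
#'
#' Simulates \code{n_sim} replicate datasets at the design of \code{data}
#' (same subjects, doses, observation times and covariates, including
#' residual error), then compares observed percentiles per time bin with the
#' simulation-based confidence band of each percentile.
#'
#' @param data dataset providing the design and the observed values.
#' @param model a [kpd_model()] (typically the fitted model).
#' @param n_sim number of replicate datasets (>= 100).
#' @param bins either a single integer (number of quantile-based time bins
#'   over the observation window) or a numeric vector of bin edges (days).
#' @param pi percentiles summarized (default 5th/50th/95th).
#' @param ci width of the simulated confidence band around each percentile
#'   (default 0.90).
#' @param seed optional seed; the result is deterministic given the seed.
#' @return object of class \code{kpd_vpc}: bin table, observed percentiles
#'   per bin, and per-percentile simulated bands.  See [plot.kpd_vpc()].
#' @export
kpd_vpc <- function(data, model, n_sim = 1000, bins = 8,
                    pi = c(0.05, 0.5, 0.95), ci = 0.90, seed = NULL) {
  if (n_sim < 100) stop_kpd("n_sim must be >= 100")
  subjects <- kpd_split(data)
  fl <- kpd_flatten(subjects)
  times <- fl$obs_t
  obs <- fl$obs_y
  if (length(bins) == 1L) {
    edges <- unique(quantile(times, probs = seq(0, 1, length.out = bins + 1)))
    edges[1] <- min(times) - 1e-9
    edges[length(edges)] <- max(times) + 1e-9
  } else {
    edges <- sort(unique(as.numeric(bins)))
  }
  bin_id <- cut(times, edges, include.lowest = TRUE, labels = FALSE)
  counts <- tabulate(bin_id, nbins = length(edges) - 1L)
  if (any(counts == 0L)) {
    empty <- which(counts == 0L)
    stop_kpd("empty VPC time bin(s): ",
             paste(sprintf("[%.3g, %.3g]", edges[empty], edges[empty + 1]),
                   collapse = ", "), class = "kpd_bin_error")
  }
  nb <- length(edges) - 1L
  sims <- simulate_design(model, subjects, fl, n_sim, seed)
  obs_pct <- t(vapply(seq_len(nb), function(b) {
    quantile(obs[bin_id == b], probs = pi, names = FALSE)
  }, numeric(length(pi))))
  # per-replicate percentiles per bin: nb x npct x n_sim
  sim_pct <- array(NA_real_, c(nb, length(pi), n_sim))
  for (b in seq_len(nb)) {
    sel <- bin_id == b
    sim_pct[b, , ] <- apply(sims$y[sel, , drop = FALSE], 2, quantile,
                            probs = pi, names = FALSE)
  }
  alpha <- (1 - ci) / 2
  band_lo <- apply(sim_pct, c(1, 2), quantile, probs = alpha, names = FALSE)
  band_md <- apply(sim_pct, c(1, 2), quantile, probs = 0.5, names = FALSE)
  band_hi <- apply(sim_pct, c(1, 2), quantile, probs = 1 - alpha,
                   names = FALSE)
  structure(list(
    bins = data.frame(lo = edges[-length(edges)], hi = edges[-1],
                      mid = (edges[-length(edges)] + edges[-1]) / 2,
                      n = counts),
    pi = pi, ci = ci, n_sim = n_sim,
    observed = obs_pct, band_lo = band_lo, band_md = band_md,
    band_hi = band_hi), class = "kpd_vpc")
}

#' @export
print.kpd_vpc <- function(x, ...) {
  cat(sprintf("Visual predictive check: %d bins, %d simulations, %.0f%% CI\n",
              nrow(x$bins), x$n_sim, 100 * x$ci))
  inside <- x$observed >= x$band_lo & x$observed <= x$band_hi
  for (j in seq_along(x$pi)) {
    cat(sprintf("  P%02.0f: observed inside simulated band in %d/%d bins\n",
                100 * x$pi[j], sum(inside[, j]), nrow(x$bins)))
  }
  invisible(x)
}

#' Plot a visual predictive check
#'
#' @param x a [kpd_vpc()] result.
#' @param ... passed to [plot()].
#' @export
plot.kpd_vpc <- function(x, ...) {
  mid <- x$bins$mid
  ylim <- range(x$band_lo, x$band_hi, x$observed)
  plot(NA, xlim = range(x$bins$lo, x$bins$hi), ylim = ylim,
       xlab = "Time (days)", ylab = "CD19+ B-cells (cells/uL)",
       main = "Visual predictive check", ...)
  shade <- grDevices::adjustcolor("steelblue", alpha.f = 0.3)
  for (j in seq_along(x$pi)) {
    polygon(c(mid, rev(mid)), c(x$band_lo[, j], rev(x$band_hi[, j])),
            col = shade, border = NA)
    lines(mid, x$band_md[, j], col = "black", lty = 2)
    lines(mid, x$observed[, j], col = "red", lwd = 2)
  }
  legend("topleft", legend = c("observed percentile",
                               "simulated median", "simulated band"),
         col = c("red", "black", shade), lty = c(1, 2, NA),
         pch = c(NA, NA, 15), bty = "n")
  invisible(x)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement (preserving the number of subjects),
#' refits each resample from \code{init}, and summarizes each parameter by
#' the median and a 95 percent percentile interval across converged
#' resamples.
#'
#' @param data dataset.
#' @param init initial [kpd_model()] defining the structure (typically the
#'   final model).
#' @param n_resample number of bootstrap resamples (>= 50).
#' @param seed optional seed; resample index sets are reproducible.
#' @param method,control,fixed passed to [kpd_fit()] (Hessians are disabled
#'   in the refits regardless).
#' @return object of class \code{kpd_bootstrap}: per-parameter median and
#'   2.5/97.5 percentiles, converged count, instability flag (> 20 percent
#'   non-convergence) and the resampled estimates.
#' @export
kpd_bootstrap <- function(data, init, n_resample = 500, seed = NULL,
                          method = "foce",
                          control = kpd_control(hessian = FALSE),
                          fixed = character()) {
  if (n_resample < 50) stop_kpd("n_resample must be >= 50")
  control$hessian <- FALSE
  data <- validate_kpd_data(data)
  ids <- unique(data$ID)
  n <- length(ids)
  idx <- with_seed(seed, {
    matrix(sample.int(n, n * n_resample, replace = TRUE), nrow = n)
  })
  est <- matrix(NA_real_, n_resample,
                length(pack_model(init, character())))
  colnames(est) <- names(pack_model(init, character()))
  est <- est[, setdiff(colnames(est), fixed), drop = FALSE]
  ok <- logical(n_resample)
  for (r in seq_len(n_resample)) {
    pieces <- lapply(seq_len(n), function(j) {
      d <- data[data$ID == ids[idx[j, r]], , drop = FALSE]
      d$ID <- j # relabel so resampled duplicates stay distinct subjects
      d
    })
    bd <- do.call(rbind, pieces)
    fit <- try(kpd_fit(bd, init = init, fixed = fixed, method = method,
                       control = control), silent = TRUE)
    if (!inherits(fit, "try-error") && is.finite(fit$ofv)) {
      est[r, names(fit$estimate)] <- natural_scale(fit$estimate)
      ok[r] <- fit$converged
    }
  }
  use <- ok & !apply(est, 1, anyNA)
  qs <- apply(est[use, , drop = FALSE], 2, quantile,
              probs = c(0.5, 0.025, 0.975), names = FALSE)
  out <- data.frame(parameter = colnames(est), median = qs[1, ],
                    lo95 = qs[2, ], hi95 = qs[3, ])
  rownames(out) <- NULL
  structure(list(summary = out, n_resample = n_resample,
                 n_converged = sum(use), idx = idx, estimates = est,
                 unstable = mean(!use) > 0.2),
            class = "kpd_bootstrap")
}

#' @export
print.kpd_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d/%d resamples converged%s\n", x$n_converged,
              x$n_resample,
              if (x$unstable) " [UNSTABLE: >20% non-convergence]" else ""))
  print(transform(x$summary, median = signif(median, 4),
                  lo95 = signif(lo95, 4), hi95 = signif(hi95, 4)))
  invisible(x)
}
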