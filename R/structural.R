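#' Structural K-PD parameters
#'
#' Bundles the six structural constants of the dose-driven turnover model:
#' first-order depot elimination \code{ke} (1/day), zero-order B-cell
#' synthesis \code{kin} (cells/uL/day), first-order B-cell degradation
#' \code{kout} (1/day), maximal fold-stimulation of degradation \code{emax}
#' (dimensionless), depot amount at half-maximal effect \code{ed50} (mg) and
#' Hill coefficient \code{gamma}.  The model baseline B-cell count is
#' \code{kin/kout}.
#'
#' @param ke,kin,kout,emax,ed50,gamma strictly positive scalars (units above).
#' @return An object of class \code{kpd_params} (named numeric vector).
#' @examples
#' p <- kpd_params(ke = 0.049, kin = 4.14, kout = 0.007,
#'                 emax = 389.7, ed50 = 1.31, gamma = 6.65)
#' kpd_baseline(p) # cells/uL
#' @export
kpd_params <- function(ke, kin, kout, emax, ed50, gamma) {
  x <- c(ke = ke, kin = kin, kout = kout, emax = emax, ed50 = ed50,
         gamma = gamma)
  if (length(x) != 6L || anyNA(x) || !is.numeric(x)) {
    stop_kpd("all six structural parameters must be numeric scalars")
  }
  if (any(x <= 0)) {
    stop_kpd("structural parameters must be strictly positive; offending: ",
             paste(names(x)[x <= 0], collapse = ", "))
  }
  if (!is.finite(kin / kout)) stop_kpd("baseline kin/kout is not finite")
  structure(x, class = "kpd_params")
}

#' @export
print.kpd_params <- function(x, ...) {
  cat("K-PD structural parameters:\n")
  print(unclass(x), ...)
  cat(sprintf("baseline B-cell count kin/kout = %.4g cells/uL\n",
              x[["kin"]] / x[["kout"]]))
  invisible(x)
}

as_kpd_params <- function(x) {
  if (inherits(x, "kpd_params")) return(x)
  x <- unlist(x)[.kpd_param_names]
  do.call(kpd_params, as.list(x))
}

#' Model baseline B-cell count
#'
#' @param params a [kpd_params] object.
#' @return \code{kin/kout} in cells/uL.
#' @export
kpd_baseline <- function(params) {
  params <- as_kpd_params(params)
  params[["kin"]] / params[["kout"]]
}

check_doses <- function(doses) {
  if (is.null(doses) || NROW(doses) == 0L) {
    return(data.frame(time = numeric(0), amount = numeric(0)))
  }
  doses <- as.data.frame(doses)
  if (!all(c("time", "amount") %in% names(doses))) {
    stop_kpd("doses must have columns 'time' and 'amount'")
  }
  if (any(doses$amount <= 0)) stop_kpd("dose amounts must be positive")
  if (any(doses$time < 0)) stop_kpd("dose times must be non-negative")
  doses[order(doses$time), c("time", "amount"), drop = FALSE]
}

#' Depot amount at given times
#'
#' Closed-form superposition of first-order bolus decays:
#' \eqn{A_1(t) = \sum_{t_j \le t} d_j e^{-K_e (t - t_j)}}.  Exact; no
#' integration is involved.
#'
#' @param doses data frame with columns \code{time} (days) and \code{amount}
#'   (mg); boluses into the virtual depot.
#' @param ke depot elimination rate constant (1/day), positive.
#' @param t vector of evaluation times (days), non-negative.
#' @return depot amounts (mg), same length as \code{t}.
#' @examples
#' depot_amount(data.frame(time = 0, amount = 100), ke = 0.049,
#'              t = log(2) / 0.049) # one half-life: 50 mg
#' @export
depot_amount <- function(doses, ke, t) {
  if (!is.numeric(ke) || length(ke) != 1L || ke <= 0) {
    stop_kpd("ke must be a positive scalar")
  }
  if (any(t < 0)) stop_kpd("evaluation times must be non-negative")
  doses <- check_doses(doses)
  kpd_depot_cpp(as.numeric(t), doses$time, doses$amount, ke)
}

#' Sigmoid Emax stimulation of B-cell degradation
#'
#' \eqn{S(A_1) = E_{max} A_1^\gamma / (A_1^\gamma + ED_{50}^\gamma)}, the
#' fold-stimulation the depot exerts on \code{kout}.  Returns exactly 0 at
#' \code{a1 = 0} and is monotone non-decreasing in \code{a1}, bounded by
#' \code{emax}.
#'
#' @param a1 depot amount(s), mg, non-negative.
#' @param emax maximal fold-stimulation.
#' @param ed50 depot amount at half-maximal stimulation, mg.
#' @param gamma Hill coefficient.
#' @return stimulation multiplier(s), dimensionless.
#' @export
hill_stimulation <- function(a1, emax, ed50, gamma) {
  if (any(a1 < 0)) stop_kpd("depot amount a1 must be non-negative")
  out <- numeric(length(a1))
  pos <- a1 > 0
  # (ed50/a1)^gamma form avoids overflow at large a1
  out[pos] <- emax / (1 + (ed50 / a1[pos])^gamma)
  out
}

#' Simulate a B-cell trajectory under a dosing schedule
#'
#' Integrates \eqn{dE/dt = K_{in} - K_{out}(1 + S(A_1(t)))E} with the depot
#' computed analytically.  The B-cell state starts at the model baseline
#' \code{kin/kout} unless \code{e0} overrides it.  Integration restarts at
#' each dose time; the state is continuous and only the depot jumps.
#'
#' @param params a [kpd_params] object (or coercible named vector).
#' @param doses data frame with \code{time} (days) and \code{amount} (mg).
#' @param times strictly increasing evaluation grid starting at 0 (days).
#'   Defaults to 0.25-day resolution over a year.
#' @param e0 optional initial B-cell count (cells/uL); default
#'   \code{kin/kout}.
#' @param rtol,atol local error tolerances of the adaptive integrator.
#' @return A \code{kpd_trajectory}: data frame with columns \code{time},
#'   \code{depot} and \code{bcell}, carrying the parameters and doses as
#'   attributes so crossings can later be refined by re-integration.
#' @examples
#' p <- kpd_params(0.049, 4.14, 0.007, 389.7, 1.31, 6.65)
#' tr <- simulate_kpd(p, data.frame(time = c(0, 7), amount = 307.5))
#' repletion_time(tr)
#' @export
simulate_kpd <- function(params, doses, times = seq(0, 365, by = 0.25),
                         e0 = NULL, rtol = 1e-8, atol = 1e-10) {
  params <- as_kpd_params(params)
  doses <- check_doses(doses)
  times <- as.numeric(times)
  if (length(times) == 0L || is.unsorted(times, strictly = TRUE) ||
      times[1] < 0) {
    stop_kpd("times must be a strictly increasing grid starting at >= 0")
  }
  if (is.null(e0)) e0 <- kpd_baseline(params)
  bcell <- kpd_solve_cpp(times, as.numeric(params), doses$time, doses$amount,
                         t0 = 0, e0 = e0, rtol = rtol, atol = atol,
                         fixed_h = -1)
  out <- data.frame(time = times,
                    depot = kpd_depot_cpp(times, doses$time, doses$amount,
                                          params[["ke"]]),
                    bcell = bcell)
  structure(out, class = c("kpd_trajectory", "data.frame"),
            params = params, doses = doses, e0 = e0, rtol = rtol, atol = atol)
}

# E(t) at one time, re-integrating from a known state (for root refinement)
.traj_state_at <- function(traj, t) {
  p <- attr(traj, "params")
  d <- attr(traj, "doses")
  i <- findInterval(t, traj$time)
  kpd_solve_cpp(t, as.numeric(p), d$time, d$amount,
                t0 = traj$time[i], e0 = traj$bcell[i],
                rtol = attr(traj, "rtol"), atol = attr(traj, "atol"),
                fixed_h = -1)
}

#' Time of B-cell repletion
#'
#' First time after \code{after} at which the B-cell count rises from below
#' \code{threshold} to at or above it.  The crossing is bracketed on the
#' trajectory grid and refined by bisection to 0.01 day (by re-integration
#' when the trajectory carries its generating parameters, by monotone linear
#' interpolation otherwise).  Returns \code{NA} when the trajectory never
#' falls below the threshold after \code{after} (never-depleted individual).
#'
#' @param traj a \code{kpd_trajectory} from [simulate_kpd()], or any data
#'   frame with \code{time} and \code{bcell} columns.
#' @param threshold repletion threshold, cells/uL; 10 cells/uL (1% of
#'   lymphocytes) is the clinical definition used throughout.
#' @param after search only for crossings after this time (days); defaults to
#'   the last dose time so brief inter-dose rebounds are ignored.
#' @return crossing time in days, or \code{NA_real_}.
#' @export
repletion_time <- function(traj, threshold = 10, after = NULL) {
  if (NROW(traj) == 0L) stop_kpd("empty trajectory")
  if (threshold <= 0) stop_kpd("threshold must be positive")
  if (is.null(after)) {
    d <- attr(traj, "doses")
    after <- if (!is.null(d) && nrow(d)) max(d$time) else traj$time[1]
  }
  tt <- traj$time
  bb <- traj$bcell
  sel <- tt >= after
  if (!any(sel)) return(NA_real_)
  tt <- tt[sel]; bb <- bb[sel]
  below <- bb < threshold
  if (!any(below)) return(NA_real_) # never depleted in the search window
  i0 <- which(below)[1]
  # first upward crossing at or after the first below-threshold point
  idx <- NA_integer_
  if (i0 < length(bb)) {
    for (i in i0:(length(bb) - 1L)) {
      if (bb[i] < threshold && bb[i + 1L] >= threshold) { idx <- i; break }
    }
  }
  if (is.na(idx)) return(NA_real_)
  lo <- tt[idx]; hi <- tt[idx + 1L]
  refine <- !is.null(attr(traj, "params"))
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    val <- if (refine) .traj_state_at(traj, mid) else {
      approx(c(tt[idx], tt[idx + 1L]), c(bb[idx], bb[idx + 1L]), mid)$y
    }
    if (val < threshold) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
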