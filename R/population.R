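#' Residual-error specification
#'
#' Observation model \eqn{y = f (1 + \epsilon_p) + \epsilon_a} with
#' \eqn{\epsilon_p \sim N(0, \sigma_{prop}^2)} and
#' \eqn{\epsilon_a \sim N(0, \sigma_{add}^2)}.  The additive kind drops the
#' proportional term, the proportional kind drops the additive term; the
#' variance at prediction \eqn{f} under the combined model is
#' \eqn{f^2\sigma_{prop}^2 + \sigma_{add}^2}.
#'
#' @param kind one of \code{"combined"}, \code{"additive"},
#'   \code{"proportional"}.
#' @param sd_add additive SD, cells/uL (ignored for kind "proportional").
#' @param sd_prop proportional SD, fraction (ignored for kind "additive").
#' @return a \code{kpd_residual} list.
#' @export
residual_error <- function(kind = c("combined", "additive", "proportional"),
                           sd_add = 0, sd_prop = 0) {
  kind <- match.arg(kind)
  if (sd_add < 0 || sd_prop < 0) stop_kpd("residual SDs must be >= 0")
  if (kind == "additive") sd_prop <- 0
  if (kind == "proportional") sd_add <- 0
  if (kind == "combined" && (sd_add <= 0 || sd_prop <= 0)) {
    stop_kpd("combined residual error requires sd_add > 0 and sd_prop > 0")
  }
  if (kind == "additive" && sd_add <= 0) {
    stop_kpd("additive residual error requires sd_add > 0")
  }
  if (kind == "proportional" && sd_prop <= 0) {
    stop_kpd("proportional residual error requires sd_prop > 0")
  }
  structure(list(kind = kind, sd_add = sd_add, sd_prop = sd_prop),
            class = "kpd_residual")
}

#' Power-law covariate effect on a structural parameter
#'
#' Multiplies the typical value of \code{param} by
#' \eqn{(x / ref)^{\beta}} where \eqn{x} is the subject's covariate value.
#'
#' @param param name of the structural parameter affected (one of
#'   \code{ke, kin, kout, emax, ed50, gamma}).
#' @param covariate covariate column name in the dataset (e.g. \code{"IGA"}).
#' @param beta power exponent.
#' @param ref normalization constant (population median of the covariate);
#'   must be positive.
#' @return a \code{kpd_covariate} list.
#' @export
covariate_effect <- function(param, covariate, beta, ref) {
  if (!param %in% .kpd_param_names) {
    stop_kpd("unknown target parameter '", param, "'")
  }
  if (ref <= 0) stop_kpd("covariate reference must be positive")
  structure(list(param = param, covariate = covariate, beta = beta,
                 ref = ref),
            class = "kpd_covariate")
}

#' Population K-PD model
#'
#' Full probabilistic model: typical structural values, log-normal
#' inter-individual variability (IIV), power-law covariate effects, and a
#' residual-error model.  Individual parameters are
#' \deqn{\theta_i = \theta_{pop} \prod (x_i/x_{ref})^{\beta} e^{\eta_i},
#'   \quad \eta_i \sim N(0, \omega^2),}
#' with independent \eqn{\eta} per parameter.
#'
#' @param typical a [kpd_params] object.
#' @param omega named vector of log-scale IIV standard deviations; names must
#'   be structural parameter names; omitted parameters get \code{omega = 0}
#'   (no IIV).
#' @param covariates list of [covariate_effect()] objects; (parameter,
#'   covariate) pairs must be distinct.
#' @param residual a [residual_error()] object.
#' @return a \code{kpd_model} object.
#' @seealso [kpd_reference_model()] for published estimates.
#' @export
kpd_model <- function(typical, omega = NULL, covariates = list(),
                      residual = residual_error("additive", sd_add = 1)) {
  typical <- as_kpd_params(typical)
  om <- setNames(numeric(6), .kpd_param_names)
  if (!is.null(omega)) {
    if (is.null(names(omega)) || !all(names(omega) %in% .kpd_param_names)) {
      stop_kpd("omega must be named with structural parameter names")
    }
    if (any(omega < 0)) stop_kpd("omega entries must be >= 0")
    om[names(omega)] <- omega
  }
  if (inherits(covariates, "kpd_covariate")) covariates <- list(covariates)
  keys <- vapply(covariates, function(e) paste(e$param, e$covariate),
                 character(1))
  if (anyDuplicated(keys)) {
    stop_kpd("duplicate (parameter, covariate) pairs in covariate effects")
  }
  if (!inherits(residual, "kpd_residual")) {
    stop_kpd("residual must be built with residual_error()")
  }
  structure(list(typical = typical, omega = om, covariates = covariates,
                 residual = residual),
            class = "kpd_model")
}

#' @export
print.kpd_model <- function(x, ...) {
  cat("Population K-PD model\n")
  cat("Typical values:\n")
  print(unclass(x$typical))
  act <- x$omega[x$omega > 0]
  if (length(act)) {
    cat("IIV (omega, SD of log-scale eta):\n")
    print(act)
  } else cat("No inter-individual variability.\n")
  for (e in x$covariates) {
    cat(sprintf("Covariate: %s on %s, beta = %.4g (ref %.4g)\n",
                e$covariate, e$param, e$beta, e$ref))
  }
  cat(sprintf("Residual error: %s (sd_add = %.4g cells/uL, sd_prop = %.4g)\n",
              x$residual$kind, x$residual$sd_add, x$residual$sd_prop))
  invisible(x)
}

#' Reference population model for rituximab in pediatric INS
#'
#' Published population estimates for rituximab-driven CD19+ B-cell
#' depletion in children with idiopathic nephrotic syndrome: Ke 0.049/day,
#' Kin 4.14 cells/uL/day, Kout 0.007/day, Emax 389.7, ED50 1.31 mg, gamma
#' 6.65; baseline IgA (g/L, reference 1.15) acts on ED50 with exponent 1.39;
#' log-normal IIV of 13.4/37.8/24.9/57.8/113.3 percent on
#' Ke/Kin/Kout/Emax/ED50; combined residual error (sd_add 2.56 cells/uL,
#' sd_prop 0.40).  Implied half-lives: depot ln(2)/Ke = 14.1 days, B-cell
#' ln(2)/Kout = 99 days.
#'
#' @return a [kpd_model()] object.
#' @export
kpd_reference_model <- function() {
  kpd_model(
    typical = kpd_params(ke = 0.049, kin = 4.14, kout = 0.007,
                         emax = 389.7, ed50 = 1.31, gamma = 6.65),
    omega = c(ke = 0.134, kin = 0.378, kout = 0.249, emax = 0.578,
              ed50 = 1.133),
    covariates = list(covariate_effect("ed50", "IGA", beta = 1.39,
                                       ref = 1.15)),
    residual = residual_error("combined", sd_add = 2.56, sd_prop = 0.40)
  )
}

# n x 6 matrix of covariate multipliers for given covariate rows
cov_factor_matrix <- function(model, covariates) {
  n <- NROW(covariates)
  fac <- matrix(1, n, 6, dimnames = list(NULL, .kpd_param_names))
  for (e in model$covariates) {
    if (!e$covariate %in% names(covariates)) {
      stop_kpd("missing covariate '", e$covariate, "' required by effect on ",
               e$param, class = "kpd_missing_covariate")
    }
    x <- covariates[[e$covariate]]
    if (any(!is.finite(x)) || any(x <= 0)) {
      stop_kpd("covariate '", e$covariate, "' must be positive and finite")
    }
    fac[, e$param] <- fac[, e$param] * (x / e$ref)^e$beta
  }
  fac
}

#' Individual structural parameters
#'
#' Applies covariate effects and random effects to the typical values:
#' \code{typical * prod((cov/ref)^beta) * exp(eta)} per parameter.
#' Parameters without effects or etas pass through unchanged.
#'
#' @param model a [kpd_model()].
#' @param covariates named list/vector of covariate values (every covariate
#'   referenced by an effect must be present and positive).
#' @param eta named vector of log-scale random effects (missing names = 0).
#' @return a [kpd_params] object.
#' @examples
#' m <- kpd_reference_model()
#' individual_params(m, c(IGA = 1.15)) # typicals recovered at the reference
#' @export
individual_params <- function(model, covariates = NULL, eta = NULL) {
  cov_df <- as.data.frame(as.list(covariates %||% setNames(numeric(0),
                                                           character(0))))
  fac <- cov_factor_matrix(model, cov_df)[1, ]
  ee <- setNames(numeric(6), .kpd_param_names)
  if (!is.null(eta)) {
    if (is.null(names(eta)) || !all(names(eta) %in% .kpd_param_names)) {
      stop_kpd("eta must be named with structural parameter names")
    }
    ee[names(eta)] <- eta
  }
  vals <- as.numeric(model$typical) * fac * exp(ee)
  do.call(kpd_params, as.list(setNames(vals, .kpd_param_names)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample individuals from the population model
#'
#' Draws independent \eqn{\eta \sim N(0, \omega^2)} per parameter and, if a
#' covariate sampler is supplied, covariates per individual.
#'
#' @param model a [kpd_model()].
#' @param n number of individuals (>= 1).
#' @param covariate_sampler \code{NULL}, a function \code{n -> data.frame} of
#'   covariate values, or a data frame/list of fixed covariate values
#'   recycled to all individuals.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return list with \code{covariates} (data frame or NULL), \code{etas}
#'   (n x 6 matrix) and \code{params} (n x 6 matrix of individual values).
#' @export
sample_individuals <- function(model, n, covariate_sampler = NULL,
                               seed = NULL) {
  if (n < 1) stop_kpd("n must be >= 1")
  with_seed(seed, {
    covs <- if (is.function(covariate_sampler)) {
      as.data.frame(covariate_sampler(n))
    } else if (!is.null(covariate_sampler)) {
      as.data.frame(as.list(covariate_sampler))[rep(1L, n), , drop = FALSE]
    } else NULL
    etas <- vapply(.kpd_param_names, function(p) {
      if (model$omega[[p]] > 0) rnorm(n, 0, model$omega[[p]]) else numeric(n)
    }, numeric(n))
    etas <- matrix(etas, nrow = n,
                   dimnames = list(NULL, .kpd_param_names))
    fac <- if (is.null(covs)) matrix(1, n, 6) else
      cov_factor_matrix(model, covs)
    params <- t(as.numeric(model$typical) * t(fac * exp(etas)))
    colnames(params) <- .kpd_param_names
    list(covariates = covs, etas = etas, params = params)
  })
}

#' Apply residual error to a prediction
#'
#' \code{y = pred * (1 + eps_prop) + eps_add} for the combined model; the
#' additive model drops the proportional term and vice versa.  No truncation
#' is applied here: small predictions with noise may yield negative values,
#' and the dataset layer decides any truncation policy.
#'
#' @param pred model prediction(s), cells/uL, non-negative.
#' @param residual a [residual_error()] object.
#' @param eps_prop,eps_add realized error draws (scalars or vectors matching
#'   \code{pred}).
#' @return perturbed observation(s).
#' @export
apply_residual <- function(pred, residual, eps_prop = 0, eps_add = 0) {
  if (any(pred < 0)) stop_kpd("pred must be non-negative")
  if (residual$kind == "additive") eps_prop <- 0
  if (residual$kind == "proportional") eps_add <- 0
  pred * (1 + eps_prop) + eps_add
}

# residual SD at prediction f
residual_sd <- function(residual, f) {
  sqrt(residual$sd_add^2 + (residual$sd_prop * f)^2)
}

# draw residual-perturbed observations at predictions f
draw_residual <- function(residual, f) {
  ep <- if (residual$sd_prop > 0) rnorm(length(f), 0, residual$sd_prop) else 0
  ea <- if (residual$sd_add > 0) rnorm(length(f), 0, residual$sd_add) else 0
  f * (1 + ep) + ea
}
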