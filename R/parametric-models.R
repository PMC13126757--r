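#' Parameters of the Gaussian age-specific incidence curve
#'
#' The incidence rate of the illness-death model is parameterised as a
#' Gaussian function of age,
#' \deqn{i(a) = \beta_1 \exp\left(-\tfrac{1}{2}\left(\frac{a-\beta_2}{\beta_3}\right)^2\right),}
#' where `beta1` is the height of the curve (the peak incidence rate, per
#' person-year), `beta2` the age at which the maximum is attained (years) and
#' `beta3` the width of the curve (years).  In the hypertension application
#' `beta2` is fixed at 87.5 years, the midpoint of the 85–89 age interval in
#' which Danish register data locate the incidence peak.
#'
#' @param beta1 Peak incidence rate, per person-year; must be >= 0.
#' @param beta2 Age of the maximum, years; must lie in \[0, 110\].
#' @param beta3 Width of the curve, years; must be > 0.
#' @return An object of class `incidence_params`.
#' @seealso [incidence_rate()], [mrr_params()]
#' @examples
#' incidence_params(beta1 = 0.076334, beta2 = 87.5, beta3 = 25.33680)
#' @export
incidence_params <- function(beta1, beta2 = 87.5, beta3 = 25) {
  stopifnot(is.numeric(beta1), length(beta1) == 1L, is.finite(beta1),
            is.numeric(beta2), length(beta2) == 1L, is.finite(beta2),
            is.numeric(beta3), length(beta3) == 1L, is.finite(beta3))
  if (beta1 < 0) stop("'beta1' must be non-negative")
  if (beta3 <= 0) stop("'beta3' must be strictly positive")
  if (beta2 < 0 || beta2 > 110) stop("'beta2' must lie in [0, 110] years")
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3),
            class = "incidence_params")
}

#' @export
print.incidence_params <- function(x, ...) {
  cat("Gaussian incidence curve parameters\n")
  cat(sprintf("  beta1 (peak rate, per py): %g\n", x$beta1))
  cat(sprintf("  beta2 (age of maximum, y): %g\n", x$beta2))
  cat(sprintf("  beta3 (width, y):          %g\n", x$beta3))
  invisible(x)
}

#' Parameters of the log-linear mortality rate ratio
#'
#' The mortality rate ratio (MRR) of the illness-death model, the ratio
#' m1/m0 of the mortality of diseased over non-diseased persons, is modelled
#' with a log-linear age course anchored at ages 30 and 100:
#' \deqn{\log MRR(a) = \gamma_1 + \frac{a - 30}{70}(\gamma_2 - \gamma_1).}
#' `gamma1` and `gamma2` are the logarithmised MRR at ages 30 and 100.  The
#' straight-line form follows from the ratio of two Gompertz hazards.  No sign
#' constraint is imposed; a fitted `gamma2` below zero simply means the MRR
#' falls below 1 before age 100.
#'
#' @param gamma1 log MRR at age 30 (dimensionless, finite).
#' @param gamma2 log MRR at age 100 (dimensionless, finite).
#' @return An object of class `mrr_params`.
#' @seealso [log_mrr()], [mrr()]
#' @examples
#' mrr_params(gamma1 = 0.408, gamma2 = -0.0171)
#' @export
mrr_params <- function(gamma1, gamma2) {
  stopifnot(is.numeric(gamma1), length(gamma1) == 1L, is.finite(gamma1),
            is.numeric(gamma2), length(gamma2) == 1L, is.finite(gamma2))
  structure(list(gamma1 = gamma1, gamma2 = gamma2), class = "mrr_params")
}

#' @export
print.mrr_params <- function(x, ...) {
  cat("Log-linear mortality rate ratio parameters\n")
  cat(sprintf("  gamma1 (log MRR at age 30):  %g\n", x$gamma1))
  cat(sprintf("  gamma2 (log MRR at age 100): %g\n", x$gamma2))
  cat(sprintf("  implied MRR(30) = %.4f, MRR(100) = %.4f\n",
              exp(x$gamma1), exp(x$gamma2)))
  invisible(x)
}

#' Gaussian age-specific incidence rate
#'
#' Evaluates the parametric incidence curve \eqn{i(a)} at continuous ages.
#' Ages are real numbers in years; no rounding is applied, because the
#' transport equation of the illness-death model operates on continuous age.
#'
#' @param a Age(s) in years; finite numeric vector.
#' @param params An [incidence_params()] object.
#' @return Incidence rate(s) per person-year, same length as `a`.  The
#'   maximum value `beta1` is attained exactly at `a = beta2` and the curve is
#'   symmetric about `beta2`.
#' @examples
#' p <- incidence_params(0.076334, 87.5, 25.33680)
#' incidence_rate(87.5, p) * 1e4   # peak: 763.34 per 10,000 person-years
#' @export
incidence_rate <- function(a, params) {
  stopifnot(inherits(params, "incidence_params"), is.numeric(a), all(is.finite(a)))
  z <- (a - params$beta2) / params$beta3
  params$beta1 * exp(-0.5 * z^2)
}

#' Log mortality rate ratio at a given age
#'
#' Linear interpolation of the log MRR between its anchor values at ages 30
#' and 100.  Ages outside \[30, 100\] are extrapolated on the same straight
#' line; the forward prevalence solver integrates from age 0, where the
#' extrapolated MRR matters little because prevalence (and hence the
#' mortality split) is near zero at young ages for late-onset diseases.
#'
#' @param a Age(s) in years; finite numeric vector.
#' @param params An [mrr_params()] object.
#' @return log MRR value(s), dimensionless.
#' @examples
#' g <- mrr_params(0.408, -0.0171)
#' log_mrr(c(30, 65, 100), g)
#' @export
log_mrr <- function(a, params) {
  stopifnot(inherits(params, "mrr_params"), is.numeric(a), all(is.finite(a)))
  params$gamma1 + (a - 30) / 70 * (params$gamma2 - params$gamma1)
}

#' Mortality rate ratio at a given age
#'
#' `exp(log_mrr(a, params))`; strictly positive, and monotone decreasing in
#' age exactly when `gamma2 < gamma1`.
#'
#' @inheritParams log_mrr
#' @return MRR value(s), dimensionless.
#' @examples
#' mrr(30, mrr_params(0.408, -0.0171))   # exp(0.408) ~ 1.504
#' @export
mrr <- function(a, params) {
  exp(log_mrr(a, params))
}
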