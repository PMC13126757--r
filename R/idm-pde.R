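#' Split all-cause mortality into state-specific rates
#'
#' In the illness-death model the population hazard is the prevalence-
#' weighted mix \eqn{m = p\,m_1 + (1-p)\,m_0} and the mortality rate ratio is
#' \eqn{MRR = m_1/m_0}.  Given `p`, `m` and `mrr`, the two constraints are
#' linear in \eqn{(m_0, m_1)} and solve to
#' \deqn{m_0 = \frac{m}{1 + p\,(MRR - 1)}, \qquad m_1 = MRR \cdot m_0.}
#'
#' @param p Prevalence proportion(s) in \[0, 1).
#' @param m All-cause mortality rate(s), per person-year, >= 0.
#' @param mrr Mortality rate ratio(s), > 0.
#' @return A list with components `m0` (mortality of the non-diseased) and
#'   `m1` (mortality of the diseased).  The reconstruction
#'   `p*m1 + (1-p)*m0` equals `m` to near machine precision.
#' @examples
#' split_mortality(p = 0.5, m = 0.02, mrr = 2)
#' @export
split_mortality <- function(p, m, mrr) {
  stopifnot(is.numeric(p), is.numeric(m), is.numeric(mrr))
  if (any(p < 0 | p >= 1)) stop("prevalence must lie in [0, 1)")
  if (any(m < 0)) stop("all-cause mortality must be non-negative")
  if (any(mrr <= 0)) stop("mortality rate ratio must be strictly positive")
  denom <- 1 + p * (mrr - 1)
  if (any(denom <= 0)) stop("invalid mortality split: 1 + p*(mrr-1) <= 0")
  m0 <- m / denom
  list(m0 = m0, m1 = mrr * m0)
}

#' Rate of change of prevalence along a characteristic
#'
#' The transport equation of the illness-death model,
#' \deqn{\left(\partial_t + \partial_a\right) p = (1-p)\,[\,i - p\,(m_1 - m_0)\,],}
#' reduces along the characteristic lines a - t = const to an ordinary
#' derivative in age.  Under the no-calendar-trend assumption used throughout
#' this package the returned value is dp/da.
#'
#' @param a Age in years (unused by the autonomous right-hand side; kept for
#'   signature clarity).
#' @param p Prevalence proportion(s) in \[0, 1).
#' @param i Incidence rate(s), per person-year.
#' @param m0,m1 State-specific mortality rates, per person-year.
#' @return dp per year.
#' @export
prevalence_derivative <- function(a, p, i, m0, m1) {
  if (any(p < 0 | p >= 1)) stop("prevalence must lie in [0, 1)")
  (1 - p) * (i - p * (m1 - m0))
}

# RHS expressed in the fitted quantities: all-cause m and the MRR.
# m1 - m0 = m0*(mrr-1) with m0 = m / (1 + p*(mrr-1)).
.prev_rhs <- function(p, i, m, R) {
  (1 - p) * (i - p * m * (R - 1) / (1 + p * (R - 1)))
}

#' Forward prevalence solver of the illness-death model
#'
#' Integrates the prevalence ODE along the age characteristic from the
#' boundary condition p(0) = 0 with a classical fixed-step fourth-order
#' Runge-Kutta scheme.  At every stage the mortality split is recomputed from
#' the current prevalence via the all-cause hazard and the MRR, so the
#' feedback of prevalence on the mortality decomposition is honoured exactly
#' in the right-hand side.
#'
#' @param inc An [incidence_params()] object.
#' @param mrrp An [mrr_params()] object.
#' @param hazard All-cause mortality as accepted by [as_hazard()].
#' @param age_grid Uniform, strictly increasing age grid starting at 0; step
#'   must be <= 0.1 year (default `seq(0, 110, by = 0.05)`).
#' @param t_ref Calendar time the curve refers to (metadata; default 2013.5).
#' @return A `prevalence_curve`: data frame with columns `age` and `p`, and
#'   attribute `t_ref`.
#' @examples
#' p <- solve_prevalence(incidence_params(0.076334, 87.5, 25.3368),
#'                       mrr_params(0.408, -0.0171),
#'                       gompertz_params(-11.117, 0.1034))
#' @export
solve_prevalence <- function(inc, mrrp, hazard,
                             age_grid = seq(0, 110, by = 0.05),
                             t_ref = 2013.5) {
  stopifnot(inherits(inc, "incidence_params"), inherits(mrrp, "mrr_params"))
  n <- length(age_grid)
  stopifnot(n >= 2L, age_grid[1] == 0)
  h <- diff(age_grid)
  if (max(h) - min(h) > 1e-10 * max(h)) stop("age grid must be uniform")
  h <- h[1]
  if (h > 0.1 + 1e-12) stop("age grid step must be <= 0.1 year")
  haz <- as_hazard(hazard)

  mid <- age_grid[-n] + h / 2
  i_n <- incidence_rate(age_grid, inc);  i_m <- incidence_rate(mid, inc)
  m_n <- haz(age_grid);                  m_m <- haz(mid)
  if (any(m_n < 0) || any(m_m < 0)) stop("hazard must be non-negative")
  R_n <- mrr(age_grid, mrrp);            R_m <- mrr(mid, mrrp)

  p <- .rk4_prevalence(h, i_n, i_m, m_n, m_m, R_n, R_m)
  structure(data.frame(age = age_grid, p = p),
            class = c("prevalence_curve", "data.frame"), t_ref = t_ref)
}

#' @export
print.prevalence_curve <- function(x, ...) {
  cat(sprintf("Prevalence curve at t = %.1f (%d grid points, ages %g-%g)\n",
              attr(x, "t_ref"), nrow(x), min(x$age), max(x$age)))
  NextMethod()
}

#' Write / read a prevalence curve as CSV
#'
#' @param curve A `prevalence_curve`.
#' @param path File path.
#' @return `path` invisibly (writer); a `prevalence_curve` (reader).
#' @export
write_prevalence_curve <- function(curve, path) {
  stopifnot(inherits(curve, "prevalence_curve"))
  utils::write.csv(data.frame(age = curve$age, p = curve$p), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Incidence rate from prevalence via the inverted transport equation
#'
#' Inverts the illness-death transport equation for the incidence:
#' \deqn{i = \frac{dp}{1-p} + m \cdot \frac{p\,(MRR-1)}{1 + p\,(MRR-1)},}
#' where `dp` is the derivative of prevalence along the characteristic
#' (dp/da under no calendar trend).  With `mrr = 1` this reduces exactly to
#' `dp / (1 - p)`.
#'
#' @param p Prevalence proportion(s) in \[0, 1); `p = 1` is a singularity.
#' @param dp Derivative(s) of prevalence along the characteristic, per year.
#' @param m All-cause mortality rate(s), per person-year.
#' @param mrr Mortality rate ratio(s), > 0.
#' @return Incidence rate(s) per person-year.
#' @examples
#' invert_incidence(p = 0.5, dp = 0.01, m = 0.02, mrr = 2)
#' @export
invert_incidence <- function(p, dp, m, mrr) {
  if (any(p >= 1)) stop("prevalence p = 1 is a singularity of the inversion")
  if (any(p < 0)) stop("prevalence must lie in [0, 1)")
  if (any(mrr <= 0)) stop("mortality rate ratio must be strictly positive")
  dp / (1 - p) + m * p * (mrr - 1) / (1 + p * (mrr - 1))
}

#' Incidence along a solved prevalence curve
#'
#' Convenience round trip: applies [invert_incidence()] to a solved
#' prevalence curve using the analytic right-hand side of the ODE for dp/da
#' (not finite differences), an all-cause hazard and an MRR model.
#'
#' @param curve A `prevalence_curve`.
#' @param hazard As accepted by [as_hazard()].
#' @param mrrp An [mrr_params()] object.
#' @param inc An [incidence_params()] object supplying the incidence used in
#'   the analytic derivative.
#' @return Data frame with columns `age` and `incidence` (per person-year).
#' @keywords internal
#' @export
incidence_from_curve <- function(curve, hazard, mrrp, inc) {
  stopifnot(inherits(curve, "prevalence_curve"))
  haz <- as_hazard(hazard)
  m <- haz(curve$age)
  R <- mrr(curve$age, mrrp)
  i <- incidence_rate(curve$age, inc)
  dp <- .prev_rhs(curve$p, i, m, R)
  data.frame(age = curve$age,
             incidence = invert_incidence(curve$p, dp, m, R))
}
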